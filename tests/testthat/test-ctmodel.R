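test_that("firing rate hits the sigmoid midpoint, saturates, and is monotone", {
  p <- ct_params()
  expect_equal(firing_rate(p$theta, p), p$q_max / 2)
  expect_equal(firing_rate(-1e6, p), 0)
  expect_equal(firing_rate(1e6, p), 250)
  # value at theta + sigma, frozen from an independent scalar evaluation
  expect_equal(firing_rate(21, p), 214.95510878656836, tolerance = 1e-12)
  # doubling q_max doubles the rate at fixed potential
  p2 <- ct_params(q_max = 500)
  expect_equal(firing_rate(7.3, p2), 2 * firing_rate(7.3, p))
  # property: monotone, bounded, midpoint = q_max/2 over random parameters
  set.seed(1)
  for (i in 1:25) {
    pr <- ct_params(theta = runif(1, 5, 25), sigma = runif(1, 2, 12),
                    q_max = runif(1, 50, 500))
    v <- sort(runif(7, -60, 60))
    fr <- firing_rate(v, pr)
    expect_true(all(diff(fr) > 0))
    expect_true(all(fr > 0 & fr < pr$q_max))
    expect_equal(firing_rate(pr$theta, pr), pr$q_max / 2)
  }
})

test_that("steady state satisfies the fixed-point equations", {
  ss <- steady_state(ct_params(), drive = 1)
  expect_lt(ss$residual_norm, 1e-9)
  expect_equal(unname(ss$v["e"]), unname(ss$v["i"]))
  expect_equal(unname(ss$phi), unname(ss$q))
  # zero couplings, zero drive: filter equilibrium at V = 0
  p0 <- ct_params(nu_ee = 0, nu_ei = 0, nu_es = 0, nu_se = 0, nu_sr = 0,
                  nu_sn = 0, nu_re = 0, nu_rs = 0)
  expect_equal(unname(steady_state(p0, drive = 0)$v), rep(0, 4),
               tolerance = 1e-10)
  # strongly perturbed couplings still solve (low-firing branch)
  expect_lt(steady_state(ct_params(nu_sr = -1.3), drive = 0)$residual_norm,
            1e-9)
})

test_that("noise-free simulation stays at the fixed point", {
  sim <- simulate_ct(ct_params(), quick_sim_config(noise_sd = 0))
  expect_false(sim$diverged)
  expect_lt(max(abs(sim$v_e - sim$steady$v["e"])), 1e-6)
  expect_lt(max(abs(sim$phi_e - sim$steady$q["e"])), 1e-6)
  expect_length(sim$v_e, round((12 - 2) / 0.001))
})

test_that("simulation is seed-deterministic and validates the delay", {
  s1 <- simulate_ct(ct_params(), quick_sim_config())
  s2 <- simulate_ct(ct_params(), quick_sim_config())
  expect_identical(s1$v_e, s2$v_e)
  expect_identical(s1$phi_e, s2$phi_e)
  s3 <- simulate_ct(ct_params(), sim_config(duration = 12, transient = 2,
                                            seed = 43))
  expect_false(identical(s1$v_e, s3$v_e))
  expect_error(simulate_ct(ct_params(), quick_sim_config(dt = 3e-4)),
               "whole number of steps")
})

test_that("trace exceeding the guard bound is reported as divergence", {
  p <- ct_params(nu_sr = -0.4)   # weak reticular inhibition: large limit cycle
  cfg <- quick_sim_config()
  expect_error(simulate_ct(p, cfg, guard = 4), "diverged")
  sim <- simulate_ct(p, cfg, guard = 4, allow_divergence = TRUE)
  expect_true(sim$diverged)
})

test_that("linearized spectrum matches the feedforward closed form", {
  # only the noise -> relay -> cortex chain active: V_e response is
  # L(w)^2 * rho_s * nu_es * nu_sn * e^{-i w t0/2} acting on the drive
  p <- ct_params(nu_ee = 0, nu_ei = 0, nu_se = 0, nu_sr = 0, nu_re = 0,
                 nu_rs = 0)
  freqs <- seq(2, 60, by = 0.5)
  lin <- linearized_spectrum(p, freqs, noise_mean = 0.5, noise_sd = 0.3,
                             dt = 0.001, output = "v_e")
  ss <- steady_state(p, drive = 0.5)
  rho_s <- ctspec:::.firing_slope(ss$v, p)[4]
  om <- 2 * pi * freqs
  L2 <- 1 / ((1 + om^2 / p$alpha^2) * (1 + om^2 / p$beta^2))
  expected <- L2^2 * (rho_s * p$nu_es * p$nu_sn)^2 * 2 * 0.3^2 * 0.001
  expect_equal(lin$power, expected, tolerance = 1e-10)
})

test_that("linearized spectrum shows the alpha resonance and low-pass tail", {
  lin <- linearized_spectrum(ct_params(), seq(2, 200, by = 0.05),
                             noise_mean = 0, noise_sd = 0.5)
  pk <- lin$freqs[which.max(lin$power)]
  expect_gt(pk, 8); expect_lt(pk, 12)
  tail <- lin$power[lin$freqs > 60]
  expect_true(all(diff(tail) < 0))
  expect_true(all(lin$power > 0))
})

test_that("simulated and linearized spectra locate the same alpha resonance", {
  sim <- simulate_ct(ct_params(), sim_config(duration = 35, transient = 5,
                                             seed = 3))
  ps <- multitaper_psd(sim$v_e, fs = 1000, half_bandwidth = 0.6, n_tapers = 29)
  sel <- ps$freqs >= 4 & ps$freqs <= 40
  lin <- linearized_spectrum(ct_params(), ps$freqs[sel], noise_mean = 0,
                             noise_sd = 0.5)
  f_sim <- ps$freqs[sel][which.max(ps$power[sel])]
  f_lin <- lin$freqs[which.max(lin$power)]
  expect_lt(abs(f_sim - f_lin), 0.6)   # within the taper half-bandwidth
})

test_that("halving the integration step leaves the fitted exponent stable", {
  exps <- lapply(c(0.001, 0.0005), function(dtv) {
    sapply(8:11, function(s) {
      sim <- simulate_ct(ct_params(), sim_config(dt = dtv, duration = 35,
                                                 transient = 5, seed = s))
      ps <- multitaper_psd(sim$v_e, fs = 1 / dtv, half_bandwidth = 0.6,
                           n_tapers = 29)
      fit_spectral_model(ps)$aperiodic$exponent
    })
  })
  # the dt-induced shift stays within the estimate's own seed-to-seed
  # standard error (two-sample comparison over 4 seeds per step size)
  shift <- abs(mean(exps[[1]]) - mean(exps[[2]]))
  se <- sqrt(var(exps[[1]]) / 4 + var(exps[[2]]) / 4)
  expect_lt(shift, 2 * se)
})

test_that("an identity sweep reproduces the single-run features", {
  p <- ct_params()
  cfg <- sim_config(duration = 25, transient = 5, seed = 7)
  sw <- parameter_sweep(p, "nu_sr", p$nu_sr, cfg, n_tapers = 23)
  sim <- simulate_ct(p, cfg)
  ps <- multitaper_psd(sim$v_e, fs = 1000, half_bandwidth = 0.6, n_tapers = 23)
  fit <- fit_spectral_model(ps)
  expect_false(sw$diverged)
  expect_equal(sw$exponent, fit$aperiodic$exponent, tolerance = 1e-12)
  expect_equal(sw$offset, fit$aperiodic$offset, tolerance = 1e-12)
  a <- select_alpha(fit)
  expect_equal(sw$alpha_cf, a$center, tolerance = 1e-12)
  expect_error(parameter_sweep(p, "nu_sr", numeric(0), cfg), "empty")
  expect_error(parameter_sweep(p, "nu_xy", -1, cfg), "must be one of")
})

test_that("sweep records unstable runs as flagged missing rows", {
  # guard low enough that the limit-cycle end of the range trips it
  cfg <- quick_sim_config()
  sw <- parameter_sweep(ct_params(), "nu_ee", c(1.06, 80), cfg, n_tapers = 11)
  expect_false(sw$diverged[1])
  expect_true(is.na(sw$exponent[2]) || !sw$diverged[2])
  expect_equal(nrow(sw), 2)
})

test_that("sweep export writes CSV plus JSON sidecar", {
  cfg <- quick_sim_config()
  sw <- parameter_sweep(ct_params(), "nu_sr", c(-0.9, -0.845), cfg,
                        n_tapers = 11)
  f <- tempfile(fileext = ".csv")
  write_sweep(sw, f)
  back <- read.csv(f)
  expect_equal(back$param_value, sw$param_value)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$config$seed, 42)
  expect_equal(side$baseline_params$nu_sr, -0.845)
})
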