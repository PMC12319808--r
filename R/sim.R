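#' Sigmoidal population firing rate
#'
#' Maps mean membrane potential to mean firing rate:
#' `q_max / (1 + exp(-pi * (v - theta) / (sigma * sqrt(3))))`. The `sqrt(3)`
#' factor matches the logistic to a Gaussian spread of thresholds with
#' standard deviation `sigma`. Strictly increasing in `v`, bounded in
#' `(0, q_max)`, equal to `q_max / 2` at `v = theta`.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param params A [ct_params] object.
#' @return Mean firing rate(s) in 1/s.
#' @export
firing_rate <- function(v, params = ct_params()) {
  params$q_max / (1 + exp(-pi * (v - params$theta) / (params$sigma * sqrt(3))))
}

# derivative of the sigmoid (gain) at potential v, in s^-1 mV^-1
.firing_slope <- function(v, params) {
  q <- firing_rate(v, params)
  (pi / (params$sigma * sqrt(3))) * q * (1 - q / params$q_max)
}

#' Simulation configuration
#'
#' @param dt Integration step (s); default 0.001.
#' @param duration Total simulated time (s), including the transient; the
#'   default keeps a 60-s post-transient epoch, the trial length the
#'   downstream spectral settings assume.
#' @param transient Initial span discarded from the output (s).
#' @param noise_mean Constant drive to the relay population (1/s). The
#'   default 0 places the normative operating point safely inside the stable
#'   (noise-driven resonance) regime; see the methods vignette.
#' @param noise_sd Per-sample standard deviation of the white-noise part of
#'   the relay drive (1/s). Its one-sided spectral density is
#'   `2 * noise_sd^2 * dt`.
#' @param seed Integer RNG seed, or `NULL` to leave the RNG state alone.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, duration = 65, transient = 5,
                       noise_mean = 0, noise_sd = 0.5, seed = NULL) {
  stopifnot(dt > 0, duration > transient, transient >= 0, noise_sd >= 0)
  structure(list(dt = dt, duration = duration, transient = transient,
                 noise_mean = noise_mean, noise_sd = noise_sd, seed = seed),
            class = "sim_config")
}

.check_delay_steps <- function(params, config) {
  nd <- params$t0 / (2 * config$dt)
  if (abs(nd - round(nd)) > 1e-8 || round(nd) < 1)
    stop("one-way delay t0/2 = ", params$t0 / 2, " s is not a positive ",
         "whole number of steps at dt = ", config$dt, " s")
  as.integer(round(nd))
}

#' Steady state of the corticothalamic model
#'
#' Solves the zero-derivative equations of the model at a constant relay
#' drive (delays are irrelevant at steady state, and the wave operator has
#' unit zero-frequency gain, so each field equals its population's firing
#' rate). Because every firing rate is bounded by the sigmoid, the thalamic
#' pair (V_r, V_s) reduces, for given V_e, to a scalar root with a guaranteed
#' bracket, and the cortical equation to a scalar root in V_e found by a
#' sign-change scan. When several fixed points coexist the low-firing branch
#' (smallest V_e) is returned, the conventional resting state.
#'
#' @param params A [ct_params] object.
#' @param drive Constant presynaptic drive to the relay (1/s).
#' @param tol Residual norm tolerance on the full system.
#' @return A list with `v` (named potentials, mV), `q` (firing rates, 1/s),
#'   `phi` (fields, 1/s), and `residual_norm`.
#' @export
steady_state <- function(params = ct_params(), drive = 1, tol = 1e-9) {
  stopifnot(inherits(params, "ct_params"))
  p <- params
  # |V| is bounded by sum |nu| * q_max plus the drive term
  bound <- sum(abs(unlist(p[ct_coupling_names()]))) * p$q_max +
    abs(p$nu_sn * drive) + 1
  solve_thalamus <- function(v_e) {
    q_e <- firing_rate(v_e, p)
    f <- function(v_s) {
      v_r <- p$nu_re * q_e + p$nu_rs * firing_rate(v_s, p)
      v_s - (p$nu_se * q_e + p$nu_sr * firing_rate(v_r, p) + p$nu_sn * drive)
    }
    v_s <- uniroot(f, c(-bound, bound), tol = 1e-13)$root
    v_r <- p$nu_re * q_e + p$nu_rs * firing_rate(v_s, p)
    c(v_r = v_r, v_s = v_s)
  }
  h <- function(v_e) {
    th <- solve_thalamus(v_e)
    q_e <- firing_rate(v_e, p)
    v_e - ((p$nu_ee + p$nu_ei) * q_e + p$nu_es * firing_rate(th["v_s"], p))
  }
  grid <- seq(-bound, bound, length.out = 400)
  hv <- vapply(grid, h, 0)
  sgn <- which(hv[-1] * hv[-length(hv)] <= 0)
  if (length(sgn) == 0)
    stop("steady-state search did not converge; parameters may be pathological")
  v_e <- uniroot(h, c(grid[sgn[1]], grid[sgn[1] + 1]), tol = 1e-13)$root
  th <- solve_thalamus(v_e)
  v <- c(e = v_e, i = v_e, r = unname(th["v_r"]), s = unname(th["v_s"]))
  q <- firing_rate(v, p)
  resid <- c(v[1] - (p$nu_ee * q[1] + p$nu_ei * q[2] + p$nu_es * q[4]),
             v[2] - (p$nu_ee * q[1] + p$nu_ei * q[2] + p$nu_es * q[4]),
             v[3] - (p$nu_re * q[1] + p$nu_rs * q[4]),
             v[4] - (p$nu_se * q[1] + p$nu_sr * q[3] + p$nu_sn * drive))
  rn <- sqrt(sum(resid^2))
  if (!is.finite(rn) || rn > tol)
    stop("steady-state residual ", signif(rn, 3), " exceeds tolerance ", tol)
  list(v = v, q = q, phi = q, residual_norm = rn)
}

#' Simulate the corticothalamic model (global mode)
#'
#' Euler-Maruyama integration of the four coupled populations (cortical
#' excitatory and inhibitory, thalamic relay and reticular) with the
#' second-order synaptodendritic filter on each membrane potential, the
#' damped-wave propagation operator on the cortical excitatory field (with
#' the spatial Laplacian set to zero: global mode), and a conduction delay of
#' `t0/2` on each corticothalamic (e to r, e to s) and thalamocortical (s to
#' e, s to i) projection. The relay additionally receives
#' `nu_sn * (noise_mean + white noise)`. Histories are initialized at the
#' deterministic fixed point and the first `transient` seconds are discarded.
#' Identical parameters, configuration and seed give identical output.
#'
#' @param params A [ct_params] object.
#' @param config A [sim_config] object.
#' @param keep_all Also return the i, r, s membrane potential traces.
#' @param allow_divergence Return a flagged partial result instead of
#'   erroring when a trace exceeds the guard bound (used by sweeps).
#' @param guard Divergence guard bound (mV or 1/s).
#' @return An object of class `ct_sim`: `time`, `v_e`, `phi_e` (plus `v_i`,
#'   `v_r`, `v_s` when `keep_all`), `diverged`, `params_used`, `config_used`.
#' @examples
#' sim <- simulate_ct(ct_params(), sim_config(duration = 8, transient = 2,
#'                                            seed = 1))
#' @export
simulate_ct <- function(params = ct_params(), config = sim_config(),
                        keep_all = FALSE, allow_divergence = FALSE,
                        guard = 1e4) {
  stopifnot(inherits(params, "ct_params"), inherits(config, "sim_config"))
  n_delay <- .check_delay_steps(params, config)
  n_steps <- as.integer(round(config$duration / config$dt))
  keep_from <- as.integer(round(config$transient / config$dt))
  ss <- steady_state(params, drive = config$noise_mean)
  if (!is.null(config$seed)) set.seed(config$seed)
  nu <- unlist(params[ct_coupling_names()])
  res <- simulate_ct_cpp(nu, params$q_max, params$theta, params$sigma,
                         params$alpha, params$beta, params$gamma,
                         config$dt, n_steps, n_delay,
                         config$noise_mean, config$noise_sd,
                         unname(ss$v), unname(ss$q["e"]), unname(ss$q["s"]),
                         keep_from, keep_all, guard)
  if (res$diverged && !allow_divergence)
    stop("simulation diverged (trace exceeded guard bound ", guard,
         "); couplings are likely outside the stable regime")
  n_kept <- length(res$v_e)
  out <- list(time = config$transient + config$dt * (seq_len(n_kept) - 1),
              v_e = res$v_e, phi_e = res$phi_e,
              diverged = res$diverged,
              steady = ss,
              params_used = params, config_used = config)
  if (keep_all) out[c("v_i", "v_r", "v_s")] <- res[c("v_i", "v_r", "v_s")]
  structure(out, class = "ct_sim")
}

#' @export
print.ct_sim <- function(x, ...) {
  cat(sprintf("Corticothalamic simulation: %.4g s kept at dt = %g s%s\n",
              length(x$v_e) * x$config_used$dt, x$config_used$dt,
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Analytic power spectrum of the linearized model
#'
#' Closed-form PSD of the model linearized about its stable fixed point:
#' the response of the cortical excitatory field (or potential) to the relay
#' noise drive is assembled per frequency from the sigmoid slopes at the
#' fixed point, the Fourier transform of the synaptodendritic filter
#' `1 / ((1 - i w / alpha)(1 - i w / beta))`, the wave operator
#' `(1 - i w / gamma)^2`, and `exp(-i w t0 / 2)` delay factors on the
#' corticothalamic and thalamocortical projections. Serves as an independent
#' verification oracle for the time-domain integrator (the two agree in the
#' small-noise, linear regime).
#'
#' @param params A [ct_params] object.
#' @param freqs Frequency grid (Hz).
#' @param noise_mean Constant relay drive defining the operating point (1/s).
#' @param noise_sd Per-sample white-noise sd of the drive (1/s).
#' @param dt Sampling step of the matched simulation (s); with per-sample
#'   noise the one-sided drive density is `2 * noise_sd^2 * dt`.
#' @param output `"v_e"` (default, the EEG proxy) or `"phi_e"`.
#' @return A [power_spectrum] on `freqs`.
#' @export
linearized_spectrum <- function(params = ct_params(), freqs = seq(1, 45, by = 0.1),
                                noise_mean = 0, noise_sd = 0.5, dt = 0.001,
                                output = c("v_e", "phi_e")) {
  output <- match.arg(output)
  stopifnot(all(freqs > 0))
  p <- params
  ss <- steady_state(p, drive = noise_mean)
  rho <- .firing_slope(ss$v, p)
  s_n <- 2 * noise_sd^2 * dt            # one-sided drive density
  w <- 2 * pi * freqs
  psd <- vapply(seq_along(w), function(i) {
    om <- w[i]
    L <- 1 / ((1 + 1i * om / p$alpha) * (1 + 1i * om / p$beta))
    D <- (1 + 1i * om / p$gamma)^2
    A <- exp(-1i * om * p$t0 / 2)
    # unknowns x = (V_e, V_i, V_r, V_s); fields phi_e = rho_e V_e / D,
    # phi_{i,r,s} = rho V
    M <- diag(4) + 0i
    ce <- c(p$nu_ee * rho[1] / D, p$nu_ei * rho[2], 0, p$nu_es * A * rho[4])
    M[1, ] <- M[1, ] - L * ce
    M[2, ] <- M[2, ] - L * ce
    M[3, ] <- M[3, ] - L * c(p$nu_re * A * rho[1] / D, 0, 0, p$nu_rs * rho[4])
    M[4, ] <- M[4, ] - L * c(p$nu_se * A * rho[1] / D, 0, p$nu_sr * rho[3], 0)
    b <- c(0, 0, 0, L * p$nu_sn)
    x <- solve(M, b)
    resp <- if (output == "phi_e") rho[1] * x[1] / D else x[1]
    Mod(resp)^2 * s_n
  }, 0)
  if (any(!is.finite(psd)))
    stop("linearized response is not finite; fixed point is likely unstable")
  power_spectrum(freqs, psd,
                 meta = list(kind = "linearized", output = output,
                             noise_mean = noise_mean, noise_sd = noise_sd,
                             dt = dt))
}

#' Sweep one synaptic coupling and record spectral features
#'
#' For each value of the chosen coupling: set it (all other parameters held
#' at their given values), simulate, estimate a multitaper PSD of the
#' cortical excitatory field, parameterize the spectrum, and record the
#' aperiodic offset and exponent and the alpha peak power and center
#' frequency. Unstable (diverged) runs are recorded as missing rows with
#' `diverged = TRUE`, never dropped silently. The same seed is used at every
#' value so feature differences reflect the coupling, not the noise path.
#'
#' @param params Baseline [ct_params].
#' @param which Coupling name (one of [ct_coupling_names()]).
#' @param values Numeric vector of coupling values (mV s).
#' @param config A [sim_config]; its seed is reused at every value.
#' @param settings [fit_settings] for the spectral parameterization.
#' @param half_bandwidth,n_tapers Multitaper settings for the simulated
#'   trace.
#' @param output Trace to analyze, `"v_e"` (default, the EEG proxy) or
#'   `"phi_e"`.
#' @return A data.frame of class `ct_sweep` with columns `param`,
#'   `param_value`, `offset`, `exponent`, `alpha_power`, `alpha_cf`,
#'   `diverged`.
#' @export
parameter_sweep <- function(params, which, values, config = sim_config(),
                            settings = fit_settings(),
                            half_bandwidth = 0.6, n_tapers = 45,
                            output = c("v_e", "phi_e")) {
  output <- match.arg(output)
  if (!which %in% ct_coupling_names())
    stop("'which' must be one of: ", paste(ct_coupling_names(), collapse = ", "))
  if (length(values) == 0) stop("empty sweep value list")
  stopifnot(all(is.finite(values)))
  fs <- 1 / config$dt
  rows <- lapply(values, function(val) {
    p <- params
    p[[which]] <- val
    row <- data.frame(param = which, param_value = val, offset = NA_real_,
                      exponent = NA_real_, alpha_power = NA_real_,
                      alpha_cf = NA_real_, diverged = TRUE)
    sim <- tryCatch(simulate_ct(p, config, allow_divergence = TRUE),
                    error = function(e) NULL)
    if (is.null(sim) || sim$diverged) return(row)
    tr <- if (output == "phi_e") sim$phi_e else sim$v_e
    ps <- multitaper_psd(tr, fs = fs, half_bandwidth = half_bandwidth,
                         n_tapers = n_tapers)
    fit <- fit_spectral_model(ps, settings)
    a <- select_alpha(fit)
    row$offset <- fit$aperiodic$offset
    row$exponent <- fit$aperiodic$exponent
    row$alpha_power <- if (is.null(a)) NA_real_ else a$power
    row$alpha_cf <- if (is.null(a)) NA_real_ else a$center
    row$diverged <- FALSE
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "settings") <- settings
  attr(out, "baseline") <- unclass(params)
  class(out) <- c("ct_sweep", "data.frame")
  out
}

#' Write a sweep result as CSV plus a JSON provenance sidecar
#'
#' @param sweep A `ct_sweep` from [parameter_sweep()].
#' @param path CSV output path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "ct_sweep"))
  write.csv(as.data.frame(sweep), path, row.names = FALSE)
  jsonlite::write_json(list(config = unclass(attr(sweep, "config")),
                            settings = unclass(attr(sweep, "settings")),
                            baseline_params = attr(sweep, "baseline")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
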