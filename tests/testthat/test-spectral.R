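test_that("detrending removes lines exactly and is idempotent on noise", {
  t <- seq_len(500)
  expect_equal(detrend_epoch(3 + 0.02 * t), rep(0, 500), tolerance = 1e-10)
  x <- sin(2 * pi * t / 50) + 1.5 - 0.01 * t
  d <- detrend_epoch(x)
  refit <- coef(lm(d ~ t))
  expect_lt(abs(refit[2]), 1e-10)
  expect_lt(abs(mean(d)), 1e-10)
  expect_error(detrend_epoch(1), "at least 2")
})

test_that("DPSS tapers are orthonormal and match frozen reference values", {
  z <- dpss_tapers(1000, 4, 8)
  expect_equal(crossprod(z), diag(8), tolerance = 1e-10,
               ignore_attr = TRUE)
  idx <- c(1, 100, 250, 500, 750, 1000)
  # frozen from an independent reference implementation of Slepian sequences
  expect_equal(z[idx, 1],
               c(2.894851e-06, 0.000591487818, 0.012907173612,
                 0.062737147302, 0.013082721331, 2.894851e-06),
               tolerance = 1e-9)
  expect_equal(z[idx, 4],
               c(0.000859044971, 0.022104676634, 0.044846648938,
                 -0.000348360301, -0.044466937362, -0.000859044971),
               tolerance = 1e-9)
  expect_equal(z[idx, 8],
               c(0.064346183544, 0.017043109654, 0.003740542457,
                 -0.00032717382, -0.004481776696, -0.064346183544),
               tolerance = 1e-9)
  # odd length: antisymmetric tapers vanish at the midpoint
  zo <- dpss_tapers(801, 3, 4)
  expect_equal(crossprod(zo), diag(4), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(zo[401, 2], 0)
  expect_equal(zo[401, 4], 0)
})

test_that("multitaper records the time-bandwidth product and enforces bounds", {
  x <- rnorm(60 * 128)
  ps <- multitaper_psd(x, fs = 128, half_bandwidth = 0.6, n_tapers = 45)
  expect_equal(ps$meta$time_bandwidth, 36)
  expect_equal(ps$meta$n_tapers, 45)
  expect_error(multitaper_psd(x, 128, 0.6, n_tapers = 72), "2\\*T\\*W - 1")
  expect_error(multitaper_psd(rnorm(64), 128, 0.6), "below 1")
})

test_that("multitaper concentrates a sinusoid and preserves total power", {
  fs <- 200
  t <- seq(1 / fs, 40, by = 1 / fs)
  x <- sqrt(2) * sin(2 * pi * 10 * t)       # unit variance
  ps <- multitaper_psd(x, fs, half_bandwidth = 0.6, n_tapers = 21)
  df <- ps$freqs[2] - ps$freqs[1]
  total <- sum(ps$power) * df
  in_band <- sum(ps$power[abs(ps$freqs - 10) <= 0.6]) * df
  expect_equal(total, var(x), tolerance = 0.05)
  expect_gt(in_band / total, 0.99)
})

test_that("white noise gives a flat spectrum at the theoretical level", {
  set.seed(2)
  x <- rnorm(40 * 250, sd = 1.7)
  ps <- multitaper_psd(x, 250, half_bandwidth = 0.6, n_tapers = 45)
  expect_equal(median(ps$power), 2 * 1.7^2 / 250, tolerance = 0.05)
  sel <- ps$freqs > 1
  slope <- coef(lm(log10(ps$power[sel]) ~ log10(ps$freqs[sel])))[2]
  expect_lt(abs(slope), 0.05)
  expect_equal(sum(ps$power) * (ps$freqs[2] - ps$freqs[1]), var(x),
               tolerance = 0.05)
})

test_that("aperiodic fit recovers noiseless power laws exactly", {
  ps <- model_spectrum(offset = 2, exponent = 1.5)
  ap <- fit_aperiodic(ps)
  expect_equal(ap$offset, 2, tolerance = 1e-6)
  expect_equal(ap$exponent, 1.5, tolerance = 1e-6)
  flat <- model_spectrum(offset = 0.7, exponent = 0)
  expect_equal(fit_aperiodic(flat)$exponent, 0, tolerance = 1e-8)
  few <- power_spectrum(c(5, 6), c(1, 0.9))
  expect_error(fit_spectral_model(few), "fewer than 3")
})

test_that("robust aperiodic fit beats a naive full-bin fit under a peak", {
  ps <- model_spectrum(offset = 2, exponent = 1.5,
                       peaks = list(list(power = 0.8, center = 10,
                                         width = 1.5)))
  sel <- ps$freqs >= 4 & ps$freqs <= 40
  naive <- coef(lm(log10(ps$power[sel]) ~ log10(ps$freqs[sel])))
  naive_err <- abs(naive[1] - 2) + abs(-naive[2] - 1.5)
  ap <- fit_aperiodic(ps)
  robust_err <- abs(ap$offset - 2) + abs(ap$exponent - 1.5)
  expect_lt(robust_err, naive_err)
  expect_lt(abs(ap$exponent - 1.5), 0.1)
})

test_that("peak extraction recovers known Gaussians in height order", {
  freqs <- seq(4, 40, by = 0.05)
  set.seed(4)
  resid1 <- 0.6 * exp(-(freqs - 10)^2 / (2 * 1.2^2)) + rnorm(length(freqs), 0, 0.01)
  pk <- extract_peaks(resid1, freqs)
  big <- Filter(function(p) p$power > 0.1, pk)
  expect_length(big, 1)
  expect_lt(abs(big[[1]]$center - 10), 0.1)
  expect_lt(abs(big[[1]]$power - 0.6), 0.05)
  # any further detections sit at the noise scale
  expect_true(all(vapply(pk[-1], `[[`, 0, "power") < 0.1))
  resid2 <- 0.5 * exp(-(freqs - 9)^2 / (2 * 1)) +
    0.9 * exp(-(freqs - 22)^2 / (2 * 1.5^2)) + rnorm(length(freqs), 0, 0.01)
  pk2 <- extract_peaks(resid2, freqs)
  big2 <- Filter(function(p) p$power > 0.1, pk2)
  expect_length(big2, 2)
  # extraction order: decreasing height
  expect_lt(abs(big2[[1]]$center - 22), 0.2)
  expect_lt(abs(big2[[2]]$center - 9), 0.2)
  expect_gt(big2[[1]]$power, big2[[2]]$power)
})

test_that("structureless residuals never produce large phantom peaks", {
  freqs <- seq(4, 40, by = 0.5)
  set.seed(6)
  heights <- unlist(lapply(1:40, function(i) {
    vapply(extract_peaks(rnorm(length(freqs), 0, 0.05), freqs),
           `[[`, 0, "power")
  }))
  # detections on pure noise exist but stay at the noise scale
  if (length(heights) > 0) expect_lt(max(heights), 5 * 0.05)
  expect_length(extract_peaks(rep(0, length(freqs)), freqs), 0)
})

test_that("full spectral model recovers noiseless parameters to 1e-2", {
  truth <- list(power = 0.6, center = 10, width = 1.2)
  ps <- model_spectrum(offset = 2, exponent = 1.5, peaks = list(truth))
  fit <- fit_spectral_model(ps)
  expect_equal(fit$aperiodic$offset, 2, tolerance = 1e-2)
  expect_equal(fit$aperiodic$exponent, 1.5, tolerance = 1e-2)
  a <- select_alpha(fit)
  expect_equal(a$center, 10, tolerance = 1e-2)
  expect_equal(a$power, 0.6, tolerance = 1e-2)
  expect_equal(a$width, 1.2, tolerance = 1e-2)
  expect_gt(fit$r_squared, 0.999)
})

test_that("peak-free spectra yield an aperiodic-only reconstruction", {
  ps <- model_spectrum(offset = 1.2, exponent = 2.2)
  fit <- fit_spectral_model(ps)
  expect_length(fit$peaks, 0)
  ap_only <- fit$aperiodic$offset - fit$aperiodic$exponent * log10(fit$freqs)
  expect_equal(fit$model, ap_only, tolerance = 1e-12)
})

test_that("reconstruction identity: stored error matches the stored model", {
  ps <- model_spectrum(peaks = list(list(power = 0.5, center = 11,
                                         width = 1.5)))
  fit <- fit_spectral_model(ps)
  recon <- fit$aperiodic$offset - fit$aperiodic$exponent * log10(fit$freqs)
  for (p in fit$peaks)
    recon <- recon + p$power * exp(-(fit$freqs - p$center)^2 / (2 * p$width^2))
  expect_equal(recon, fit$model, tolerance = 1e-12)
  expect_equal(mean(abs(fit$data - fit$model)), fit$error, tolerance = 1e-12)
  expect_equal(cor(fit$data, fit$model)^2, fit$r_squared, tolerance = 1e-12)
})

test_that("scaling a spectrum shifts only the offset", {
  ps <- model_spectrum(offset = 1.8, exponent = 1.2,
                       peaks = list(list(power = 0.5, center = 10,
                                         width = 1.3)))
  f1 <- fit_spectral_model(ps)
  k <- 50
  f2 <- fit_spectral_model(power_spectrum(ps$freqs, k * ps$power))
  expect_equal(f2$aperiodic$offset - f1$aperiodic$offset, log10(k),
               tolerance = 1e-6)
  expect_equal(f2$aperiodic$exponent, f1$aperiodic$exponent, tolerance = 1e-6)
  expect_equal(vapply(f2$peaks, `[[`, 0, "center"),
               vapply(f1$peaks, `[[`, 0, "center"), tolerance = 1e-6)
  expect_equal(vapply(f2$peaks, `[[`, 0, "power"),
               vapply(f1$peaks, `[[`, 0, "power"), tolerance = 1e-6)
})

test_that("alpha selection follows the maximum-power rule within band", {
  mk_fit <- function(peaks) {
    ps <- model_spectrum(peaks = peaks)
    fit_spectral_model(ps)
  }
  two <- mk_fit(list(list(power = 0.5, center = 10, width = 1),
                     list(power = 0.7, center = 9, width = 1)))
  expect_equal(select_alpha(two)$center, 9, tolerance = 0.1)
  outside <- mk_fit(list(list(power = 0.6, center = 5.5, width = 0.8),
                         list(power = 0.6, center = 20, width = 1)))
  expect_null(select_alpha(outside))
  single <- mk_fit(list(list(power = 0.6, center = 10.5, width = 1)))
  expect_equal(select_alpha(single)$center, 10.5, tolerance = 0.1)
})

test_that("feature tables and fit exports round-trip", {
  ps <- model_spectrum(peaks = list(list(power = 0.6, center = 10,
                                         width = 1.2)))
  fit <- fit_spectral_model(ps)
  row <- spectral_features(fit, epoch_id = "e1")
  expect_equal(row$n_peaks, length(fit$peaks))
  expect_equal(row$exponent, fit$aperiodic$exponent)
  f <- tempfile(fileext = ".json")
  write_spectral_fit(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$aperiodic$exponent, fit$aperiodic$exponent,
               tolerance = 1e-9)
  csv <- tempfile(fileext = ".csv")
  write_feature_table(list(fit, fit), csv, epoch_ids = c("a", "b"))
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$epoch_id, c("a", "b"))
})
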