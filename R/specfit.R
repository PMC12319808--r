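#' Settings for spectral parameterization
#'
#' Controls the decomposition of a power spectrum into an aperiodic
#' (power-law) component plus Gaussian peaks. Defaults follow the standard
#' parameterization of task EEG spectra: fit range 4--40 Hz, at most 5 peaks,
#' minimum peak height 0 (log10 units above the aperiodic fit), peak widths
#' limited to 0.5--12 Hz, a detection threshold of 2.0 residual standard
#' deviations, and a fixed (knee-free) aperiodic mode.
#'
#' @param freq_range Two-element numeric, fit range in Hz.
#' @param max_peaks Maximum number of Gaussian peaks.
#' @param min_peak_height Minimum absolute peak height (log10 power).
#' @param peak_width_limits Limits on peak width in Hz; the Gaussian standard
#'   deviation is bounded by half these values.
#' @param peak_threshold Peak detection threshold in multiples of the
#'   standard deviation of the flattened (residual) spectrum.
#' @param aperiodic_mode `"fixed"` (default) or `"knee"`.
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(freq_range = c(4, 40), max_peaks = 5,
                         min_peak_height = 0, peak_width_limits = c(0.5, 12),
                         peak_threshold = 2, aperiodic_mode = "fixed") {
  stopifnot(length(freq_range) == 2, freq_range[1] > 0,
            freq_range[2] > freq_range[1])
  stopifnot(length(peak_width_limits) == 2, peak_width_limits[1] > 0,
            peak_width_limits[2] > peak_width_limits[1])
  stopifnot(max_peaks >= 0, min_peak_height >= 0, peak_threshold >= 0)
  aperiodic_mode <- match.arg(aperiodic_mode, c("fixed", "knee"))
  structure(list(freq_range = as.numeric(freq_range),
                 max_peaks = as.integer(max_peaks),
                 min_peak_height = min_peak_height,
                 peak_width_limits = as.numeric(peak_width_limits),
                 peak_threshold = peak_threshold,
                 aperiodic_mode = aperiodic_mode),
            class = "fit_settings")
}

# ---- internal constants of the robust fitting procedure (documented in the
# methods vignette): percentile of positive residuals retained in the second
# aperiodic pass; center-frequency bound factor for the joint Gaussian fit;
# edge exclusion and overlap pruning for peak guesses, in units of the
# guessed standard deviation.
.ap_percentile_thresh <- 0.025
.cf_bound <- 1.5
.bw_std_edge <- 1.0
.gauss_overlap_thresh <- 0.75

.gauss_std_limits <- function(settings) settings$peak_width_limits / 2

#' Evaluate the aperiodic model in log10 power
#' @noRd
.gen_aperiodic <- function(freqs, offset, exponent, knee = NULL) {
  if (is.null(knee)) offset - exponent * log10(freqs)
  else offset - log10(knee + freqs^exponent)
}

.gaussian <- function(freqs, center, height, sdev) {
  height * exp(-(freqs - center)^2 / (2 * sdev^2))
}

.peak_model <- function(freqs, peaks) {
  m <- rep(0, length(freqs))
  for (p in peaks) m <- m + .gaussian(freqs, p$center, p$power, p$width)
  m
}

# single-pass aperiodic fit in log10-log10 space
.simple_ap_fit <- function(freqs, logpow, mode) {
  if (mode == "fixed") {
    co <- coef(lm(logpow ~ log10(freqs)))
    list(offset = unname(co[1]), exponent = -unname(co[2]), knee = NULL)
  } else {
    guess_off <- logpow[1]
    guess_exp <- abs((logpow[length(logpow)] - logpow[1]) /
                       (log10(freqs[length(freqs)]) - log10(freqs[1])))
    fit <- minpack.lm::nls.lm(
      par = c(offset = guess_off, knee = 0, exponent = guess_exp),
      lower = c(-Inf, 0, 0),
      fn = function(p) logpow - .gen_aperiodic(freqs, p[1], p[3], p[2]))
    p <- fit$par
    list(offset = unname(p[1]), exponent = unname(p[3]), knee = unname(p[2]))
  }
}

#' Fit the aperiodic component of a power spectrum
#'
#' Robust two-pass fit of the power-law (Lorentzian) background in log10
#' power over the configured frequency range: an initial least-squares fit,
#' flattening of the spectrum, retention of the bins whose positive residual
#' is at or below the 2.5th percentile (so narrowband peaks are ignored), and
#' a refit on the retained bins. In `"fixed"` mode the model is
#' `offset - exponent * log10(f)`; in `"knee"` mode
#' `offset - log10(knee + f^exponent)`.
#'
#' @param spectrum A [power_spectrum].
#' @param settings A [fit_settings] object.
#' @return A list of class `aperiodic_fit` with elements `offset`,
#'   `exponent`, and (knee mode only) `knee`.
#' @export
fit_aperiodic <- function(spectrum, settings = fit_settings()) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sel <- .trim_range(spectrum, settings$freq_range)
  ap <- .robust_ap_fit(sel$freqs, log10(sel$power), settings$aperiodic_mode)
  structure(ap, class = "aperiodic_fit")
}

.trim_range <- function(spectrum, freq_range) {
  keep <- spectrum$freqs >= freq_range[1] & spectrum$freqs <= freq_range[2]
  if (sum(keep) < 3)
    stop("fewer than 3 spectral bins inside the fit range ",
         freq_range[1], "-", freq_range[2], " Hz")
  list(freqs = spectrum$freqs[keep], power = spectrum$power[keep])
}

.robust_ap_fit <- function(freqs, logpow, mode) {
  init <- .simple_ap_fit(freqs, logpow, mode)
  flat <- logpow - .gen_aperiodic(freqs, init$offset, init$exponent, init$knee)
  flat[flat < 0] <- 0
  thresh <- quantile(flat, .ap_percentile_thresh, names = FALSE)
  keep <- flat <= thresh
  if (sum(keep) < 3) keep <- rep(TRUE, length(freqs))
  .simple_ap_fit(freqs[keep], logpow[keep], mode)
}

#' Extract Gaussian peaks from a flattened spectrum
#'
#' Iteratively locates the maximum of the peak-free (flattened) log-power
#' residual; a candidate is accepted while its height exceeds both
#' `peak_threshold` standard deviations of the current residual and
#' `min_peak_height`. Its width is guessed from the half-height crossing,
#' clipped to the configured limits, the guessed Gaussian is subtracted, and
#' the search repeats up to `max_peaks`. All guesses are then refit jointly
#' (bounded Levenberg-Marquardt) against the original flattened spectrum, and
#' peaks whose fitted centers leave the fit range are dropped. Peaks are
#' returned in extraction (decreasing height) order.
#'
#' @param flattened Numeric vector: residual log10 power after removing the
#'   aperiodic fit.
#' @param freqs Frequency grid (Hz) matching `flattened`.
#' @param settings A [fit_settings] object.
#' @return A list of peaks, each a list with `power` (log10-height above the
#'   aperiodic fit), `center` (Hz), and `width` (Gaussian sd, Hz). Empty list
#'   when nothing passes the threshold.
#' @export
extract_peaks <- function(flattened, freqs, settings = fit_settings()) {
  stopifnot(length(flattened) == length(freqs))
  std_limits <- .gauss_std_limits(settings)
  freq_res <- freqs[2] - freqs[1]
  flat_iter <- flattened
  guesses <- list()
  while (length(guesses) < settings$max_peaks) {
    max_ind <- which.max(flat_iter)
    max_height <- flat_iter[max_ind]
    if (max_height <= settings$peak_threshold * sd(flat_iter)) break
    # second condition is the configured floor; the 1e-9 is a numerical
    # guard so machine-precision residuals of exact model spectra are not
    # chased as peaks
    if (max_height <= max(settings$min_peak_height, 1e-9)) break
    guess_cf <- freqs[max_ind]
    half <- max_height / 2
    le <- which(flat_iter[seq_len(max_ind - 1)] <= half)
    le_ind <- if (length(le)) max(le) else NA_integer_
    ri <- which(flat_iter[seq(max_ind + 1, length(flat_iter))] <= half)
    ri_ind <- if (length(ri) && max_ind < length(flat_iter)) max_ind + min(ri)
              else NA_integer_
    side <- suppressWarnings(min(c(max_ind - le_ind, ri_ind - max_ind),
                                 na.rm = TRUE))
    guess_std <- if (is.finite(side)) {
      fwhm <- 2 * side * freq_res
      fwhm / (2 * sqrt(2 * log(2)))
    } else mean(std_limits)
    guess_std <- min(max(guess_std, std_limits[1]), std_limits[2])
    # fit this single Gaussian to the current residual before subtracting,
    # so the residue left behind carries no structure of its own
    g <- .fit_single_gaussian(flat_iter, freqs,
                              list(power = max_height, center = guess_cf,
                                   width = guess_std), std_limits)
    flat_iter <- flat_iter - .gaussian(freqs, g$center, g$power, g$width)
    guesses[[length(guesses) + 1]] <- g
  }
  if (length(guesses) == 0) return(list())
  guesses <- .drop_edge_guesses(guesses, settings$freq_range)
  guesses <- .drop_overlap_guesses(guesses)
  if (length(guesses) == 0) return(list())
  peaks <- .fit_peak_guesses(flattened, freqs, guesses, std_limits)
  Filter(function(p) p$center >= settings$freq_range[1] &&
           p$center <= settings$freq_range[2], peaks)
}

# drop guesses whose center sits within one (guessed) sd of the range edge
.drop_edge_guesses <- function(guesses, freq_range) {
  Filter(function(g) {
    bw <- .bw_std_edge * g$width
    abs(g$center - freq_range[1]) > bw && abs(g$center - freq_range[2]) > bw
  }, guesses)
}

# among overlapping guesses (centers closer than the overlap threshold in sd
# units), keep the taller one
.drop_overlap_guesses <- function(guesses) {
  if (length(guesses) < 2) return(guesses)
  ord <- order(vapply(guesses, `[[`, 0, "center"))
  sorted <- guesses[ord]
  drop <- rep(FALSE, length(sorted))
  for (i in seq_len(length(sorted) - 1)) {
    a <- sorted[[i]]; b <- sorted[[i + 1]]
    if (a$center + .gauss_overlap_thresh * a$width >=
        b$center - .gauss_overlap_thresh * b$width) {
      if (a$power < b$power) drop[i] <- TRUE else drop[i + 1] <- TRUE
    }
  }
  kept <- sorted[!drop]
  # restore extraction order (decreasing height order of discovery)
  kept[order(match(vapply(kept, `[[`, 0, "center"),
                   vapply(guesses, `[[`, 0, "center")))]
}

.fit_single_gaussian <- function(target, freqs, guess, std_limits) {
  fit <- withCallingHandlers(
    minpack.lm::nls.lm(
      par = c(guess$center, guess$power, guess$width),
      lower = c(guess$center - 2 * .cf_bound * guess$width, 0, std_limits[1]),
      upper = c(guess$center + 2 * .cf_bound * guess$width, Inf,
                std_limits[2]),
      fn = function(p) target - .gaussian(freqs, p[1], p[2], p[3]),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    warning = function(w) {
      if (grepl("maxiter", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(power = fit$par[2], center = fit$par[1], width = fit$par[3])
}

.fit_peak_guesses <- function(flattened, freqs, guesses, std_limits) {
  k <- length(guesses)
  par0 <- unlist(lapply(guesses, function(g) c(g$center, g$power, g$width)))
  lower <- unlist(lapply(guesses, function(g)
    c(g$center - 2 * .cf_bound * g$width, 0, std_limits[1])))
  upper <- unlist(lapply(guesses, function(g)
    c(g$center + 2 * .cf_bound * g$width, Inf, std_limits[2])))
  resid_fn <- function(p) {
    m <- rep(0, length(freqs))
    for (i in seq_len(k)) {
      j <- 3 * (i - 1)
      m <- m + .gaussian(freqs, p[j + 1], p[j + 2], p[j + 3])
    }
    flattened - m
  }
  fit <- withCallingHandlers(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    warning = function(w) {
      if (grepl("maxiter", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p <- fit$par
  peaks <- lapply(seq_len(k), function(i) {
    j <- 3 * (i - 1)
    list(power = p[j + 2], center = p[j + 1], width = p[j + 3])
  })
  # info codes 1-4 are successful terminations; anything else means the
  # joint refit stopped early and is flagged on the result
  attr(peaks, "joint_converged") <- fit$info %in% 1:4
  peaks
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Full decomposition in log10 power over the configured range: robust
#' aperiodic fit, peak extraction from the flattened spectrum, removal of the
#' fitted peaks, a final aperiodic refit on the peak-free spectrum, and
#' goodness of fit (R-squared and mean absolute error in log10 space) of the
#' combined model.
#'
#' @inheritParams fit_aperiodic
#' @return An object of class `spectral_fit`: `aperiodic` (offset, exponent),
#'   `peaks` (list of power/center/width), `fit_range`, `r_squared`, `error`
#'   (MAE, log10 units), `settings`, plus the trimmed `freqs`, the log10
#'   `data` and the `model` reconstruction.
#' @examples
#' f <- seq(4, 40, by = 0.05)
#' p <- 10^(2 - 1.5 * log10(f) + 0.6 * exp(-(f - 10)^2 / (2 * 1.2^2)))
#' fit <- fit_spectral_model(power_spectrum(f, p))
#' fit$aperiodic$exponent  # ~1.5
#' @export
fit_spectral_model <- function(spectrum, settings = fit_settings()) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sel <- .trim_range(spectrum, settings$freq_range)
  logpow <- log10(sel$power)
  ap <- .robust_ap_fit(sel$freqs, logpow, settings$aperiodic_mode)
  flat <- logpow - .gen_aperiodic(sel$freqs, ap$offset, ap$exponent, ap$knee)
  # the peak set is decided once, from the robust-fit residual; afterwards
  # only the continuous part is iterated (aperiodic refit on the
  # peak-removed spectrum, joint Gaussian refit on the re-flattened one),
  # which contracts the tilt the peaks induce in the first aperiodic
  # estimate without the instability of re-deciding the peak set
  peaks <- extract_peaks(flat, sel$freqs, settings)
  peak_fit <- .peak_model(sel$freqs, peaks)
  std_limits <- .gauss_std_limits(settings)
  for (pass in 1:8) {
    ap_new <- .simple_ap_fit(sel$freqs, logpow - peak_fit,
                             settings$aperiodic_mode)
    done <- abs(ap_new$offset - ap$offset) +
      abs(ap_new$exponent - ap$exponent) < 1e-5
    ap <- ap_new
    if (done || length(peaks) == 0) break
    flat <- logpow - .gen_aperiodic(sel$freqs, ap$offset, ap$exponent,
                                    ap$knee)
    peaks <- .fit_peak_guesses(flat, sel$freqs, peaks, std_limits)
    peaks <- Filter(function(p) p$center >= settings$freq_range[1] &&
                      p$center <= settings$freq_range[2] && p$power > 0,
                    peaks)
    peak_fit <- .peak_model(sel$freqs, peaks)
  }
  model <- .gen_aperiodic(sel$freqs, ap$offset, ap$exponent, ap$knee) + peak_fit
  structure(list(
    aperiodic = structure(ap, class = "aperiodic_fit"),
    peaks = peaks,
    fit_range = settings$freq_range,
    r_squared = cor(logpow, model)^2,
    error = mean(abs(logpow - model)),
    settings = settings,
    freqs = sel$freqs,
    data = logpow,
    model = model), class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("Spectral fit over %g-%g Hz\n", x$fit_range[1], x$fit_range[2]))
  cat(sprintf("  aperiodic: offset = %.4f, exponent = %.4f%s\n",
              x$aperiodic$offset, x$aperiodic$exponent,
              if (!is.null(x$aperiodic$knee))
                sprintf(", knee = %.4f", x$aperiodic$knee) else ""))
  if (length(x$peaks) == 0) cat("  peaks: none\n")
  else for (p in x$peaks)
    cat(sprintf("  peak: center = %.2f Hz, height = %.3f log10, sd = %.2f Hz\n",
                p$center, p$power, p$width))
  cat(sprintf("  R^2 = %.4f, MAE = %.4f (log10 power)\n", x$r_squared, x$error))
  invisible(x)
}

#' Select the alpha peak from a spectral fit
#'
#' Among fitted peaks with center frequency inside the alpha band, returns
#' the one with maximum power (log10-height above the aperiodic fit), the
#' rule used when several alpha peaks are detected. `NULL` when no peak
#' qualifies.
#'
#' @param fit A `spectral_fit`.
#' @param band Two-element numeric band in Hz; default `c(8, 12)`.
#' @return A single peak (list with `power`, `center`, `width`) or `NULL`.
#' @export
select_alpha <- function(fit, band = c(8, 12)) {
  stopifnot(inherits(fit, "spectral_fit"))
  cand <- Filter(function(p) p$center >= band[1] && p$center <= band[2],
                 fit$peaks)
  if (length(cand) == 0) return(NULL)
  cand[[which.max(vapply(cand, `[[`, 0, "power"))]]
}

#' Flatten a spectral fit into a one-row feature table
#'
#' @param fit A `spectral_fit`.
#' @param epoch_id Optional identifier carried into the row.
#' @param alpha_band Band used by [select_alpha()].
#' @return A one-row data.frame with columns `epoch_id`, `offset`,
#'   `exponent`, `alpha_power`, `alpha_cf`, `n_peaks`, `r2`. Alpha columns
#'   are `NA` when no alpha peak was detected.
#' @export
spectral_features <- function(fit, epoch_id = NA, alpha_band = c(8, 12)) {
  a <- select_alpha(fit, alpha_band)
  data.frame(epoch_id = epoch_id,
             offset = fit$aperiodic$offset,
             exponent = fit$aperiodic$exponent,
             alpha_power = if (is.null(a)) NA_real_ else a$power,
             alpha_cf = if (is.null(a)) NA_real_ else a$center,
             n_peaks = length(fit$peaks),
             r2 = fit$r_squared)
}

#' Export spectral fits
#'
#' `write_spectral_fit()` writes one fit as JSON (aperiodic parameters, peak
#' list, goodness of fit, settings); `write_feature_table()` writes a flat
#' CSV of per-epoch features from a list of fits.
#'
#' @param fit A `spectral_fit`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spectral_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spectral_fit"))
  jsonlite::write_json(list(
    aperiodic = fit$aperiodic[!vapply(fit$aperiodic, is.null, TRUE)],
    peaks = fit$peaks,
    fit_range = fit$fit_range,
    r_squared = fit$r_squared,
    error = fit$error,
    settings = unclass(fit$settings)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param fits A list of `spectral_fit` objects.
#' @param epoch_ids Identifiers, recycled against `fits`.
#' @rdname write_spectral_fit
#' @export
write_feature_table <- function(fits, path, epoch_ids = seq_along(fits)) {
  rows <- Map(spectral_features, fits, epoch_ids)
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
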