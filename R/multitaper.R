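#' Remove a linear trend from an epoch
#'
#' Least-squares removal of the best-fit line, applied before multitaper
#' spectral estimation so that slow drifts do not leak into low-frequency
#' power. The output has zero mean and zero linear slope.
#'
#' @param x Numeric vector (time series).
#' @return Detrended numeric vector of the same length.
#' @export
detrend_epoch <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("detrend_epoch() needs a numeric series of at least 2 samples")
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2          # centered time index
  slope <- sum(t * (x - mean(x))) / sum(t * t)
  x - mean(x) - slope * t
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `k` DPSS of length `n` at time-half-bandwidth product `nw`, unit
#' norm, in decreasing concentration order. Computed from the Slepian
#' tridiagonal eigenproblem so long epochs (tens of thousands of samples)
#' remain fast; results are cached per `(n, nw, k)`.
#'
#' @param n Series length in samples.
#' @param nw Time-half-bandwidth product (duration times half-bandwidth).
#' @param k Number of tapers. Tapers beyond `2 * nw - 1` are poorly
#'   concentrated; [multitaper_psd()] refuses them, but they can be computed
#'   here for inspection.
#' @return An `n` by `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (nw < 1) stop("time-bandwidth product nw must be >= 1")
  if (k > n) stop("cannot request more tapers than samples")
  key <- paste0("dpss_", n, "_", nw, "_", k)
  cached <- .ctspec_cache[[key]]
  if (!is.null(cached)) return(cached)
  z <- dpss_tapers_cpp(as.integer(n), as.numeric(nw), as.integer(k))
  .ctspec_cache[[key]] <- z
  z
}

#' Construct a power spectrum object
#'
#' @param freqs Strictly increasing, uniformly spaced frequency grid (Hz).
#' @param power Linear power values (units^2/Hz), positive.
#' @param meta Named list of provenance (epoch id, channel, taper settings).
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power, meta = list()) {
  stopifnot(is.numeric(freqs), is.numeric(power), length(freqs) == length(power))
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (any(!is.finite(power)) || any(power <= 0))
    stop("power must be finite and positive at every bin")
  structure(list(freqs = freqs, power = power, meta = meta),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d bins, %.3g-%.3g Hz (df = %.4g Hz)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  if (!is.null(x$meta$time_bandwidth))
    cat(sprintf("  multitaper: TW = %g, %d tapers\n",
                x$meta$time_bandwidth, x$meta$n_tapers))
  invisible(x)
}

#' Multitaper power spectral density
#'
#' One-sided PSD by averaging DPSS eigenspectra. The taper half-bandwidth is
#' given in Hz, so a 60-s epoch at 0.6 Hz gives a time-bandwidth product of
#' 36 (recorded in `meta`). The taper count is a setting, not derived from
#' the bandwidth: the classical bound `n_tapers <= 2*T*W - 1` is enforced but
#' fewer tapers may be (and typically are) requested.
#'
#' @param x Numeric vector, one epoch.
#' @param fs Sampling rate (Hz).
#' @param half_bandwidth Taper half-bandwidth W (Hz); default 0.6.
#' @param n_tapers Number of tapers; default `floor(2*T*W) - 1`.
#' @param detrend Remove a linear trend first (default TRUE).
#' @param epoch_id,channel Optional provenance labels stored in `meta`.
#' @return A [power_spectrum] with `meta$time_bandwidth = T * W`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 5, by = 1 / 128))
#' ps <- multitaper_psd(x, fs = 128, half_bandwidth = 0.6, n_tapers = 5)
#' @export
multitaper_psd <- function(x, fs, half_bandwidth = 0.6, n_tapers = NULL,
                           detrend = TRUE, epoch_id = NA, channel = NA) {
  n <- length(x)
  if (n < 8) stop("epoch too short for spectral estimation")
  dur <- n / fs
  tw <- dur * half_bandwidth
  if (tw < 1) stop("time-bandwidth product ", signif(tw, 3), " is below 1; ",
                   "increase epoch length or bandwidth")
  k_max <- floor(2 * tw - 1)
  if (is.null(n_tapers)) n_tapers <- k_max
  if (n_tapers > k_max)
    stop("n_tapers = ", n_tapers, " exceeds the 2*T*W - 1 bound (", k_max, ")")
  if (n_tapers < 1) stop("n_tapers must be >= 1")
  if (detrend) x <- detrend_epoch(x)
  tap <- dpss_tapers(n, tw, n_tapers)
  J <- mvfft(tap * x)                     # n x k eigencoefficients
  n_keep <- floor(n / 2) + 1
  S <- rowMeans(Mod(J[seq_len(n_keep), , drop = FALSE])^2) / fs
  # one-sided: double all bins except DC (and Nyquist when n is even)
  scale <- rep(2, n_keep)
  scale[1] <- 1
  if (n %% 2 == 0) scale[n_keep] <- 1
  S <- S * scale
  freqs <- (seq_len(n_keep) - 1) * fs / n
  # drop the DC bin: log-frequency fitting downstream cannot use it, and
  # detrending has removed its mass anyway
  keep <- freqs > 0 & S > 0
  power_spectrum(freqs[keep], S[keep],
                 meta = list(fs = fs, half_bandwidth = half_bandwidth,
                             n_tapers = n_tapers, time_bandwidth = tw,
                             n_samples = n, epoch_id = epoch_id,
                             channel = channel))
}
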