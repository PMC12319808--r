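#' Configuration for the DEAP-shaped synthetic study generator
#'
#' Defines a synthetic affective-EEG study: subjects rate arousal and
#' valence on continuous 1--9 scales over repeated 60-s trials, and each
#' trial carries task and prestimulus spectral features (aperiodic exponent
#' and offset, alpha peak power) generated from the same mixed-model
#' structure the estimator assumes, with known subject random effects.
#'
#' Effect-size defaults: the arousal effect on the task exponent is 0.0162
#' (the reported marginal effect at DEAP scale) and the prestimulus
#' couplings 0.2587 (exponent) and 0.2017 (offset) are the reported fixed
#' effects; subject intercept standard deviations 0.2770 / 0.3507 / 0.2669
#' (exponent / offset / alpha) are the reported between-subject variabilities.
#' Remaining defaults (arousal effects on offset and alpha, slope and
#' residual scales, rating distribution) are the package's own choices,
#' documented in the methods vignette.
#'
#' @param n_subjects,n_trials Study shape; defaults 32 and 40.
#' @param epoch_s,pre_s Task and prestimulus epoch lengths (s).
#' @param fs Sampling rate (Hz) for synthesized epochs.
#' @param effects Named list per response (`exponent`, `offset`, `alpha`),
#'   each with `intercept`, `pre`, `arousal`, `valence`, `interaction`
#'   fixed-effect coefficients on the raw 1--9 rating scale.
#' @param pre_mean Named numeric: mean prestimulus level per response.
#' @param pre_sd Named numeric: within-subject prestimulus sd per response.
#' @param subj_intercept_sd Named numeric: between-subject intercept sd per
#'   response (applied to both the prestimulus level and the task model).
#' @param subj_slope_sd Named numeric: between-subject sd of the arousal and
#'   valence random slopes per response.
#' @param resid_sd Named numeric: trial-level residual sd per response.
#' @param rating_mean,rating_sd Normal parameters of the continuous ratings,
#'   clipped to \[1, 9\] (no rounding: the scales are continuous).
#' @param alpha_miss_rate Fraction of trials whose alpha peak goes
#'   undetected (alpha features set missing), emulating absent alpha peaks.
#' @param alpha_cf_mean,alpha_cf_sd,alpha_bw Alpha center-frequency
#'   distribution (Hz) and Gaussian bandwidth (sd, Hz) used when epochs are
#'   synthesized.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_subjects = 32, n_trials = 40, epoch_s = 60, pre_s = 5, fs = 256,
    effects = list(
      exponent = list(intercept = 1.0, pre = 0.2587, arousal = 0.0162,
                      valence = 0, interaction = 0),
      offset = list(intercept = 1.2, pre = 0.2017, arousal = 0.01,
                    valence = 0, interaction = 0),
      alpha = list(intercept = 0.40, pre = 0.20, arousal = -0.01,
                   valence = 0, interaction = 0)),
    pre_mean = c(exponent = 1.5, offset = 1.5, alpha = 0.6),
    pre_sd = c(exponent = 0.15, offset = 0.15, alpha = 0.15),
    subj_intercept_sd = c(exponent = 0.2770, offset = 0.3507, alpha = 0.2669),
    subj_slope_sd = c(exponent = 0.005, offset = 0.005, alpha = 0.005),
    resid_sd = c(exponent = 0.18, offset = 0.18, alpha = 0.25),
    rating_mean = 5, rating_sd = 2,
    alpha_miss_rate = 0.05,
    alpha_cf_mean = 10, alpha_cf_sd = 0.8, alpha_bw = 1.2,
    seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials = as.integer(n_trials),
              epoch_s = epoch_s, pre_s = pre_s, fs = fs, effects = effects,
              pre_mean = pre_mean, pre_sd = pre_sd,
              subj_intercept_sd = subj_intercept_sd,
              subj_slope_sd = subj_slope_sd, resid_sd = resid_sd,
              rating_mean = rating_mean, rating_sd = rating_sd,
              alpha_miss_rate = alpha_miss_rate,
              alpha_cf_mean = alpha_cf_mean, alpha_cf_sd = alpha_cf_sd,
              alpha_bw = alpha_bw, seed = as.integer(seed))
  .validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

.validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 1 || cfg$n_trials < 1) stop("counts must be positive")
  if (cfg$fs <= 2 * (cfg$alpha_cf_mean + 4 * cfg$alpha_cf_sd))
    stop("fs must exceed twice the highest modeled frequency")
  for (r in c("exponent", "offset", "alpha")) {
    if (!all(c("intercept", "pre", "arousal", "valence", "interaction") %in%
             names(cfg$effects[[r]])))
      stop("effects$", r, " is missing coefficients")
    for (nm in c("pre_sd", "subj_intercept_sd", "subj_slope_sd", "resid_sd"))
      if (cfg[[nm]][[r]] < 0) stop(nm, " must be non-negative")
  }
  if (cfg$alpha_miss_rate < 0 || cfg$alpha_miss_rate > 1)
    stop("alpha_miss_rate must be in [0, 1]")
  invisible(cfg)
}

.rclip <- function(n, mean, sd, lo = 1, hi = 9) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic affective-EEG study with known ground truth
#'
#' Draws per-subject random intercepts and arousal/valence random slopes for
#' each spectral response, per-trial continuous ratings (clipped normal on
#' 1--9), prestimulus feature levels (sharing the subject intercept, so the
#' task-prestimulus coupling is recoverable), and task features from the
#' mixed-model structure `task = b0 + b_pre * pre + b_A * A + b_V * V +
#' b_AV * A * V + u0 + uA * A + uV * V + e`. A configurable fraction of
#' trials has its alpha peak marked undetected. The same seed always yields
#' identical tables.
#'
#' @param config A [generator_config].
#' @return List with `records` (TrialRecord data.frame: subject_id,
#'   trial_id, arousal, valence, task_/pre_ exponent, offset, alpha,
#'   task_alpha_cf) and `truth` (generating coefficients, per-subject
#'   effects, per-trial noiseless feature values).
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  ns <- config$n_subjects; nt <- config$n_trials
  responses <- c("exponent", "offset", "alpha")
  subj <- sprintf("s%02d", seq_len(ns))
  u0 <- uA <- uV <- matrix(0, ns, 3, dimnames = list(subj, responses))
  for (j in seq_along(responses)) {
    r <- responses[j]
    u0[, j] <- rnorm(ns, 0, config$subj_intercept_sd[[r]])
    uA[, j] <- rnorm(ns, 0, config$subj_slope_sd[[r]])
    uV[, j] <- rnorm(ns, 0, config$subj_slope_sd[[r]])
  }
  n <- ns * nt
  rec <- data.frame(subject_id = rep(subj, each = nt),
                    trial_id = rep(sprintf("t%02d", seq_len(nt)), ns),
                    arousal = .rclip(n, config$rating_mean, config$rating_sd),
                    valence = .rclip(n, config$rating_mean, config$rating_sd),
                    stringsAsFactors = FALSE)
  si <- rep(seq_len(ns), each = nt)
  true_task <- matrix(0, n, 3, dimnames = list(NULL, responses))
  for (j in seq_along(responses)) {
    r <- responses[j]
    ef <- config$effects[[r]]
    pre <- config$pre_mean[[r]] + u0[si, j] + rnorm(n, 0, config$pre_sd[[r]])
    mu <- ef$intercept + ef$pre * pre + ef$arousal * rec$arousal +
      ef$valence * rec$valence + ef$interaction * rec$arousal * rec$valence +
      u0[si, j] + uA[si, j] * rec$arousal + uV[si, j] * rec$valence
    rec[[paste0("pre_", r)]] <- pre
    rec[[paste0("task_", r)]] <- mu + rnorm(n, 0, config$resid_sd[[r]])
    true_task[, j] <- mu
  }
  rec$task_alpha_cf <- .rclip(n, config$alpha_cf_mean, config$alpha_cf_sd,
                              lo = 8, hi = 12)
  missed <- runif(n) < config$alpha_miss_rate
  rec$task_alpha[missed] <- NA_real_
  rec$task_alpha_cf[missed] <- NA_real_
  list(records = rec,
       truth = list(effects = config$effects,
                    subject_intercepts = u0,
                    subject_arousal_slopes = uA,
                    subject_valence_slopes = uV,
                    true_task = as.data.frame(true_task),
                    config = unclass(config)))
}

#' Synthesize a time-domain epoch with a prescribed spectral decomposition
#'
#' Builds a stationary Gaussian signal whose expected one-sided PSD follows
#' the log-additive model `log10 S(f) = (b - X log10 f) + a exp(-(f - c)^2 /
#' (2 w^2))`: an aperiodic component made by shaping white noise to
#' `10^b / f^X` in the frequency domain, plus an independent narrowband
#' (amplitude-modulated) alpha component whose linear spectrum is the exact
#' difference `10^(L+G) - 10^L`, so the log-height above the aperiodic fit
#' equals `a` in closed form (no numerical calibration step). Round-tripping
#' through [multitaper_psd()] and [fit_spectral_model()] recovers the
#' generating parameters within the documented tolerances.
#'
#' @param offset Aperiodic offset b (log10 power).
#' @param exponent Aperiodic exponent X (>= 0).
#' @param alpha_power Alpha log10-height a above the aperiodic component;
#'   0 gives a pure aperiodic signal.
#' @param alpha_cf Alpha center frequency (Hz), below Nyquist.
#' @param alpha_bw Alpha Gaussian bandwidth (sd, Hz).
#' @param epoch_s Epoch length (s).
#' @param fs Sampling rate (Hz).
#' @param seed Optional integer seed.
#' @return Numeric vector of `epoch_s * fs` samples.
#' @export
synthesize_epoch <- function(offset, exponent, alpha_power = 0,
                             alpha_cf = 10, alpha_bw = 1.2,
                             epoch_s = 60, fs = 256, seed = NULL) {
  stopifnot(exponent >= 0, alpha_bw > 0, epoch_s > 0, fs > 0)
  if (alpha_power < 0) stop("alpha_power must be >= 0 (log10 height)")
  if (alpha_cf >= fs / 2) stop("alpha center frequency is at or above Nyquist")
  if (!is.null(seed)) set.seed(seed)
  n <- round(epoch_s * fs)
  freqs <- seq_len(floor(n / 2)) * fs / n      # positive-frequency bins
  s_ap <- 10^offset / freqs^exponent
  gauss <- alpha_power * exp(-(freqs - alpha_cf)^2 / (2 * alpha_bw^2))
  s_alpha <- s_ap * (10^gauss - 1)
  draw <- function(s_target) {
    # Hermitian spectrum with E|X_k|^2 = n * fs * S/2 (two-sided density)
    amp <- sqrt(n * fs * s_target / 2)
    z <- complex(real = rnorm(length(amp), 0, sqrt(0.5)),
                 imaginary = rnorm(length(amp), 0, sqrt(0.5)))
    X <- amp * z
    if (n %% 2 == 0)                           # Nyquist bin must be real
      X[length(X)] <- sqrt(n * fs * s_target[length(X)]) * rnorm(1)
    full <- complex(real = numeric(n))
    full[2:(length(X) + 1)] <- X
    full[n:(n - length(X) + if (n %% 2 == 0) 2 else 1)] <-
      Conj(X[seq_len(length(X) - if (n %% 2 == 0) 1 else 0)])
    Re(fft(full, inverse = TRUE)) / n
  }
  x <- draw(s_ap)
  if (alpha_power > 0) x <- x + draw(s_alpha)
  x
}

#' Write a synthetic study to disk
#'
#' Writes the trial table as CSV, the ground truth as JSON, and (optionally)
#' per-trial epochs as single-column text files with a JSON manifest
#' recording the sampling rate, units and the file for every epoch.
#'
#' @param study A list from [generate_study()].
#' @param path Output directory (created if absent).
#' @param epochs Optional named list of numeric vectors (epoch time series).
#' @param fs Sampling rate recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(study, path, epochs = NULL, fs = 256) {
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE))
      stop("could not create output directory: ", path)
  write.csv(study$records, file.path(path, "trial_table.csv"),
            row.names = FALSE)
  truth <- study$truth
  truth$subject_intercepts <- as.data.frame(truth$subject_intercepts)
  truth$subject_arousal_slopes <- as.data.frame(truth$subject_arousal_slopes)
  truth$subject_valence_slopes <- as.data.frame(truth$subject_valence_slopes)
  jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest <- list(fs = fs, units = "a.u.", epochs = list())
  if (!is.null(epochs)) {
    stopifnot(!is.null(names(epochs)))
    for (nm in names(epochs)) {
      f <- paste0("epoch_", nm, ".txt")
      writeLines(format(epochs[[nm]], digits = 10),
                 file.path(path, f))
      manifest$epochs[[nm]] <- f
    }
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tabular epoch and trial data
#'
#' `read_epoch_table()` reads a delimited numeric table of EEG samples (one
#' row per sample, one column per channel, optional header of channel
#' names) into a channels-by-time matrix suitable for
#' [cluster_pca_reduce()]. `read_trial_table()` reads a TrialRecord CSV as
#' written by [write_dataset()].
#'
#' @param path File path.
#' @param header Whether the epoch table has a channel-name header row.
#' @param sep Field separator.
#' @return A channels-by-time numeric matrix, or a TrialRecord data.frame.
#' @export
read_epoch_table <- function(path, header = TRUE, sep = ",") {
  d <- utils::read.table(path, header = header, sep = sep)
  if (!all(vapply(d, is.numeric, TRUE)))
    stop("epoch table must be entirely numeric: ", path)
  m <- t(as.matrix(d))
  if (!header) rownames(m) <- paste0("ch", seq_len(nrow(m)))
  m
}

#' @rdname read_epoch_table
#' @export
read_trial_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_id", "arousal", "valence")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("trial table lacks column(s): ",
                         paste(miss, collapse = ", "))
  d
}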