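#' Electrode cluster maps for the 32-channel montage
#'
#' Groups the EEG montage into spatial clusters: prefrontal, frontal,
#' central, centroparietal, parietal, parietooccipital and the two temporal
#' singletons. The 9-cluster variant adds a frontocentral group (FC1, FC2,
#' FC5, FC6), which otherwise goes unassigned.
#'
#' @param n_clusters 8 (as listed) or 9 (adds frontocentral).
#' @return Named list mapping cluster label to channel names; channels are
#'   disjoint across clusters.
#' @export
cluster_map <- function(n_clusters = 8) {
  stopifnot(n_clusters %in% c(8, 9))
  m <- list(
    prefrontal = c("AF3", "AF4", "FP1", "FP2"),
    frontal = c("F7", "F3", "Fz", "F4", "F8"),
    central = c("C3", "Cz", "C4"),
    centroparietal = c("CP1", "CP5", "CP6", "CP2"),
    parietal = c("P7", "P3", "Pz", "P4", "P8"),
    parietooccipital = c("PO3", "O1", "Oz", "O2", "PO4"),
    temporal_right = "T8",
    temporal_left = "T7")
  if (n_clusters == 9)
    m$frontocentral <- c("FC1", "FC2", "FC5", "FC6")
  m
}

#' Reduce multichannel epochs to per-cluster time series by PCA
#'
#' For each cluster with two or more channels, centers the channels over
#' time and projects onto the first principal axis of the channels-by-time
#' matrix; the loading sign is fixed so the loadings sum to a positive
#' value. Single-channel clusters pass through unchanged (unit loading).
#' Loadings are returned so cluster-level model estimates can be mapped back
#' to channels.
#'
#' @param epoch Numeric matrix, channels by time, with channel rownames.
#' @param map A [cluster_map()]-style named list. Clusters with no matching
#'   channels are skipped.
#' @return Named list per cluster: `series` (numeric vector) and `loadings`
#'   (named numeric vector over the cluster's channels).
#' @export
cluster_pca_reduce <- function(epoch, map = cluster_map()) {
  if (!is.matrix(epoch) || is.null(rownames(epoch)))
    stop("epoch must be a channels-by-time matrix with channel rownames")
  out <- list()
  for (cl in names(map)) {
    ch <- intersect(map[[cl]], rownames(epoch))
    if (length(ch) == 0) next
    X <- epoch[ch, , drop = FALSE]
    if (length(ch) == 1) {
      out[[cl]] <- list(series = as.numeric(X),
                        loadings = setNames(1, ch))
      next
    }
    Xc <- X - rowMeans(X)
    sv <- svd(Xc, nu = 1, nv = 0)
    u <- sv$u[, 1]
    if (sum(u) < 0) u <- -u
    out[[cl]] <- list(series = as.numeric(crossprod(u, Xc)),
                      loadings = setNames(u, ch))
  }
  out
}

#' Filter trial records before mixed-model fitting
#'
#' Applies the two exclusion rules used on trial-level spectral features:
#' trials with non-positive task exponent are removed (a negative exponent
#' means rising power with frequency, indicative of noise), and subjects
#' with fewer than `min_alpha_trials` trials carrying a detected alpha peak
#' (non-missing `task_alpha`) are removed entirely. Every exclusion is
#' listed with its reason.
#'
#' @param records TrialRecord data.frame (see [generate_study()] for the
#'   column layout).
#' @param min_alpha_trials Minimum alpha-peak trials a subject must retain.
#' @return List with `records` (filtered data.frame) and `exclusions`
#'   (data.frame: subject_id, trial_id, reason; trial_id `NA` for
#'   whole-subject removals).
#' @export
filter_trials <- function(records, min_alpha_trials = 10) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  need <- c("subject_id", "trial_id", "task_exponent", "task_alpha")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lacks column(s): ", paste(miss, collapse = ", "))
  excl <- data.frame(subject_id = character(), trial_id = character(),
                     reason = character(), stringsAsFactors = FALSE)
  bad <- !is.na(records$task_exponent) & records$task_exponent <= 0
  if (any(bad)) {
    excl <- rbind(excl, data.frame(
      subject_id = as.character(records$subject_id[bad]),
      trial_id = as.character(records$trial_id[bad]),
      reason = "non-positive task exponent", stringsAsFactors = FALSE))
    records <- records[!bad, , drop = FALSE]
  }
  n_alpha <- tapply(!is.na(records$task_alpha), records$subject_id, sum)
  drop_subj <- names(n_alpha)[n_alpha < min_alpha_trials]
  if (length(drop_subj)) {
    excl <- rbind(excl, data.frame(
      subject_id = drop_subj, trial_id = NA_character_,
      reason = sprintf("fewer than %d trials with detected alpha peak",
                       min_alpha_trials), stringsAsFactors = FALSE))
    records <- records[!records$subject_id %in% drop_subj, , drop = FALSE]
  }
  if (nrow(records) == 0)
    stop("all subjects excluded; check features or lower min_alpha_trials")
  list(records = records, exclusions = excl)
}

#' Holm step-down adjustment of p-values
#'
#' Step-down familywise-error control: p-values are sorted ascending, the
#' k-th smallest is multiplied by (m - k + 1), monotonicity is enforced by a
#' running maximum, results are capped at 1 and returned in the original
#' order. Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  p.adjust(p, method = "holm")
}

.response_cols <- function(response) {
  response <- match.arg(response, c("exponent", "offset", "alpha"))
  list(task = paste0("task_", response), pre = paste0("pre_", response))
}

# Fit by REML, simplifying the random structure only when optimization
# actually fails (a singular fit -- a random-effect variance estimated at
# zero -- is a valid REML solution and is kept, but recorded).
.fit_lmm_with_fallback <- function(fixed, records) {
  structures <- c("(1 + arousal + valence | subject_id)",
                  "(1 + arousal + valence || subject_id)",
                  "(1 | subject_id)")
  for (i in seq_along(structures)) {
    form <- stats::as.formula(paste(fixed, "+", structures[i]))
    fit <- tryCatch(
      suppressMessages(withCallingHandlers(
        lmerTest::lmer(form, data = records, REML = TRUE),
        warning = function(w) {
          if (grepl("converge|singular|gradient|Hessian",
                    conditionMessage(w)))
            invokeRestart("muffleWarning") else warning(w)
        })),
      error = function(e) NULL)
    if (is.null(fit)) next
    msgs <- fit@optinfo$conv$lme4$messages
    failed <- !is.null(msgs) && any(grepl("failed to converge", msgs))
    if (!failed || i == length(structures))
      return(list(fit = fit, random_structure = structures[i],
                  converged = !failed,
                  singular = lme4::isSingular(fit)))
  }
  stop("mixed model could not be fitted")
}

.varcorr_table <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc[, c("grp", "var1", "var2", "vcov", "sdcor")]
}

#' Fit the global arousal/valence mixed model for one spectral feature
#'
#' Fits, by REML, `task feature ~ prestimulus feature + arousal * valence`
#' with a by-subject random intercept and random slopes for arousal and
#' valence, and reports marginal F-tests with Satterthwaite denominator
#' degrees of freedom for each fixed term. If the full random structure is
#' singular or fails to converge, progressively simpler structures are used
#' and recorded in the result.
#'
#' @param records Filtered TrialRecord data.frame with columns `subject_id`,
#'   `arousal`, `valence` and the `task_*`/`pre_*` feature pair for the
#'   chosen response. Rows with missing values in the model variables are
#'   dropped.
#' @param response One of `"exponent"`, `"offset"`, `"alpha"`.
#' @return An object of class `lmm_fit`: `fixed_effects` (term, estimate,
#'   se, df, t, p), `f_tests` (term, num_df, den_df, f, p, p_holm = NA for
#'   the global model), `random_effects`, `converged`, `random_structure`,
#'   `n_obs`, `n_subjects`, `response`, and the underlying `model`.
#' @export
fit_global_lmm <- function(records, response = c("exponent", "offset", "alpha")) {
  cols <- .response_cols(match.arg(response))
  d <- records
  d$.y <- d[[cols$task]]
  d$.pre <- d[[cols$pre]]
  d <- d[stats::complete.cases(d[, c(".y", ".pre", "arousal", "valence",
                                     "subject_id")]), , drop = FALSE]
  if (nrow(d) < 10) stop("too few complete observations for the mixed model")
  d$subject_id <- factor(d$subject_id)
  res <- .fit_lmm_with_fallback(".y ~ .pre + arousal * valence", d)
  fit <- res$fit
  sm <- as.data.frame(stats::coef(summary(fit)))
  fixed <- data.frame(term = sub("^\\.pre$", "prestimulus", rownames(sm)),
                      estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
                      df = sm[, "df"], t = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"], row.names = NULL)
  an <- suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
  f_tests <- data.frame(term = sub("^\\.pre$", "prestimulus", rownames(an)),
                        num_df = an$NumDF, den_df = an$DenDF,
                        f = an$`F value`, p = an$`Pr(>F)`,
                        p_holm = NA_real_, row.names = NULL)
  structure(list(fixed_effects = fixed, f_tests = f_tests,
                 random_effects = .varcorr_table(fit),
                 converged = res$converged, singular = res$singular,
                 random_structure = res$random_structure,
                 n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                 response = cols$task, model = fit),
            class = "lmm_fit")
}

#' Fit the electrode-cluster interaction mixed model
#'
#' Fits, for one spectral feature, the cluster-based design: the prestimulus
#' covariate, arousal and valence each interact with the electrode cluster
#' (so every cluster gets its own slope), plus the arousal-by-valence
#' interaction, with the same by-subject random structure as the global
#' model. The per-cluster arousal and valence slopes are reported as
#' contrasts with Satterthwaite degrees of freedom, Wald statistics, and
#' Holm-adjusted p-values; the Holm family is all cluster-by-arousal and
#' cluster-by-valence contrasts of this one response model.
#'
#' @param records TrialRecord data.frame that also carries a `cluster`
#'   column; (subject, trial, cluster) rows are the observations.
#' @inheritParams fit_global_lmm
#' @return An `lmm_fit` whose `contrasts` element holds the per-cluster
#'   interaction table (term, estimate, se, df, z, p, p_holm).
#' @export
fit_cluster_lmm <- function(records, response = c("exponent", "offset", "alpha")) {
  if (!"cluster" %in% names(records))
    stop("records must carry a 'cluster' column for the cluster model")
  cols <- .response_cols(match.arg(response))
  d <- records
  d$.y <- d[[cols$task]]
  d$.pre <- d[[cols$pre]]
  d <- d[stats::complete.cases(d[, c(".y", ".pre", "arousal", "valence",
                                     "subject_id", "cluster")]), , drop = FALSE]
  d$subject_id <- factor(d$subject_id)
  d$cluster <- factor(d$cluster)
  fixed <- if (nlevels(d$cluster) > 1) {
    ".y ~ .pre:cluster + cluster:arousal + cluster:valence + arousal:valence"
  } else {
    # one cluster: the interaction design collapses to the global model
    ".y ~ .pre + arousal * valence"
  }
  res <- .fit_lmm_with_fallback(fixed, d)
  fit <- res$fit
  sm <- as.data.frame(stats::coef(summary(fit)))
  rows <- if (nlevels(d$cluster) > 1) {
    grepl("cluster.*:(arousal|valence)$|^(arousal|valence):cluster",
          rownames(sm))
  } else {
    rownames(sm) %in% c("arousal", "valence")
  }
  contrasts <- data.frame(term = rownames(sm)[rows],
                          estimate = sm[rows, "Estimate"],
                          se = sm[rows, "Std. Error"],
                          df = sm[rows, "df"],
                          z = sm[rows, "t value"],
                          p = sm[rows, "Pr(>|t|)"], row.names = NULL)
  contrasts$p_holm <- holm_adjust(contrasts$p)
  fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  structure(list(fixed_effects = fixed, contrasts = contrasts,
                 f_tests = NULL,
                 random_effects = .varcorr_table(fit),
                 converged = res$converged, singular = res$singular,
                 random_structure = res$random_structure,
                 n_obs = nrow(d), n_subjects = nlevels(d$subject_id),
                 response = cols$task, model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Mixed model for %s (%d obs, %d subjects)\n",
              x$response, x$n_obs, x$n_subjects))
  cat("  random structure:", x$random_structure,
      if (!x$converged) "[did not fully converge]" else "", "\n")
  cat("Fixed effects:\n")
  print(x$fixed_effects, digits = 4)
  if (!is.null(x$f_tests)) {
    cat("Satterthwaite F-tests:\n")
    print(x$f_tests, digits = 4)
  }
  if (!is.null(x$contrasts)) {
    cat("Cluster contrasts (Holm-adjusted):\n")
    print(x$contrasts, digits = 4)
  }
  invisible(x)
}

#' Export a mixed-model fit
#'
#' Writes the full fit as JSON and, optionally, a CSV summary shaped like a
#' results table (term, estimate or F, df, raw p, adjusted p).
#'
#' @param fit An `lmm_fit`.
#' @param path JSON output path.
#' @param csv_path Optional CSV summary path.
#' @return `path`, invisibly.
#' @export
write_lmm_fit <- function(fit, path, csv_path = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  payload <- fit[c("fixed_effects", "f_tests", "contrasts", "random_effects",
                   "converged", "random_structure", "n_obs", "n_subjects",
                   "response")]
  payload <- payload[!vapply(payload, is.null, TRUE)]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) {
    tab <- if (!is.null(fit$contrasts)) fit$contrasts else fit$f_tests
    write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(path)
}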