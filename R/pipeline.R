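#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration with sections `params` (model parameter
#' overrides or a `file` pointing to a key-value parameter file), `sim`
#' ([sim_config] fields), `fit` ([fit_settings] fields), `generator`
#' ([generator_config] fields), `sweep` (list of `parameter`, `from`, `to`,
#' `steps` entries), `validate` (`n_replicates`, `n_null`), `output_dir`,
#' and `seed`. Unknown keys anywhere are rejected with a clear message.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("params", "sim", "fit", "generator", "sweep", "validate",
             "output_dir", "seed", "log_level")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  check_keys <- function(x, fn, label) {
    if (is.null(x)) return(list())
    bad <- setdiff(names(x), names(formals(fn)))
    if (length(bad)) stop("unknown ", label, " key(s): ",
                          paste(bad, collapse = ", "))
    x
  }
  params <- if (!is.null(raw$params$file)) {
    read_ct_params(raw$params$file)
  } else {
    do.call(ct_params, check_keys(raw$params, ct_params, "params"))
  }
  cfg <- list(
    params = params,
    sim = do.call(sim_config, check_keys(raw$sim, sim_config, "sim")),
    fit = do.call(fit_settings, check_keys(raw$fit, fit_settings, "fit")),
    generator = do.call(generator_config,
                        check_keys(raw$generator, generator_config,
                                   "generator")),
    sweep = if (is.null(raw$sweep)) .default_sweeps() else raw$sweep,
    validate = modifyList(list(n_replicates = 20, n_null = 0,
                               min_alpha_trials = 10),
                          if (is.null(raw$validate)) list() else raw$validate),
    output_dir = if (is.null(raw$output_dir)) "ctspec_out" else raw$output_dir,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    log_level = if (is.null(raw$log_level)) "INFO" else raw$log_level)
  for (sw in cfg$sweep) {
    need <- c("parameter", "from", "to", "steps")
    if (!all(need %in% names(sw)))
      stop("each sweep entry needs keys: ", paste(need, collapse = ", "))
    if (!sw$parameter %in% ct_coupling_names())
      stop("unknown sweep parameter: ", sw$parameter)
  }
  structure(cfg, class = "pipeline_config")
}

# Default sweeps: each coupling moved from its normative value toward the
# configuration that increases net inhibition of the relay population,
# staying on the stable (noise-driven) side of the resonance.
.default_sweeps <- function() {
  list(list(parameter = "nu_sr", from = -0.845, to = -1.15, steps = 8),
       list(parameter = "nu_es", from = 2.20, to = 1.70, steps = 8),
       list(parameter = "nu_re", from = 0.91, to = 1.35, steps = 8))
}

# Deterministic per-stage seed derivation from the global seed, so stages
# can be rerun in isolation and still reproduce the full-pipeline results.
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, sweep = 211L, synth = 307L, stats = 401L,
               validate = 503L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

.log_msg <- function(config, level, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (levels[[level]] >= levels[[config$log_level]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

# taper count for simulated traces: the empirical setting (45) unless the
# kept epoch is too short for it, then the largest admissible count
.taper_count <- function(kept_s, w = 0.6) {
  max(1, min(45, floor(2 * kept_s * w) - 1))
}

# provenance sidecar: configuration hash, package version, seed
.write_provenance <- function(config, path, stage, seed) {
  payload <- list(params = unclass(config$params),
                  sim = unclass(config$sim), fit = unclass(config$fit),
                  generator = unclass(config$generator))
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_md5 = h,
         package_version = as.character(utils::packageVersion("ctspec")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the normative simulation and parameterize its spectrum
#'
#' Simulates the corticothalamic model under the configured parameters,
#' estimates the multitaper PSD of the cortical trace, fits the spectral
#' model, and writes the spectrum (CSV), the fit (JSON), a feature row
#' (CSV) and a provenance sidecar into the output directory.
#'
#' @param config A [pipeline_config].
#' @param output Trace to analyze (`"v_e"` default, or `"phi_e"`).
#' @return Invisibly, a list with the simulation, spectrum and fit.
#' @export
cmd_simulate <- function(config = pipeline_config(), output = "v_e") {
  dir <- .ensure_dir(config$output_dir)
  seed <- .stage_seed(config$seed, "simulate")
  sim_cfg <- config$sim
  sim_cfg$seed <- seed
  .log_msg(config, "INFO", "simulate: ", sim_cfg$duration, " s at dt = ",
           sim_cfg$dt, " s, seed ", seed)
  sim <- simulate_ct(config$params, sim_cfg)
  tr <- if (output == "v_e") sim$v_e else sim$phi_e
  kept <- sim_cfg$duration - sim_cfg$transient
  ps <- multitaper_psd(tr, fs = 1 / sim_cfg$dt, half_bandwidth = 0.6,
                       n_tapers = .taper_count(kept))
  fit <- fit_spectral_model(ps, config$fit)
  write.csv(data.frame(freq_hz = ps$freqs, power = ps$power),
            file.path(dir, "normative_spectrum.csv"), row.names = FALSE)
  write_spectral_fit(fit, file.path(dir, "normative_fit.json"))
  write_feature_table(list(fit), file.path(dir, "normative_features.csv"),
                      epoch_ids = "normative")
  .write_provenance(config, file.path(dir, "simulate_provenance.json"),
                    "simulate", seed)
  .log_msg(config, "INFO", "simulate: top peak at ",
           round(fit$peaks[[which.max(vapply(fit$peaks, `[[`, 0, "power"))]]$center, 2),
           " Hz")
  invisible(list(sim = sim, spectrum = ps, fit = fit))
}

#' Run the configured coupling sweeps
#'
#' Runs [parameter_sweep()] for every configured coupling, writes one CSV
#' (plus JSON sidecar) per coupling and a trend summary giving the Spearman
#' correlation sign of each spectral feature against the coupling
#' direction of increased relay inhibition.
#'
#' @param config A [pipeline_config].
#' @param output Trace to analyze.
#' @return Invisibly, a named list of `ct_sweep` tables plus the summary.
#' @export
cmd_sweep <- function(config = pipeline_config(), output = "v_e") {
  if (length(config$sweep) == 0) stop("no sweeps configured")
  dir <- .ensure_dir(config$output_dir)
  seed <- .stage_seed(config$seed, "sweep")
  sim_cfg <- config$sim
  sim_cfg$seed <- seed
  sweeps <- list()
  summary_rows <- list()
  for (sw in config$sweep) {
    .log_msg(config, "INFO", "sweep: ", sw$parameter, " over [", sw$from,
             ", ", sw$to, "], ", sw$steps, " steps")
    values <- seq(sw$from, sw$to, length.out = sw$steps)
    kept <- sim_cfg$duration - sim_cfg$transient
    res <- parameter_sweep(config$params, sw$parameter, values, sim_cfg,
                           config$fit, n_tapers = .taper_count(kept),
                           output = output)
    sweeps[[sw$parameter]] <- res
    write_sweep(res, file.path(dir, paste0("sweep_", sw$parameter, ".csv")))
    ok <- !res$diverged
    # direction of increasing net relay inhibition along the sweep
    x <- seq_len(nrow(res))
    rho <- function(y) if (sum(ok) > 2)
      suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
      else NA_real_
    summary_rows[[sw$parameter]] <- data.frame(
      param = sw$parameter,
      exponent_trend = rho(res$exponent),
      offset_trend = rho(res$offset),
      alpha_trend = rho(res$alpha_power),
      n_diverged = sum(res$diverged))
  }
  summary <- do.call(rbind, summary_rows)
  write.csv(summary, file.path(dir, "sweep_trends.csv"), row.names = FALSE)
  .write_provenance(config, file.path(dir, "sweep_provenance.json"),
                    "sweep", seed)
  invisible(list(sweeps = sweeps, summary = summary))
}

#' Generate a synthetic study and write it to disk
#'
#' @param config A [pipeline_config].
#' @return Invisibly, the generated study.
#' @export
cmd_synth <- function(config = pipeline_config()) {
  dir <- .ensure_dir(config$output_dir)
  gen <- config$generator
  gen$seed <- .stage_seed(config$seed, "synth")
  study <- generate_study(gen)
  write_dataset(study, file.path(dir, "synthetic_study"), fs = gen$fs)
  .write_provenance(config, file.path(dir, "synth_provenance.json"),
                    "synth", gen$seed)
  .log_msg(config, "INFO", "synth: ", nrow(study$records), " trial records")
  invisible(study)
}

#' Parameterize a table of power spectra
#'
#' Reads a delimited PSD table with columns `freq_hz`, `power` and
#' (optionally) `epoch_id`, fits the spectral model per epoch and writes a
#' feature table.
#'
#' @param psd_path Input CSV path.
#' @param config A [pipeline_config].
#' @return Invisibly, the feature data.frame.
#' @export
cmd_parameterize <- function(psd_path, config = pipeline_config()) {
  dir <- .ensure_dir(config$output_dir)
  d <- read.csv(psd_path)
  if (!all(c("freq_hz", "power") %in% names(d)))
    stop("PSD table needs columns freq_hz and power")
  if (is.null(d$epoch_id)) d$epoch_id <- "epoch1"
  ids <- unique(d$epoch_id)
  fits <- lapply(ids, function(id) {
    sub <- d[d$epoch_id == id, ]
    fit_spectral_model(power_spectrum(sub$freq_hz, sub$power,
                                      meta = list(epoch_id = id)),
                       config$fit)
  })
  out <- file.path(dir, "parameterized_features.csv")
  write_feature_table(fits, out, epoch_ids = ids)
  .log_msg(config, "INFO", "parameterize: ", length(ids), " epochs -> ", out)
  invisible(do.call(rbind, Map(spectral_features, fits, ids)))
}

#' Fit the mixed models on a trial table
#'
#' Applies [filter_trials()] then [fit_global_lmm()] for each requested
#' response, writing JSON fits and CSV summaries.
#'
#' @param trial_path Trial table CSV ([read_trial_table()] format).
#' @param config A [pipeline_config].
#' @param responses Character vector of responses to model.
#' @return Invisibly, a named list of `lmm_fit` objects.
#' @export
cmd_stats <- function(trial_path, config = pipeline_config(),
                      responses = c("exponent", "offset", "alpha")) {
  dir <- .ensure_dir(config$output_dir)
  rec <- read_trial_table(trial_path)
  flt <- filter_trials(rec, config$validate$min_alpha_trials)
  if (nrow(flt$exclusions))
    write.csv(flt$exclusions, file.path(dir, "exclusions.csv"),
              row.names = FALSE)
  fits <- list()
  for (r in responses) {
    .log_msg(config, "INFO", "stats: fitting ", r)
    fits[[r]] <- fit_global_lmm(flt$records, r)
    write_lmm_fit(fits[[r]], file.path(dir, paste0("lmm_", r, ".json")),
                  file.path(dir, paste0("lmm_", r, ".csv")))
  }
  invisible(fits)
}

#' Validate parameter recovery on synthetic studies
#'
#' Generates `n_replicates` studies from the configured generator (fresh
#' seeds derived from the global seed), fits the global exponent model on
#' each, and reports bias and confidence-interval coverage of the arousal
#' effect. Optionally runs `n_null` additional null studies (all emotion
#' effects zero) and reports the familywise false-positive rate of the
#' Holm-adjusted arousal/valence/interaction family.
#'
#' @param config A [pipeline_config]; `config$validate$n_replicates` and
#'   `config$validate$n_null` control the study counts.
#' @param response Response to validate (default `"exponent"`).
#' @return Invisibly, a list with per-replicate estimates and the summary
#'   (bias, relative bias, coverage, and null familywise rate when
#'   requested).
#' @export
cmd_validate <- function(config = pipeline_config(), response = "exponent") {
  dir <- .ensure_dir(config$output_dir)
  base_seed <- .stage_seed(config$seed, "validate")
  n_rep <- config$validate$n_replicates
  n_null <- config$validate$n_null
  true_beta <- config$generator$effects[[response]]$arousal
  est <- se <- df <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    gen <- config$generator
    gen$seed <- (base_seed + i) %% 2147483647L
    study <- generate_study(gen)
    flt <- filter_trials(study$records, config$validate$min_alpha_trials)
    fit <- fit_global_lmm(flt$records, response)
    row <- fit$fixed_effects[fit$fixed_effects$term == "arousal", ]
    est[i] <- row$estimate; se[i] <- row$se; df[i] <- row$df
  }
  crit <- stats::qt(0.975, df)
  covered <- abs(est - true_beta) <= crit * se
  summary <- list(response = response, n_replicates = n_rep,
                  true_arousal_effect = true_beta,
                  mean_estimate = mean(est),
                  bias = mean(est) - true_beta,
                  relative_bias = (mean(est) - true_beta) /
                    ifelse(true_beta != 0, true_beta, NA),
                  ci_coverage = mean(covered))
  if (n_null > 0) {
    any_sig <- logical(n_null)
    for (i in seq_len(n_null)) {
      gen <- config$generator
      gen$seed <- (base_seed + 10000L + i) %% 2147483647L
      for (r in names(gen$effects))
        gen$effects[[r]][c("arousal", "valence", "interaction")] <-
          list(0, 0, 0)
      study <- generate_study(gen)
      flt <- filter_trials(study$records, config$validate$min_alpha_trials)
      fit <- fit_global_lmm(flt$records, response)
      fam <- fit$f_tests[fit$f_tests$term %in%
                           c("arousal", "valence", "arousal:valence"), ]
      any_sig[i] <- any(holm_adjust(fam$p) < 0.05)
    }
    summary$null_familywise_rate <- mean(any_sig)
    summary$n_null <- n_null
  }
  jsonlite::write_json(summary, file.path(dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_provenance(config, file.path(dir, "validate_provenance.json"),
                    "validate", base_seed)
  .log_msg(config, "INFO", "validate: coverage ",
           round(summary$ci_coverage, 3), ", relative bias ",
           signif(summary$relative_bias, 3))
  invisible(list(estimates = data.frame(estimate = est, se = se, df = df,
                                        covered = covered),
                 summary = summary))
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `sweep`, `synth`, `parameterize`, `stats` or
#' `validate` with `--config`, `--seed`, `--out` and input-path options.
#' Installed as an executable script under `inst/cli/ctspec.R`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the subcommand's result.
#' @export
ctspec_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: ctspec.R <simulate|sweep|synth|parameterize|stats|validate>",
        "[--config FILE] [--seed N] [--out DIR] [--input FILE]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML pipeline configuration"),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "global seed override"),
    optparse::make_option("--out", type = "character", default = NULL,
                          help = "output directory override"),
    optparse::make_option("--input", type = "character", default = NULL,
                          help = "input table (parameterize/stats)")))
  opts <- optparse::parse_args(parser, args = args[-1])
  config <- pipeline_config(opts$config)
  if (!is.null(opts$seed)) config$seed <- opts$seed
  if (!is.null(opts$out)) config$output_dir <- opts$out
  res <- switch(cmd,
    simulate = cmd_simulate(config),
    sweep = cmd_sweep(config),
    synth = cmd_synth(config),
    parameterize = {
      if (is.null(opts$input)) stop("parameterize needs --input")
      cmd_parameterize(opts$input, config)
    },
    stats = {
      if (is.null(opts$input)) stop("stats needs --input")
      cmd_stats(opts$input, config)
    },
    validate = cmd_validate(config),
    stop("unknown subcommand: ", cmd))
  invisible(res)
}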