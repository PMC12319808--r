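# Shared fixtures, all generated in code.

# spectrum following the log-additive aperiodic + Gaussian model exactly
model_spectrum <- function(offset = 2, exponent = 1.5, peaks = list(),
                           freqs = seq(3, 45, by = 0.05)) {
  logp <- offset - exponent * log10(freqs)
  for (p in peaks)
    logp <- logp + p$power * exp(-(freqs - p$center)^2 / (2 * p$width^2))
  power_spectrum(freqs, 10^logp)
}

# short, cheap simulation configuration for structural tests
quick_sim_config <- function(...) {
  sim_config(duration = 12, transient = 2, seed = 42, ...)
}

# small TrialRecord table with known structure, no randomness
toy_records <- function() {
  data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 4),
    trial_id = rep(paste0("t", 1:4), 3),
    arousal = rep(c(2, 4, 6, 8), 3),
    valence = rep(c(3, 5, 7, 5), 3),
    task_exponent = rep(1.5, 12), pre_exponent = rep(1.4, 12),
    task_offset = rep(1.2, 12), pre_offset = rep(1.1, 12),
    task_alpha = rep(0.5, 12), pre_alpha = rep(0.6, 12),
    stringsAsFactors = FALSE)
}

# expand a study's records into per-cluster rows, adding a cluster-specific
# arousal effect on the task exponent for `hot_cluster`
clusterize_records <- function(records, clusters = c("central", "frontal",
                                                     "parietal"),
                               hot_cluster = "central", hot_effect = 0,
                               cluster_noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(clusters, function(cl) {
    d <- records
    d$cluster <- cl
    extra <- if (cl == hot_cluster) hot_effect * d$arousal else 0
    d$task_exponent <- d$task_exponent + extra +
      rnorm(nrow(d), 0, cluster_noise_sd)
    d
  }))
  rownames(out) <- NULL
  out
}
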