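test_that("Holm adjustment matches the hand-enumerated step-down", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "within")
  expect_error(holm_adjust(c(0.5, NA)), "finite")
})

test_that("Holm output dominates raw p, is below Bonferroni, and is
          permutation-equivariant", {
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    h <- holm_adjust(p)
    expect_true(all(h >= p))
    expect_true(all(h <= pmin(length(p) * p, 1)))
    expect_true(all(h <= 1))
    perm <- sample(seq_along(p))
    expect_equal(holm_adjust(p[perm]), h[perm])
  }
})

test_that("trial filtering applies the stated exclusion rules", {
  rec <- toy_records()
  rec$task_exponent[5] <- -0.3
  out <- filter_trials(rec, min_alpha_trials = 2)
  expect_equal(nrow(out$records), 11)
  expect_equal(out$exclusions$reason, "non-positive task exponent")
  expect_equal(out$exclusions$subject_id, "s2")

  rec2 <- toy_records()
  rec2$task_alpha[rec2$subject_id == "s3"] <- NA
  out2 <- filter_trials(rec2, min_alpha_trials = 2)
  expect_false("s3" %in% out2$records$subject_id)
  expect_true(any(grepl("alpha peak", out2$exclusions$reason)))

  clean <- filter_trials(toy_records(), min_alpha_trials = 2)
  expect_equal(nrow(clean$records), 12)
  expect_equal(nrow(clean$exclusions), 0)

  all_bad <- toy_records()
  all_bad$task_alpha <- NA
  expect_error(filter_trials(all_bad, min_alpha_trials = 1), "all subjects")
})

test_that("cluster PCA reduction handles rank-1, generic and singleton cases", {
  t <- seq(0, 2, by = 0.01)
  # two perfectly correlated channels: loadings equal, series proportional
  base <- sin(2 * pi * 3 * t)
  ep <- rbind(C3 = base, Cz = 2 * base, C4 = base * 0 + 5)
  red <- cluster_pca_reduce(ep, list(central = c("C3", "Cz")))
  expect_equal(red$central$loadings[["C3"]] * 2,
               red$central$loadings[["Cz"]] * 1, tolerance = 1e-8)
  cc <- cor(red$central$series, base)
  expect_equal(abs(cc), 1, tolerance = 1e-10)
  # orthogonal sinusoids of unequal variance: PC1 is the stronger channel
  ep2 <- rbind(P3 = 3 * sin(2 * pi * 5 * t), P4 = sin(2 * pi * 8 * t))
  red2 <- cluster_pca_reduce(ep2, list(parietal = c("P3", "P4")))
  expect_gt(abs(red2$parietal$loadings[["P3"]]), 0.99)
  expect_lt(abs(red2$parietal$loadings[["P4"]]), 0.1)
  # hand eigendecomposition of the 2x2 covariance agrees
  ev <- eigen(cov(t(ep2 - rowMeans(ep2))))$vectors[, 1]
  expect_equal(abs(sum(ev * red2$parietal$loadings)), 1, tolerance = 1e-8)
  # single-channel cluster passes through
  ep3 <- rbind(T7 = base)
  red3 <- cluster_pca_reduce(ep3, list(temporal_left = "T7"))
  expect_equal(red3$temporal_left$series, base)
  expect_equal(unname(red3$temporal_left$loadings), 1)
  expect_error(cluster_pca_reduce(base, cluster_map()), "matrix")
})

test_that("degenerate mixed-model data reproduce least-squares coefficients", {
  set.seed(3)
  n <- 120
  d <- data.frame(subject_id = rep(c("a", "b", "c"), each = 40),
                  trial_id = as.character(1:n),
                  arousal = runif(n, 1, 9), valence = runif(n, 1, 9))
  d$pre_exponent <- runif(n, 1, 2)
  d$task_exponent <- 0.5 + 0.3 * d$pre_exponent + 0.02 * d$arousal -
    0.01 * d$valence + 0.002 * d$arousal * d$valence + rnorm(n, 0, 1e-6)
  d$task_alpha <- 0.5
  fit <- fit_global_lmm(d, "exponent")
  ols <- coef(lm(task_exponent ~ pre_exponent + arousal * valence, data = d))
  expect_equal(fit$fixed_effects$estimate, unname(ols), tolerance = 1e-4)
})

test_that("Satterthwaite denominator df fall in the admissible range", {
  study <- generate_study(generator_config(n_subjects = 12, n_trials = 20,
                                           seed = 21))
  fit <- fit_global_lmm(study$records, "exponent")
  rank <- nrow(fit$fixed_effects)
  expect_true(all(fit$f_tests$den_df >= fit$n_subjects - rank))
  expect_true(all(fit$f_tests$den_df <= fit$n_obs - rank))
  expect_true(all(fit$f_tests$f >= 0))
  expect_true(all(fit$f_tests$p >= 0 & fit$f_tests$p <= 1))
})

test_that("permuting arousal within subject centers its estimate on zero", {
  study <- generate_study(generator_config(n_subjects = 16, n_trials = 30,
                                           seed = 31))
  ests <- sapply(1:8, function(i) {
    d <- study$records
    set.seed(100 + i)
    d$arousal <- unlist(tapply(d$arousal, d$subject_id, sample),
                        use.names = FALSE)
    f <- fit_global_lmm(d, "exponent")
    row <- f$fixed_effects[f$fixed_effects$term == "arousal", ]
    c(row$estimate, row$se)
  })
  z <- ests[1, ] / ests[2, ]
  expect_lt(abs(mean(z)), 2 / sqrt(8) * 2.5)
})

test_that("single-cluster interaction model collapses to the global model", {
  study <- generate_study(generator_config(n_subjects = 10, n_trials = 25,
                                           seed = 41))
  rec <- study$records
  rec$cluster <- "central"
  g <- fit_global_lmm(rec, "exponent")
  cl <- fit_cluster_lmm(rec, "exponent")
  ga <- g$fixed_effects$estimate[g$fixed_effects$term == "arousal"]
  ca <- cl$contrasts$estimate[grepl("arousal", cl$contrasts$term)]
  expect_equal(ca, ga, tolerance = 1e-6)
  expect_error(fit_cluster_lmm(study$records, "exponent"), "cluster")
})

test_that("a cluster-specific arousal effect lands on the right contrast", {
  study <- generate_study(generator_config(n_subjects = 14, n_trials = 30,
                                           seed = 51))
  rec <- clusterize_records(study$records, hot_cluster = "central",
                            hot_effect = 0.06, seed = 2)
  fit <- fit_cluster_lmm(rec, "exponent")
  ar <- fit$contrasts[grepl("arousal", fit$contrasts$term), ]
  hot <- grepl("central", ar$term)
  expect_equal(sum(hot), 1)
  # the hot cluster carries the largest arousal slope and is significant
  expect_equal(which.max(ar$estimate), which(hot))
  expect_lt(ar$p_holm[hot], 0.05)
  expect_true(all(ar$p_holm >= ar$p - 1e-12))
})

test_that("mixed-model export writes JSON and table-shaped CSV", {
  study <- generate_study(generator_config(n_subjects = 8, n_trials = 15,
                                           seed = 61))
  fit <- fit_global_lmm(study$records, "offset")
  f <- tempfile(fileext = ".json"); csv <- tempfile(fileext = ".csv")
  write_lmm_fit(fit, f, csv)
  back <- jsonlite::read_json(f)
  expect_equal(back$n_subjects, 8)
  expect_equal(length(back$fixed_effects), nrow(fit$fixed_effects))
  tab <- read.csv(csv)
  expect_true(all(c("term", "f", "p") %in% names(tab)))
})
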