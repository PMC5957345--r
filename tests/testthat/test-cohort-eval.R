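test_that("two-proportion chi-squared test matches the closed form", {
  # identical proportions: statistic 0, p = 1, and symmetry
  t0 <- two_proportion_test(30, 100, 15, 50)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  # hand-computed Pearson statistic for 90/100 vs 50/100:
  # pooled p = 0.7, chi2 = (0.9-0.5)^2 / (0.7*0.3*(1/100+1/100))
  tt <- two_proportion_test(90, 100, 50, 100)
  chi2 <- (0.9 - 0.5)^2 / (0.7 * 0.3 * (1 / 100 + 1 / 100))
  expect_equal(tt$statistic, chi2, tolerance = 1e-12)
  expect_equal(tt$p_value, pchisq(chi2, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # symmetric in group order
  ts <- two_proportion_test(50, 100, 90, 100)
  expect_equal(ts$p_value, tt$p_value)
  expect_error(two_proportion_test(1, 0, 1, 2), "zero trials")
})

test_that("rank tests match exhaustive small-sample enumeration", {
  # unpaired: enumerate all C(8,4) rank splits of 4-vs-4 distinct values
  a <- c(1.2, 3.4, 5.1, 7.9); b <- c(2.2, 4.6, 6.3, 8.8)
  got <- rank_test(a, b)
  r <- rank(c(a, b))
  w_obs <- sum(r[1:4]) - 4 * 5 / 2                 # Mann-Whitney U of group a
  splits <- utils::combn(8, 4)
  u_null <- apply(splits, 2, function(s) sum(r[s]) - 4 * 5 / 2)
  p_enum <- mean(abs(u_null - 8) >= abs(w_obs - 8))  # U symmetric around n1*n2/2
  expect_equal(got$p_value, p_enum, tolerance = 1e-12)

  # paired signed-rank: enumerate all 2^7 sign assignments
  x <- c(0.5, 1.1, -0.4, 2.2, 0.9, -1.5, 0.3)
  y <- rep(0, 7)
  gotp <- rank_test(x, y, paired = TRUE)
  ar <- rank(abs(x))
  v_obs <- sum(ar[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 7))
  v_null <- as.matrix(signs) %*% ar
  mu <- sum(ar) / 2
  p_enum_p <- mean(abs(v_null - mu) >= abs(v_obs - mu) - 1e-12)
  expect_equal(gotp$p_value, p_enum_p, tolerance = 1e-12)

  # behavioral extremes
  set.seed(2)
  same <- rnorm(30)
  expect_gt(rank_test(same, same)$p_value, 0.9)
  expect_lt(rank_test(rnorm(50), rnorm(50, 10))$p_value, 1e-3)
  expect_error(rank_test(1:3, 1:4, paired = TRUE), "equal-length")
  expect_error(rank_test(c(1, 2), c(1, 2), paired = TRUE), "degenerate")
})

test_that("group-wise rates partition the cohort and match the global report", {
  cc <- canonical()
  v <- cc$v12
  global <- evaluate_verifier(v$model, v$operating_point, cc$test)

  # one all-encompassing group reproduces the global rates
  g1 <- grouped_performance(v$model, v$operating_point, cc$test,
                            group_spec("age_band", bins = numeric(0)))
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$tar, global$tar)
  expect_equal(g1$trr, global$trr)
  expect_equal(g1$tvr, global$tvr)

  # gender split partitions the pair counts exactly
  gg <- grouped_performance(v$model, v$operating_point, cc$test,
                            group_spec("gender"))
  expect_equal(sum(gg$n_equal), global$n_equal)
  expect_equal(sum(gg$n_different), global$n_different)
  expect_true(all(gg$tvr >= 0 & gg$tvr <= 100, na.rm = TRUE))

  # age and HR-change groupings stay exhaustive
  ga <- grouped_performance(v$model, v$operating_point, cc$test,
                            group_spec("age_band"))
  expect_equal(sum(ga$n_equal), global$n_equal)
  gd <- grouped_performance(v$model, v$operating_point, cc$test,
                            group_spec("hr_delta_band"))
  expect_equal(sum(gd$n_different), global$n_different)
})

test_that("a noisier subgroup shows lower acceptance in grouped evaluation", {
  quiet <- simulate_cohort(10, seed = 31)
  harsh <- simulate_cohort(10, var = session_variability(amp_jitter = 0.35,
                                                        time_jitter_ms = 4,
                                                        noise_uv = 80),
                           seed = 32)
  relabel <- function(sim, prefix, sex) {
    sim$covariates$subject_id <- sub("SYN", prefix, sim$covariates$subject_id)
    sim$covariates$sex <- sex
    sim$beats <- lapply(sim$beats, function(b) {
      b$subject_id <- sub("SYN", prefix, b$subject_id); b
    })
    sim
  }
  quiet <- relabel(quiet, "LOW", "M")
  harsh <- relabel(harsh, "HIG", "F")
  # interleave so both subgroups appear in training and test halves
  ord <- as.vector(rbind(1:10, 11:20))
  beats <- c(quiet$beats, harsh$beats)
  beat_of <- function(k) beats[c(2 * k - 1, 2 * k)]
  cohort <- extract_cohort_patterns(
    unlist(lapply(ord, beat_of), recursive = FALSE),
    covariates = rbind(quiet$covariates, harsh$covariates))
  ds <- build_pair_datasets(cohort, rng_seed = 5)
  v <- qrs_verifier(ds$train, "all")
  gg <- grouped_performance(v$model, v$operating_point, ds$test,
                            group_spec("gender"))
  expect_lt(gg$tar[gg$group == "F"], gg$tar[gg$group == "M"] + 1e-9)
})

test_that("sample-size sweep reproduces the global report and combinatorics", {
  cc <- canonical()
  v <- cc$v12
  n_test <- length(unique(c(cc$test$id_s1, cc$test$id_s2)))
  global <- evaluate_verifier(v$model, v$operating_point, cc$test)

  sw <- sample_size_sweep(v$model, v$operating_point, cc$test,
                          sizes = c(n_test - 1, n_test), max_subsets = 200)
  full <- sw[sw$size == n_test, ]
  expect_equal(full$n_subsets, 1L)
  expect_true(full$exhaustive)
  expect_equal(full$tvr_mean, global$tvr)
  expect_equal(full$tvr_min, full$tvr_max)
  # leave-one-out: exactly n subsets when the cap allows
  expect_equal(sw$n_subsets[sw$size == n_test - 1], n_test)

  expect_error(sample_size_sweep(v$model, v$operating_point, cc$test,
                                 sizes = n_test + 1), "range error")
})

test_that("the min-max performance envelope narrows with subset size", {
  cc <- canonical()
  v <- cc$v12
  widths <- sapply(1:5, function(seed) {
    sw <- sample_size_sweep(v$model, v$operating_point, cc$test,
                            sizes = c(10, 45), max_subsets = 150,
                            rng_seed = seed)
    sw$tvr_max - sw$tvr_min
  })
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
})
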