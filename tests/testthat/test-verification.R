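test_that("pair-scheme counts follow the closed-form combinatorics", {
  # smallest valid cohort and a fully enumerable case
  c2 <- pair_scheme_counts(2)
  expect_equal(c2$train_equal, 1); expect_equal(c2$train_different, 1)
  expect_equal(c2$test_equal, 1); expect_equal(c2$test_different, 1)
  c4 <- pair_scheme_counts(4)
  expect_equal(c4$train_equal, 2); expect_equal(c4$train_different, 2)
  expect_equal(c4$test_equal, 2); expect_equal(c4$test_different, 10)
  expect_equal(c4$different_total, 12)
})

test_that("pair dataset construction conserves and partitions all pairs", {
  sim <- simulate_cohort(6, seed = 23)
  cohort <- extract_cohort_patterns(sim$beats, covariates = sim$covariates)
  ds <- build_pair_datasets(cohort, rng_seed = 4)
  tr <- ds$train; te <- ds$test
  expect_s3_class(tr, "pair_dataset")
  expect_equal(attr(tr, "role"), "training")
  # balanced training: 3 equal + 3 different, all from the first half
  expect_equal(sum(tr$label == "equal"), 3L)
  expect_equal(sum(tr$label == "different"), 3L)
  first_half <- cohort$subject_ids[1:3]
  expect_true(all(tr$id_s1 %in% first_half & tr$id_s2 %in% first_half))
  # conservation: 6 equal pairs and 6*5 = 30 different pairs, no overlap
  expect_equal(sum(te$label == "equal"), 3L)
  expect_equal(sum(te$label == "different"), 30L - 3L)
  key <- function(d) paste(d$id_s1, d$id_s2)
  expect_length(intersect(key(tr), key(te)), 0L)
  all_keys <- as.vector(outer(cohort$subject_ids, cohort$subject_ids, paste))
  expect_setequal(c(key(tr), key(te)), all_keys)       # 6 equal + 30 different
  expect_length(c(key(tr), key(te)), 36L)
  # labels encode identity equality
  expect_equal(tr$label == "equal", tr$id_s1 == tr$id_s2)
  expect_equal(te$label == "equal", te$id_s1 == te$id_s2)
  # same seed reproduces the same balanced draw
  ds2 <- build_pair_datasets(cohort, rng_seed = 4)
  expect_equal(ds2$train, ds$train)

  # incomplete subject is rejected
  broken <- cohort; broken$s2[[2]] <- NULL
  expect_error(build_pair_datasets(broken), "both S1 and S2|incomplete")
})

test_that("LDA separates separable classes and is null on permuted labels", {
  set.seed(101)
  n <- 1000
  x <- rbind(matrix(rnorm(2 * n, 0, 0.1), n, 2),
             matrix(rnorm(2 * n, 10, 0.1), n, 2))
  colnames(x) <- c("tEQU_I", "aDIF_I")
  labs <- rep(c("different", "equal"), each = n)
  ds <- make_pair_dataset(x, labs)
  m <- fit_lda(ds, c("tEQU_I", "aDIF_I"))
  expect_equal(roc_auc(compute_roc(m, ds)), 1.0)

  # permuted labels: training AUC within 0.5 +/- 0.05
  ds_perm <- make_pair_dataset(x, sample(labs))
  m2 <- fit_lda(ds_perm, c("tEQU_I", "aDIF_I"))
  expect_lt(abs(roc_auc(compute_roc(m2, ds_perm)) - 0.5), 0.05)
})

test_that("uninformative features get negligible discriminant weight", {
  set.seed(7)
  n <- 2000
  informative <- c(rnorm(n, 0, 1), rnorm(n, 4, 1))
  flat <- rnorm(2 * n, 50, 1)                 # same distribution in both classes
  x <- cbind(tEQU_I = informative, aDIF_I = flat)
  ds <- make_pair_dataset(x, rep(c("different", "equal"), each = n))
  m <- fit_lda(ds, colnames(x))
  expect_lt(abs(m$weights["aDIF_I"] / m$weights["tEQU_I"]), 0.05)
})

test_that("discriminant scores agree with the reference LDA implementation", {
  set.seed(15)
  n <- 300
  x <- rbind(matrix(rnorm(4 * n, 0, 1), n, 4),
             matrix(rnorm(4 * n, 1.5, 1), n, 4))
  colnames(x) <- c("tEQU_I", "aDIF_I", "tEQU_II", "aDIF_II")
  labs <- rep(c("different", "equal"), each = n)
  ds <- make_pair_dataset(x, labs)
  m <- fit_lda(ds, colnames(x))
  ref <- MASS::lda(x, grouping = labs)
  ref_scores <- as.numeric(predict(ref)$x)
  # identical ranking up to orientation => identical ROC
  ours <- lda_scores(m, ds)
  rho <- cor(ours, ref_scores, method = "spearman")
  expect_equal(abs(rho), 1, tolerance = 1e-12)
  expect_equal(auc_rank_test_helper(ours, labs),
               auc_rank_test_helper(ref_scores * sign(rho), labs),
               tolerance = 1e-12)
})

test_that("singular covariance falls back to shrinkage with a warning", {
  set.seed(3)
  n <- 50
  a <- rnorm(2 * n)
  x <- cbind(tEQU_I = a, aDIF_I = a, tEQU_II = rnorm(2 * n))  # exact collinearity
  ds <- make_pair_dataset(x, rep(c("equal", "different"), n))
  expect_warning(m <- fit_lda(ds, colnames(x)), "shrinkage")
  expect_gt(m$shrinkage_gamma, 0)
  expect_true(all(is.finite(m$weights)))
})

test_that("stepwise selection keeps informative features, drops noise and duplicates", {
  set.seed(55)
  n <- 1000
  signal <- c(rnorm(n, 0, 1), rnorm(n, 3, 1))
  noise <- rnorm(2 * n)
  x <- cbind(tEQU_I = signal, aDIF_I = noise)
  ds <- make_pair_dataset(x, rep(c("different", "equal"), each = n))
  sel <- stepwise_select(ds, colnames(x))
  expect_equal(sel[1], "tEQU_I")
  expect_equal(sel, "tEQU_I")                # noise adds <= epsilon AUC

  # candidate order only matters through the canonical tie-break
  expect_equal(stepwise_select(ds, rev(colnames(x))), sel)

  # a duplicated feature cannot change the selected model's AUC
  x2 <- cbind(x, tEQU_I_copy = signal)
  ds2 <- make_pair_dataset(x2, rep(c("different", "equal"), each = n))
  sel2 <- stepwise_select(ds2, colnames(x2))
  auc1 <- roc_auc(compute_roc(fit_lda(ds, sel), ds))
  auc2 <- roc_auc(compute_roc(suppressWarnings(fit_lda(ds2, sel2)), ds2))
  expect_equal(auc2, auc1, tolerance = 1e-9)

  # single-lead configuration bounds the candidate set to 2 features
  expect_lte(length(stepwise_select(canonical()$train, lead_feature_set("II"))), 2L)
})

test_that("ROC sweep, trapezoid AUC and rank statistic coincide", {
  set.seed(77)
  n <- 500
  scores <- c(rnorm(n, 1), rnorm(n, 0))
  labs <- rep(c("equal", "different"), each = n)
  x <- cbind(tEQU_I = scores)
  ds <- make_pair_dataset(x, labs)
  m <- fit_lda(ds, "tEQU_I")
  roc <- compute_roc(m, ds)
  # curve is monotone along the sweep
  expect_true(all(diff(roc$tar) >= 0))
  expect_true(all(diff(roc$trr) <= 0))
  # trapezoid AUC equals the O(n^2) pairwise rank count with tie credit
  s <- lda_scores(m, ds)
  pos <- s[labs == "equal"]; neg <- s[labs == "different"]
  brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(roc), brute, tolerance = 1e-12)

  # AUC is invariant under strictly monotone transforms of the score
  ds_t <- ds; ds_t$tEQU_I <- exp(ds$tEQU_I / 50)
  m_t <- fit_lda(ds_t, "tEQU_I")
  expect_equal(roc_auc(compute_roc(m_t, ds_t)), roc_auc(roc), tolerance = 1e-12)

  # degenerate cases
  ds_tie <- make_pair_dataset(cbind(tEQU_I = rep(1, 2 * n)), labs)
  m_tie <- suppressWarnings(fit_lda(ds_tie, "tEQU_I"))
  expect_equal(roc_auc(compute_roc(m_tie, ds_tie)), 0.5)
  expect_error(compute_roc(m, ds[ds$label == "equal", ]), "single class")
})

test_that("EER operating point balances TAR and TRR by interpolation", {
  set.seed(9)
  n <- 1000
  scores <- c(rnorm(n, 2), rnorm(n, -2))     # symmetric classes
  labs <- rep(c("equal", "different"), each = n)
  ds <- make_pair_dataset(cbind(tEQU_I = scores), labs)
  m <- fit_lda(ds, "tEQU_I")
  roc <- compute_roc(m, ds)
  op <- pick_eer_operating_point(roc)
  expect_lt(abs(op$tar - op$trr), 1e-9)

  # interpolated EER matches a dense 1e5-threshold sweep within 0.1 points
  s <- lda_scores(m, ds)
  dense_thr <- seq(min(s) - 1e-9, max(s) + 1e-9, length.out = 1e5)
  pos <- s[labs == "equal"]; neg <- s[labs == "different"]
  dense_gap <- abs(100 * sapply(dense_thr, function(t) mean(pos >= t)) -
                   100 * sapply(dense_thr, function(t) mean(neg < t)))
  k <- which.min(dense_gap)
  dense_tar <- 100 * mean(pos >= dense_thr[k])
  expect_lt(abs(op$tar - dense_tar), 0.1)

  # degenerate one-threshold ROC returns that threshold
  one <- structure(data.frame(threshold = c(Inf, 0), tar = c(0, 100),
                              trr = c(100, 0)),
                   class = c("roc_curve", "data.frame"))
  op1 <- pick_eer_operating_point(one)
  expect_true(is.finite(op1$threshold))
})

test_that("verification rates follow their definitions at a fixed threshold", {
  # 10 equal pairs (9 accepted), 10 different (8 rejected)
  scores <- c(rep(1, 9), -1, rep(-1, 8), 1, 1)
  labs <- c(rep("equal", 10), rep("different", 10))
  ds <- make_pair_dataset(cbind(tEQU_I = scores), labs)
  m <- structure(list(selected_features = "tEQU_I",
                      weights = c(tEQU_I = 1), intercept = 0,
                      shrinkage_gamma = 0),
                 class = "lda_model")
  op <- structure(list(threshold = 0, tar = NA, trr = NA),
                  class = "operating_point")
  rep1 <- evaluate_verifier(m, op, ds)
  expect_equal(rep1$tar, 90)
  expect_equal(rep1$trr, 80)
  expect_equal(rep1$tvr, 85)
  # accept-everything threshold
  op_all <- structure(list(threshold = -10, tar = NA, trr = NA),
                      class = "operating_point")
  rep2 <- evaluate_verifier(m, op_all, ds)
  expect_equal(c(rep2$tar, rep2$trr, rep2$tvr), c(100, 0, 50))
  # EER = 100 - TVR whenever TAR = TRR
  expect_equal(100 - rep1$tvr, (100 - rep1$tar + 100 - rep1$trr) / 2)
  expect_error(evaluate_verifier(m, op, ds[ds$label == "equal", ]), "undefined")
})

test_that("feature tables round-trip through CSV and map flexible schemas", {
  ds <- canonical()$train[1:20, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ds, path)
  back <- load_feature_table(path)
  expect_s3_class(back, "pair_dataset")
  expect_equal(nrow(back), 20L)
  expect_equal(back$label, ds$label)
  for (f in feature_names())
    expect_equal(back[[f]], ds[[f]], tolerance = 5e-5)  # 4-decimal writer

  # toy 3-row CSV with renamed columns still maps
  toy <- utils::read.csv(path, check.names = FALSE)[1:3, ]
  names(toy)[names(toy) == "label"] <- "identity"
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(toy, p2, row.names = FALSE)
  got <- load_feature_table(p2)
  expect_equal(nrow(got), 3L)
  expect_equal(as.character(got$label), as.character(ds$label[1:3]))

  # missing feature columns produce a column-mapping error naming them
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(toy[, !grepl("aDIF_V6", names(toy))], p3, row.names = FALSE)
  expect_error(load_feature_table(p3), "aDIF_V6")
})

test_that("verifier object exposes the standard modelling interface", {
  cc <- canonical()
  v <- cc$v12
  expect_s3_class(v, "qrs_verifier")
  expect_output(print(v), "verifier")
  s <- summary(v)
  expect_lt(abs(s$train_tar - s$train_trr), 0.5)
  cf <- coef(v)
  expect_true("(intercept)" %in% names(cf))
  sc <- predict(v, cc$test)
  expect_length(sc, nrow(cc$test))
  dec <- predict(v, cc$test, type = "decision")
  expect_s3_class(dec, "factor")
  expect_equal(as.vector(table(dec)[["accept"]]),
               sum(sc >= v$operating_point$threshold))

  # JSON round-trip preserves scoring and decisions
  path <- withr::local_tempfile(fileext = ".json")
  write_verifier_json(v, path)
  v2 <- read_verifier_json(path)
  expect_equal(predict(v2, cc$test), sc, tolerance = 1e-9)
  expect_equal(predict(v2, cc$test, type = "decision"), dec)
})
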