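# Literal per-cell reference implementations of the binary matching
# definitions, kept deliberately loop-based and independent of the package's
# vectorized code paths.

# Occupancy predicate, cell by cell: a cell is set when its row center lies
# within +/- tolerance of the pattern value at the column or at either
# clamped time neighbor; each column is then filled to contiguity between
# its extreme set rows.
oracle_binarize <- function(pattern, grid = grid_spec()) {
  tol <- grid$tolerance_steps * grid$da + 1e-9
  cells <- matrix(FALSE, grid$n_cols, grid$n_rows)
  for (ti in seq_len(grid$n_cols)) {
    neigh <- pattern[pmin(pmax(c(ti - 1L, ti, ti + 1L), 1L), length(pattern))]
    for (aj in seq_len(grid$n_rows)) {
      centre <- grid$row_centers[aj]
      for (v in neigh) if (abs(centre - v) <= tol) cells[ti, aj] <- TRUE
    }
    occ <- which(cells[ti, ])
    if (length(occ)) cells[ti, min(occ):max(occ)] <- TRUE
  }
  cells
}

# Column-wise AND overlap count, scaled to percent of the pattern length.
oracle_tequ <- function(cells_a, cells_b, grid = grid_spec()) {
  n <- 0L
  for (ti in seq_len(grid$n_cols)) {
    hit <- FALSE
    for (aj in seq_len(grid$n_rows))
      if (cells_a[ti, aj] && cells_b[ti, aj]) hit <- TRUE
    if (hit) n <- n + 1L
  }
  n * grid$dt_ms / 100 * 100
}

# Nearest row center of a value; equidistant boundary values go to the
# lower row.
oracle_row <- function(v, grid) {
  d <- abs(grid$row_centers - v)
  min(which(d <= min(d) + 1e-12))
}

# NAND count restricted to the rows enclosed between the two pattern values
# per column, scaled so full-range disagreement at every step gives 100.
oracle_adif <- function(cells_a, cells_b, pa, pb, grid = grid_spec()) {
  count <- 0L
  for (ti in seq_len(grid$n_cols)) {
    r1 <- oracle_row(min(pa[ti], pb[ti]), grid)
    r2 <- oracle_row(max(pa[ti], pb[ti]), grid)
    for (aj in r1:r2)
      if (!(cells_a[ti, aj] && cells_b[ti, aj])) count <- count + 1L
  }
  count * (grid$dt_ms / 100) * (grid$da / 2) * 100
}

# Random smooth pattern normalized into [-1, 1] with max |value| = 1.
random_pattern <- function(n = 100L) {
  x <- cumsum(stats::rnorm(n))
  x <- stats::filter(c(x[3:1], x, x[n - 0:2]), rep(1 / 7, 7), sides = 2)
  x <- x[!is.na(x)][seq_len(n)]
  x <- x - x[1L]
  m <- max(abs(x))
  if (m == 0) x[n] <- 1 else x <- x / m
  x
}

# Pairwise rank AUC, brute force.
auc_rank_test_helper <- function(scores, labs) {
  pos <- scores[labs == "equal"]; neg <- scores[labs == "different"]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Wrap a plain feature matrix as the minimal pair_dataset the verifier
# functions need.
make_pair_dataset <- function(features, labels, role = "training") {
  df <- data.frame(id_s1 = sprintf("A%04d", seq_len(nrow(features))),
                   id_s2 = sprintf("B%04d", seq_len(nrow(features))),
                   label = factor(labels, levels = c("equal", "different")),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(features))
  structure(df, role = role, class = c("pair_dataset", "data.frame"))
}

# Canonical synthetic study conditions shared by the end-to-end tests:
# 100 subjects, default variability, seed 1, half split, computed once per
# test run.
canonical <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohort(100, seed = 1)
      cohort <- extract_cohort_patterns(sim$beats, covariates = sim$covariates)
      ds <- build_pair_datasets(cohort, rng_seed = 1)
      v12 <- qrs_verifier(ds$train, "all")
      cache <<- list(sim = sim, cohort = cohort, train = ds$train,
                     test = ds$test, v12 = v12)
    }
    cache
  }
})
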