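#' Time-amplitude grid for binary QRS approximation
#'
#' Defines the discretization of the 100 ms x [-1, 1] pattern plane. Columns
#' are 1 ms time steps (at the default `dt_ms = 1`); rows are amplitude bins
#' of width `da` with centers at `-1 + (j + 0.5) * da`, j = 0..n_rows-1 (80
#' rows at the default `da = 0.025`, i.e. a bin is 1.25% of the full [-1, 1]
#' range). `tolerance_steps` is the half-width of the occupancy band in
#' amplitude bins: a cell is occupied when its center lies within
#' `tolerance_steps * da` of the pattern value at the column or at either
#' neighboring time step, equalizing variations of +/-1 ms in time and
#' +/-2.5% of the amplitude range at the defaults.
#'
#' @param dt_ms Time resolution in ms; must divide 100.
#' @param da Amplitude resolution in normalized units; 2/da must be integer.
#' @param tolerance_steps Amplitude tolerance in units of `da` (default 2).
#' @return Object of class `grid_spec` with fields `dt_ms`, `da`,
#'   `tolerance_steps`, `n_cols`, `n_rows`, `row_centers`.
#' @export
grid_spec <- function(dt_ms = 1, da = 0.025, tolerance_steps = 2) {
  if (dt_ms <= 0 || abs(100 / dt_ms - round(100 / dt_ms)) > 1e-9)
    stop("dt_ms must be a positive divisor of 100 ms", call. = FALSE)
  if (da <= 0 || abs(2 / da - round(2 / da)) > 1e-9)
    stop("da must be a positive divisor of the 2-unit amplitude range",
         call. = FALSE)
  n_cols <- as.integer(round(100 / dt_ms))
  n_rows <- as.integer(round(2 / da))
  structure(list(dt_ms = dt_ms, da = da,
                 tolerance_steps = as.integer(tolerance_steps),
                 n_cols = n_cols, n_rows = n_rows,
                 row_centers = -1 + (seq_len(n_rows) - 0.5) * da),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows (dt = %g ms, da = %g, tol = %d bins)\n",
              x$n_cols, x$n_rows, x$dt_ms, x$da, x$tolerance_steps))
  invisible(x)
}

## Comparison slack: boundary hits of |center - value| <= tol are decided
## inclusively and consistently across the interval and brute-force paths.
EPS_GRID <- 1e-9

## Map amplitude values to 0-based row indices: nearest bin center, ties
## (values exactly on a bin boundary) toward the lower row.
value_to_row <- function(v, grid) {
  j <- ceiling((v + 1) / grid$da - EPS_GRID) - 1
  pmin(pmax(as.integer(j), 0L), grid$n_rows - 1L)
}

## 0-based row index of the lowest/highest bin center inside [lo, hi].
row_ge <- function(lo, grid) {
  j <- ceiling((lo + 1) / grid$da - 0.5 - EPS_GRID)
  pmin(pmax(as.integer(j), 0L), grid$n_rows - 1L)
}
row_le <- function(hi, grid) {
  j <- floor((hi + 1) / grid$da - 0.5 + EPS_GRID)
  pmin(pmax(as.integer(j), 0L), grid$n_rows - 1L)
}

## Per-column occupancy band [lo, hi] (0-based rows) of a pattern: the union
## of +/- tolerance bands around the value at the column and its clamped
## time neighbors, filled to contiguity between the extremes. Returns a
## 2 x n_cols matrix, or per-pattern when given a matrix of patterns.
pattern_band_rows <- function(pattern, grid) {
  sampled <- pattern_time_samples(pattern, grid)
  nb_min <- pmin(sampled, c(sampled[1L], sampled[-length(sampled)]),
                 c(sampled[-1L], sampled[length(sampled)]))
  nb_max <- pmax(sampled, c(sampled[1L], sampled[-length(sampled)]),
                 c(sampled[-1L], sampled[length(sampled)]))
  tol <- grid$tolerance_steps * grid$da
  rbind(lo = row_ge(nb_min - tol, grid), hi = row_le(nb_max + tol, grid))
}

## Column values of a 100-sample 1 ms pattern on a (possibly coarser) time
## grid: T(ti) = 1, 1+dt, ..., 100 ms -> 1-based sample indices.
pattern_time_samples <- function(pattern, grid) {
  if (length(pattern) != 100L)
    stop("pattern must have exactly 100 samples", call. = FALSE)
  idx <- as.integer(round(seq(1, 100, length.out = grid$n_cols)))
  pattern[idx]
}

#' Binarize a normalized QRS pattern into a time-amplitude occupancy matrix
#'
#' Transforms a 100-sample normalized lead pattern into an
#' `n_cols x n_rows` boolean matrix (100 x 80 at the default grid, 8000
#' cells, 1 kB per lead): cell (ti, aj) is occupied when the amplitude bin
#' center `aj` lies within `tolerance_steps * da` of the pattern value at
#' time ti or at either adjacent time step (clamped at the pattern ends),
#' with each column filled to contiguity between its band extremes. The
#' occupied band is the grey "approximation span" around the pattern trace:
#' it absorbs +/-1 ms timing and +/-2.5% amplitude variation of the
#' depolarization wavefront between recording sessions.
#'
#' @param pattern Numeric vector of 100 normalized samples in [-1, 1].
#' @param grid A [grid_spec()].
#' @param lead Optional lead name carried along for reporting.
#' @return Object of class `binary_pattern_matrix` with fields `grid`,
#'   `cells` (n_cols x n_rows logical, rows of the matrix = time columns),
#'   `band` (2 x n_cols row-interval representation) and `lead`.
#' @export
binarize <- function(pattern, grid = grid_spec(), lead = NA_character_) {
  pattern <- as.numeric(pattern)
  if (any(!is.finite(pattern)) || any(abs(pattern) > 1 + EPS_GRID))
    stop("normalization violation: pattern values must be finite and in [-1, 1]",
         call. = FALSE)
  band <- pattern_band_rows(pattern, grid)
  cells <- matrix(FALSE, grid$n_cols, grid$n_rows)
  rows <- .row(dim(cells)); cols <- .col(dim(cells))
  cells <- (cols - 1L) >= band["lo", rows] & (cols - 1L) <= band["hi", rows]
  structure(list(grid = grid, cells = cells, band = band, lead = lead),
            class = "binary_pattern_matrix")
}

#' @export
print.binary_pattern_matrix <- function(x, ...) {
  cat(sprintf("<binary_pattern_matrix>%s %d x %d, %d occupied cells\n",
              if (is.na(x$lead)) "" else paste0(" lead ", x$lead),
              x$grid$n_cols, x$grid$n_rows, sum(x$cells)))
  invisible(x)
}

check_same_grid <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  if (ga$n_cols != gb$n_cols || ga$n_rows != gb$n_rows ||
      ga$tolerance_steps != gb$tolerance_steps)
    stop("incompatible grids: both matrices must share the same grid_spec",
         call. = FALSE)
}

#' Matching time between two binary QRS matrices
#'
#' tEQU counts the time columns at which the two patterns' occupancy bands
#' overlap (the AND matrix has at least one occupied cell in the column),
#' expressed in percent of the 100 ms pattern length. 100% means the bands
#' meet at every 1 ms step; 0% means they never meet. Symmetric in its
#' arguments.
#'
#' @param a,b [binarize()] results on the same grid.
#' @return Percentage in [0, 100].
#' @export
compute_tequ <- function(a, b) {
  check_same_grid(a, b)
  lo <- pmax(a$band["lo", ], b$band["lo", ])
  hi <- pmin(a$band["hi", ], b$band["hi", ])
  sum(lo <= hi) * a$grid$dt_ms / 100 * 100
}

#' Mismatch area between two binary QRS matrices
#'
#' aDIF accumulates, per time column, the cells between the two patterns'
#' amplitudes (inclusive row range from the lower to the higher of the two
#' pattern values) at which the occupancy bands do NOT both cover the cell
#' (the NAND matrix restricted to the enclosed amplitude range), expressed
#' in percent of the full time-amplitude plane: one cell contributes
#' `dt_ms/100 * da/2 * 100`, so disagreement covering the full [-1, 1] range
#' at every time step yields exactly 100. Identical patterns yield 0.
#' Symmetric in the two patterns.
#'
#' @param a,b [binarize()] results on the same grid.
#' @param pa,pb The normalized 100-sample patterns that produced `a` and `b`
#'   (needed for the enclosed amplitude range).
#' @return Percentage in [0, 100].
#' @export
compute_adif <- function(a, b, pa, pb) {
  check_same_grid(a, b)
  grid <- a$grid
  va <- pattern_time_samples(as.numeric(pa), grid)
  vb <- pattern_time_samples(as.numeric(pb), grid)
  rmin <- value_to_row(pmin(va, vb), grid)
  rmax <- value_to_row(pmax(va, vb), grid)
  in_range <- rmax - rmin + 1L
  ## overlap of the two occupancy bands clipped to the enclosed range
  olo <- pmax(a$band["lo", ], b$band["lo", ], rmin)
  ohi <- pmin(a$band["hi", ], b$band["hi", ], rmax)
  overlap <- pmax(0L, ohi - olo + 1L)
  count <- sum(in_range - overlap)
  count * (grid$dt_ms / 100) * (grid$da / 2) * 100
}

#' Extract the 24 pattern-matching features for one subject pair
#'
#' Runs [binarize()], [compute_tequ()] and [compute_adif()] on each of the
#' 12 leads of a pair-normalized session pair: 12 x (tEQU, aDIF) = 24
#' features quantifying QRS waveform similarity in time and dissimilarity in
#' amplitude between the two recordings.
#'
#' @param s1,s2 Normalized [normalize_pair()] outputs (same lead order, same
#'   pair-shared scale factors).
#' @param grid A [grid_spec()].
#' @return Named numeric vector of 24 features in canonical order
#'   (`tEQU_I, aDIF_I, tEQU_II, ..., aDIF_V6`).
#' @export
extract_pair_features <- function(s1, s2, grid = grid_spec()) {
  stopifnot(inherits(s1, "qrs_pattern_set"), inherits(s2, "qrs_pattern_set"))
  if (!s1$normalized || !s2$normalized)
    stop("pattern sets must be pair-normalized first", call. = FALSE)
  out <- numeric(24)
  names(out) <- feature_names()
  for (li in seq_along(LEAD_NAMES)) {
    lead <- LEAD_NAMES[li]
    pa <- s1$patterns[, lead]; pb <- s2$patterns[, lead]
    ba <- binarize(pa, grid, lead); bb <- binarize(pb, grid, lead)
    out[2L * li - 1L] <- compute_tequ(ba, bb)
    out[2L * li] <- compute_adif(ba, bb, pa, pb)
  }
  out
}

#' Canonical feature-name order
#'
#' Lead order I..V6, `tEQU` before `aDIF` within each lead. This order also
#' defines the deterministic tie-break of stepwise feature selection.
#'
#' @return Character vector of 24 feature names.
#' @export
feature_names <- function() {
  as.vector(rbind(paste0("tEQU_", LEAD_NAMES), paste0("aDIF_", LEAD_NAMES)))
}
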