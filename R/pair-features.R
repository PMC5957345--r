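#' Align and window a whole two-session cohort
#'
#' Runs the per-beat pipeline (resample to 1000 Hz, cross-correlation
#' alignment to the lead-I reference, synchronized 100 ms window extraction)
#' over a list of average beats and groups the resulting pattern sets by
#' subject. Every subject must appear with both sessions.
#'
#' @param beats List of [average_beat()]s (both sessions of every subject).
#' @param reference A [reference_pattern()]; defaults to the package's
#'   canonical synthetic lead-I reference.
#' @param max_lag_ms Alignment search half-range in ms.
#' @param covariates Optional data.frame with `subject_id`, `age`, `sex`,
#'   `hr_s1`, `hr_s2`.
#' @return Object of class `qrs_cohort`: list with `subject_ids`, `s1`,
#'   `s2` (per-subject unnormalized `qrs_pattern_set`s) and `covariates`.
#' @export
extract_cohort_patterns <- function(beats, reference = default_reference(),
                                    max_lag_ms = 100, covariates = NULL) {
  sets <- lapply(beats, function(b) {
    b <- resample_to_1ms(b)
    fid <- align_to_reference(b, reference, max_lag_ms)
    extract_patterns(b, fid)
  })
  ids <- vapply(sets, `[[`, "", "subject_id")
  ses <- vapply(sets, `[[`, "", "session")
  subject_ids <- unique(ids)
  s1 <- s2 <- vector("list", length(subject_ids))
  for (k in seq_along(sets)) {
    i <- match(ids[k], subject_ids)
    if (ses[k] == "S1") s1[[i]] <- sets[[k]] else s2[[i]] <- sets[[k]]
  }
  miss <- subject_ids[vapply(s1, is.null, TRUE) | vapply(s2, is.null, TRUE)]
  if (length(miss))
    stop("incomplete subject(s), missing one session: ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(subject_ids = subject_ids, s1 = s1, s2 = s2,
                 covariates = covariates),
            class = "qrs_cohort")
}

#' @export
print.qrs_cohort <- function(x, ...) {
  cat(sprintf("<qrs_cohort> %d subjects x 2 sessions (12-lead QRS patterns)\n",
              length(x$subject_ids)))
  invisible(x)
}

#' Batch pair-feature computation over a cohort
#'
#' Computes the 24 matching features for many S2-vs-S1 subject pairs at
#' once. For every pair the two patterns are normalized jointly per lead
#' (onset-level shift, shared scale factor) exactly as in
#' [normalize_pair()], then matched on the row-interval representation of
#' their binary occupancy matrices; results are identical to the per-pair
#' [extract_pair_features()] path. Pairs are processed in chunks to bound
#' memory on large cohorts.
#'
#' @param cohort A [extract_cohort_patterns()] result.
#' @param pairs data.frame with integer columns `i` (S1 subject index) and
#'   `j` (S2 subject index).
#' @param grid A [grid_spec()].
#' @param chunk_size Pairs per processing block.
#' @return Numeric matrix, one row per pair, 24 columns ([feature_names()]).
#' @export
cohort_pair_features <- function(cohort, pairs, grid = grid_spec(),
                                 chunk_size = 20000L) {
  np <- nrow(pairs)
  out <- matrix(NA_real_, np, 24, dimnames = list(NULL, feature_names()))
  tol <- grid$tolerance_steps * grid$da
  idx <- as.integer(round(seq(1, 100, length.out = grid$n_cols)))
  nc <- grid$n_cols
  for (li in seq_along(LEAD_NAMES)) {
    lead <- LEAD_NAMES[li]
    A1 <- vapply(cohort$s1, function(p) (p$patterns[, lead] - p$onset_level[[lead]])[idx],
                 numeric(nc))
    A2 <- vapply(cohort$s2, function(p) (p$patterns[, lead] - p$onset_level[[lead]])[idx],
                 numeric(nc))
    nb <- function(A) {
      up <- rbind(A[1L, , drop = FALSE], A[-nc, , drop = FALSE])
      dn <- rbind(A[-1L, , drop = FALSE], A[nc, , drop = FALSE])
      list(lo = pmin(A, up, dn), hi = pmax(A, up, dn))
    }
    n1 <- nb(A1); n2 <- nb(A2)
    m1 <- apply(abs(A1), 2, max); m2 <- apply(abs(A2), 2, max)
    for (start in seq(1L, np, by = chunk_size)) {
      sel <- start:min(np, start + chunk_size - 1L)
      i <- pairs$i[sel]; j <- pairs$j[sel]
      scale <- pmax(m1[i], m2[j])
      if (any(scale == 0))
        stop("degenerate lead ", lead,
             ": both patterns identically at onset level", call. = FALSE)
      sc <- rep(scale, each = nc)
      lo1 <- band_lo(n1$lo[, i] / sc - tol, grid)
      hi1 <- band_hi(n1$hi[, i] / sc + tol, grid)
      lo2 <- band_lo(n2$lo[, j] / sc - tol, grid)
      hi2 <- band_hi(n2$hi[, j] / sc + tol, grid)
      olo <- pmax(lo1, lo2); ohi <- pmin(hi1, hi2)
      tequ <- colSums(matrix(olo <= ohi, nc)) * grid$dt_ms
      v1 <- A1[, i] / sc; v2 <- A2[, j] / sc
      rmin <- row_nearest(pmin(v1, v2), grid)
      rmax <- row_nearest(pmax(v1, v2), grid)
      ov <- pmax(0, pmin(ohi, rmax) - pmax(olo, rmin) + 1)
      count <- colSums(matrix(rmax - rmin + 1 - ov, nc))
      out[sel, 2L * li - 1L] <- tequ
      out[sel, 2L * li] <- count * (grid$dt_ms / 100) * (grid$da / 2) * 100
    }
  }
  out
}

## Vectorized (dim-preserving) variants of the row-mapping helpers.
band_lo <- function(lo, grid)
  pmin(pmax(ceiling((lo + 1) / grid$da - 0.5 - EPS_GRID), 0), grid$n_rows - 1)
band_hi <- function(hi, grid)
  pmin(pmax(floor((hi + 1) / grid$da - 0.5 + EPS_GRID), 0), grid$n_rows - 1)
row_nearest <- function(v, grid)
  pmin(pmax(ceiling((v + 1) / grid$da - EPS_GRID) - 1, 0), grid$n_rows - 1)
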