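#' Construct a lead-I reference pattern
#'
#' The reference pattern is a single-lead (lead I) average beat at 1000 Hz
#' with a marked R-peak, against which every subject's beat is time-aligned
#' by maximal cross-correlation before QRS-window extraction.
#'
#' @param samples Numeric vector, lead-I amplitudes at 1000 Hz (microvolts).
#' @param r_peak_index 0-based sample index of the R peak.
#' @return Object of class `reference_pattern`.
#' @export
reference_pattern <- function(samples, r_peak_index) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("reference samples must be finite", call. = FALSE)
  r_peak_index <- as.integer(r_peak_index)
  if (r_peak_index < 0L || r_peak_index >= length(samples))
    stop("r_peak_index out of bounds", call. = FALSE)
  structure(list(samples = samples, r_peak_index = r_peak_index),
            class = "reference_pattern")
}

#' Default synthetic reference pattern
#'
#' A canonical, positively deflected P-QRS-T lead-I average beat rendered by
#' the synthetic beat generator with a fixed internal seed, resampled to
#' 1000 Hz. Any user-supplied [reference_pattern()] (e.g. read with
#' [read_reference_pattern()]) can be used instead.
#'
#' @return A `reference_pattern` at 1000 Hz, 500 samples.
#' @export
default_reference <- function() {
  rng <- rng_stream(190521L)
  params <- sample_subject(rng)
  beat <- render_average_beat(params, session = "S1",
                              var = session_variability(noise_uv = 0), rng = rng)
  beat <- resample_to_1ms(beat)
  lead1 <- beat$samples[, "I"]
  reference_pattern(lead1, which.max(lead1) - 1L)
}

#' Read / write a reference pattern in the beat CSV dialect
#'
#' Stored as a single-lead CSV with header `time_ms,I,r_peak_ms`; the
#' `r_peak_ms` column is constant and gives the R-peak time in ms.
#'
#' @param path CSV path.
#' @return For the reader, a `reference_pattern`; the writer returns `path`
#'   invisibly.
#' @export
read_reference_pattern <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ms", "I", "r_peak_ms")
  if (length(setdiff(need, names(df))))
    stop("reference CSV must have columns time_ms, I, r_peak_ms", call. = FALSE)
  dt <- diff(df$time_ms)
  if (any(abs(dt - 1) > 1e-6))
    stop("reference pattern must be sampled at 1000 Hz (1 ms grid)", call. = FALSE)
  reference_pattern(df$I, as.integer(round(df$r_peak_ms[1L])))
}

#' @rdname read_reference_pattern
#' @param ref A `reference_pattern`.
#' @export
write_reference_pattern <- function(ref, path) {
  df <- data.frame(time_ms = seq_along(ref$samples) - 1L,
                   I = formatC(ref$samples, format = "g", digits = 15),
                   r_peak_ms = ref$r_peak_index)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a beat to the reference pattern by maximal cross-correlation
#'
#' Slides the reference over the beat's lead I within `max_lag_ms` and finds
#' the lag maximizing the normalized cross-correlation (inner product scaled
#' by the overlapping segments' energies, so the match is amplitude-scale
#' invariant). Ties are broken toward the smallest absolute lag, negative
#' before positive. Only lead I drives alignment; all 12 windows are then
#' cut at the identical sample indices.
#'
#' @param beat An [average_beat()] at 1000 Hz.
#' @param ref A [reference_pattern()].
#' @param max_lag_ms Search half-range in ms (default 100).
#' @return 0-based sample index in `beat` aligned with `ref$r_peak_index`
#'   (the beat's fiducial point).
#' @export
align_to_reference <- function(beat, ref, max_lag_ms = 100) {
  stopifnot(inherits(beat, "average_beat"), inherits(ref, "reference_pattern"))
  if (beat$fs != 1000)
    stop("beat must be resampled to 1000 Hz before alignment", call. = FALSE)
  x <- beat$samples[, "I"]
  r <- ref$samples
  if (all(x == 0)) stop("degenerate signal: lead I is identically zero", call. = FALSE)
  lags <- -as.integer(max_lag_ms):as.integer(max_lag_ms)
  n <- length(x); m <- length(r)
  best <- -Inf; best_lag <- NA_integer_
  ## order lags by |lag| (negative first) so the first strict maximum wins ties
  for (lag in lags[order(abs(lags), lags)]) {
    ## beat index i overlaps ref index i - lag
    i0 <- max(1L, 1L + lag); i1 <- min(n, m + lag)
    if (i1 - i0 + 1L < 100L)
      stop("alignment range error: overlap below 100 ms at lag ", lag, call. = FALSE)
    xs <- x[i0:i1]; rs <- r[(i0 - lag):(i1 - lag)]
    den <- sqrt(sum(xs^2) * sum(rs^2))
    cc <- if (den > 0) sum(xs * rs) / den else -Inf
    if (cc > best + 1e-12) { best <- cc; best_lag <- lag }
  }
  ref$r_peak_index + best_lag
}

#' Extract the synchronized 100 ms 12-lead QRS windows
#'
#' Cuts a window of 30 ms before and 70 ms after the fiducial point,
#' synchronously in all 12 leads: 0-based samples
#' `fiducial_index - 30 .. fiducial_index + 69` (100 samples, half-open at
#' the right edge). The window length reflects the average duration of a
#' normal QRS complex and deliberately excludes P, ST and T segments.
#'
#' @param beat An [average_beat()] at 1000 Hz.
#' @param fiducial_index 0-based R-peak-aligned sample index from
#'   [align_to_reference()].
#' @return Object of class `qrs_pattern_set`: unnormalized, with per-lead
#'   `onset_level` (the amplitude at the annotated QRS onset when present,
#'   else at the window start, taken as pre-QRS baseline).
#' @export
extract_patterns <- function(beat, fiducial_index) {
  stopifnot(inherits(beat, "average_beat"))
  if (beat$fs != 1000) stop("beat must be at 1000 Hz", call. = FALSE)
  fid <- as.integer(fiducial_index)
  start <- fid - 30L                       # 0-based first sample
  n <- nrow(beat$samples)
  if (start < 0L || start + 100L > n) {
    pad_left <- max(0L, -start)
    pad_right <- max(0L, start + 100L - n)
    stop(sprintf(paste0("extraction window [%d, %d) out of bounds for %d-sample ",
                        "beat: would require %d sample(s) of left and %d of ",
                        "right padding"),
                 start, start + 100L, n, pad_left, pad_right), call. = FALSE)
  }
  idx <- (start + 1L):(start + 100L)       # 1-based rows
  pat <- beat$samples[idx, , drop = FALSE]
  if (is.finite(beat$qrs_onset_ms)) {
    oi <- as.integer(round(beat$qrs_onset_ms)) + 1L
    oi <- min(max(oi, 1L), n)
    onset <- beat$samples[oi, ]
  } else {
    onset <- pat[1L, ]                     # window start = pre-QRS baseline
  }
  structure(list(subject_id = beat$subject_id, session = beat$session,
                 patterns = pat, normalized = FALSE,
                 onset_level = onset, window_start = start),
            class = "qrs_pattern_set")
}

#' @export
print.qrs_pattern_set <- function(x, ...) {
  cat(sprintf("<qrs_pattern_set> subject %s session %s: 12 x 100 samples%s\n",
              x$subject_id, x$session,
              if (x$normalized) " (normalized to [-1,1])" else " (raw uV)"))
  invisible(x)
}

#' Normalize a pair of QRS pattern sets to [-1, 1]
#'
#' Per lead, each session's pattern is first shifted so its QRS-onset level
#' lies at 0 V, then both sessions are divided by the same scale factor: the
#' maximal absolute shifted amplitude over both sessions and all 100 time
#' steps. This removes inter-subject and inter-lead amplitude spans while
#' preserving the relative amplitude difference between the two sessions; at
#' least one sample across the pair attains |value| = 1 in every lead.
#'
#' @param a,b Unnormalized [extract_patterns()] results with identical lead
#'   order.
#' @return List with elements `a` and `b`: normalized `qrs_pattern_set`s.
#' @export
normalize_pair <- function(a, b) {
  stopifnot(inherits(a, "qrs_pattern_set"), inherits(b, "qrs_pattern_set"))
  if (a$normalized || b$normalized)
    stop("inputs must be unnormalized pattern sets", call. = FALSE)
  pa <- sweep(a$patterns, 2, a$onset_level)
  pb <- sweep(b$patterns, 2, b$onset_level)
  scale <- pmax(apply(abs(pa), 2, max), apply(abs(pb), 2, max))
  if (any(scale == 0)) {
    bad <- colnames(pa)[scale == 0]
    stop("degenerate lead(s) ", paste(bad, collapse = ", "),
         ": both patterns identically at onset level", call. = FALSE)
  }
  na <- a; nb <- b
  na$patterns <- sweep(pa, 2, scale, "/")
  nb$patterns <- sweep(pb, 2, scale, "/")
  na$normalized <- nb$normalized <- TRUE
  na$onset_level <- nb$onset_level <- stats::setNames(numeric(12), LEAD_NAMES)
  list(a = na, b = nb)
}
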