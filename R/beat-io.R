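#' @keywords internal
"_PACKAGE"

## Canonical 12-lead order used throughout the package.
LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")

#' Standard 12-lead names in canonical order
#'
#' Limb leads I, II, III, aVR, aVL, aVF followed by chest leads V1-V6. All
#' multi-lead containers in the package order their leads this way.
#'
#' @return Character vector of length 12.
#' @export
lead_names <- function() LEAD_NAMES

#' Construct a 12-lead average-beat object
#'
#' An average beat is one subject-session's representative heartbeat waveform,
#' one trace per lead, typically obtained by averaging consecutive beats of a
#' 10 s resting ECG. Amplitudes are in microvolts.
#'
#' @param subject_id Opaque subject identifier (coerced to character).
#' @param session Session label, `"S1"` (reference) or `"S2"` (remote).
#' @param samples Numeric matrix, one column per lead (canonical order,
#'   column names must be the 12 lead names), one row per sample.
#' @param fs Sampling rate in Hz.
#' @param qrs_onset_ms Optional annotated QRS-onset time in ms from the start
#'   of the beat, or `NA` when unannotated.
#' @return An object of class `average_beat`.
#' @export
average_beat <- function(subject_id, session, samples, fs, qrs_onset_ms = NA_real_) {
  session <- match.arg(as.character(session), c("S1", "S2"))
  samples <- as.matrix(samples)
  if (ncol(samples) != 12L || !identical(colnames(samples), LEAD_NAMES)) {
    ## accept any column order but require all 12 leads present
    missing <- setdiff(LEAD_NAMES, colnames(samples))
    if (length(missing))
      stop("missing lead column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    samples <- samples[, LEAD_NAMES, drop = FALSE]
  }
  storage.mode(samples) <- "double"
  rownames(samples) <- NULL
  if (!all(is.finite(samples)))
    stop("non-finite amplitude in beat for subject ", subject_id, call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  beat <- structure(
    list(subject_id = as.character(subject_id),
         session = session,
         leads = LEAD_NAMES,
         samples = samples,
         fs = as.numeric(fs),
         duration_ms = nrow(samples) * 1000 / as.numeric(fs),
         qrs_onset_ms = as.numeric(qrs_onset_ms)),
    class = "average_beat")
  beat
}

#' @export
print.average_beat <- function(x, ...) {
  cat(sprintf("<average_beat> subject %s session %s: %d samples/lead @ %g Hz (%g ms)%s\n",
              x$subject_id, x$session, nrow(x$samples), x$fs, x$duration_ms,
              if (is.finite(x$qrs_onset_ms))
                sprintf(", QRS onset %g ms", x$qrs_onset_ms) else ""))
  invisible(x)
}

#' Read 12-lead average beats from CSV
#'
#' The CSV dialect has header
#' `subject_id,session,time_ms,I,II,III,aVR,aVL,aVF,V1,V2,V3,V4,V5,V6`
#' with one row per sample and an optional `qrs_onset_ms` column (constant
#' within each subject-session block). Amplitudes are microvolts, decimal
#' separator `.`, UTF-8. Each (subject, session) block becomes one
#' [average_beat()].
#'
#' @param path Path to the CSV file.
#' @param dialect Input format; only `"csv"` is implemented. `"wfdb"` is
#'   reserved and raises an unsupported-dialect error.
#' @return List of `average_beat` objects, in order of first appearance.
#' @export
read_average_beats <- function(path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "wfdb")
    stop("the 'wfdb' dialect is not supported by this build; ",
         "convert the record to the beat CSV dialect", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "session", "time_ms", LEAD_NAMES)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("beat CSV format error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (lead in c("time_ms", LEAD_NAMES)) {
    v <- df[[lead]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("parse error in column '%s': non-numeric value at data row %d",
                   lead, bad), call. = FALSE)
    }
  }
  key <- paste(df$subject_id, df$session, sep = "\r")
  blocks <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  seen <- character(0)
  beats <- lapply(blocks, function(idx) {
    sub <- df[idx, , drop = FALSE]
    sid <- as.character(sub$subject_id[1L])
    ses <- as.character(sub$session[1L])
    tag <- paste(sid, ses)
    if (tag %in% seen)
      stop("duplicate record for subject ", sid, " session ", ses, call. = FALSE)
    seen <<- c(seen, tag)
    ## contiguity check: split() regroups interleaved blocks, which would hide
    ## a duplicated (subject, session) appearing later in the file
    if (any(diff(idx) != 1L))
      stop("duplicate record for subject ", sid, " session ", ses, call. = FALSE)
    t_ms <- sub$time_ms
    dt <- diff(t_ms)
    if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1L])) > 1e-6))
      stop("time_ms not uniformly increasing for subject ", sid, call. = FALSE)
    fs <- if (length(dt)) 1000 / dt[1L] else stop("empty block", call. = FALSE)
    onset <- if ("qrs_onset_ms" %in% names(sub)) sub$qrs_onset_ms[1L] else NA_real_
    average_beat(sid, ses, as.matrix(sub[, LEAD_NAMES]), fs = fs,
                 qrs_onset_ms = onset)
  })
  names(beats) <- NULL
  beats
}

#' Write average beats to the beat CSV dialect
#'
#' Inverse of [read_average_beats()]; amplitudes are written with full
#' double precision (15 significant digits), so a write/read round-trip is
#' lossless at that precision.
#'
#' @param beats A single `average_beat` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_average_beats <- function(beats, path) {
  if (inherits(beats, "average_beat")) beats <- list(beats)
  rows <- lapply(beats, function(b) {
    n <- nrow(b$samples)
    out <- data.frame(subject_id = rep(b$subject_id, n),
                      session = rep(b$session, n),
                      time_ms = (seq_len(n) - 1L) * 1000 / b$fs,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(b$samples))
    out$qrs_onset_ms <- rep(b$qrs_onset_ms, n)
    out
  })
  df <- do.call(rbind, rows)
  ## drop the onset column when no beat is annotated
  if (all(!is.finite(df$qrs_onset_ms))) df$qrs_onset_ms <- NULL
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  num_cols <- setdiff(names(df), c("subject_id", "session"))
  for (cn in num_cols) df[[cn]] <- fmt(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Kaiser window of length n (0-based index 0..n-1), shape parameter beta.
## besselI(x, 0) is the modified Bessel function of order zero.
kaiser_window <- function(n, beta) {
  m <- n - 1
  k <- 0:m
  besselI(beta * sqrt(pmax(0, 1 - ((2 * k - m) / m)^2)), 0) / besselI(beta, 0)
}

#' Resample an average beat to the 1 ms analysis grid
#'
#' Doubles the sampling rate of a 500 Hz average beat to 1000 Hz so that one
#' sample corresponds to one 1 ms time-grid column of the binary matching
#' matrices. Upsampling interleaves zeros and applies a Kaiser-windowed sinc
#' anti-aliasing low-pass (cutoff at the original Nyquist frequency); the
#' signal is symmetrically padded before filtering so that edge transients
#' stay outside the interior. 1000 Hz input is returned unchanged.
#'
#' @param beat An [average_beat()] at 500 or 1000 Hz.
#' @param beta Kaiser window shape parameter of the anti-aliasing filter.
#' @param half_len_ms Filter half-length in ms of output-rate samples.
#' @return An `average_beat` at 1000 Hz with twice the sample count (for
#'   500 Hz input) and unchanged `duration_ms`.
#' @export
resample_to_1ms <- function(beat, beta = 5, half_len_ms = 10) {
  stopifnot(inherits(beat, "average_beat"))
  if (beat$fs == 1000) return(beat)
  if (beat$fs != 500)
    stop("unsupported sampling rate ", beat$fs,
         " Hz: expected 500 or 1000", call. = FALSE)
  up <- apply(beat$samples, 2, upsample2_kaiser, beta = beta,
              half_len = as.integer(half_len_ms))
  colnames(up) <- LEAD_NAMES
  average_beat(beat$subject_id, beat$session, up, fs = 1000,
               qrs_onset_ms = beat$qrs_onset_ms)
}

## Factor-2 upsampler: zero-stuff then convolve with a Kaiser-windowed sinc
## (gain 2, cutoff pi/2), with symmetric (reflective) padding at both ends.
upsample2_kaiser <- function(x, beta = 5, half_len = 10L) {
  n <- length(x)
  if (n < 2L) stop("signal too short to resample", call. = FALSE)
  ## pad in the input domain by enough samples to cover the filter support
  pad <- ceiling(half_len / 2) + 2L
  pad <- min(pad, n - 1L)
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  np <- length(xp)
  z <- numeric(2L * np)
  z[seq(1L, 2L * np, by = 2L)] <- xp
  ## windowed sinc, odd length 2*half_len+1, centered; cutoff 0.5 of output
  ## Nyquist, gain 2 so original samples are preserved
  k <- (-half_len):half_len
  h <- 2 * 0.5 * sinc(0.5 * k) * kaiser_window(2L * half_len + 1L, beta)
  ## normalize each polyphase branch to unit DC gain (the branch holding the
  ## original samples is already exact; the interpolating branch carries a
  ## small window-truncation error otherwise)
  odd <- k %% 2L != 0L
  h[odd] <- h[odd] / sum(h[odd])
  y <- stats::convolve(z, rev(h), type = "open")
  y <- y[(half_len + 1L):(half_len + 2L * np)]   # compensate group delay
  y <- y[(2L * pad + 1L):(2L * pad + 2L * n)]    # strip padding
  y
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
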