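#' Seeded random-number stream
#'
#' A small handle around R's Mersenne-Twister state so that the synthetic
#' generator can thread an explicit RNG through nested calls without
#' touching the caller's global random state.
#'
#' @param seed Integer seed.
#' @return Object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  restore_rng(old)
  class(e) <- "rng_stream"
  e
}

with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    restore_rng(old)
  })
  expr
}

WAVES <- c("P", "Q", "R", "S", "T")

#' Default priors for synthetic subject morphology
#'
#' Uniform bounds for per-wave Gaussian amplitudes (microvolts), shared wave
#' center times (ms within the 500 ms beat, R near 250 ms) and widths (ms)
#' of the two frontal-plane dipole components (rendered as leads I and III,
#' from which the remaining limb leads follow by the Einthoven/Goldberger
#' identities) and of each chest lead V1-V6. Ranges are chosen so that every
#' draw satisfies the morphology invariants: wave centers ordered
#' P < Q < R < S < T and a dominant R wave in lead II.
#'
#' @return Nested list of `c(lower, upper)` bounds.
#' @export
subject_priors <- function() {
  list(
    centers_ms = list(P = c(160, 190), Q = c(230, 242), R = c(244, 254),
                      S = c(256, 268), T = c(330, 380)),
    widths_ms = list(P = c(12, 22), Q = c(3, 8), R = c(4, 14),
                     S = c(3, 10), T = c(28, 45)),
    ## per-source intrinsic-deflection time offsets (sd, ms) around the
    ## shared centers: the depolarization wavefront reaches each projection
    ## at slightly different, subject-specific times
    offset_sd_ms = c(P = 5, Q = 2, R = 2, S = 2, T = 8),
    amplitudes_uv = list(
      comp1 = list(P = c(40, 120), Q = c(-200, -20), R = c(600, 1600),
                   S = c(-700, -50), T = c(150, 350)),
      comp2 = list(P = c(10, 80), Q = c(-150, -10), R = c(150, 900),
                   S = c(-500, -30), T = c(50, 250)),
      chest = list(P = c(20, 100), Q = c(-250, 0), R = c(250, 2000),
                   S = c(-1200, -50), T = c(100, 400))))
}

#' Draw one subject's stable 12-lead morphology parameters
#'
#' Samples per-wave Gaussian parameters from [subject_priors()]: shared wave
#' centers (one heart), per-component/per-lead amplitudes and widths. Limb
#' leads are derived from the two frontal-plane components so the
#' Einthoven/Goldberger identities hold by construction; chest leads are
#' drawn independently, reflecting their idiosyncratic projections.
#'
#' @param rng A [rng_stream()].
#' @param priors Prior bounds, defaults [subject_priors()].
#' @return Object of class `subject_params` with `centers_ms`, and per
#'   source (comp1, comp2, V1..V6) `amplitudes_uv` and `widths_ms`; also
#'   `axis_deg`, the derived frontal-plane QRS axis.
#' @export
sample_subject <- function(rng, priors = subject_priors()) {
  with_rng(rng, {
    u <- function(b) stats::runif(1, b[1L], b[2L])
    centers <- vapply(priors$centers_ms, u, numeric(1))
    sources <- c("comp1", "comp2", paste0("V", 1:6))
    amps <- widths <- offsets <- list()
    for (s in sources) {
      ab <- if (s %in% c("comp1", "comp2")) priors$amplitudes_uv[[s]]
            else priors$amplitudes_uv$chest
      amps[[s]] <- vapply(ab, u, numeric(1))
      widths[[s]] <- vapply(priors$widths_ms, u, numeric(1))
      offsets[[s]] <- stats::rnorm(length(WAVES), 0, priors$offset_sd_ms)
    }
    r_i <- amps$comp1[["R"]]; r_iii <- amps$comp2[["R"]]
    ## net frontal QRS projection: lead I along 0 deg, aVF = II - I/2
    axis <- atan2(r_i / 2 + r_iii, r_i) * 180 / pi
    structure(list(centers_ms = centers, amplitudes_uv = amps,
                   widths_ms = widths, offsets_ms = offsets, axis_deg = axis),
              class = "subject_params")
  })
}

#' Session-to-session variability settings
#'
#' Controls how the remote session S2 differs from the reference session S1
#' and how much measurement noise both sessions carry. Defaults emulate a
#' clinically realistic long-term re-recording: a small global time shift of
#' the average beat, relative per-wave amplitude changes of about 10%,
#' per-wave timing changes of about 2 ms, and 15 uV RMS of band-limited
#' additive noise, with session heart rates emitted as covariates.
#'
#' @param shift_ms Half-range of the uniform global S2 time shift (ms).
#' @param amp_jitter Relative sd of per-wave S2 amplitude jitter.
#' @param time_jitter_ms Sd of per-wave S2 center jitter (ms), shared
#'   across leads (the wavefront moves as a whole).
#' @param noise_uv RMS amplitude (microvolts) of band-limited additive
#'   noise, applied to both sessions.
#' @param lead_scale_sd Sd of a per-lead log-normal S2 amplitude rescaling
#'   emulating electrode misplacement; 0 (off) by default.
#' @param hr_s1_range Uniform range of session-1 heart rate (bpm).
#' @param hr_delta_sd Sd of the normal S2-S1 heart-rate change (bpm).
#' @return Object of class `session_variability`.
#' @export
session_variability <- function(shift_ms = 10, amp_jitter = 0.10,
                                time_jitter_ms = 1, noise_uv = 15,
                                lead_scale_sd = 0,
                                hr_s1_range = c(50, 95), hr_delta_sd = 8) {
  stopifnot(shift_ms >= 0, amp_jitter >= 0, time_jitter_ms >= 0,
            noise_uv >= 0, lead_scale_sd >= 0)
  structure(list(shift_ms = shift_ms, amp_jitter = amp_jitter,
                 time_jitter_ms = time_jitter_ms, noise_uv = noise_uv,
                 lead_scale_sd = lead_scale_sd, hr_s1_range = hr_s1_range,
                 hr_delta_sd = hr_delta_sd),
            class = "session_variability")
}

#' Render one session's 12-lead average beat from subject parameters
#'
#' Sums per-wave Gaussians on a 500 ms, 500 Hz grid. Session S1 renders the
#' subject's stable morphology; session S2 first perturbs the parameters
#' (global shift, per-wave amplitude and timing jitter, optional per-lead
#' rescaling) to emulate a remote re-recording. Limb leads are derived from
#' the two frontal components, so II = I + III, aVR = -(I + II)/2,
#' aVL = I - II/2 and aVF = II - I/2 hold exactly before noise; band-limited
#' noise is then added per lead. The QRS onset is annotated from the
#' (possibly shifted) Q-wave parameter as `Q_center - 2 * Q_width`.
#'
#' @param params A [sample_subject()] result.
#' @param session `"S1"` or `"S2"`.
#' @param var A [session_variability()].
#' @param rng A [rng_stream()].
#' @param subject_id Identifier stamped on the returned beat.
#' @return An [average_beat()] (500 Hz, 250 samples per lead).
#' @export
render_average_beat <- function(params, session, var = session_variability(),
                                rng, subject_id = "synthetic") {
  session <- match.arg(session, c("S1", "S2"))
  with_rng(rng, {
    centers <- params$centers_ms
    amps <- params$amplitudes_uv
    widths <- params$widths_ms
    shift <- 0
    if (session == "S2") {
      shift <- stats::runif(1, -var$shift_ms, var$shift_ms)
      centers <- centers + shift +
        stats::rnorm(length(WAVES), 0, var$time_jitter_ms)
      amps <- lapply(amps, function(a)
        a * (1 + stats::rnorm(length(a), 0, var$amp_jitter)))
    }
    t <- (0:249) * 2                       # ms, 500 Hz
    gauss_sum <- function(src) {
      a <- amps[[src]]; w <- widths[[src]]
      cs <- centers + params$offsets_ms[[src]]
      out <- numeric(length(t))
      for (k in seq_along(WAVES))
        out <- out + a[k] * exp(-(t - cs[k])^2 / (2 * w[k]^2))
      out
    }
    I <- gauss_sum("comp1"); III <- gauss_sum("comp2")
    II <- I + III
    leads <- cbind(I = I, II = II, III = III,
                   aVR = -(I + II) / 2, aVL = I - II / 2, aVF = II - I / 2)
    chest <- vapply(paste0("V", 1:6), gauss_sum, numeric(length(t)))
    samples <- cbind(leads, chest)[, LEAD_NAMES]
    if (session == "S2" && var$lead_scale_sd > 0)
      samples <- sweep(samples, 2,
                       exp(stats::rnorm(12, 0, var$lead_scale_sd)), "*")
    if (var$noise_uv > 0) {
      noise <- vapply(1:12, function(...) band_limited_noise(length(t), var$noise_uv),
                      numeric(length(t)))
      samples <- samples + noise
    }
    onset <- centers[["Q"]] - 2 * widths$comp1[["Q"]]
    average_beat(subject_id, session, samples, fs = 500, qrs_onset_ms = onset)
  })
}

## White noise smoothed by a short Gaussian FIR kernel (sd ~4 ms at 500 Hz),
## rescaled to the requested RMS: crude emulation of residual baseline and
## muscle noise surviving beat averaging.
band_limited_noise <- function(n, rms_uv) {
  w <- stats::dnorm(-4:4, sd = 2)
  x <- stats::filter(stats::rnorm(n + 8L), w / sum(w), sides = 2)
  x <- x[!is.na(x)][seq_len(n)]
  x * (rms_uv / sqrt(mean(x^2)))
}

#' Simulate a paired-session cohort in memory
#'
#' Draws `n_subjects` independent morphologies and renders both sessions of
#' each, together with covariates (age, sex, per-session heart rate). Fully
#' reproducible from `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param var A [session_variability()].
#' @param seed Integer seed.
#' @param priors Morphology priors, defaults [subject_priors()].
#' @return List with `beats` (list of 2 * n `average_beat`s) and
#'   `covariates` (data.frame: subject_id, age, sex, hr_s1, hr_s2).
#' @export
simulate_cohort <- function(n_subjects, var = session_variability(), seed = 1,
                            priors = subject_priors()) {
  stopifnot(n_subjects >= 2)
  rng <- rng_stream(seed)
  beats <- vector("list", 2L * n_subjects)
  ids <- sprintf("SYN%04d", seq_len(n_subjects))
  cov <- with_rng(rng, data.frame(
    subject_id = ids,
    age = sample(18:90, n_subjects, replace = TRUE),
    sex = sample(c("M", "F"), n_subjects, replace = TRUE),
    hr_s1 = round(stats::runif(n_subjects, var$hr_s1_range[1L],
                               var$hr_s1_range[2L])),
    stringsAsFactors = FALSE))
  cov$hr_s2 <- with_rng(rng, pmin(pmax(
    round(cov$hr_s1 + stats::rnorm(n_subjects, 0, var$hr_delta_sd)), 40), 160))
  for (k in seq_len(n_subjects)) {
    params <- sample_subject(rng, priors)
    beats[[2L * k - 1L]] <- render_average_beat(params, "S1", var, rng, ids[k])
    beats[[2L * k]] <- render_average_beat(params, "S2", var, rng, ids[k])
  }
  list(beats = beats, covariates = cov)
}

#' Generate a synthetic cohort on disk
#'
#' Writes the beat CSV dialect consumed by [read_average_beats()] plus a
#' covariate CSV (`subject_id,age,sex,hr_s1,hr_s2`) to a directory.
#'
#' @inheritParams simulate_cohort
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the two file paths and the covariates.
#' @export
generate_cohort <- function(n_subjects, var = session_variability(), seed = 1,
                            dir = ".") {
  sim <- simulate_cohort(n_subjects, var, seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  beats_path <- file.path(dir, "beats.csv")
  cov_path <- file.path(dir, "covariates.csv")
  write_average_beats(sim$beats, beats_path)
  utils::write.csv(sim$covariates, cov_path, row.names = FALSE, quote = FALSE)
  invisible(list(beats = beats_path, covariates = cov_path,
                 covariate_table = sim$covariates))
}
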