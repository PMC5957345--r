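#' Grouping specification for cohort robustness analyses
#'
#' Defines how test subjects are partitioned for group-wise performance:
#' by gender, by age band (session-S1 age), by absolute heart-rate band
#' (session-S1 HR) or by absolute between-session HR change. Numeric bands
#' are left-closed, right-open intervals over the given edges, extended
#' with -Inf/Inf to be exhaustive.
#'
#' @param grouping One of `"gender"`, `"age_band"`, `"hr_band"`,
#'   `"hr_delta_band"`.
#' @param bins For numeric groupings, the interior band edges; defaults are
#'   age `c(30, 40, 50, 60, 70)`, HR `c(60, 70, 80, 90)`, HR change
#'   `c(10, 20)`. Ignored for gender.
#' @return Object of class `group_spec`.
#' @export
group_spec <- function(grouping = c("gender", "age_band", "hr_band",
                                    "hr_delta_band"),
                       bins = NULL) {
  grouping <- match.arg(grouping)
  if (is.null(bins))
    bins <- switch(grouping,
                   gender = c("M", "F"),
                   age_band = c(30, 40, 50, 60, 70),
                   hr_band = c(60, 70, 80, 90),
                   hr_delta_band = c(10, 20))
  if (grouping != "gender" && is.unsorted(bins, strictly = TRUE))
    stop("bins must be strictly increasing band edges", call. = FALSE)
  structure(list(grouping = grouping, bins = bins), class = "group_spec")
}

group_assignment <- function(data, spec) {
  val <- switch(spec$grouping,
                gender = data$sex,
                age_band = data$age,
                hr_band = data$hr_s1,
                hr_delta_band = abs(data$hr_s1 - data$hr_s2))
  if (is.null(val) || all(is.na(val)))
    stop("covariate for grouping '", spec$grouping,
         "' not present in dataset", call. = FALSE)
  if (spec$grouping == "gender") factor(val, levels = spec$bins)
  else cut(val, breaks = c(-Inf, spec$bins, Inf), right = FALSE)
}

#' Group-wise verification performance of a fixed verifier
#'
#' Evaluates a trained model at its fixed operating point separately within
#' subject groups. TAR of a group uses the equal-ID pairs whose subject is
#' in the group; TRR uses the different-ID pairs whose claimed-identity
#' (S2-session) subject is in the group, so every pair is attributed to
#' exactly one group and pair counts are conserved. Groups with an empty
#' class are reported with `NA` rates and flagged.
#'
#' @param model An [fit_lda()] model.
#' @param point An [pick_eer_operating_point()] operating point.
#' @param test A test `pair_dataset` with covariate columns.
#' @param spec A [group_spec()].
#' @return Object of class `group_report`: data.frame with one row per
#'   group (`group`, `n_equal`, `n_different`, `tar`, `trr`, `tvr`,
#'   `flagged`).
#' @export
grouped_performance <- function(model, point, test, spec) {
  g <- group_assignment(test, spec)
  scores <- lda_scores(model, test)
  acc <- scores >= point$threshold
  eq <- test$label == "equal"
  rows <- lapply(levels(g), function(lv) {
    in_g <- !is.na(g) & g == lv
    ne <- sum(in_g & eq); nd <- sum(in_g & !eq)
    tar <- if (ne) 100 * sum(acc[in_g & eq]) / ne else NA_real_
    trr <- if (nd) 100 * sum(!acc[in_g & !eq]) / nd else NA_real_
    data.frame(group = lv, n_equal = ne, n_different = nd,
               tar = tar, trr = trr, tvr = (tar + trr) / 2,
               flagged = ne == 0L || nd == 0L, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), grouping = spec$grouping,
            class = c("group_report", "data.frame"))
}

#' Verification performance versus test-cohort size
#'
#' Evaluates the fixed model on subject subsets of the test cohort: for each
#' requested size, either all subject combinations (when their count does
#' not exceed `max_subsets`) or a seeded uniform sample of `max_subsets`
#' subsets. A subset's pairs are the test pairs with both endpoints inside
#' the subset. Reports the mean and min-max envelope of TAR/TRR/TVR per
#' size; at the full cohort size the single subset reproduces the global
#' report exactly.
#'
#' @param model An [fit_lda()] model.
#' @param point Operating point.
#' @param test Test `pair_dataset`.
#' @param sizes Integer vector of subset sizes.
#' @param max_subsets Cap on evaluated subsets per size.
#' @param rng_seed Seed for subset sampling.
#' @return Object of class `size_sweep_report`: data.frame with one row per
#'   size (`size`, `n_subsets`, `exhaustive`, and
#'   `{tar,trr,tvr}_{mean,min,max}`).
#' @export
sample_size_sweep <- function(model, point, test, sizes,
                              max_subsets = 10000L, rng_seed = 1) {
  subjects <- unique(c(test$id_s1, test$id_s2))
  n <- length(subjects)
  if (any(sizes > n))
    stop("range error: requested size exceeds the ", n, "-subject cohort",
         call. = FALSE)
  scores <- lda_scores(model, test)
  acc <- scores >= point$threshold
  eq <- test$label == "equal"
  i1 <- match(test$id_s1, subjects); i2 <- match(test$id_s2, subjects)
  rows <- lapply(sizes, function(sz) {
    n_comb <- choose(n, sz)
    exhaustive <- n_comb <= max_subsets
    subsets <- if (exhaustive) {
      utils::combn(n, sz, simplify = FALSE)
    } else {
      local_seed(rng_seed + sz, replicate(max_subsets, sort(sample(n, sz)),
                                          simplify = FALSE))
    }
    rates <- vapply(subsets, function(s) {
      member <- logical(n); member[s] <- TRUE
      keep <- member[i1] & member[i2]
      ne <- sum(keep & eq); nd <- sum(keep & !eq)
      tar <- if (ne) 100 * sum(acc[keep & eq]) / ne else NA_real_
      trr <- if (nd) 100 * sum(!acc[keep & !eq]) / nd else NA_real_
      c(tar, trr, (tar + trr) / 2)
    }, numeric(3))
    data.frame(size = sz, n_subsets = length(subsets), exhaustive = exhaustive,
               tar_mean = mean(rates[1, ]), tar_min = min(rates[1, ]),
               tar_max = max(rates[1, ]),
               trr_mean = mean(rates[2, ]), trr_min = min(rates[2, ]),
               trr_max = max(rates[2, ]),
               tvr_mean = mean(rates[3, ]), tvr_min = min(rates[3, ]),
               tvr_max = max(rates[3, ]))
  })
  structure(do.call(rbind, rows), class = c("size_sweep_report", "data.frame"))
}

#' Two-proportion chi-squared test
#'
#' Pearson chi-squared test (1 df) of equality of two binomial proportions
#' on the 2x2 success/failure table; no continuity correction by default,
#' matching the large-sample comparison of verification rates between
#' groups.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `p_value`, `proportions`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop("undefined test: zero trials", call. = FALSE)
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  if (k1 / n1 == k2 / n2) {
    ## chi-squared statistic is exactly 0; prop.test warns on degenerate tables
    return(list(statistic = 0, p_value = 1,
                proportions = c(k1 / n1, k2 / n2)))
  }
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       proportions = unname(ht$estimate))
}

#' Wilcoxon rank tests for group comparisons
#'
#' Paired mode runs the Wilcoxon signed-rank test, unpaired mode the
#' rank-sum (Mann-Whitney) test, via [stats::wilcox.test()]. The exact null
#' distribution is used for small samples (both groups <= 25) without ties;
#' otherwise the normal approximation with tie correction and without
#' continuity correction.
#'
#' @param group_a,group_b Numeric samples.
#' @param paired Use the signed-rank test on paired differences.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
rank_test <- function(group_a, group_b, paired = FALSE) {
  if (paired && length(group_a) != length(group_b))
    stop("paired test requires equal-length samples", call. = FALSE)
  if (paired && all(group_a == group_b))
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  n <- max(length(group_a), length(group_b))
  vals <- if (paired) group_a - group_b else c(group_a, group_b)
  exact <- n <= 25 && !anyDuplicated(abs(vals))
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, paired = paired, exact = exact,
                       correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}
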