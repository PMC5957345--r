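#' Pair-scheme combinatorics for a two-session verification cohort
#'
#' For `n_subjects` subjects with two sessions each, the S2-vs-S1 comparison
#' scheme yields `n_subjects` equal-identity pairs and
#' `n_subjects * (n_subjects - 1)` ordered different-identity pairs. The
#' training partition takes the equal pairs of the first `n_train` subjects
#' plus an equally sized balanced sample of different pairs among them; the
#' test partition takes the remaining equal pairs plus all different pairs
#' not used in training.
#'
#' @param n_subjects Total number of subjects (N).
#' @param n_train Number of training subjects (default `N %/% 2`).
#' @return List with `equal_total`, `different_total`, `train_equal`,
#'   `train_different`, `test_equal`, `test_different`, `imbalance_ratio`
#'   (different-to-equal ratio of the test partition).
#' @export
pair_scheme_counts <- function(n_subjects, n_train = n_subjects %/% 2) {
  n <- as.numeric(n_subjects); n1 <- as.numeric(n_train)
  stopifnot(n >= 2, n1 >= 1, n1 <= n)
  diff_total <- n * (n - 1)
  list(equal_total = n,
       different_total = diff_total,
       train_equal = n1,
       train_different = n1,
       test_equal = n - n1,
       test_different = diff_total - n1,
       imbalance_ratio = (diff_total - n1) / (n - n1))
}

#' Build balanced training and full test pair datasets
#'
#' Constructs all S2-vs-S1 identity pairs from a cohort of per-subject
#' two-session QRS pattern sets, computes the 24 matching features for every
#' pair, and partitions them: training = equal-ID pairs of the first
#' `n_train_subjects` subjects (input order) plus a seeded uniform sample of
#' equally many different-ID pairs among those subjects; test = equal-ID
#' pairs of the remaining subjects plus all different-ID pairs not used in
#' training. Pair totals are conserved: N equal and N(N-1) different pairs,
#' partitioned without overlap.
#'
#' @param cohort A [extract_cohort_patterns()] result (or any list with
#'   `subject_ids`, `s1`, `s2` pattern-set lists and optional `covariates`).
#' @param n_train_subjects Size of the training half (default `N %/% 2`).
#' @param rng_seed Seed for the balanced different-pair draw.
#' @param grid A [grid_spec()].
#' @return List with elements `train` and `test`, each a `pair_dataset`:
#'   a data.frame with `id_s1`, `id_s2`, `label` (factor equal/different),
#'   the 24 features, and covariate columns when available, plus attributes
#'   `role` and `n_subjects`.
#' @export
build_pair_datasets <- function(cohort, n_train_subjects = NULL, rng_seed = 1,
                                grid = grid_spec()) {
  ids <- cohort$subject_ids
  n <- length(ids)
  if (n < 2L) stop("cohort must contain at least 2 subjects", call. = FALSE)
  if (length(cohort$s1) != n || length(cohort$s2) != n ||
      any(vapply(cohort$s1, is.null, TRUE)) || any(vapply(cohort$s2, is.null, TRUE)))
    stop("incomplete subject: every subject needs both S1 and S2 sessions",
         call. = FALSE)
  n1 <- if (is.null(n_train_subjects)) n %/% 2L else as.integer(n_train_subjects)
  stopifnot(n1 >= 1L, n1 < n)

  ## all ordered pairs (S1 subject i, S2 subject j)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  feat <- cohort_pair_features(cohort, pairs, grid)
  equal <- pairs$i == pairs$j
  first_half <- pairs$i <= n1 & pairs$j <= n1

  diff_first <- which(!equal & first_half)
  take <- local_seed(rng_seed, sample(diff_first, n1))
  train_idx <- c(which(equal & pairs$i <= n1), sort(take))
  test_idx <- c(which(equal & pairs$i > n1),
                setdiff(which(!equal), take))

  mk <- function(idx, role) {
    df <- data.frame(id_s1 = ids[pairs$i[idx]], id_s2 = ids[pairs$j[idx]],
                     label = factor(ifelse(pairs$i[idx] == pairs$j[idx],
                                           "equal", "different"),
                                    levels = c("equal", "different")),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(feat[idx, , drop = FALSE]))
    if (!is.null(cohort$covariates)) {
      ## covariates of the S2-session (claimed identity) subject
      cv <- cohort$covariates[match(df$id_s2, cohort$covariates$subject_id),
                              c("age", "sex", "hr_s1", "hr_s2")]
      rownames(cv) <- NULL
      df <- cbind(df, cv)
    }
    structure(df, role = role, n_subjects = n, class = c("pair_dataset", "data.frame"))
  }
  list(train = mk(train_idx, "training"), test = mk(test_idx, "test"))
}

## Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  expr
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else suppressWarnings(rm(".Random.seed", envir = globalenv()))
}

#' Fit a two-class linear discriminant on pair features
#'
#' Plain pooled-covariance LDA with equal class priors: the discriminant
#' direction is `solve(S_pooled, mu_equal - mu_different)` and the score of
#' a pair is the signed distance from the midpoint hyperplane, oriented so
#' that higher scores mean "equal identity". When the pooled covariance is
#' numerically singular, a minimal diagonal shrinkage
#' `(1 - g) * S + g * diag(diag(S))` is applied with the smallest `g` from a
#' fixed ladder that restores invertibility (with a warning).
#'
#' @param train A balanced training `pair_dataset`.
#' @param feature_subset Character vector of feature names to use.
#' @return Object of class `lda_model` with `selected_features`, `weights`,
#'   `intercept`, `class_means`, `pooled_covariance`, `shrinkage_gamma`.
#' @export
fit_lda <- function(train, feature_subset) {
  stopifnot(length(feature_subset) >= 1L, !anyDuplicated(feature_subset))
  missing <- setdiff(feature_subset, names(train))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  x <- as.matrix(train[, feature_subset, drop = FALSE])
  y <- train$label
  if (nlevels(droplevels(y)) != 2L)
    stop("training data must contain both classes", call. = FALSE)
  xe <- x[y == "equal", , drop = FALSE]
  xd <- x[y == "different", , drop = FALSE]
  mu_e <- colMeans(xe); mu_d <- colMeans(xd)
  ce <- crossprod(sweep(xe, 2, mu_e)); cd <- crossprod(sweep(xd, 2, mu_d))
  s <- (ce + cd) / (nrow(x) - 2)
  gamma <- 0
  w <- tryCatch(solve(s, mu_e - mu_d), error = function(e) NULL)
  if (is.null(w)) {
    for (g in 10^seq(-8, 0)) {
      sg <- (1 - g) * s + g * diag(diag(s), ncol(s))
      w <- tryCatch(solve(sg, mu_e - mu_d), error = function(e) NULL)
      if (!is.null(w)) { gamma <- g; s <- sg; break }
    }
    if (is.null(w)) {
      ## fully degenerate (zero-variance) features: fall back to the mean
      ## difference direction, which scores all-constant data as ties
      w <- mu_e - mu_d
      gamma <- 1
      warning("degenerate pooled covariance: using mean-difference direction",
              call. = FALSE)
    } else {
      warning(sprintf("singular pooled covariance: applied diagonal shrinkage gamma = %g",
                      gamma), call. = FALSE)
    }
  }
  structure(list(selected_features = feature_subset,
                 weights = stats::setNames(as.numeric(w), feature_subset),
                 intercept = -sum((mu_e + mu_d) / 2 * w),
                 class_means = rbind(equal = mu_e, different = mu_d),
                 pooled_covariance = s,
                 shrinkage_gamma = gamma),
            class = "lda_model")
}

#' Discriminant scores for a pair dataset
#'
#' @param model An [fit_lda()] model.
#' @param data A `pair_dataset` (or data.frame with the model's features).
#' @return Numeric vector of scores; higher favors "equal identity".
#' @export
lda_scores <- function(model, data) {
  x <- as.matrix(data[, model$selected_features, drop = FALSE])
  as.numeric(x %*% model$weights + model$intercept)
}

#' Greedy forward stepwise feature selection maximizing training AUC
#'
#' Starting from the empty set, repeatedly adds the candidate feature whose
#' inclusion maximizes the training ROC AUC of the refitted discriminant;
#' stops when the best improvement is `<= epsilon` or candidates are
#' exhausted. Ties are broken by the canonical feature order
#' ([feature_names()]), making the selection deterministic and invariant to
#' the candidate ordering.
#'
#' @param train A balanced training `pair_dataset`.
#' @param candidate_features Candidate feature names (e.g. the two features
#'   of one lead, or all 24).
#' @param epsilon Minimal AUC improvement to continue (default 1e-4).
#' @return Ordered character vector of selected features (selection order).
#' @export
stepwise_select <- function(train, candidate_features, epsilon = 1e-4) {
  canon <- intersect(feature_names(), candidate_features)
  extra <- setdiff(candidate_features, canon)
  candidates <- c(canon, sort(extra))      # canonical order defines tie-break
  selected <- character(0)
  best_auc <- -Inf
  y <- train$label
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    aucs <- vapply(remaining, function(f) {
      m <- suppressWarnings(fit_lda(train, c(selected, f)))
      auc_rank(lda_scores(m, train), y)
    }, numeric(1))
    top_auc <- max(aucs)
    top <- remaining[which.max(aucs)]      # which.max: first maximum = canonical
    if (length(selected) && top_auc - best_auc <= epsilon) break
    selected <- c(selected, top)
    best_auc <- top_auc
  }
  selected
}

## Rank-statistic AUC: P(score_equal > score_different) with half credit for
## ties; exactly the trapezoidal area under the full threshold-sweep ROC.
auc_rank <- function(scores, labels) {
  pos <- scores[labels == "equal"]; neg <- scores[labels == "different"]
  if (!length(pos) || !length(neg))
    stop("undefined ROC: need both classes", call. = FALSE)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Full threshold-sweep ROC of a discriminant on a pair dataset
#'
#' Sweeps the acceptance threshold over all distinct scores (the equivalent
#' of scanning the full range of class prior probabilities): at threshold t,
#' TAR is the percentage of equal-ID pairs with score >= t and TRR the
#' percentage of different-ID pairs with score < t. The AUC is the
#' trapezoidal area under (FAR, TAR), which equals the rank statistic
#' P(score_equal > score_different) with half credit for ties.
#'
#' @param model An [fit_lda()] model.
#' @param data A `pair_dataset` containing both classes.
#' @return Object of class `roc_curve`: data.frame with `threshold`, `tar`,
#'   `trr` (percent), ordered by decreasing threshold, with attribute `auc`.
#' @export
compute_roc <- function(model, data) {
  scores <- lda_scores(model, data)
  y <- data$label
  pos <- scores[y == "equal"]; neg <- scores[y == "different"]
  if (!length(pos) || !length(neg))
    stop("undefined ROC: dataset contains a single class", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tar <- vapply(thr, function(t) mean(pos >= t), numeric(1)) * 100
  trr <- vapply(thr, function(t) mean(neg < t), numeric(1)) * 100
  curve <- data.frame(threshold = thr, tar = tar, trr = trr)
  far <- 100 - trr
  auc <- sum(diff(far) * (tar[-1] + tar[-length(tar)]) / 2) / 1e4
  structure(curve, auc = auc, class = c("roc_curve", "data.frame"))
}

#' Area under a ROC curve
#' @param roc A [compute_roc()] result.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Equal-error-rate operating point of a training ROC
#'
#' Finds the acceptance threshold at which TAR and TRR are balanced. When the
#' crossing TAR = TRR falls between two sweep points, the reported operating
#' TAR/TRR (equal at the crossing) and threshold are obtained by linear
#' interpolation between the two neighboring points.
#'
#' @param roc A [compute_roc()] result from training data.
#' @return Object of class `operating_point`: list with `threshold`, `tar`,
#'   `trr` (training values at the point).
#' @export
pick_eer_operating_point <- function(roc) {
  d <- roc$tar - roc$trr
  k <- which.min(abs(d))
  ## adjacent sweep point on the other side of the TAR = TRR crossing
  k2 <- if (k > 1L && sign(d[k - 1L]) != sign(d[k])) k - 1L
        else if (k < nrow(roc) && sign(d[k + 1L]) != sign(d[k])) k + 1L
        else NA_integer_
  if (d[k] == 0 || is.na(k2)) {
    pt <- list(threshold = roc$threshold[k], tar = roc$tar[k], trr = roc$trr[k])
  } else {
    i <- min(k, k2); j <- max(k, k2)
    alpha <- d[i] / (d[i] - d[j])
    thr_i <- roc$threshold[i]; thr_j <- roc$threshold[j]
    if (!is.finite(thr_i)) thr_i <- thr_j     # Inf endpoint: keep finite threshold
    pt <- list(threshold = thr_i + alpha * (thr_j - thr_i),
               tar = roc$tar[i] + alpha * (roc$tar[j] - roc$tar[i]),
               trr = roc$trr[i] + alpha * (roc$trr[j] - roc$trr[i]))
  }
  structure(pt, class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> threshold %.4g: TAR %.2f%%, TRR %.2f%%\n",
              x$threshold, x$tar, x$trr))
  invisible(x)
}

#' Evaluate a fixed verifier at a fixed operating point
#'
#' Applies the decision rule "accept when score >= threshold" to a pair
#' dataset and reports the true acceptance rate (TAR, over equal-ID pairs),
#' true rejection rate (TRR, over different-ID pairs) and true verification
#' rate TVR = (TAR + TRR) / 2, all in percent. The complements are the
#' usual error rates: FAR = 100 - TAR, FRR = 100 - TRR, and EER = 100 - TVR
#' when TAR = TRR.
#'
#' @param model An [fit_lda()] model.
#' @param point An [pick_eer_operating_point()] result (threshold fixed
#'   before seeing `data`).
#' @param data A `pair_dataset`.
#' @return Object of class `verification_report`: list with `tar`, `trr`,
#'   `tvr`, `n_equal`, `n_different`, `accepted_equal`, `rejected_different`.
#' @export
evaluate_verifier <- function(model, point, data) {
  scores <- lda_scores(model, data)
  y <- data$label
  ne <- sum(y == "equal"); nd <- sum(y == "different")
  if (ne == 0L || nd == 0L)
    stop("undefined rate: dataset must contain both equal and different pairs",
         call. = FALSE)
  acc <- scores >= point$threshold
  ke <- sum(acc[y == "equal"]); kd <- sum(!acc[y == "different"])
  structure(list(tar = 100 * ke / ne, trr = 100 * kd / nd,
                 tvr = 100 * (ke / ne + kd / nd) / 2,
                 n_equal = ne, n_different = nd,
                 accepted_equal = ke, rejected_different = kd),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("TAR %.2f%% (%d/%d)  TRR %.2f%% (%d/%d)  TVR %.2f%%\n",
              x$tar, x$accepted_equal, x$n_equal,
              x$trr, x$rejected_different, x$n_different, x$tvr))
  invisible(x)
}

#' Load a pattern-matching feature table
#'
#' Reads pair records (24 features, identity label, optional train/test
#' subset labels and covariates) from a CSV/TSV file or from a ZIP archive
#' containing one (the layout of published supplementary feature archives).
#' Column names are matched case-insensitively: features by the presence of
#' a `tEQU`/`aDIF` token and a lead token, the label by values in
#' {equal, different} or {1, 0}, the subset by values in {training, test}.
#'
#' @param path CSV/TSV file or ZIP archive.
#' @return When subset labels are present, a list with `train` and `test`
#'   `pair_dataset`s; otherwise a single `pair_dataset` with role "test".
#' @export
load_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("s1file")
    files <- utils::unzip(path, exdir = exdir)
    tab <- files[grepl("\\.(csv|tsv|txt)$", files, ignore.case = TRUE)]
    if (!length(tab))
      stop("no CSV/TSV table found inside archive ", path, call. = FALSE)
    path <- tab[[1L]]
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  canon <- map_feature_columns(names(df))
  unmatched <- setdiff(feature_names(), canon$feature_map$canonical)
  if (length(unmatched))
    stop("column-mapping error: no source column for feature(s): ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  out <- data.frame(
    id_s1 = pick_col(df, canon$id_s1, as.character, "S1-"),
    id_s2 = pick_col(df, canon$id_s2, as.character, "S2-"),
    stringsAsFactors = FALSE)
  lab_raw <- if (!is.na(canon$label)) df[[canon$label]] else
    stop("column-mapping error: no identity-label column found", call. = FALSE)
  out$label <- factor(ifelse(normalize_label(lab_raw), "equal", "different"),
                      levels = c("equal", "different"))
  for (k in seq_len(nrow(canon$feature_map)))
    out[[canon$feature_map$canonical[k]]] <-
      as.numeric(df[[canon$feature_map$source[k]]])
  for (cv in c("age", "sex", "hr_s1", "hr_s2"))
    if (!is.na(canon[[cv]])) out[[cv]] <- df[[canon[[cv]]]]
  if (!is.na(canon$subset)) {
    subs <- tolower(as.character(df[[canon$subset]]))
    is_train <- grepl("train", subs)
    list(train = structure(out[is_train, , drop = FALSE], role = "training",
                           class = c("pair_dataset", "data.frame")),
         test = structure(out[!is_train, , drop = FALSE], role = "test",
                          class = c("pair_dataset", "data.frame")))
  } else {
    structure(out, role = "test", class = c("pair_dataset", "data.frame"))
  }
}

pick_col <- function(df, col, f, fallback_prefix) {
  if (!is.na(col)) f(df[[col]]) else paste0(fallback_prefix, seq_len(nrow(df)))
}

normalize_label <- function(x) {
  if (is.numeric(x)) return(x != 0)
  lx <- tolower(trimws(as.character(x)))
  if (all(lx %in% c("equal", "different"))) return(lx == "equal")
  if (all(lx %in% c("1", "0"))) return(lx == "1")
  if (all(lx %in% c("same", "different"))) return(lx == "same")
  stop("column-mapping error: unrecognized identity labels: ",
       paste(utils::head(unique(lx), 5), collapse = ", "), call. = FALSE)
}

## Heuristic, case-insensitive mapping of source columns onto the canonical
## schema; returns NA for absent optional columns.
map_feature_columns <- function(cols) {
  lc <- tolower(cols)
  find1 <- function(pattern) {
    hit <- grep(pattern, lc)
    if (length(hit)) cols[hit[1L]] else NA_character_
  }
  lead_pat <- c(I = "(^|[^a-z])i([^a-z]|$)|lead_?i$", II = "(^|[^a-z])ii([^a-z]|$)",
                III = "(^|[^a-z])iii([^a-z]|$)", aVR = "avr", aVL = "avl",
                aVF = "avf", V1 = "v1", V2 = "v2", V3 = "v3", V4 = "v4",
                V5 = "v5", V6 = "v6")
  fmap <- do.call(rbind, lapply(c("tequ", "adif"), function(feat) {
    do.call(rbind, lapply(names(lead_pat), function(lead) {
      hits <- grep(feat, lc)
      hits <- hits[grepl(lead_pat[[lead]], lc[hits])]
      ## exclude longer lead names swallowing shorter ones (I vs II vs III)
      if (lead %in% c("I", "II"))
        hits <- hits[!grepl(if (lead == "I") "iii|ii" else "iii",
                            sub(feat, "", lc[hits]))]
      data.frame(canonical = paste0(ifelse(feat == "tequ", "tEQU_", "aDIF_"), lead),
                 source = if (length(hits)) cols[hits[1L]] else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }))
  fmap <- fmap[!is.na(fmap$source), , drop = FALSE]
  list(feature_map = fmap,
       id_s1 = find1("id.*s1|s1.*id|subject_id_s1"),
       id_s2 = find1("id.*s2|s2.*id|subject_id_s2"),
       label = find1("label|identity|equal"),
       subset = find1("subset|dataset|partition|train"),
       age = find1("^age$|age"),
       sex = find1("sex|gender"),
       hr_s1 = find1("hr.*s1|s1.*hr"),
       hr_s2 = find1("hr.*s2|s2.*hr"))
}

#' Write a pair-feature table to CSV
#'
#' Schema `subject_id_s1,subject_id_s2,label,{tEQU,aDIF}_{I..V6}` (plus any
#' covariate columns present), percentages with 4 decimals; the same layout
#' [load_feature_table()] reads back.
#'
#' @param data A `pair_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  df <- as.data.frame(data)
  names(df)[names(df) == "id_s1"] <- "subject_id_s1"
  names(df)[names(df) == "id_s2"] <- "subject_id_s2"
  for (f in intersect(feature_names(), names(df)))
    df[[f]] <- formatC(df[[f]], format = "f", digits = 4)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-lead feature medians and quartiles by identity label
#'
#' Summarizes the distribution of tEQU and aDIF per lead separately for
#' equal-ID and different-ID pairs: median and interquartile bounds, the
#' format in which cohort-level feature stability is usually reported.
#'
#' @param data A `pair_dataset` (or rbind of several).
#' @return data.frame with one row per lead and columns
#'   `{tEQU,aDIF}_{equal,different}_{median,q1,q3}`.
#' @export
feature_summary <- function(data) {
  out <- data.frame(lead = LEAD_NAMES, stringsAsFactors = FALSE)
  for (feat in c("tEQU", "aDIF")) for (lab in c("equal", "different")) {
    vals <- vapply(LEAD_NAMES, function(lead) {
      v <- data[data$label == lab, paste0(feat, "_", lead)]
      stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    }, numeric(3))
    out[[paste(feat, lab, "median", sep = "_")]] <- vals[1L, ]
    out[[paste(feat, lab, "q1", sep = "_")]] <- vals[2L, ]
    out[[paste(feat, lab, "q3", sep = "_")]] <- vals[3L, ]
  }
  out
}
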