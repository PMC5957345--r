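#' Train a QRS template-matching identity verifier
#'
#' The top-level fitting function: from a balanced training set of
#' S2-vs-S1 pair features it (1) selects features by greedy forward
#' stepwise search maximizing the training ROC AUC within the requested
#' lead configuration, (2) fits the pooled-covariance linear discriminant
#' on the selection, (3) computes the full training ROC, and (4) calibrates
#' the acceptance threshold at the equal-error-rate point (TAR = TRR) of
#' that ROC. The returned object verifies claimed identities on new pairs
#' with `predict()` and is evaluated on an independent test set with
#' [verification_report()].
#'
#' @param train A training `pair_dataset` (balanced equal/different pairs),
#'   from [build_pair_datasets()] or [load_feature_table()].
#' @param leads Lead configuration: a single lead name (its 2 features),
#'   `"limb"` (12 features of I..aVF), `"chest"` (V1..V6), `"all"` (24
#'   features, default), or a character vector of lead names.
#' @param epsilon Stepwise stopping threshold on AUC improvement.
#' @return Object of class `qrs_verifier` with components `model`
#'   ([fit_lda()] result), `operating_point`, `roc_train`, `auc_train`,
#'   `leads`, `candidate_features`, `call`.
#' @seealso [predict.qrs_verifier()], [verification_report()],
#'   [plot.qrs_verifier()]
#' @examples
#' sim <- simulate_cohort(12, seed = 42)
#' cohort <- extract_cohort_patterns(sim$beats, covariates = sim$covariates)
#' ds <- build_pair_datasets(cohort)
#' v <- qrs_verifier(ds$train, leads = "all")
#' verification_report(v, ds$test)
#' @export
qrs_verifier <- function(train, leads = "all", epsilon = 1e-4) {
  candidates <- lead_feature_set(leads)
  candidates <- intersect(candidates, names(train))
  if (!length(candidates))
    stop("no candidate features for lead configuration in the data", call. = FALSE)
  selected <- stepwise_select(train, candidates, epsilon)
  model <- fit_lda(train, selected)
  roc <- compute_roc(model, train)
  point <- pick_eer_operating_point(roc)
  structure(list(model = model, operating_point = point, roc_train = roc,
                 auc_train = roc_auc(roc), leads = leads,
                 candidate_features = candidates, call = match.call()),
            class = "qrs_verifier")
}

#' Feature names of a lead configuration
#'
#' @param leads As in [qrs_verifier()].
#' @return Character vector of feature names in canonical order.
#' @export
lead_feature_set <- function(leads) {
  limb <- LEAD_NAMES[1:6]; chest <- LEAD_NAMES[7:12]
  sel <- if (identical(leads, "all")) LEAD_NAMES
         else if (identical(leads, "limb")) limb
         else if (identical(leads, "chest")) chest
         else leads
  bad <- setdiff(sel, LEAD_NAMES)
  if (length(bad))
    stop("unknown lead(s): ", paste(bad, collapse = ", "), call. = FALSE)
  intersect(feature_names(),
            as.vector(rbind(paste0("tEQU_", sel), paste0("aDIF_", sel))))
}

#' @export
print.qrs_verifier <- function(x, ...) {
  cat("QRS template-matching identity verifier\n")
  cat(sprintf("  leads: %s  |  features: %s\n",
              paste(x$leads, collapse = ","),
              paste(x$model$selected_features, collapse = ", ")))
  cat(sprintf("  training AUC %.4f; EER operating point: threshold %.4g (TAR = TRR = %.2f%%)\n",
              x$auc_train, x$operating_point$threshold, x$operating_point$tar))
  invisible(x)
}

#' @export
summary.qrs_verifier <- function(object, ...) {
  op <- object$operating_point
  structure(list(leads = object$leads,
                 selected_features = object$model$selected_features,
                 coefficients = stats::coef(object),
                 auc_train = object$auc_train,
                 train_tar = op$tar, train_trr = op$trr,
                 train_tvr = (op$tar + op$trr) / 2,
                 train_eer = 100 - (op$tar + op$trr) / 2,
                 shrinkage_gamma = object$model$shrinkage_gamma),
            class = "summary.qrs_verifier")
}

#' @export
print.summary.qrs_verifier <- function(x, ...) {
  cat("QRS template-matching identity verifier\n")
  cat(sprintf("Lead configuration: %s\n", paste(x$leads, collapse = ",")))
  cat("Selected features (stepwise order):\n")
  print(x$coefficients)
  cat(sprintf("Training: AUC %.4f; EER point TAR = TRR = %.2f%% (EER %.2f%%)\n",
              x$auc_train, x$train_tar, x$train_eer))
  if (x$shrinkage_gamma > 0)
    cat(sprintf("(pooled covariance shrunk, gamma = %g)\n", x$shrinkage_gamma))
  invisible(x)
}

#' @export
coef.qrs_verifier <- function(object, ...) {
  c(object$model$weights, `(intercept)` = object$model$intercept)
}

#' Predict identity-verification outcomes for new pairs
#'
#' @param object A [qrs_verifier()].
#' @param newdata A `pair_dataset` or data.frame with the model's features.
#' @param type `"score"` for the discriminant score (higher favors equal
#'   identity), `"decision"` for the accept/reject factor at the trained
#'   EER threshold.
#' @param ... Unused.
#' @return Numeric scores or a factor with levels accept/reject.
#' @export
predict.qrs_verifier <- function(object, newdata,
                                 type = c("score", "decision"), ...) {
  type <- match.arg(type)
  s <- lda_scores(object$model, newdata)
  if (type == "score") s
  else factor(ifelse(s >= object$operating_point$threshold, "accept", "reject"),
              levels = c("accept", "reject"))
}

#' Evaluate a trained verifier on an independent pair dataset
#'
#' Convenience wrapper around [evaluate_verifier()] using the verifier's
#' trained EER threshold; also reports the test ROC AUC.
#'
#' @param verifier A [qrs_verifier()].
#' @param data A test `pair_dataset`.
#' @return A `verification_report` with an additional `auc` element.
#' @export
verification_report <- function(verifier, data) {
  stopifnot(inherits(verifier, "qrs_verifier"))
  rep <- evaluate_verifier(verifier$model, verifier$operating_point, data)
  rep$auc <- auc_rank(lda_scores(verifier$model, data), data$label)
  rep
}

#' Plot training (and optionally test) ROC curves of a verifier
#'
#' Base-graphics ROC plot (TAR vs FAR) with the EER diagonal TAR = TRR and
#' the trained operating point marked.
#'
#' @param x A [qrs_verifier()].
#' @param test Optional test `pair_dataset` whose ROC is overlaid.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qrs_verifier <- function(x, test = NULL, ...) {
  roc <- x$roc_train
  graphics::plot(100 - roc$trr, roc$tar, type = "l", xlim = c(0, 100),
                 ylim = c(0, 100), xlab = "FAR = 100 - TRR (%)",
                 ylab = "TAR (%)",
                 main = "QRS-matching verifier ROC", ...)
  graphics::abline(100, -1, lty = 3, col = "grey50")   # EER line TAR = TRR
  op <- x$operating_point
  graphics::points(100 - op$trr, op$tar, pch = 1, cex = 1.3)
  if (!is.null(test)) {
    roc_t <- compute_roc(x$model, test)
    graphics::lines(100 - roc_t$trr, roc_t$tar, col = "red3")
    graphics::legend("bottomright", c("training", "test"),
                     col = c("black", "red3"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Serialize / restore a trained verifier as JSON
#'
#' Stores the selected features, discriminant weights, intercept, operating
#' threshold and a configuration fingerprint; enough to score and decide on
#' new feature tables.
#'
#' @param verifier A [qrs_verifier()].
#' @param path Output JSON path.
#' @return `path` invisibly; `read_verifier_json()` returns a reduced
#'   `qrs_verifier` usable with [predict()] and [verification_report()].
#' @export
write_verifier_json <- function(verifier, path) {
  op <- verifier$operating_point
  obj <- list(package = "qrsmatch",
              leads = verifier$leads,
              selected_features = verifier$model$selected_features,
              weights = as.list(verifier$model$weights),
              intercept = verifier$model$intercept,
              threshold = op$threshold,
              train_tar = op$tar, train_trr = op$trr,
              auc_train = verifier$auc_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_verifier_json
#' @export
read_verifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(selected_features = obj$selected_features,
                          weights = unlist(obj$weights),
                          intercept = obj$intercept,
                          class_means = NULL, pooled_covariance = NULL,
                          shrinkage_gamma = 0),
                     class = "lda_model")
  structure(list(model = model,
                 operating_point = structure(list(threshold = obj$threshold,
                                                  tar = obj$train_tar,
                                                  trr = obj$train_trr),
                                             class = "operating_point"),
                 roc_train = NULL, auc_train = obj$auc_train,
                 leads = obj$leads, candidate_features = NULL,
                 call = NULL),
            class = "qrs_verifier")
}
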