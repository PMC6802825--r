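# The random forest fold classifier: fitting, confidence tiers, per-target
# cross-validation, and the TM-score regression variant.

TIER_LEVELS <- c("failed", "low", "medium", "high")

#' Confidence tier of a classifier score
#'
#' high: score > 0.5; medium: 0.3 < score <= 0.5; low: 0.1 < score <= 0.3;
#' failed: score <= 0.1. Boundaries belong to the lower tier.
#'
#' @param score Numeric scores in `[0, 1]`.
#' @return Ordered factor with levels failed < low < medium < high.
#' @export
confidence_tier <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 1))
    stop("scores must lie in [0, 1]")
  cut(score, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf), labels = TIER_LEVELS,
      right = TRUE, ordered_result = TRUE)
}

strip_meta <- function(features) {
  features[setdiff(names(features), c("target_id", "model_id", "tm",
                                      "label"))]
}

#' Fit the random forest fold classifier
#'
#' Fits a random forest to per-model feature vectors (see
#' [featurize_ensemble()]). With `task = "classify"` the response is the
#' correct-fold label (TM-score >= 0.5) and [predict.rfqa()] returns the
#' fraction of trees voting correct, interpreted as an estimated
#' probability that the model is in the correct fold; with `task =
#' "regress"` the forest predicts the TM-score itself. Defaults follow the
#' published configuration: 500 trees and 7 candidate features per split,
#' with no class reweighting and no feature normalisation (tree ensembles
#' need none).
#'
#' @param features Data frame of feature columns; `target_id`, `model_id`,
#'   `tm`, and `label` columns are ignored as predictors. The column set
#'   becomes the stored feature manifest.
#' @param labels Logical correct-fold labels (`classify`) or numeric
#'   TM-scores (`regress`).
#' @param ntree Number of trees (default 500).
#' @param mtry Candidate features per split (default 7).
#' @param seed Integer seed fixing the forest; results are deterministic
#'   for a fixed seed.
#' @param task `"classify"` or `"regress"`.
#' @param classwt Optional class weights (default none).
#' @param importance Compute permutation importance (default TRUE).
#' @return An object of class `rfqa` with elements `forest`, `manifest`,
#'   and `config`.
#' @seealso [predict.rfqa()], [confidence_tier()], [rfqa_cv()]
#' @export
rfqa <- function(features, labels, ntree = 500L, mtry = 7L, seed = NULL,
                 task = c("classify", "regress"), classwt = NULL,
                 importance = TRUE) {
  task <- match.arg(task)
  x <- strip_meta(features)
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  if (anyNA(x)) stop("features contain missing values; impute first")
  if (length(labels) != nrow(x))
    stop("labels must match feature rows")
  if (mtry < 1L || mtry > ncol(x))
    stop("mtry must be between 1 and the number of features")
  if (task == "classify") {
    if (is.numeric(labels) && !is.logical(labels)) {
      message("numeric labels interpreted as TM-scores; using tm >= 0.5")
      labels <- is_correct_fold(labels)
    }
    if (anyNA(labels)) stop("labels contain missing values")
    if (length(unique(labels)) < 2L)
      stop("both classes must be present to train a classifier")
    y <- factor(labels, levels = c(FALSE, TRUE))
  } else {
    if (anyNA(labels) || !is.numeric(labels))
      stop("regression labels must be numeric TM-scores")
    y <- as.numeric(labels)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(ntree), mtry = as.integer(mtry),
    classwt = classwt, importance = importance)
  structure(
    list(forest = forest,
         manifest = names(x),
         config = list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                       seed = seed, task = task,
                       manifest_hash = paste(names(x), collapse = "|")),
         n_obs = nrow(x)),
    class = "rfqa")
}

#' @export
print.rfqa <- function(x, ...) {
  cat(sprintf("<rfqa> random forest %s (%d trees, mtry %d, %d features, %d models)\n",
              x$config$task, x$config$ntree, x$config$mtry,
              length(x$manifest), x$n_obs))
  invisible(x)
}

#' @export
summary.rfqa <- function(object, n_top = 10L, ...) {
  print(object)
  imp <- randomForest::importance(object$forest)
  ord <- order(imp[, ncol(imp)], decreasing = TRUE)
  cat("top features by importance:\n")
  print(utils::head(imp[ord, , drop = FALSE], n_top))
  invisible(object)
}

#' @export
plot.rfqa <- function(x, n = 20L, ...) {
  randomForest::varImpPlot(x$forest, n.var = min(n, length(x$manifest)),
                           main = "rfqa feature importance", ...)
}

#' Predict correct-fold scores for new models
#'
#' For a classifier, returns the fraction of trees voting correct together
#' with the confidence tier; for a regressor, the predicted TM-score and
#' the derived correct/incorrect call at the 0.5 cutoff.
#'
#' @param object A fitted [rfqa()] model.
#' @param features Data frame containing every column of the stored feature
#'   manifest (id columns are carried through when present).
#' @param ... Unused.
#' @return Data frame with `score` and `tier` (classify) or `tm_pred` and
#'   `correct` (regress), preceded by `target_id`/`model_id` when present.
#' @export
predict.rfqa <- function(object, features, ...) {
  miss <- setdiff(object$manifest, names(features))
  if (length(miss))
    stop("features lack manifest columns: ", paste(miss, collapse = ", "))
  x <- features[object$manifest]
  if (anyNA(x)) stop("features contain missing values; impute first")
  meta <- features[intersect(c("target_id", "model_id"), names(features))]
  if (object$config$task == "classify") {
    votes <- predict(object$forest, newdata = x, type = "vote",
                     norm.votes = TRUE)
    score <- as.numeric(votes[, "TRUE"])
    out <- data.frame(score = score, tier = confidence_tier(score))
  } else {
    tm_pred <- as.numeric(predict(object$forest, newdata = x))
    out <- data.frame(tm_pred = tm_pred, correct = tm_pred >= 0.5)
  }
  if (ncol(meta)) out <- cbind(meta, out)
  rownames(out) <- NULL
  out
}

#' Per-target cross-validation
#'
#' Splits targets (not models) into folds so that all models of a target
#' fall in exactly one fold, fits on the remaining folds, and reports the
#' held-out per-model AUC for each fold.
#'
#' @param features Feature data frame including a `target_id` column.
#' @param labels Logical correct-fold labels per row.
#' @param folds Number of folds (default 5); must not exceed the number of
#'   targets.
#' @param seed Integer seed controlling the fold assignment and the
#'   forests.
#' @param ... Passed to [rfqa()].
#' @return List with `metrics` (per-fold data frame: fold, n_targets,
#'   n_models, auc) and `assignments` (target to fold).
#' @export
rfqa_cv <- function(features, labels, folds = 5L, seed = 1L, ...) {
  if (!"target_id" %in% names(features))
    stop("features need a target_id column for per-target splitting")
  targets <- unique(features$target_id)
  if (length(targets) < folds)
    stop("fewer targets than folds")
  set.seed(as.integer(seed))
  assign <- sample(rep(seq_len(folds), length.out = length(targets)))
  names(assign) <- targets
  metrics <- data.frame(fold = seq_len(folds), n_targets = NA_integer_,
                        n_models = NA_integer_, auc = NA_real_)
  for (f in seq_len(folds)) {
    test_targets <- targets[assign == f]
    te <- features$target_id %in% test_targets
    fit <- rfqa(features[!te, , drop = FALSE], labels[!te],
                seed = seed + f, ...)
    pr <- predict(fit, features[te, , drop = FALSE])
    metrics$n_targets[[f]] <- length(test_targets)
    metrics$n_models[[f]] <- sum(te)
    metrics$auc[[f]] <- roc_auc(pr$score, labels[te])
  }
  list(metrics = metrics, assignments = assign)
}
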