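# Evaluation surfaces: per-target ranking, tier reports, ROC/AUC,
# true-positive-vs-FPR curves, and the two large-scale-study baselines.

#' Rank models and select the top k
#'
#' Descending score; ties broken lexicographically by model id.
#'
#' @param scores Numeric scores.
#' @param model_ids Character model identifiers.
#' @param k Number of models to return.
#' @return Character vector of the top-k model ids.
#' @export
rank_and_select <- function(scores, model_ids, k = 1L) {
  if (!length(scores)) stop("at least one model is required")
  model_ids <- as.character(model_ids)
  ord <- order(-scores, model_ids)
  model_ids[ord][seq_len(min(k, length(ord)))]
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

per_target_top <- function(predictions, labels) {
  need <- c("target_id", "model_id", "score")
  if (!all(need %in% names(predictions)))
    stop("predictions need columns: ", paste(need, collapse = ", "))
  if (!all(c("target_id", "model_id", "tm") %in% names(labels)))
    stop("labels need columns target_id, model_id, tm")
  df <- merge(predictions, labels[c("target_id", "model_id", "tm")],
              by = c("target_id", "model_id"))
  if (nrow(df) != nrow(predictions))
    stop("missing labels for some predictions")
  split_df <- split(df, df$target_id)
  rows <- lapply(split_df, function(d) {
    ord <- order(-d$score, d$model_id)
    d <- d[ord, , drop = FALSE]
    data.frame(target_id = d$target_id[[1L]],
               top_score = d$score[[1L]],
               tier = as.character(confidence_tier(d$score[[1L]])),
               top1_correct = is_correct_fold(d$tm[[1L]]),
               top5_correct = any(is_correct_fold(
                 d$tm[seq_len(min(5L, nrow(d)))])),
               top1_tm = d$tm[[1L]],
               top5_best_tm = max(d$tm[seq_len(min(5L, nrow(d)))]),
               max_correct = any(is_correct_fold(d$tm)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

tier_tally <- function(tt) {
  total <- nrow(tt)
  top1 <- sum(tt$top1_correct)
  top5 <- sum(tt$top5_correct)
  data.frame(total = total,
             max = sum(tt$max_correct),
             top1 = top1,
             top5 = top5,
             top1_precision = if (total) round(100 * top1 / total, 1)
                              else NA_real_,
             top5_precision = if (total) round(100 * top5 / total, 1)
                              else NA_real_,
             top1_pct = if (total) round(100 * top1 / total) else NA_real_,
             top5_pct = if (total) round(100 * top5 / total) else NA_real_)
}

#' Per-confidence-tier evaluation report
#'
#' Categorises each target by the confidence tier of its highest-ranking
#' model, then tallies per tier: the number of targets (Total), the number
#' with at least one correct model (Max), and the number whose
#' highest-ranking model (Top1) or best of the five highest-ranking models
#' (Top5) is correct, with precisions both to one decimal
#' (`top1_precision`) and as integer percent (`top1_pct`). A combined
#' high+medium row is attached as `$combined`.
#'
#' @param predictions Data frame with `target_id`, `model_id`, `score`.
#' @param labels Data frame with `target_id`, `model_id`, `tm`.
#' @return An object of class `tier_report`: list with `table` (one row
#'   per tier), `combined`, and `targets` (per-target detail).
#' @export
tier_report <- function(predictions, labels) {
  tt <- per_target_top(predictions, labels)
  tabs <- lapply(TIER_LEVELS, function(tier) {
    cbind(data.frame(tier = tier, stringsAsFactors = FALSE),
          tier_tally(tt[tt$tier == tier, , drop = FALSE]))
  })
  tab <- do.call(rbind, tabs)
  tab <- tab[rev(seq_len(nrow(tab))), ] # high first
  rownames(tab) <- NULL
  combined <- cbind(data.frame(tier = "high+medium",
                               stringsAsFactors = FALSE),
                    tier_tally(tt[tt$tier %in% c("high", "medium"), ,
                                  drop = FALSE]))
  stopifnot(sum(tab$total) == nrow(tt),
            all(tab$top1 <= tab$top5, na.rm = TRUE),
            all(tab$top5 <= tab$max, na.rm = TRUE),
            all(tab$max <= tab$total, na.rm = TRUE))
  structure(list(table = tab, combined = combined, targets = tt),
            class = "tier_report")
}

#' @export
print.tier_report <- function(x, ...) {
  cat("Per-tier model selection performance\n")
  t <- x$table
  cat(sprintf("%-10s %6s %5s %14s %14s\n", "Confidence", "Total", "Max",
              "Top1", "Top5"))
  for (r in seq_len(nrow(t))) {
    cat(sprintf("%-10s %6d %5d %6d (%5.1f%%) %6d (%5.1f%%)\n",
                t$tier[[r]], t$total[[r]], t$max[[r]],
                t$top1[[r]], t$top1_precision[[r]],
                t$top5[[r]], t$top5_precision[[r]]))
  }
  invisible(x)
}

#' True positives against false positive rate, per target
#'
#' Evaluated at every distinct top-model score: targets whose top score is
#' at or above the threshold are called positive; reports the number of
#' called targets whose highest-ranking model is correct (true positives)
#' against the false positive rate.
#'
#' @param predictions,labels As in [tier_report()].
#' @return Data frame with `threshold`, `tp`, `fp`, `fpr`.
#' @export
tp_vs_fpr_curve <- function(predictions, labels) {
  tt <- per_target_top(predictions, labels)
  neg <- sum(!tt$top1_correct)
  if (neg == 0L || neg == nrow(tt))
    stop("both correct and incorrect top-ranked targets are required")
  thr <- sort(unique(tt$top_score), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    called <- tt$top_score >= t
    data.frame(threshold = t,
               tp = sum(called & tt$top1_correct),
               fp = sum(called & !tt$top1_correct),
               fpr = sum(called & !tt$top1_correct) / neg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score threshold achieving a target false positive rate
#'
#' Finds the smallest threshold whose empirical FPR (fraction of negatives
#' scoring strictly above it) does not exceed `fpr_target`, i.e. the most
#' permissive cutoff within the FPR budget, and the resulting
#' classification.
#'
#' @param scores Numeric scores.
#' @param labels Logical labels (both classes required).
#' @param fpr_target Desired false positive rate (e.g. 0.01 or 0.1).
#' @return List with `threshold`, `classification` (logical: score strictly
#'   above threshold), `fpr`, and `tpr`.
#' @export
fpr_threshold_baseline <- function(scores, labels, fpr_target) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  if (fpr_target < 0) stop("unattainable FPR target")
  neg <- scores[!labels]
  cand <- sort(unique(scores))
  thr <- NA_real_
  for (t in cand) {
    if (mean(neg > t) <= fpr_target) { thr <- t; break }
  }
  cls <- scores > thr
  list(threshold = thr,
       classification = cls,
       fpr = mean(cls[!labels]),
       tpr = mean(cls[labels]))
}

#' Convergence baseline for calling targets correct
#'
#' For each target, computes the mean pairwise TM-score of the ten models
#' with the highest value of a chosen score and predicts the target correct
#' when it is strictly above `cutoff` (default 0.65).
#'
#' @param ensembles Named list: per target, a list of at least ten
#'   equal-length models.
#' @param scores Named list: per target, the per-model scores used for the
#'   top-10 selection.
#' @param cutoff Convergence cutoff (default 0.65; 0.37 trades precision
#'   for recall).
#' @return Data frame with `target_id`, `mean_pairwise_tm`,
#'   `predicted_correct`.
#' @export
convergence_baseline <- function(ensembles, scores, cutoff = 0.65) {
  stopifnot(length(ensembles) == length(scores))
  ids <- names(ensembles)
  if (is.null(ids)) ids <- as.character(seq_along(ensembles))
  rows <- lapply(seq_along(ensembles), function(k) {
    mp <- mean_pairwise_topk(ensembles[[k]], scores[[k]])
    data.frame(target_id = ids[[k]], mean_pairwise_tm = mp,
               predicted_correct = mp > cutoff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
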