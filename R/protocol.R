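# Iterative generate-and-assess protocol: grow an ensemble in fixed-size
# batches, re-scoring the whole ensemble after every batch (the ensemble
# feature block changes as models accumulate), until a model of the
# requested confidence appears or the model budget is exhausted.

tier_rank <- function(tier) match(as.character(tier), TIER_LEVELS)

#' Run the iterative generate-and-assess protocol
#'
#' `generator(n)` must return a data frame of model-specific features for
#' `n` new models (columns as in [assemble_features()]: `model_id`, the 12
#' model features, `n_satisfied`, and optionally `tm` for bookkeeping). At
#' every step the ensemble block is recomputed over the full accumulated
#' ensemble, all models are re-scored with the classifier, and the loop
#' stops at the first step whose best model reaches `stop_tier`, or when
#' `max_models` have been generated. A short final batch is accepted (and
#' logged); an empty batch terminates the loop.
#'
#' @param generator Function of one argument `n` producing model batches.
#' @param classifier A fitted [rfqa()] classifier.
#' @param target Named list with `length`, `beff`, `n_predicted_contacts`.
#' @param batch Batch size (default 500).
#' @param max_models Model budget (default 10000).
#' @param stop_tier Confidence tier triggering the stop (default
#'   `"high"`).
#' @param target_id Target identifier.
#' @param fallback_medians See [assemble_features()].
#' @return An object of class `protocol_trace`: a data frame with one row
#'   per step (`n_models`, `best_score`, `best_tier`, and `top5_best_tm`
#'   when labels are available), with attributes `status`
#'   (`"stopped_<tier>"` or `"exhausted"`) and `n_models`.
#' @export
run_protocol <- function(generator, classifier, target, batch = 500L,
                         max_models = 10000L, stop_tier = "high",
                         target_id = "target", fallback_medians = NULL) {
  stopifnot(is.function(generator), inherits(classifier, "rfqa"))
  stop_tier <- match.arg(stop_tier, TIER_LEVELS)
  stop_rank <- tier_rank(stop_tier)
  pool <- NULL
  trace <- list()
  status <- "exhausted"
  while (is.null(pool) || nrow(pool) < max_models) {
    want <- min(batch, max_models - if (is.null(pool)) 0L else nrow(pool))
    new <- generator(want)
    if (is.null(new) || nrow(new) == 0L) {
      message("generator exhausted before the model budget")
      break
    }
    if (nrow(new) < want)
      message("partial batch: ", nrow(new), " of ", want, " models")
    pool <- if (is.null(pool)) new else rbind(pool, new)
    feats <- assemble_features(target, pool, target_id = target_id,
                               fallback_medians = fallback_medians)
    pr <- predict(classifier, feats)
    ord <- order(-pr$score, pr$model_id)
    best <- ord[[1L]]
    step <- data.frame(n_models = nrow(pool),
                       best_score = pr$score[[best]],
                       best_tier = as.character(pr$tier[[best]]),
                       stringsAsFactors = FALSE)
    if ("tm" %in% names(pool)) {
      top5 <- ord[seq_len(min(5L, length(ord)))]
      step$top5_best_tm <- max(pool$tm[top5])
    }
    trace[[length(trace) + 1L]] <- step
    if (tier_rank(step$best_tier) >= stop_rank) {
      status <- paste0("stopped_", stop_tier)
      break
    }
    if (nrow(new) < want) break
  }
  out <- do.call(rbind, trace)
  rownames(out) <- NULL
  structure(out, status = status,
            n_models = if (is.null(pool)) 0L else nrow(pool),
            class = c("protocol_trace", "data.frame"))
}

#' @export
print.protocol_trace <- function(x, ...) {
  cat(sprintf("<protocol_trace> %d step(s), %d models, status %s\n",
              nrow(x), attr(x, "n_models"), attr(x, "status")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Summarise protocol runs over several targets
#'
#' @param traces List of [run_protocol()] traces.
#' @return Data frame with per-target models generated and status, plus a
#'   `median_models` attribute (the median number of models generated).
#' @export
protocol_summary <- function(traces) {
  ids <- names(traces)
  if (is.null(ids)) ids <- as.character(seq_along(traces))
  df <- data.frame(
    target_id = ids,
    n_models = vapply(traces, function(t) as.integer(attr(t, "n_models")),
                      integer(1)),
    status = vapply(traces, function(t) attr(t, "status"), character(1)),
    stringsAsFactors = FALSE)
  attr(df, "median_models") <- stats::median(df$n_models)
  df
}
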