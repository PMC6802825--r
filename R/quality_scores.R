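# Model quality measures: TM-score with fixed correspondence, contact
# satisfaction (PPV), a contact potential, ensemble consensus, the PcombC
# combination, and the top-10 mean pairwise TM convergence statistic.

#' TM-score normalisation distance
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at 0.5 Angstrom as in the
#' standard TM-score implementation (the raw formula is non-positive for
#' very short chains).
#'
#' @param L Chain length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L) {
  max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
}

#' TM-score sum for a fixed set of distances
#'
#' `(1/L) sum_i 1 / (1 + (d_i / d0)^2)`. Useful for closed-form checks; the
#' full score maximises this over superpositions.
#'
#' @param d Per-residue distances in Angstrom.
#' @param L Normalising length (defaults to `length(d)`).
#' @param d0 Normalisation distance; defaults to [tm_d0()] of `L`.
#' @return TM-score contribution in (0, 1].
#' @export
tm_from_distances <- function(d, L = length(d), d0 = tm_d0(L)) {
  sum(1 / (1 + (d / d0)^2)) / L
}

coords_of <- function(x) {
  if (inherits(x, "structure_model")) return(x$xyz)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must be an n x 3 matrix")
  x
}

#' TM-score between two equal-length structures (fixed correspondence)
#'
#' Maximises the TM-score sum over rigid superpositions found by
#' fragment-seeded iterative least-squares superposition (fragment lengths
#' L, L/2, L/4 at stride 4; iterate superpose-on-subset / reselect residues
#' with `d_i < d0` to a fixed point, at most 20 iterations; the best value
#' over all seeds is kept). Residue correspondence is positional: residue i
#' of `model` pairs with residue i of `reference`.
#'
#' @param model,reference [structure_model()]s (or n x 3 matrices) of equal
#'   length `L >= 16` with identical residue indexing.
#' @return TM-score in (0, 1].
#' @export
tm_score_fixed <- function(model, reference) {
  X <- coords_of(reference)
  Y <- coords_of(model)
  if (nrow(X) != nrow(Y)) stop("length mismatch between model and reference")
  if (inherits(model, "structure_model") &&
      inherits(reference, "structure_model") &&
      !identical(model$res_index, reference$res_index))
    stop("model and reference must share residue indexing")
  L <- nrow(X)
  if (L < 16L) stop("TM-score requires length >= 16")
  cpp_tm_score(Y, X, tm_d0(L))
}

#' Correct-fold label from a TM-score
#'
#' @param tm_score Numeric TM-score(s).
#' @return Logical: `tm_score >= 0.5` (correct topology).
#' @export
is_correct_fold <- function(tm_score) {
  tm_score >= 0.5
}

thresholded_pred <- function(predicted, p_threshold) {
  ent <- predicted$entries
  ent[ent$p > p_threshold, , drop = FALSE]
}

contact_pair_key <- function(i, j) paste(i, j)

#' Satisfied predicted contacts
#'
#' Number of predicted contacts (with probability strictly above
#' `p_threshold`) present in the model's observed contact map.
#'
#' @param map_model Observed [contact_map()] of the model.
#' @param predicted [pred_contact_map()] for the target.
#' @param p_threshold Probability threshold (strict).
#' @return Integer count.
#' @export
satisfied_count <- function(map_model, predicted, p_threshold = 0.5) {
  stopifnot(inherits(map_model, "contact_map"),
            inherits(predicted, "pred_contact_map"))
  if (map_model$length != predicted$length)
    stop("map lengths differ")
  ent <- thresholded_pred(predicted, p_threshold)
  if (nrow(ent) == 0L) return(0L)
  obs <- contact_pair_key(map_model$pairs[, 1L], map_model$pairs[, 2L])
  sum(contact_pair_key(ent$i, ent$j) %in% obs)
}

#' Proportion of satisfied predicted contacts (PPV)
#'
#' @inheritParams satisfied_count
#' @return PPV in `[0, 1]`; 0 with a warning when no predicted contact
#'   exceeds the threshold.
#' @export
contact_ppv <- function(map_model, predicted, p_threshold = 0.5) {
  stopifnot(inherits(map_model, "contact_map"),
            inherits(predicted, "pred_contact_map"))
  if (map_model$length != predicted$length)
    stop("map lengths differ")
  ent <- thresholded_pred(predicted, p_threshold)
  if (nrow(ent) == 0L) {
    warning("no predicted contacts above threshold; PPV set to 0")
    return(0)
  }
  satisfied_count(map_model, predicted, p_threshold) / nrow(ent)
}

#' Predicted-contact potential of a model
#'
#' `sum p over satisfied predicted contacts - lambda * sum p over
#' unsatisfied ones`, over all predicted entries (no probability
#' threshold). With `lambda = 0` this is monotone in the satisfied set.
#'
#' @inheritParams satisfied_count
#' @param lambda Penalty weight for unsatisfied contacts (default 0).
#' @return Numeric potential.
#' @export
contact_potential <- function(map_model, predicted, lambda = 0) {
  stopifnot(inherits(map_model, "contact_map"),
            inherits(predicted, "pred_contact_map"))
  if (map_model$length != predicted$length)
    stop("map lengths differ")
  ent <- predicted$entries
  if (nrow(ent) == 0L) return(0)
  obs <- contact_pair_key(map_model$pairs[, 1L], map_model$pairs[, 2L])
  sat <- contact_pair_key(ent$i, ent$j) %in% obs
  sum(ent$p[sat]) - lambda * sum(ent$p[!sat])
}

#' Pairwise TM-score matrix of an ensemble
#'
#' @param models List of equal-length [structure_model()]s (or coordinate
#'   matrices).
#' @return Symmetric numeric matrix of pairwise TM-scores (diagonal 1).
#' @export
tm_matrix <- function(models) {
  coords <- lapply(models, coords_of)
  L <- unique(vapply(coords, nrow, integer(1)))
  if (length(L) != 1L) stop("all models must have equal length")
  if (L < 16L) stop("TM-score requires length >= 16")
  M <- cpp_tm_matrix(coords, tm_d0(L))
  ids <- vapply(seq_along(models), function(k) {
    if (inherits(models[[k]], "structure_model")) models[[k]]$model_id
    else as.character(k)
  }, character(1))
  dimnames(M) <- list(ids, ids)
  M
}

#' Ensemble consensus scores
#'
#' For each model, the mean pairwise TM-score against every other model of
#' the ensemble: a consensus quality estimate in the spirit of pairwise
#' structural agreement scoring.
#'
#' @param models List of at least two equal-length models.
#' @param tm Optional precomputed [tm_matrix()] (avoids recomputation).
#' @return Named numeric vector of per-model consensus scores in (0, 1].
#' @export
consensus_scores <- function(models, tm = NULL) {
  if (length(models) < 2L) stop("consensus requires at least 2 models")
  if (is.null(tm)) tm <- tm_matrix(models)
  n <- nrow(tm)
  (rowSums(tm) - diag(tm)) / (n - 1)
}

#' PcombC-style weighted score combination
#'
#' Weighted sum of a single-model global quality score, a consensus score,
#' and the contact PPV. The combination weights are configurable; the
#' defaults (0.2, 0.5, 0.3) weight the consensus component most.
#'
#' @param proq3d,pcons,ppv Numeric vectors (recycled to a common length).
#'   Missing values propagate.
#' @param weights Numeric vector of three weights.
#' @return Numeric vector of combined scores.
#' @export
pcombc <- function(proq3d, pcons, ppv, weights = c(0.2, 0.5, 0.3)) {
  if (length(weights) != 3L) stop("weights must have length 3")
  weights[1L] * proq3d + weights[2L] * pcons + weights[3L] * ppv
}

#' Mean pairwise TM-score of the ten top-scoring models
#'
#' Selects the ten models with the highest score (ties broken by model id)
#' and returns the mean of their 45 pairwise TM-scores; the convergence
#' statistic used to call a target correct when it exceeds a cutoff.
#'
#' @param models List of at least ten equal-length models.
#' @param scores Numeric score per model (higher is better).
#' @param model_ids Optional ids for tie-breaking; defaults to model ids of
#'   `models` or positional ids.
#' @param k Number of models to select (default 10).
#' @return Mean pairwise TM-score of the selected models.
#' @export
mean_pairwise_topk <- function(models, scores, model_ids = NULL, k = 10L) {
  if (length(models) < k) stop("need at least ", k, " models")
  if (length(scores) != length(models))
    stop("scores must match models in length")
  if (is.null(model_ids))
    model_ids <- vapply(seq_along(models), function(i) {
      if (inherits(models[[i]], "structure_model")) models[[i]]$model_id
      else as.character(i)
    }, character(1))
  top <- order(-scores, model_ids)[seq_len(k)]
  tm <- tm_matrix(models[top])
  mean(tm[upper.tri(tm)])
}
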