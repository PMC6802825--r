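# Contact map alignment: local dynamic-programming alignment with iterative
# refinement (map_align-style) and spectral eigenprofile alignment
# (EigenTHREADER-style).

#' Construct an alignment result
#'
#' @param score Non-negative alignment score.
#' @param mapping Two-column integer matrix of aligned residue positions
#'   (map A, map B), strictly increasing in both columns.
#' @return An object of class `alignment_result`.
#' @export
alignment_result <- function(score, mapping) {
  mapping <- as.matrix(mapping)
  if (NROW(mapping) == 0L) mapping <- matrix(integer(0), 0L, 2L)
  storage.mode(mapping) <- "integer"
  if (ncol(mapping) != 2L) stop("mapping must have two columns")
  if (nrow(mapping) > 1L &&
      (any(diff(mapping[, 1L]) <= 0L) || any(diff(mapping[, 2L]) <= 0L)))
    stop("mapping must be strictly increasing in both coordinates")
  if (!is.finite(score) || score < 0) stop("score must be non-negative")
  colnames(mapping) <- c("a", "b")
  structure(list(score = as.numeric(score),
                 aligned_length = nrow(mapping),
                 mapping = mapping),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %.4f over %d aligned positions\n",
              x$score, x$aligned_length))
  invisible(x)
}

as_obs_pairs <- function(map) {
  if (inherits(map, "contact_map")) return(map)
  if (inherits(map, "pred_contact_map"))
    return(contact_map(map$length, as.matrix(map$entries[, c("i", "j")]),
                       min_separation = 1L))
  stop("expected a contact_map or pred_contact_map")
}

as_pred_entries <- function(map) {
  if (inherits(map, "pred_contact_map")) return(map)
  if (inherits(map, "contact_map")) {
    pr <- map$pairs
    return(pred_contact_map(map$length, pr[, 1L], pr[, 2L],
                            rep(1, nrow(pr))))
  }
  stop("expected a contact_map or pred_contact_map")
}

check_gap_penalties <- function(gap_open, gap_extend) {
  if (!is.finite(gap_open) || !is.finite(gap_extend) ||
      gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be non-positive")
}

pred_matrix_for_cpp <- function(pred) {
  ent <- pred$entries
  cbind(ent$i, ent$j, ent$p)
}

#' Local contact map alignment
#'
#' Aligns an observed (binary) contact map to a predicted (probabilistic)
#' map by iterated double dynamic programming. A matched contact scores
#' `p_pred / (1 + |sep_obs - sep_pred| / sep_tolerance)`; affine gap costs
#' apply to gaps between consecutive aligned positions, and unaligned
#' overhangs are free. The search seeds the residue-pair score matrix from
#' contact-neighbourhood overlap, from diagonal shifts, and (for small maps)
#' from individual contact pairs, refines each seed up to
#' `refinement_iterations` times, and reports the mapping with the best
#' exact score.
#'
#' @param map_obs Observed map ([contact_map()]).
#' @param map_pred Predicted map ([pred_contact_map()]; a binary map is
#'   accepted and treated as probability 1).
#' @param gap_open,gap_extend Non-positive affine gap penalties.
#' @param sep_tolerance Scale of the sequence-separation mismatch discount.
#' @param refinement_iterations Refinement sweeps per seeding.
#' @param shift_stride Stride between diagonal-shift seeds; default adapts
#'   to map size.
#' @return An [alignment_result()].
#' @export
align_local <- function(map_obs, map_pred, gap_open = -1, gap_extend = -0.1,
                        sep_tolerance = 10, refinement_iterations = 20L,
                        shift_stride = NULL) {
  obs <- as_obs_pairs(map_obs)
  pred <- as_pred_entries(map_pred)
  if (obs$length < 1L || pred$length < 1L) stop("zero-length map")
  check_gap_penalties(gap_open, gap_extend)
  if (is.null(shift_stride))
    shift_stride <- max(1L, as.integer((obs$length + pred$length) %/% 40L))
  res <- cpp_align_local(obs$length, pred$length, obs$pairs,
                         pred_matrix_for_cpp(pred),
                         gap_open, gap_extend, sep_tolerance,
                         as.integer(refinement_iterations),
                         as.integer(shift_stride))
  alignment_result(max(res$score, 0), res$mapping)
}

#' Brute-force contact map alignment (testing oracle)
#'
#' Exhaustively enumerates every monotone partial correspondence between two
#' small maps and returns the true optimum under the same scoring as
#' [align_local()]. Exponential: both maps must have length at most
#' `max_length`.
#'
#' @inheritParams align_local
#' @param map_a,map_b The two maps.
#' @param max_length Hard size limit (default 10).
#' @return An [alignment_result()].
#' @export
brute_force_align <- function(map_a, map_b, max_length = 10L,
                              gap_open = -1, gap_extend = -0.1,
                              sep_tolerance = 10) {
  obs <- as_obs_pairs(map_a)
  pred <- as_pred_entries(map_b)
  if (obs$length > max_length || pred$length > max_length)
    stop("maps too large for brute-force alignment (max_length = ",
         max_length, ")")
  check_gap_penalties(gap_open, gap_extend)
  res <- cpp_brute_force_align(obs$length, pred$length, obs$pairs,
                               pred_matrix_for_cpp(pred),
                               gap_open, gap_extend, sep_tolerance)
  alignment_result(max(res$score, 0), res$mapping)
}

#' Score a given mapping under the local-alignment objective
#'
#' @inheritParams align_local
#' @param mapping Two-column matrix of aligned positions.
#' @return Numeric score.
#' @export
mapping_score <- function(map_obs, map_pred, mapping, gap_open = -1,
                          gap_extend = -0.1, sep_tolerance = 10) {
  obs <- as_obs_pairs(map_obs)
  pred <- as_pred_entries(map_pred)
  mapping <- as.matrix(mapping)
  storage.mode(mapping) <- "integer"
  cpp_mapping_score(obs$length, pred$length, obs$pairs,
                    pred_matrix_for_cpp(pred), mapping,
                    gap_open, gap_extend, sep_tolerance)
}

#' Eigenvector profiles of a contact map
#'
#' Leading eigenvectors (by absolute eigenvalue) of the symmetric contact
#' matrix (binary for an observed map, probabilities for a predicted map),
#' each scaled by the square root of its absolute eigenvalue. The sign of
#' each vector is fixed so that its entry of largest magnitude is positive.
#'
#' @param map A [contact_map()] or [pred_contact_map()].
#' @param k Number of eigenvectors (clamped to the map length with a
#'   warning).
#' @return Numeric matrix (length x k).
#' @export
eigen_profiles <- function(map, k = 15L) {
  if (k < 1L) stop("k must be >= 1")
  if (inherits(map, "contact_map")) {
    n <- map$length
    A <- matrix(0, n, n)
    if (nrow(map$pairs)) {
      A[map$pairs] <- 1
      A[map$pairs[, c(2L, 1L), drop = FALSE]] <- 1
    }
  } else if (inherits(map, "pred_contact_map")) {
    n <- map$length
    A <- matrix(0, n, n)
    ent <- map$entries
    if (nrow(ent)) {
      A[cbind(ent$i, ent$j)] <- ent$p
      A[cbind(ent$j, ent$i)] <- ent$p
    }
  } else stop("expected a contact_map or pred_contact_map")
  if (k > n) {
    warning("k exceeds map length; clamped to ", n)
    k <- n
  }
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(k)]
  U <- e$vectors[, ord, drop = FALSE]
  lam <- abs(e$values[ord])
  U <- sweep(U, 2L, sqrt(lam), "*")
  for (c in seq_len(ncol(U))) {
    m <- which.max(abs(U[, c]))
    if (U[m, c] < 0) U[, c] <- -U[, c]
  }
  U
}

#' Align two eigenvector profile sets
#'
#' Residue-pair similarity `S(i, j) = sum_k |u_k(i) v_k(j)|` followed by a
#' global affine-gap alignment. The similarity uses absolute products, so
#' the score is invariant under any per-eigenvector sign flip.
#'
#' @param U,V Profile matrices from [eigen_profiles()] (equal column
#'   counts).
#' @param gap_open,gap_extend Non-positive affine gap penalties.
#' @return An [alignment_result()].
#' @export
align_profiles <- function(U, V, gap_open = -1, gap_extend = -0.1) {
  check_gap_penalties(gap_open, gap_extend)
  if (ncol(U) != ncol(V)) stop("profile column counts differ")
  S <- abs(U) %*% t(abs(V))
  res <- cpp_affine_dp(S, gap_open, gap_extend, FALSE)
  alignment_result(max(res$score, 0), res$mapping)
}

#' Spectral contact map alignment
#'
#' Aligns the leading eigenvector profiles of two contact maps with a global
#' affine-gap dynamic programme (see [eigen_profiles()] and
#' [align_profiles()]).
#'
#' @inheritParams align_local
#' @param k Number of leading eigenvectors (default 15, clamped to the
#'   shorter map with a warning).
#' @return An [alignment_result()].
#' @export
align_spectral <- function(map_obs, map_pred, k = 15L, gap_open = -1,
                           gap_extend = -0.1) {
  la <- map_obs$length
  lb <- map_pred$length
  if (is.null(la) || is.null(lb) || la < 1L || lb < 1L)
    stop("zero-length map")
  k <- min(as.integer(k), la, lb)
  U <- eigen_profiles(map_obs, k)
  V <- eigen_profiles(map_pred, k)
  align_profiles(U, V, gap_open, gap_extend)
}
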