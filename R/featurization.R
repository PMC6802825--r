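# Assembly of the 58-column feature scheme: 3 target-specific + 12
# model-specific + 43 ensemble-specific features per model.

MODEL_FEATURES <- c("saint2", "proq2d", "proq3d", "proqroscend", "proqrosfad",
                    "pcons", "pcombc", "saint2_contact", "ppv", "eigen_score",
                    "mapalign_score", "mapalign_length")
# features summarised with max/min/median/spread (10 of the 12)
ENSEMBLE_FULL <- setdiff(MODEL_FEATURES, c("mapalign_length", "ppv"))
# features contributing only their per-target maximum (note n_satisfied is
# an auxiliary quantity, not one of the 12 model features)
ENSEMBLE_MAX_ONLY <- c("mapalign_length", "ppv", "n_satisfied")
TARGET_FEATURES <- c("length", "beff", "n_predicted_contacts")
EXTERNAL_FEATURES <- c("saint2", "proq2d", "proq3d", "proqroscend",
                       "proqrosfad")

#' The frozen 58-column feature manifest
#'
#' Feature order is fixed: 3 target-specific features, 12 model-specific
#' features, then 43 ensemble-specific features (max, min, median and
#' spread of 10 model features, plus the per-target maxima of the alignment
#' hit length, the contact PPV, and the satisfied-contact count). A fitted
#' classifier stores this manifest and refuses mismatched inputs.
#'
#' @return Character vector of 58 feature names.
#' @export
feature_manifest <- function() {
  ens <- as.vector(vapply(
    ENSEMBLE_FULL,
    function(f) paste0("ens_", c("max", "min", "median", "spread"), "_", f),
    character(4)))
  c(TARGET_FEATURES, MODEL_FEATURES, ens,
    paste0("ens_max_", ENSEMBLE_MAX_ONLY))
}

#' Ensemble summary statistics
#'
#' Maximum, minimum, median, and spread (maximum minus median) of a feature
#' across all models of one target. Missing values are excluded before the
#' statistics are taken.
#'
#' @param values Numeric vector (at least one non-missing value).
#' @return Named numeric vector `c(max, min, median, spread)`.
#' @export
ensemble_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values for ensemble statistics")
  mx <- max(values)
  md <- stats::median(values)
  c(max = mx, min = min(values), median = md, spread = mx - md)
}

#' Read a multiple sequence alignment
#'
#' FASTA alignments are read as-is; A3M input is normalised by deleting
#' lowercase (insertion) columns so all sequences share the master length.
#'
#' @param path Path to the alignment.
#' @param format `"auto"` (by extension), `"fasta"`, or `"a3m"`.
#' @return Character vector of aligned sequences.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m"
              else "fasta"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[#;]", lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no FASTA headers in ", path)
  bounds <- c(heads, length(lines) + 1L)
  seqs <- vapply(seq_along(heads), function(k) {
    paste(lines[(bounds[[k]] + 1L):(bounds[[k + 1L]] - 1L)], collapse = "")
  }, character(1))
  if (format == "a3m")
    seqs <- gsub("[a-z.]", "", seqs)
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment in ", path)
  seqs
}

#' Effective number of sequences (B_eff)
#'
#' Redundancy-weighted sequence count of an alignment:
#' `sum_i 1 / |{j : identity(i, j) >= identity_threshold}|`, where identity
#' is the fraction of alignment columns with identical characters. A single
#' sequence gives 1.
#'
#' @param msa Character vector of equal-length aligned sequences.
#' @param identity_threshold Fractional identity defining redundancy
#'   (default 0.8).
#' @return B_eff, a real `>= 1` (for non-empty alignments).
#' @export
compute_beff <- function(msa, identity_threshold = 0.8) {
  if (!length(msa)) stop("empty alignment")
  lens <- unique(nchar(msa))
  if (length(lens) != 1L) stop("ragged alignment")
  n <- length(msa)
  if (n == 1L) return(1)
  M <- do.call(rbind, strsplit(toupper(msa), ""))
  counts <- numeric(n)
  for (i in seq_len(n)) {
    ident <- rowMeans(M == matrix(M[i, ], n, lens, byrow = TRUE))
    counts[[i]] <- sum(ident >= identity_threshold)
  }
  sum(1 / counts)
}

impute_per_target <- function(df, cols, fallback = NULL) {
  imputed <- character(0)
  for (cl in cols) {
    v <- df[[cl]]
    if (anyNA(v)) {
      if (all(is.na(v))) {
        if (is.null(fallback) || is.na(fallback[[cl]]))
          stop("feature '", cl, "' entirely missing and no fallback median ",
               "available")
        v[] <- fallback[[cl]]
      } else {
        v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      }
      df[[cl]] <- v
      imputed <- c(imputed, cl)
    }
  }
  if (length(imputed))
    message("imputed missing values per-target for: ",
            paste(unique(imputed), collapse = ", "))
  df
}

#' Assemble the 58-column feature vectors for one target
#'
#' Combines the target-specific features, the per-model features, and the
#' ensemble block (computed once across all models of the target and
#' repeated on every row). Missing model-feature values are imputed with
#' the per-target median of the available values (a column missing entirely
#' uses `fallback_medians`); imputation is logged.
#'
#' @param target Named list or vector with `length`, `beff`, and
#'   `n_predicted_contacts`.
#' @param models Data frame with a `model_id` column, the 12 model features
#'   (`saint2`, `proq2d`, `proq3d`, `proqroscend`, `proqrosfad`, `pcons`,
#'   `pcombc`, `saint2_contact`, `ppv`, `eigen_score`, `mapalign_score`,
#'   `mapalign_length`), and the auxiliary `n_satisfied` count.
#' @param target_id Target identifier attached to the output.
#' @param fallback_medians Optional named numeric vector of medians used
#'   when a feature column is entirely missing for the target.
#' @return Data frame with `target_id`, `model_id`, and the 58 feature
#'   columns in [feature_manifest()] order.
#' @export
assemble_features <- function(target, models, target_id = "target",
                              fallback_medians = NULL) {
  need <- c("model_id", MODEL_FEATURES, "n_satisfied")
  miss <- setdiff(need, names(models))
  if (length(miss))
    stop("models table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(models) < 1L) stop("at least one model is required")
  models <- impute_per_target(models, c(MODEL_FEATURES, "n_satisfied"),
                              fallback_medians)
  ens <- numeric(0)
  for (f in ENSEMBLE_FULL) {
    st <- ensemble_stats(models[[f]])
    names(st) <- paste0("ens_", c("max", "min", "median", "spread"), "_", f)
    ens <- c(ens, st)
  }
  for (f in ENSEMBLE_MAX_ONLY)
    ens[[paste0("ens_max_", f)]] <- max(models[[f]], na.rm = TRUE)

  out <- data.frame(target_id = target_id, model_id = models$model_id,
                    stringsAsFactors = FALSE)
  out$length <- as.numeric(target[["length"]])
  out$beff <- as.numeric(target[["beff"]])
  out$n_predicted_contacts <- as.numeric(target[["n_predicted_contacts"]])
  for (f in MODEL_FEATURES) out[[f]] <- models[[f]]
  for (f in names(ens)) out[[f]] <- ens[[f]]
  manifest <- feature_manifest()
  stopifnot(identical(setdiff(names(out), c("target_id", "model_id")),
                      manifest))
  out[c("target_id", "model_id", manifest)]
}

#' Compute features for one target's model ensemble
#'
#' Runs the full per-target feature pipeline: observed contact maps,
#' contact satisfaction (PPV, count, potential), consensus (mean pairwise
#' TM-score), the two contact map alignment scores, the PcombC combination,
#' and the ensemble block. Externally computed single-model scores are
#' merged by `model_id`; absent ones are imputed (see
#' [assemble_features()]).
#'
#' @param models List of [structure_model()]s for one target.
#' @param predicted [pred_contact_map()] for the target.
#' @param external Optional data frame keyed by `model_id` with columns
#'   among `saint2`, `proq2d`, `proq3d`, `proqroscend`, `proqrosfad`.
#' @param beff Effective sequence count of the target's alignment.
#' @param target_id Target identifier.
#' @param native Optional native [structure_model()]; when given, a
#'   TM-score label column `tm` is attached.
#' @param cutoff,min_separation Observed contact map parameters.
#' @param p_threshold Probability threshold for contact counting.
#' @param pcombc_weights Weights passed to [pcombc()].
#' @param fallback_medians See [assemble_features()].
#' @param ... Further arguments passed to [align_local()].
#' @return Data frame of feature vectors (plus `tm` when `native` is
#'   given).
#' @export
featurize_ensemble <- function(models, predicted, external = NULL,
                               beff = 1, target_id = "target",
                               native = NULL, cutoff = 8,
                               min_separation = 5L, p_threshold = 0.5,
                               pcombc_weights = c(0.2, 0.5, 0.3),
                               fallback_medians = NULL, ...) {
  stopifnot(length(models) >= 1L, inherits(predicted, "pred_contact_map"))
  ids <- vapply(models, function(m) m$model_id, character(1))
  maps <- lapply(models, observed_contact_map, cutoff = cutoff,
                 min_separation = min_separation)
  n_pred_thr <- sum(predicted$entries$p > p_threshold)

  ppv <- vapply(maps, function(m) {
    suppressWarnings(contact_ppv(m, predicted, p_threshold))
  }, numeric(1))
  nsat <- vapply(maps, satisfied_count, numeric(1), predicted = predicted,
                 p_threshold = p_threshold)
  pot <- vapply(maps, contact_potential, numeric(1), predicted = predicted)

  if (length(models) >= 2L) {
    cons <- as.numeric(consensus_scores(models))
  } else {
    cons <- 1
  }

  loc <- lapply(maps, align_local, map_pred = predicted, ...)
  spec <- lapply(maps, align_spectral, map_pred = predicted)

  feats <- data.frame(model_id = ids,
                      saint2_contact = pot,
                      ppv = ppv,
                      n_satisfied = as.numeric(nsat),
                      pcons = cons,
                      eigen_score = vapply(spec, `[[`, numeric(1), "score"),
                      mapalign_score = vapply(loc, `[[`, numeric(1), "score"),
                      mapalign_length = vapply(loc, function(a)
                        as.numeric(a$aligned_length), numeric(1)),
                      stringsAsFactors = FALSE)
  for (cl in EXTERNAL_FEATURES) feats[[cl]] <- NA_real_
  if (!is.null(external)) {
    if (!"model_id" %in% names(external))
      stop("external scores need a model_id column")
    m <- match(feats$model_id, external$model_id)
    for (cl in intersect(EXTERNAL_FEATURES, names(external)))
      feats[[cl]] <- as.numeric(external[[cl]])[m]
  }
  feats$pcombc <- pcombc(feats$proq3d, feats$pcons, feats$ppv,
                         pcombc_weights)

  target <- list(length = models[[1L]]$length, beff = beff,
                 n_predicted_contacts = n_pred_thr)
  out <- assemble_features(target, feats, target_id = target_id,
                           fallback_medians = fallback_medians)
  if (!is.null(native)) {
    out$tm <- vapply(models, tm_score_fixed, numeric(1),
                     reference = native)
  }
  out
}
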