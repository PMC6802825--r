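# Self-contained synthetic benchmarks: native-like helical-bundle traces,
# perturbed decoy ensembles spanning a TM-score range, noisy predicted
# contacts with tunable precision/coverage, and simulated external quality
# scores. These emulate the study conditions (per-target decoy ensembles,
# coevolution-derived contacts, external single-model scores) so that the
# whole pipeline is testable without any download.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Generate a native-like backbone trace
#'
#' Builds a compact, self-avoiding representative-atom trace shaped like a
#' bundle of helical segments joined by short turns, with a realistic
#' long-range contact density (contacts per residue between about 1 and 3
#' at 8 Angstrom, minimum separation 5). Deterministic for a fixed seed.
#'
#' @param length Number of residues (at least 16).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param target_id,model_id Identifiers for the returned model.
#' @return A [structure_model()].
#' @export
synth_native <- function(length, seed = NULL, target_id = "synthetic",
                         model_id = "native") {
  if (length < 16L) stop("synthetic natives require length >= 16")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_seg <- max(3L, round(length / 12))
  seg_len <- diff(round(seq(0L, length, length.out = n_seg + 1L)))
  ncol_grid <- ceiling(sqrt(n_seg))
  for (attempt in seq_len(20L)) {
    xyz <- matrix(NA_real_, length, 3L)
    pos <- 0L
    for (s in seq_len(n_seg)) {
      row <- (s - 1L) %/% ncol_grid
      col <- (s - 1L) %% ncol_grid
      if (row %% 2L == 1L) col <- ncol_grid - 1L - col # serpentine
      cx <- col * 8.3 + stats::rnorm(1, 0, 0.4)
      cy <- row * 8.3 + stats::rnorm(1, 0, 0.4)
      up <- s %% 2L == 1L
      t <- seq_len(seg_len[[s]]) - 1L
      theta <- 100 * pi / 180 * t + stats::runif(1, 0, 2 * pi)
      z <- 1.5 * t
      if (!up) z <- max(z) - z
      z <- z - mean(z)
      xyz[pos + seq_len(seg_len[[s]]), ] <-
        cbind(cx + 2.3 * cos(theta), cy + 2.3 * sin(theta), z)
      pos <- pos + seg_len[[s]]
    }
    xyz <- xyz + matrix(stats::rnorm(3L * length, 0, 0.35), length, 3L)
    D <- as.matrix(stats::dist(xyz))
    sep <- abs(outer(seq_len(length), seq_len(length), "-"))
    if (min(D[sep >= 2L]) >= 3) break
    if (attempt == 20L) stop("failed to generate a self-avoiding trace")
  }
  res_name <- sample(AA3, length, replace = TRUE,
                     prob = ifelse(AA3 == "GLY", 2, 1))
  structure_model(model_id, target_id, seq_len(length), res_name, xyz)
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3L, 3L)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# unit-RMS smooth displacement field (low-frequency sinusoidal modes)
smooth_field <- function(L) {
  t <- seq_len(L) / L
  disp <- vapply(1:3, function(cc) {
    f <- rep(0, L)
    for (m in 1:3)
      f <- f + stats::rnorm(1) * sin(pi * m * t + stats::runif(1, 0, 2 * pi))
    f
  }, numeric(L))
  disp / sqrt(mean(rowSums(disp^2)))
}

#' Generate decoys around a native structure
#'
#' Each decoy is the native trace displaced by a smooth, chain-correlated
#' random field (a sum of low-frequency sinusoidal modes per coordinate)
#' scaled to an exact root-mean-square magnitude, plus a random rigid-body
#' motion. Larger noise gives stochastically lower TM-scores.
#'
#' @param native A [structure_model()].
#' @param noise_levels Numeric vector of RMS displacement magnitudes in
#'   Angstrom.
#' @param n_per_level Decoys per noise level.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with `models` (list of [structure_model()]) and `tm`
#'   (numeric labels from [tm_score_fixed()] against the native).
#' @export
synth_decoys <- function(native, noise_levels, n_per_level, seed = NULL) {
  stopifnot(inherits(native, "structure_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- native$length
  models <- list()
  tm <- numeric(0)
  k <- 0L
  for (lv in seq_along(noise_levels)) {
    sigma <- noise_levels[[lv]]
    for (r in seq_len(n_per_level)) {
      k <- k + 1L
      disp <- matrix(0, L, 3L)
      if (sigma > 0) {
        disp <- smooth_field(L) + matrix(stats::rnorm(3L * L, 0, 0.25), L, 3L)
        rms <- sqrt(mean(rowSums(disp^2)))
        disp <- disp * (sigma / rms)
      }
      xyz <- native$xyz + disp
      xyz <- sweep(xyz, 2L, colMeans(xyz)) %*% random_rotation()
      xyz <- sweep(xyz, 2L, stats::rnorm(3, 0, 20), "+")
      id <- sprintf("m%02d_%03d", lv, r)
      models[[k]] <- structure_model(id, native$target_id, native$res_index,
                                     native$res_name, xyz)
      tm[[k]] <- tm_score_fixed(models[[k]], native)
    }
  }
  list(models = models, tm = tm)
}

#' Generate a single-basin (uninformative) decoy ensemble
#'
#' Emulates a modelling run converged to one wrong basin: all decoys
#' cluster tightly around a single attractor structure whose similarity to
#' the native is calibrated (by bisection on the displacement scale) so
#' that decoy TM-scores straddle `tm_target`, with fixed-magnitude
#' isotropic wobble around the attractor. Because every decoy sits at the
#' same distance from the attractor in an independent random direction,
#' pairwise model agreement (the consensus channel) is geometrically
#' decoupled from fold correctness, and correct/incorrect labels flip on
#' sub-Angstrom differences that no ensemble feature tracks.
#'
#' @param native A [structure_model()].
#' @param n Number of decoys.
#' @param tm_target Decoy TM-score the calibration aims at (near the 0.5
#'   fold threshold).
#' @param wobble RMS magnitude of the isotropic within-basin scatter in
#'   Angstrom.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with `models` and `tm` as in [synth_decoys()].
#' @export
synth_basin_decoys <- function(native, n, tm_target = 0.5, wobble = 2.5,
                               seed = NULL) {
  stopifnot(inherits(native, "structure_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- native$length
  field <- smooth_field(L)
  probe <- matrix(stats::rnorm(3L * L), L, 3L)
  probe <- probe * (wobble / sqrt(mean(rowSums(probe^2))))
  lo <- 0; hi <- 25
  for (it in seq_len(18L)) {
    mid <- (lo + hi) / 2
    tmv <- tm_score_fixed(native$xyz + mid * field + probe, native$xyz)
    if (tmv > tm_target) lo <- mid else hi <- mid
  }
  attractor <- native$xyz + ((lo + hi) / 2) * field
  models <- vector("list", n)
  tm <- numeric(n)
  for (r in seq_len(n)) {
    W <- matrix(stats::rnorm(3L * L), L, 3L)
    W <- W * (wobble / sqrt(mean(rowSums(W^2))))
    xyz <- attractor + W
    xyz <- sweep(xyz, 2L, colMeans(xyz)) %*% random_rotation()
    xyz <- sweep(xyz, 2L, stats::rnorm(3, 0, 20), "+")
    models[[r]] <- structure_model(sprintf("b00_%03d", r), native$target_id,
                                   native$res_index, native$res_name, xyz)
    tm[[r]] <- tm_score_fixed(models[[r]], native)
  }
  list(models = models, tm = tm)
}

#' Simulate predicted contacts of tunable quality
#'
#' Keeps a `coverage` fraction of the native contacts as true positives and
#' adds false (non-contact) pairs so that the expected precision against
#' the native map equals `precision`. True entries draw higher
#' probabilities than false ones; all probabilities exceed 0.5.
#'
#' @param native_map Native [contact_map()].
#' @param precision Target precision in (0, 1].
#' @param coverage Fraction of native contacts predicted, in (0, 1].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param min_separation Sequence-separation filter for false pairs
#'   (defaults to the native map's).
#' @return A [pred_contact_map()].
#' @export
synth_predicted_contacts <- function(native_map, precision, coverage,
                                     seed = NULL,
                                     min_separation = NULL) {
  stopifnot(inherits(native_map, "contact_map"))
  if (precision <= 0 || precision > 1 || coverage <= 0 || coverage > 1)
    stop("precision and coverage must lie in (0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(min_separation)) min_separation <- native_map$min_separation
  L <- native_map$length
  nat <- native_map$pairs
  if (nrow(nat) == 0L) stop("native map has no contacts")
  n_tp <- max(1L, round(coverage * nrow(nat)))
  tp <- nat[sample(nrow(nat), n_tp), , drop = FALSE]
  n_fp <- round(n_tp * (1 - precision) / precision)
  ij <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  ij <- ij[ij[, 2L] - ij[, 1L] >= min_separation, , drop = FALSE]
  natkey <- paste(nat[, 1L], nat[, 2L])
  cand <- ij[!(paste(ij[, 1L], ij[, 2L]) %in% natkey), , drop = FALSE]
  if (n_fp > nrow(cand))
    stop("map too small for the requested precision/coverage")
  fp <- cand[sample(nrow(cand), n_fp), , drop = FALSE]
  i <- c(tp[, 1L], fp[, 1L])
  j <- c(tp[, 2L], fp[, 2L])
  p <- c(stats::runif(n_tp, 0.6, 0.99), stats::runif(n_fp, 0.5, 0.8))
  pred_contact_map(L, i, j, p)
}

#' Simulate external quality-score columns
#'
#' Each simulated column is an informativeness-weighted mix of the
#' standardised true TM-score and Gaussian noise, plus a per-target random
#' offset emulating scores that are not comparable between targets.
#'
#' @param tm Numeric vector of true per-model TM-scores.
#' @param informativeness Within-target correlation with the true quality,
#'   in `[0, 1]`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param columns Names of the simulated score columns.
#' @param offset_sd Standard deviation of the per-target offset.
#' @return Data frame of simulated score columns.
#' @export
synth_external_scores <- function(tm, informativeness, seed = NULL,
                                  columns = c("saint2", "proq2d", "proq3d",
                                              "proqroscend", "proqrosfad"),
                                  offset_sd = 1) {
  if (informativeness < 0 || informativeness > 1)
    stop("informativeness must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(tm)
  z <- if (stats::sd(tm) > 0) as.numeric(scale(tm)) else rep(0, n)
  out <- lapply(columns, function(cl) {
    informativeness * z +
      sqrt(1 - informativeness^2) * stats::rnorm(n) +
      stats::rnorm(1, 0, offset_sd)
  })
  names(out) <- columns
  as.data.frame(out)
}

#' Specification of a synthetic benchmark
#'
#' Defaults describe the benchmark used throughout the package's own
#' validation: 8 targets of 40-80 residues with 50 decoys each spanning
#' five perturbation levels, a quarter of the targets "hard" (all
#' perturbations scaled up so modelling essentially fails, emulating
#' mixed-success target sets), contacts predicted at precision 0.7 with
#' coverage 0.9, and external scores correlated 0.8 with the true quality.
#' `ensemble_geometry = "single_basin"` switches the decoy generator to
#' the uninformative condition of [synth_basin_decoys()].
#'
#' @param n_targets Number of targets.
#' @param models_per_target Decoys per target (split over the noise
#'   levels).
#' @param length_range Integer range of target lengths.
#' @param noise_levels RMS decoy perturbations in Angstrom.
#' @param hard_fraction Probability that a target is hard.
#' @param hard_scale Noise multiplier for hard targets.
#' @param contact_precision,contact_coverage Predicted-contact quality.
#' @param informativeness External-score informativeness in `[0, 1]`.
#' @param ensemble_geometry `"basin_mix"` (decoys around the native at the
#'   given noise levels) or `"single_basin"` (uninformative condition).
#' @param attractor_tm_range Range of per-target decoy TM calibration
#'   targets for the single-basin geometry.
#' @param wobble Within-basin scatter for the single-basin geometry.
#' @param beff_log_mean,beff_log_sd Log-normal parameters of the simulated
#'   effective sequence counts.
#' @param seed Integer seed.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_targets = 8L, models_per_target = 50L,
                           length_range = c(40L, 80L),
                           noise_levels = c(1, 2, 3, 5, 8),
                           hard_fraction = 0.25, hard_scale = 4,
                           contact_precision = 0.7,
                           contact_coverage = 0.9,
                           informativeness = 0.8,
                           ensemble_geometry = c("basin_mix",
                                                 "single_basin"),
                           attractor_tm_range = c(0.47, 0.53),
                           wobble = 2.5,
                           beff_log_mean = 5, beff_log_sd = 1.5,
                           seed = 1L) {
  ensemble_geometry <- match.arg(ensemble_geometry)
  if (n_targets < 1L || models_per_target < 1L)
    stop("counts must be >= 1")
  if (contact_precision <= 0 || contact_precision > 1 ||
      contact_coverage <= 0 || contact_coverage > 1)
    stop("contact precision/coverage must lie in (0, 1]")
  if (informativeness < 0 || informativeness > 1)
    stop("informativeness must lie in [0, 1]")
  if (hard_fraction < 0 || hard_fraction > 1)
    stop("hard_fraction must lie in [0, 1]")
  if (models_per_target %% length(noise_levels) != 0L)
    stop("models_per_target must be a multiple of the number of noise levels")
  structure(list(n_targets = as.integer(n_targets),
                 models_per_target = as.integer(models_per_target),
                 length_range = as.integer(length_range),
                 noise_levels = as.numeric(noise_levels),
                 hard_fraction = hard_fraction,
                 hard_scale = hard_scale,
                 contact_precision = contact_precision,
                 contact_coverage = contact_coverage,
                 informativeness = informativeness,
                 ensemble_geometry = ensemble_geometry,
                 attractor_tm_range = as.numeric(attractor_tm_range),
                 wobble = wobble,
                 beff_log_mean = beff_log_mean,
                 beff_log_sd = beff_log_sd,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' The uninformative benchmark condition
#'
#' Convenience constructor for the null condition used in the package's
#' validation: single-basin ensembles ([synth_basin_decoys()]), predicted
#' contacts at precision 0.05 with coverage 0.3, and external scores with
#' informativeness 0. Target length is held fixed so that chain length
#' carries no label information either.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [benchmark_spec()].
#' @return A `benchmark_spec` list.
#' @export
null_benchmark_spec <- function(seed = 1L, ...) {
  benchmark_spec(length_range = c(60L, 60L),
                 hard_fraction = 0,
                 contact_precision = 0.05, contact_coverage = 0.3,
                 informativeness = 0,
                 ensemble_geometry = "single_basin",
                 seed = seed, ...)
}

#' Generate an in-memory synthetic benchmark
#'
#' @param spec A [benchmark_spec()].
#' @return List of per-target lists with elements `target_id`, `native`,
#'   `models`, `tm`, `predicted`, `external`, `beff`.
#' @export
synth_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  n_per_level <- spec$models_per_target %/% length(spec$noise_levels)
  lapply(seq_len(spec$n_targets), function(tix) {
    tid <- sprintf("T%03d", tix)
    L <- if (spec$length_range[[1L]] == spec$length_range[[2L]])
      spec$length_range[[1L]]
    else sample(spec$length_range[[1L]]:spec$length_range[[2L]], 1L)
    native <- synth_native(L, target_id = tid)
    if (spec$ensemble_geometry == "single_basin") {
      dec <- synth_basin_decoys(native, spec$models_per_target,
                                tm_target = stats::runif(
                                  1, spec$attractor_tm_range[[1L]],
                                  spec$attractor_tm_range[[2L]]),
                                wobble = spec$wobble)
      # contacts from an unrelated fold: even sparse true contacts would
      # otherwise leak the per-target attractor quality
      contact_src <- observed_contact_map(synth_native(L))
    } else {
      levels <- spec$noise_levels
      if (stats::runif(1) < spec$hard_fraction)
        levels <- levels * spec$hard_scale
      dec <- synth_decoys(native, levels, n_per_level)
      contact_src <- observed_contact_map(native)
    }
    predicted <- synth_predicted_contacts(contact_src,
                                          spec$contact_precision,
                                          spec$contact_coverage)
    ext <- synth_external_scores(dec$tm, spec$informativeness)
    ext <- cbind(data.frame(
      target_id = tid,
      model_id = vapply(dec$models, `[[`, character(1), "model_id"),
      stringsAsFactors = FALSE), ext)
    beff <- exp(stats::rnorm(1, spec$beff_log_mean, spec$beff_log_sd))
    list(target_id = tid, native = native, models = dec$models,
         tm = dec$tm, predicted = predicted, external = ext, beff = beff)
  })
}

#' Featurize a synthetic benchmark
#'
#' @param bench Output of [synth_benchmark()].
#' @param ... Passed to [featurize_ensemble()].
#' @return Data frame of feature vectors with the true `tm` label column.
#' @export
featurize_benchmark <- function(bench, ...) {
  rows <- lapply(bench, function(tgt) {
    featurize_ensemble(tgt$models, tgt$predicted, external = tgt$external,
                       beff = tgt$beff, target_id = tgt$target_id,
                       native = tgt$native, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic benchmark to disk
#'
#' Emits standard plain-text artifacts consumable end-to-end by the
#' pipeline: one PDB per model (plus the native), one RR contact file per
#' target, an external score table, a true-label table, and a target table
#' with lengths and effective sequence counts.
#'
#' @param spec A [benchmark_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the benchmark list (as from [synth_benchmark()]).
#' @export
make_benchmark <- function(spec, dir) {
  bench <- synth_benchmark(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext_all <- list()
  lab_all <- list()
  tgt_all <- list()
  for (tgt in bench) {
    tdir <- file.path(dir, tgt$target_id)
    dir.create(tdir, showWarnings = FALSE)
    write_model(tgt$native, file.path(tdir, "native.pdb"))
    for (m in tgt$models)
      write_model(m, file.path(tdir, paste0(m$model_id, ".pdb")))
    write_contacts(tgt$predicted,
                   file.path(dir, paste0(tgt$target_id, ".rr")))
    ext_all[[tgt$target_id]] <- tgt$external
    lab_all[[tgt$target_id]] <- data.frame(
      target_id = tgt$target_id,
      model_id = vapply(tgt$models, `[[`, character(1), "model_id"),
      tm = tgt$tm, stringsAsFactors = FALSE)
    tgt_all[[tgt$target_id]] <- data.frame(
      target_id = tgt$target_id, length = tgt$native$length,
      beff = tgt$beff, stringsAsFactors = FALSE)
  }
  write_score_table(do.call(rbind, ext_all), file.path(dir, "scores.tsv"))
  write_score_table(do.call(rbind, lab_all), file.path(dir, "labels.tsv"))
  utils::write.table(do.call(rbind, tgt_all), file.path(dir, "targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bench)
}

#' Read a benchmark directory back into memory
#'
#' @param dir Directory written by [make_benchmark()].
#' @return List shaped like the output of [synth_benchmark()].
#' @export
read_benchmark <- function(dir) {
  targets <- utils::read.table(file.path(dir, "targets.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  ext <- read_score_table(file.path(dir, "scores.tsv"))
  lab <- read_score_table(file.path(dir, "labels.tsv"))
  lapply(seq_len(nrow(targets)), function(k) {
    tid <- targets$target_id[[k]]
    tdir <- file.path(dir, tid)
    native <- read_model(file.path(tdir, "native.pdb"), tid,
                         model_id = "native")
    ids <- lab$model_id[lab$target_id == tid]
    models <- lapply(ids, function(id)
      read_model(file.path(tdir, paste0(id, ".pdb")), tid, model_id = id))
    predicted <- read_predicted_contacts(
      file.path(dir, paste0(tid, ".rr")), native$length)
    list(target_id = tid, native = native, models = models,
         tm = lab$tm[lab$target_id == tid], predicted = predicted,
         external = ext[ext$target_id == tid, , drop = FALSE],
         beff = targets$beff[[k]])
  })
}
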