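# Structure and contact I/O: PDB models, observed/predicted contact maps,
# delimited score tables.

#' Construct a structure model
#'
#' A minimal representation of one predicted (or native) structure: one
#' representative atom per residue, the C-beta atom, or C-alpha for glycine.
#'
#' @param model_id Character scalar identifying the model.
#' @param target_id Character scalar identifying the modelling target.
#' @param res_index Integer vector of 1-based residue indices, strictly
#'   increasing.
#' @param res_name Character vector of 3-letter residue codes.
#' @param xyz Numeric matrix (n x 3) of representative-atom coordinates in
#'   Angstrom.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(model_id, target_id, res_index, res_name, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  res_index <- as.integer(res_index)
  n <- length(res_index)
  if (n < 1L) stop("structure model must contain at least one residue")
  if (nrow(xyz) != n || ncol(xyz) != 3L)
    stop("xyz must be an n x 3 matrix matching res_index")
  if (length(res_name) != n) stop("res_name length mismatch")
  if (any(diff(res_index) <= 0L))
    stop("residue indices must be strictly increasing")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  structure(
    list(model_id = as.character(model_id),
         target_id = as.character(target_id),
         res_index = res_index,
         res_name = toupper(as.character(res_name)),
         xyz = xyz,
         length = n),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (target %s): %d residues\n",
              x$model_id, x$target_id, x$length))
  invisible(x)
}

#' Read a model from a PDB file
#'
#' Extracts one representative atom per residue: C-beta, substituting C-alpha
#' for glycine or when C-beta is absent (with a warning for non-glycine
#' residues). Only the first MODEL and a single chain are used; insertion
#' codes are rejected.
#'
#' @param path Path to a PDB file with ATOM records.
#' @param target_id Target identifier to attach.
#' @param model_id Model identifier; default is the file name without
#'   extension.
#' @param chain Chain identifier; required when the file contains several
#'   chains.
#' @return A [structure_model()].
#' @export
read_model <- function(path, target_id, model_id = NULL, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported (", path, ")")
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("multiple chains present (", paste(chains, collapse = ", "),
           "); specify `chain`")
    chain <- chains[[1L]]
  }
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)
  # first-listed altloc per (residue, atom name)
  key <- paste(at$resno, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]

  resno <- sort(unique(at$resno))
  idx <- name <- keep <- vector("list", length(resno))
  coords <- matrix(NA_real_, length(resno), 3L)
  resnam <- character(length(resno))
  use <- logical(length(resno))
  fellback <- character(0)
  for (k in seq_along(resno)) {
    rows <- at[at$resno == resno[[k]], , drop = FALSE]
    resnam[[k]] <- rows$resid[[1L]]
    cb <- rows[rows$elety == "CB", , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(cb) >= 1L) {
      coords[k, ] <- as.numeric(cb[1L, c("x", "y", "z")])
      use[[k]] <- TRUE
    } else if (nrow(ca) >= 1L) {
      coords[k, ] <- as.numeric(ca[1L, c("x", "y", "z")])
      use[[k]] <- TRUE
      if (!identical(resnam[[k]], "GLY"))
        fellback <- c(fellback, as.character(resno[[k]]))
    }
  }
  if (length(fellback))
    warning("no CB atom for non-glycine residue(s) ",
            paste(fellback, collapse = ", "), "; using CA")
  if (!any(use)) stop("no residues with a representative atom in ", path)
  structure_model(model_id, target_id, resno[use], resnam[use],
                  coords[use, , drop = FALSE])
}

#' Write a structure model as a PDB file
#'
#' One representative atom per residue (CB, or CA for glycine) so that
#' [read_model()] round-trips the coordinates.
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  ele <- ifelse(model$res_name == "GLY", "CA", "CB")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(model$xyz)),
                   resno = model$res_index,
                   resid = model$res_name,
                   elety = ele,
                   chain = "A")
  invisible(path)
}

#' Construct an observed (binary) contact map
#'
#' @param length Number of residues.
#' @param pairs Two-column integer matrix of residue pairs (any order;
#'   normalised to i < j, duplicates removed).
#' @param min_separation Minimum sequence separation `j - i` for a stored
#'   pair.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(length, pairs, min_separation = 5L) {
  length <- as.integer(length)
  min_separation <- as.integer(min_separation)
  if (length < 1L) stop("length must be >= 1")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), 0L, 2L)
  } else {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "integer"
    if (ncol(pairs) != 2L) stop("pairs must have two columns")
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                   pmax(pairs[, 1L], pairs[, 2L]))
    pairs <- unique(pairs)
    if (any(pairs[, 1L] < 1L) || any(pairs[, 2L] > length))
      stop("contact indices out of [1, length]")
    if (any(pairs[, 1L] == pairs[, 2L])) stop("self-contacts are not allowed")
    if (any(pairs[, 2L] - pairs[, 1L] < min_separation))
      stop("contact pair closer in sequence than min_separation")
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(list(length = length, pairs = pairs,
                 min_separation = min_separation),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> L=%d, %d contacts (min separation %d)\n",
              x$length, nrow(x$pairs), x$min_separation))
  invisible(x)
}

#' Construct a predicted (probabilistic) contact map
#'
#' @param length Number of residues.
#' @param i,j Integer vectors of residue indices.
#' @param p Numeric vector of contact probabilities in `[0, 1]`.
#' @return An object of class `pred_contact_map`.
#' @export
pred_contact_map <- function(length, i, j, p) {
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1")
  i <- as.integer(i); j <- as.integer(j); p <- as.numeric(p)
  if (!(length(i) == length(j) && length(j) == length(p)))
    stop("i, j, p must have equal length")
  if (length(i)) {
    ii <- pmin(i, j); jj <- pmax(i, j)
    if (any(ii < 1L) || any(jj > length)) stop("indices out of [1, length]")
    if (any(ii == jj)) stop("self-contacts are not allowed")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop("probabilities must lie in [0, 1]")
    # deduplicate keeping the highest probability per pair
    ord <- order(ii, jj, -p)
    ii <- ii[ord]; jj <- jj[ord]; p <- p[ord]
    dup <- duplicated(cbind(ii, jj))
    ii <- ii[!dup]; jj <- jj[!dup]; p <- p[!dup]
    ent <- data.frame(i = ii, j = jj, p = p)
  } else {
    ent <- data.frame(i = integer(0), j = integer(0), p = numeric(0))
  }
  structure(list(length = length, entries = ent), class = "pred_contact_map")
}

#' @export
print.pred_contact_map <- function(x, ...) {
  cat(sprintf("<pred_contact_map> L=%d, %d entries\n",
              x$length, nrow(x$entries)))
  invisible(x)
}

#' Observed contact map of a model
#'
#' A residue pair is a contact when its representative atoms (C-beta;
#' C-alpha for glycine) are strictly closer than `cutoff` Angstrom and at
#' least `min_separation` apart in sequence. Indices refer to sequential
#' residue positions 1..length.
#'
#' @param model A [structure_model()].
#' @param cutoff Distance cutoff in Angstrom (strict less-than).
#' @param min_separation Minimum sequence separation.
#' @return A [contact_map()].
#' @export
observed_contact_map <- function(model, cutoff = 8, min_separation = 5L) {
  stopifnot(inherits(model, "structure_model"))
  n <- model$length
  D <- as.matrix(stats::dist(model$xyz))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  hit <- which(D < cutoff & sep >= min_separation & upper.tri(D),
               arr.ind = TRUE)
  contact_map(n, hit, min_separation)
}

#' Read predicted contacts in CASP RR style
#'
#' Data lines are `i j d1 d2 p` or `i j p`; header, sequence, and terminator
#' lines are tolerated. Duplicate pairs keep the highest probability.
#'
#' @param path Path to the contact file.
#' @param length Target length used for index validation.
#' @return A [pred_contact_map()].
#' @export
read_predicted_contacts <- function(path, length) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  skip <- grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END)", lines) |
    grepl("^[A-Za-z-]+$", lines)
  lines <- lines[!skip]
  i <- integer(0); j <- integer(0); p <- numeric(0)
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(f) < 3L) stop("malformed contact line: '", ln, "'")
    ii <- suppressWarnings(as.integer(f[[1L]]))
    jj <- suppressWarnings(as.integer(f[[2L]]))
    pp <- suppressWarnings(as.numeric(f[[length(f)]]))
    if (is.na(ii) || is.na(jj) || is.na(pp))
      stop("malformed contact line: '", ln, "'")
    i <- c(i, ii); j <- c(j, jj); p <- c(p, pp)
  }
  if (length(i) && (any(pmin(i, j) < 1L) || any(pmax(i, j) > length)))
    stop("contact index out of [1, ", length, "]")
  pred_contact_map(length, i, j, p)
}

#' Write contacts in CASP RR style
#'
#' @param map A [contact_map()] (written with probability 1) or a
#'   [pred_contact_map()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_contacts <- function(map, path) {
  if (inherits(map, "contact_map")) {
    ent <- data.frame(i = map$pairs[, 1L], j = map$pairs[, 2L], p = 1)
  } else if (inherits(map, "pred_contact_map")) {
    ent <- map$entries
  } else stop("map must be a contact_map or pred_contact_map")
  writeLines(sprintf("%d %d 0 8 %.6g", ent$i, ent$j, ent$p), path)
  invisible(path)
}

#' Read a delimited score table keyed by target and model
#'
#' Tab- or comma-delimited text with a header row naming at least
#' `target_id` and `model_id`. Blank numeric cells become `NA` (absent, not
#' zero); duplicate keys are an error.
#'
#' @param path Path to the table.
#' @return A data frame.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          check.names = FALSE)
  if (!all(c("target_id", "model_id") %in% names(df)))
    stop("score table must contain target_id and model_id columns")
  key <- paste(df$target_id, df$model_id)
  if (anyDuplicated(key))
    stop("duplicate (target_id, model_id) rows in ", path)
  df
}

#' Write a score table
#'
#' @param df Data frame with `target_id` and `model_id` columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
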