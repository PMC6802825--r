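# Shared fixtures: random contact maps, toy PDB text, a pure-R spectral
# alignment oracle, and tier-report count fixtures.

# random binary contact map of given length
rand_map <- function(L, ncont, minsep = 2L) {
  ij <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  ij <- ij[ij[, 2L] - ij[, 1L] >= minsep, , drop = FALSE]
  pick <- sample(nrow(ij), min(ncont, nrow(ij)))
  contact_map(L, ij[pick, , drop = FALSE], min_separation = minsep)
}

# random probabilistic map derived from a random binary map
rand_pred <- function(L, ncont, minsep = 2L, pmin = 0.3) {
  m <- rand_map(L, ncont, minsep)
  pred_contact_map(L, m$pairs[, 1L], m$pairs[, 2L],
                   runif(nrow(m$pairs), pmin, 1))
}

# minimal PDB ATOM record
pdb_atom_line <- function(serial, elety, resid, resno, x, y, z,
                          alt = " ", chain = "A", insert = " ") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00",
          serial, elety, alt, resid, chain, resno, insert, x, y, z)
}

write_toy_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# random rigid-body transform of an n x 3 coordinate matrix
rigid_transform <- function(xyz, shift = c(5, -3, 11)) {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(xyz %*% Q, 2, shift, "+")
}

# textbook global affine-gap DP (Gotoh), score only: the independent
# oracle for the spectral aligner
gotoh_global_score <- function(S, go, ge) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -1e100
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1) # gap consuming columns of S (j)
  F_ <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 2:(m + 1)) {
    E[1, j] <- go + (j - 2) * ge
    H[1, j] <- E[1, j]
  }
  for (i in 2:(n + 1)) {
    F_[i, 1] <- go + (i - 2) * ge
    H[i, 1] <- F_[i, 1]
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
      F_[i, j] <- max(H[i - 1, j] + go, F_[i - 1, j] + ge)
      H[i, j] <- max(H[i - 1, j - 1] + S[i - 1, j - 1], E[i, j], F_[i, j])
    }
  }
  H[n + 1, m + 1]
}

# spectral-alignment oracle: explicit eigendecomposition + Gotoh DP
spectral_oracle <- function(map_a, map_b, k, go = -1, ge = -0.1) {
  dense <- function(map) {
    n <- map$length
    A <- matrix(0, n, n)
    if (inherits(map, "contact_map")) {
      if (nrow(map$pairs)) {
        A[map$pairs] <- 1
        A[map$pairs[, c(2, 1), drop = FALSE]] <- 1
      }
    } else {
      e <- map$entries
      if (nrow(e)) {
        A[cbind(e$i, e$j)] <- e$p
        A[cbind(e$j, e$i)] <- e$p
      }
    }
    A
  }
  prof <- function(A, k) {
    e <- eigen(A, symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)[seq_len(k)]
    sweep(e$vectors[, ord, drop = FALSE], 2,
          sqrt(abs(e$values[ord])), "*")
  }
  U <- prof(dense(map_a), k)
  V <- prof(dense(map_b), k)
  S <- abs(U) %*% t(abs(V))
  gotoh_global_score(S, go, ge)
}

# synthetic feature frames built through the real assembly path; one
# feature (ppv) carries the label, scaled by `signal`
synth_feature_frame <- function(n_targets, n_models, signal = 1,
                                seed = 1) {
  set.seed(seed)
  out <- list()
  labels <- logical(0)
  for (t in seq_len(n_targets)) {
    lab <- rep(c(TRUE, FALSE), length.out = n_models)
    rows <- scripted_model_rows(lab, ifelse(lab, 0.8, 0.2) * signal +
                                  (1 - signal) * runif(n_models) +
                                  rnorm(n_models, 0, 0.05))
    target <- list(length = 50 + t, beff = exp(runif(1, 2, 7)),
                   n_predicted_contacts = 40)
    out[[t]] <- assemble_features(target, rows, sprintf("T%03d", t))
    labels <- c(labels, lab)
  }
  list(features = do.call(rbind, out), labels = labels)
}

# model-feature rows whose ppv column is prescribed; other features are
# uninformative noise
scripted_model_rows <- function(lab, ppv, ids = NULL) {
  n <- length(lab)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_len(n))
  rows <- data.frame(model_id = ids, stringsAsFactors = FALSE)
  for (f in c("saint2", "proq2d", "proq3d", "proqroscend", "proqrosfad",
              "pcons", "pcombc", "saint2_contact", "eigen_score",
              "mapalign_score"))
    rows[[f]] <- runif(n)
  rows$ppv <- pmin(pmax(ppv, 0), 1)
  rows$mapalign_length <- sample(10:40, n, replace = TRUE)
  rows$n_satisfied <- sample(0:30, n, replace = TRUE)
  rows
}

# a classifier whose score is driven by the ppv feature
train_ppv_classifier <- function() {
  d <- synth_feature_frame(4, 40, signal = 1, seed = 61)
  rfqa(d$features, d$labels, ntree = 200, seed = 1)
}

# generator emitting batches whose best ppv follows `schedule` (one value
# per batch), all other features noise
scripted_generator <- function(schedule, seed = 1) {
  batch_no <- 0L
  count <- 0L
  function(n) {
    batch_no <<- batch_no + 1L
    if (batch_no > length(schedule)) return(NULL)
    set.seed(seed * 1000L + batch_no)
    ppv <- rep(0.15, n)
    ppv[1] <- schedule[[batch_no]]
    ids <- sprintf("g%05d", count + seq_len(n))
    count <<- count + n
    rows <- scripted_model_rows(rep(FALSE, n), ppv, ids = ids)
    rows$tm <- 0.2 + 0.5 * ppv
    rows
  }
}

# per-target prediction/label fixture reproducing given tier counts:
# for each tier, `total` targets whose top-ranked model scores in the tier
# band, `top1` of them with a correct top model, `top5` with a correct
# model in the top five, and `max_correct` with a correct model anywhere
tier_fixture <- function(counts) {
  # counts: data.frame(tier, total, top1, top5, max_correct)
  band <- c(high = 0.8, medium = 0.4, low = 0.2, failed = 0.05)
  preds <- list()
  labs <- list()
  n <- 0L
  for (r in seq_len(nrow(counts))) {
    tier <- counts$tier[[r]]
    for (t in seq_len(counts$total[[r]])) {
      n <- n + 1L
      tid <- sprintf("t%04d", n)
      ids <- sprintf("m%02d", 1:6)
      scores <- band[[tier]] * (1 - (0:5) / 100) # descending, top in band
      tm <- rep(0.3, 6)
      if (t <= counts$top1[[r]]) {
        tm[1] <- 0.6
      } else if (t <= counts$top5[[r]]) {
        tm[3] <- 0.6
      } else if (t <= counts$max_correct[[r]]) {
        tm[6] <- 0.6
      }
      preds[[n]] <- data.frame(target_id = tid, model_id = ids,
                               score = scores, stringsAsFactors = FALSE)
      labs[[n]] <- data.frame(target_id = tid, model_id = ids, tm = tm,
                              stringsAsFactors = FALSE)
    }
  }
  list(predictions = do.call(rbind, preds), labels = do.call(rbind, labs))
}
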