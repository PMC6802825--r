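test_that("TM-score closed forms and rigid invariance hold", {
  m <- synth_native(40, seed = 2)
  expect_equal(tm_score_fixed(m, m), 1.0, tolerance = 1e-9)
  set.seed(3)
  mt <- structure_model("r", m$target_id, m$res_index, m$res_name,
                        rigid_transform(m$xyz))
  expect_equal(tm_score_fixed(mt, m), 1.0, tolerance = 1e-6)
  # every residue at d0 gives exactly one half
  L <- 40
  expect_identical(tm_from_distances(rep(tm_d0(L), L), L), 0.5)
  expect_error(tm_score_fixed(m$xyz, m$xyz[1:20, ]), "mismatch")
  expect_error(tm_score_fixed(m$xyz[1:10, ], m$xyz[1:10, ]), ">= 16")
})

test_that("TM-score is symmetric and at least the plain-superposition value", {
  set.seed(9)
  nat <- synth_native(50)
  dec <- synth_decoys(nat, c(2, 5), 2)
  for (mod in dec$models) {
    a <- tm_score_fixed(mod, nat)
    b <- tm_score_fixed(nat, mod)
    expect_equal(a, b, tolerance = 1e-6)
    # independent lower bound: single whole-chain least-squares fit
    inds <- bio3d::atom2xyz(seq_len(nat$length))
    fit <- bio3d::fit.xyz(as.numeric(t(nat$xyz)), as.numeric(t(mod$xyz)),
                          fixed.inds = inds, mobile.inds = inds)
    d <- sqrt(rowSums((nat$xyz - matrix(fit, ncol = 3, byrow = TRUE))^2))
    expect_gte(a + 1e-9, tm_from_distances(d, nat$length))
  }
})

test_that("contact satisfaction (PPV) follows its counting definition", {
  m <- contact_map(12, rbind(c(1, 7), c(2, 9), c(4, 10)))
  identical_pred <- pred_contact_map(12, c(1, 2, 4), c(7, 9, 10),
                                     rep(0.9, 3))
  expect_equal(contact_ppv(m, identical_pred), 1.0)
  none <- pred_contact_map(12, c(1, 3), c(8, 11), c(0.9, 0.8))
  expect_equal(contact_ppv(m, none), 0)
  # 4 predicted above threshold, 3 present
  four <- pred_contact_map(12, c(1, 2, 4, 3), c(7, 9, 10, 11),
                           c(0.9, 0.8, 0.7, 0.6))
  expect_equal(contact_ppv(m, four), 0.75)
  expect_equal(satisfied_count(m, four), 3L)
  # thresholding is strict; denominator zero warns and returns 0
  low <- pred_contact_map(12, 1, 7, 0.5)
  expect_warning(v <- contact_ppv(m, low), "threshold")
  expect_equal(v, 0)
  expect_error(contact_ppv(contact_map(8, NULL), four), "differ")
})

test_that("satisfied_count equals the set intersection on random maps", {
  set.seed(17)
  for (k in 1:10) {
    m <- rand_map(15, 8, minsep = 3)
    p <- rand_pred(15, 8, minsep = 3, pmin = 0.55)
    obs_keys <- paste(m$pairs[, 1], m$pairs[, 2])
    pred_keys <- paste(p$entries$i, p$entries$j)
    expect_equal(satisfied_count(m, p, 0.5),
                 length(intersect(obs_keys, pred_keys)))
  }
})

test_that("contact potential sums satisfied probabilities", {
  m <- contact_map(12, rbind(c(1, 7), c(2, 9)))
  pr <- pred_contact_map(12, c(1, 2, 3), c(7, 9, 11), c(0.9, 0.4, 0.7))
  expect_equal(contact_potential(m, pr), 0.9 + 0.4)
  expect_equal(contact_potential(m, pr, lambda = 0.5), 1.3 - 0.5 * 0.7)
  none <- contact_map(12, rbind(c(3, 8)))
  expect_equal(contact_potential(none, pr), 0)
  # monotone: adding a satisfied contact never decreases the potential
  bigger <- contact_map(12, rbind(c(1, 7), c(2, 9), c(3, 11)))
  expect_gte(contact_potential(bigger, pr), contact_potential(m, pr))
})

test_that("consensus is exact for identical models and order-invariant", {
  nat <- synth_native(30, seed = 4)
  same <- lapply(1:3, function(i)
    structure_model(paste0("c", i), "t", nat$res_index, nat$res_name,
                    nat$xyz))
  expect_equal(unname(consensus_scores(same)), rep(1, 3))
  set.seed(6)
  dec <- synth_decoys(nat, c(2, 4), 2)
  cons <- consensus_scores(dec$models)
  perm <- c(3, 1, 4, 2)
  cons_p <- consensus_scores(dec$models[perm])
  expect_equal(unname(cons_p), unname(cons[perm]), tolerance = 1e-6)
  # hand average from the pairwise matrix
  tm <- tm_matrix(dec$models)
  expect_equal(unname(cons[1]), mean(tm[1, -1]))
  expect_error(consensus_scores(dec$models[1]), "at least 2")
})

test_that("pcombc is the declared weighted sum", {
  expect_equal(pcombc(0.7, 0.4, 0.9, weights = c(1, 0, 0)), 0.7)
  expect_equal(pcombc(0.6, 0.6, 0.6, weights = c(0.2, 0.5, 0.3)), 0.6)
  expect_equal(pcombc(0.1, 0.2, 0.3, weights = c(0.5, 0.25, 0.25)),
               0.5 * 0.1 + 0.25 * 0.2 + 0.25 * 0.3)
  expect_true(is.na(pcombc(NA, 0.2, 0.3)))
})

test_that("top-10 mean pairwise TM selects deterministically and averages", {
  nat <- synth_native(30, seed = 12)
  copies <- lapply(1:10, function(i)
    structure_model(sprintf("c%02d", i), "t", nat$res_index, nat$res_name,
                    nat$xyz))
  expect_equal(mean_pairwise_topk(copies, rep(0.5, 10)), 1.0)
  # mixed ensemble of two distinct conformations: hand mean
  set.seed(13)
  other <- synth_decoys(nat, 5, 1)$models[[1]]
  mix <- c(copies[1:5], lapply(1:5, function(i)
    structure_model(sprintf("d%02d", i), "t", other$res_index,
                    other$res_name, other$xyz)))
  tm_ab <- tm_score_fixed(other, nat)
  got <- mean_pairwise_topk(mix, rep(1, 10))
  expect_equal(got, (20 * 1 + 25 * tm_ab) / 45, tolerance = 1e-6)
  expect_error(mean_pairwise_topk(copies[1:5], rep(1, 5)), "at least 10")
})
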