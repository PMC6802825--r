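test_that("B_eff clusters redundant sequences", {
  expect_equal(compute_beff("ACDEFGHIKL"), 1)
  expect_equal(compute_beff(rep("ACDEFGHIKL", 5)), 1)
  # two identical + one sequence below 80% identity to both:
  # cluster sizes 2, 2, 1 give 1/2 + 1/2 + 1 = 2
  msa <- c("ACDEFGHIKL", "ACDEFGHIKL", "ACWWWWHIKL")
  expect_equal(compute_beff(msa), 2)
  expect_error(compute_beff(c("ACDE", "ACD")), "ragged")
  # threshold is configurable: at 40% identity all three cluster together
  expect_equal(compute_beff(msa, identity_threshold = 0.4), 1)
})

test_that("read_msa handles FASTA and strips a3m insertions", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDE", "FGHI", ">s2", "ACDEFGH-"), fa)
  expect_equal(read_msa(fa), c("ACDEFGHI", "ACDEFGH-"))
  a3m <- withr::local_tempfile(fileext = ".a3m")
  writeLines(c(">s1", "ACDEFGHI", ">s2", "ACDefgEFGHI"), a3m)
  expect_equal(read_msa(a3m), c("ACDEFGHI", "ACDEFGHI"))
})

test_that("ensemble statistics follow the max/min/median/spread scheme", {
  expect_equal(unname(ensemble_stats(c(1, 2, 4))), c(4, 1, 2, 2))
  expect_equal(unname(ensemble_stats(rep(3, 5))), c(3, 3, 3, 0))
  expect_equal(unname(ensemble_stats(c(1, 3))), c(3, 1, 2, 1))
  expect_equal(unname(ensemble_stats(c(1, NA, 3))), c(3, 1, 2, 1))
  expect_error(ensemble_stats(c(NA_real_, NA_real_)), "non-missing")
})

make_model_rows <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(model_id = sprintf("m%03d", seq_len(n)))
  for (f in c("saint2", "proq2d", "proq3d", "proqroscend", "proqrosfad",
              "pcons", "pcombc", "saint2_contact", "ppv", "eigen_score",
              "mapalign_score"))
    df[[f]] <- runif(n)
  df$mapalign_length <- sample(0:40, n, replace = TRUE)
  df$n_satisfied <- sample(0:30, n, replace = TRUE)
  df
}

test_that("assembled vectors always have the 58 frozen columns", {
  manifest <- feature_manifest()
  expect_length(manifest, 58L)
  expect_length(grep("^ens_", manifest), 43L)
  target <- list(length = 60, beff = 150, n_predicted_contacts = 40)
  for (n in c(1L, 3L, 20L)) {
    out <- assemble_features(target, make_model_rows(n), "T1")
    expect_equal(nrow(out), n)
    expect_identical(setdiff(names(out), c("target_id", "model_id")),
                     manifest)
  }
})

test_that("the ensemble block is shared, order-invariant, and consistent", {
  target <- list(length = 60, beff = 150, n_predicted_contacts = 40)
  rows <- make_model_rows(7, seed = 3)
  out <- assemble_features(target, rows, "T1")
  ens_cols <- grep("^ens_", names(out), value = TRUE)
  for (cl in ens_cols) expect_length(unique(out[[cl]]), 1L)
  # min <= median <= max and spread = max - median for every full feature
  for (f in c("saint2", "pcons", "eigen_score")) {
    expect_lte(out[[paste0("ens_min_", f)]][1],
               out[[paste0("ens_median_", f)]][1])
    expect_lte(out[[paste0("ens_median_", f)]][1],
               out[[paste0("ens_max_", f)]][1])
    expect_equal(out[[paste0("ens_spread_", f)]][1],
                 out[[paste0("ens_max_", f)]][1] -
                   out[[paste0("ens_median_", f)]][1])
  }
  # permuting models permutes rows but changes no values
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  out_p <- assemble_features(target, rows[perm, ], "T1")
  expect_equal(out_p[order(out_p$model_id), names(out)],
               out[order(out$model_id), ], ignore_attr = TRUE)
  # single model: max = min = median = value, spread 0
  one <- assemble_features(target, rows[1, ], "T1")
  expect_equal(one$ens_max_saint2, one$saint2)
  expect_equal(one$ens_spread_saint2, 0)
  # hand check against direct statistics
  expect_equal(out$ens_max_ppv[1], max(rows$ppv))
  expect_equal(out$ens_median_proq3d[1], median(rows$proq3d))
  expect_equal(out$ens_max_n_satisfied[1], max(rows$n_satisfied))
})

test_that("missing model features are imputed with the per-target median", {
  target <- list(length = 60, beff = 150, n_predicted_contacts = 40)
  rows <- make_model_rows(5, seed = 9)
  rows$proq3d[2] <- NA
  expect_message(out <- assemble_features(target, rows, "T1"), "imputed")
  expect_equal(out$proq3d[2], median(rows$proq3d, na.rm = TRUE))
  rows$proq3d[] <- NA
  expect_error(suppressMessages(assemble_features(target, rows, "T1")),
               "entirely missing")
  fb <- setNames(0.42, "proq3d")
  out2 <- suppressMessages(assemble_features(target, rows, "T1",
                                             fallback_medians = fb))
  expect_true(all(out2$proq3d == 0.42))
})

test_that("the end-to-end featurizer emits bounded, labelled vectors", {
  set.seed(41)
  nat <- synth_native(40, target_id = "T1")
  dec <- synth_decoys(nat, c(1, 4), 3)
  pm <- synth_predicted_contacts(observed_contact_map(nat), 0.8, 0.8)
  ext <- cbind(data.frame(model_id = vapply(dec$models, `[[`,
                                            character(1), "model_id")),
               synth_external_scores(dec$tm, 0.7))
  f <- featurize_ensemble(dec$models, pm, external = ext, beff = 80,
                          target_id = "T1", native = nat)
  expect_equal(nrow(f), 6L)
  expect_identical(setdiff(names(f), c("target_id", "model_id", "tm")),
                   feature_manifest())
  expect_true(all(f$ppv >= 0 & f$ppv <= 1))
  expect_true(all(f$pcons > 0 & f$pcons <= 1))
  expect_true(all(f$tm > 0 & f$tm <= 1))
  expect_true(all(f$mapalign_length == floor(f$mapalign_length)))
})
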