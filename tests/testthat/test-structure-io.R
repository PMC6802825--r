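test_that("read_model extracts CB atoms, substituting CA for glycine", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, c(
    pdb_atom_line(1, "CA", "GLY", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CB", "ALA", 2, 4.5, 1.2, 0),
    pdb_atom_line(4, "CA", "LEU", 3, 7.6, 0, 0),
    pdb_atom_line(5, "CB", "LEU", 3, 8.2, -1.4, 0.3)))
  m <- read_model(path, "tgt")
  expect_s3_class(m, "structure_model")
  expect_equal(m$length, 3L)
  expect_equal(m$res_name, c("GLY", "ALA", "LEU"))
  # GLY uses CA; others use CB
  expect_equal(unname(m$xyz[1, ]), c(0, 0, 0))
  expect_equal(unname(m$xyz[2, ]), c(4.5, 1.2, 0))
})

test_that("read_model uses the first-listed altloc and warns on CA fallback", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, c(
    pdb_atom_line(1, "CA", "ALA", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", 1, 1.0, 0, 0, alt = "A"),
    pdb_atom_line(3, "CB", "ALA", 1, 9.0, 0, 0, alt = "B"),
    pdb_atom_line(4, "CA", "SER", 2, 3.8, 0, 0)))
  expect_warning(m <- read_model(path, "tgt"), "no CB atom")
  expect_equal(m$length, 2L)
  expect_equal(unname(m$xyz[1, ]), c(1.0, 0, 0)) # altloc A, listed first
  expect_equal(unname(m$xyz[2, ]), c(3.8, 0, 0)) # CA fallback for SER
})

test_that("read_model rejects degenerate and unsupported input", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_model(empty, "tgt"))
  noatoms <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), noatoms)
  expect_error(read_model(noatoms, "tgt"))
  icode <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(icode, c(
    pdb_atom_line(1, "CB", "ALA", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", 1, 2, 0, 0, insert = "A")))
  expect_error(read_model(icode, "tgt"), "insertion")
  expect_error(read_model(tempfile(), "tgt"), "not found")
})

test_that("write_model/read_model round-trips representative coordinates", {
  m <- synth_native(24, seed = 5, target_id = "tgt")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, path)
  back <- read_model(path, "tgt")
  expect_equal(back$length, m$length)
  expect_equal(back$res_name, m$res_name)
  expect_equal(back$xyz, m$xyz, tolerance = 1e-3) # PDB stores 3 decimals
})

test_that("observed contacts use a strict 8 A cutoff and separation filter", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0),
               c(15.2, 0, 0), c(18, 0, 0), c(0, 7.9, 0), c(0, 8.0, 1000))
  m <- structure_model("m", "t", 1:8, rep("ALA", 8), xyz)
  cm <- observed_contact_map(m, cutoff = 8, min_separation = 5)
  # residue 7 is 7.9 A from residue 1 (separation 6): contact
  expect_true(any(cm$pairs[, 1] == 1 & cm$pairs[, 2] == 7))
  # exactly 8.0 A is not a contact (strict less-than)
  xyz2 <- xyz; xyz2[7, ] <- c(0, 8.0, 0)
  m2 <- structure_model("m", "t", 1:8, rep("ALA", 8), xyz2)
  cm2 <- observed_contact_map(m2)
  expect_false(any(cm2$pairs[, 1] == 1 & cm2$pairs[, 2] == 7))
})

test_that("observed map equals the exhaustive distance computation", {
  set.seed(31)
  xyz <- matrix(rnorm(30, sd = 6), 10, 3)
  m <- structure_model("m", "t", 1:10, rep("ALA", 10), xyz)
  cm <- observed_contact_map(m, cutoff = 8, min_separation = 3)
  D <- as.matrix(dist(xyz))
  expected <- which(D < 8 & abs(row(D) - col(D)) >= 3 & upper.tri(D),
                    arr.ind = TRUE)
  expected <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
  expect_equal(unname(cm$pairs), unname(expected))
})

test_that("observed map is invariant under rigid motion and monotone in
           its parameters", {
  set.seed(8)
  m <- synth_native(30)
  cm <- observed_contact_map(m)
  mt <- structure_model("r", "t", m$res_index, m$res_name,
                        rigid_transform(m$xyz))
  expect_equal(observed_contact_map(mt)$pairs, cm$pairs)
  n_wide <- nrow(observed_contact_map(m, cutoff = 10)$pairs)
  n_sep <- nrow(observed_contact_map(m, min_separation = 8)$pairs)
  expect_gte(n_wide, nrow(cm$pairs))
  expect_lte(n_sep, nrow(cm$pairs))
})

test_that("contact map constructors enforce their invariants", {
  expect_error(contact_map(10, cbind(1, 12)), "out of")
  expect_error(contact_map(10, cbind(3, 3)), "self-contacts")
  expect_error(contact_map(10, cbind(1, 3), min_separation = 5), "separation")
  expect_error(pred_contact_map(10, 1, 8, 1.2), "\\[0, 1\\]")
  expect_error(pred_contact_map(10, 1, 11, 0.5), "out of")
  # unordered input pairs are normalised and deduplicated
  cm <- contact_map(10, rbind(c(8, 2), c(2, 8)), min_separation = 2)
  expect_equal(nrow(cm$pairs), 1L)
  expect_equal(unname(cm$pairs[1, ]), c(2L, 8L))
})

test_that("RR reading dedupes to the highest probability and skips headers", {
  path <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "TARGET T001", "MAEILK", "2 9 0 8 0.9",
               "9 2 0 8 0.4", "1 7 0 8 0.55", "END"), path)
  pm <- read_predicted_contacts(path, 10)
  expect_equal(nrow(pm$entries), 2L)
  hit <- pm$entries[pm$entries$i == 2, ]
  expect_equal(hit$j, 9L)
  expect_equal(hit$p, 0.9)
  bad <- withr::local_tempfile(fileext = ".rr")
  writeLines("2 9 0 8 1.2", bad)
  expect_error(read_predicted_contacts(bad, 10))
  oob <- withr::local_tempfile(fileext = ".rr")
  writeLines("2 14 0 8 0.5", oob)
  expect_error(read_predicted_contacts(oob, 10), "out of")
})

test_that("contacts and score tables round-trip through disk", {
  pm <- pred_contact_map(12, c(1, 2, 4), c(7, 9, 11), c(0.9, 0.5, 0.71))
  path <- withr::local_tempfile(fileext = ".rr")
  write_contacts(pm, path)
  back <- read_predicted_contacts(path, 12)
  expect_equal(back$entries$p, pm$entries$p, tolerance = 1e-6)
  expect_equal(back$entries$i, pm$entries$i)

  df <- data.frame(target_id = c("T1", "T1"), model_id = c("a", "b"),
                   proq3d = c(0.5, NA), saint2 = c(-12.5, -10.1),
                   stringsAsFactors = FALSE)
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(df, tpath)
  back <- read_score_table(tpath)
  expect_equal(back$proq3d, df$proq3d) # blank cell read back as NA
  expect_equal(back$saint2, df$saint2)
  dup <- rbind(df, df[1, ])
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(dup, dpath)
  expect_error(read_score_table(dpath), "duplicate")
})
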