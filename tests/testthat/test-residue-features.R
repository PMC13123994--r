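# a minimal classic-format DSSP body with controllable columns
write_classic_dssp <- function(path, resno, chain, aa, ss, asa) {
  hdr <- c("==== Secondary Structure Definition (synthetic test file)",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  body <- sprintf("%5d%5d %s %s  %s%s%4.0f",
                  seq_along(resno), resno, chain, aa,
                  ifelse(is.na(ss), " ", ss),
                  strrep(" ", 17), asa)
  writeLines(c(hdr, body), path)
  path
}

test_that("classic DSSP bodies parse field-for-field", {
  path <- write_classic_dssp(tempfile(), 1:3, "A", c("A", "G", "V"),
                             c("H", "E", "-"), c(10, 20, 30))
  d <- parse_dssp(path)
  expect_equal(d$ss, c("H", "E", "-"))
  expect_equal(d$asa, c(10, 20, 30))
  expect_equal(d$resno, 1:3)
})

test_that("lowercase and out-of-alphabet SS letters map to unknown", {
  path <- write_classic_dssp(tempfile(), 1:3, "A", c("C", "A", "A"),
                             c("a", "P", "T"), c(5, 5, 5))
  d <- parse_dssp(path)
  expect_true(is.na(d$ss[1]))   # disulfide-bridge lowercase convention
  expect_true(is.na(d$ss[2]))   # PPII state outside the 8-letter set
  expect_equal(d$ss[3], "T")
})

test_that("malformed DSSP headers raise a parse error", {
  path <- tempfile()
  writeLines(c("not a dssp file", "at all"), path)
  expect_error(parse_dssp(path), "malformed")
})

test_that("DSSP records shorter than the chain give unknown/0 tails", {
  st <- make_backbone(rep(-57, 5), rep(-47, 5))
  path <- write_classic_dssp(tempfile(), 1:3, "A", rep("A", 3),
                             c("H", "H", "H"), c(50, 50, 50))
  ali <- align_dssp(parse_dssp(path), st, "A")
  expect_equal(ali$ss, c("H", "H", "H", NA, NA))
  expect_equal(ali$asa, c(50, 50, 50, 0, 0))
})

test_that("the mmCIF DSSP dialect parses", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_synthetic-dssp", "loop_",
    "_dssp_struct_summary.entry_id",
    "_dssp_struct_summary.label_comp_id",
    "_dssp_struct_summary.label_asym_id",
    "_dssp_struct_summary.label_seq_id",
    "_dssp_struct_summary.secondary_structure",
    "_dssp_struct_summary.accessibility",
    "X ALA A 1 H 12.0",
    "X GLY A 2 . 34.0"), path)
  d <- parse_dssp(path)
  expect_equal(d$ss, c("H", "-"))
  expect_equal(d$asa, c(12, 34))
})

test_that("secondary-structure one-hot is a bijection onto basis vectors", {
  oh <- encode_ss("H")
  expect_equal(as.integer(oh), c(1L, rep(0L, 8)))
  expect_equal(as.integer(encode_ss(NA)), c(rep(0L, 8), 1L))
  all9 <- encode_ss(c("H", "B", "E", "G", "I", "T", "S", "-", NA))
  expect_equal(rowSums(all9), rep(1, 9))
  expect_equal(nrow(unique(all9)), 9)
})

test_that("relative accessibility normalizes, caps and validates", {
  expect_equal(compute_rasa(129, "A"), 1.0)
  expect_equal(compute_rasa(0, "A"), 0.0)
  expect_equal(compute_rasa(2 * 104, "G"), 1.0)
  expect_equal(compute_rasa(64.5, "A"), 0.5)
  expect_error(compute_rasa(-1, "A"), "negative")
})

test_that("torsions recover generator angles at interior residues", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    phi <- runif(n, -179.9, 180)
    psi <- runif(n, -179.9, 180)
    st <- make_backbone(phi, psi)
    tor <- backbone_torsions(st, "A")
    expect_true(is.na(tor$phi[1]) && is.na(tor$psi[n]))
    wrap <- function(x) ((x + pi) %% (2 * pi)) - pi
    expect_lt(max(abs(wrap(tor$phi[-1] - phi[-1] * pi / 180))), 1e-6)
    expect_lt(max(abs(wrap(tor$psi[-n] - psi[-n] * pi / 180))), 1e-6)
  }
})

test_that("a hand-placed 90-degree dihedral is exact", {
  ang <- epigcn:::dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                           c(0, 1, 1))
  expect_equal(ang, pi / 2, tolerance = 1e-9)
})

test_that("single-residue chains have no defined torsions", {
  st <- make_backbone(-57, -47)
  tor <- backbone_torsions(st, "A")
  expect_true(is.na(tor$phi) && is.na(tor$psi))
})

test_that("torsion features encode angles and the undefined state", {
  expect_equal(as.numeric(torsion_features(0, 0)), c(0, 1, 0, 1))
  expect_equal(as.numeric(torsion_features(pi / 2, -pi / 2)),
               c(1, 0, -1, 0))
  expect_equal(as.numeric(torsion_features(NA, 0)), c(0, 0, 0, 1))
  # sin^2 + cos^2 = 1 for defined angles
  tf <- torsion_features(runif(10, -pi, pi), runif(10, -pi, pi))
  expect_equal(tf[, 1]^2 + tf[, 2]^2, rep(1, 10))
  expect_equal(tf[, 3]^2 + tf[, 4]^2, rep(1, 10))
})

test_that("epitope labeling is inclusive at 4 A and matches brute force", {
  tc <- make_toy_complex(8, c(1, 4), gap = 3.9)
  expect_equal(label_epitopes(tc$antigen, "A", tc$antibody_atoms),
               as.integer(0:7 %in% c(1, 4)))
  tc2 <- make_toy_complex(8, c(1, 4), gap = 4.1)
  expect_equal(sum(label_epitopes(tc2$antigen, "A",
                                  tc2$antibody_atoms)), 0)
  tc3 <- make_toy_complex(8, c(2), gap = 4.0)  # boundary inclusive
  expect_equal(label_epitopes(tc3$antigen, "A", tc3$antibody_atoms)[3],
               1L)

  # random geometry vs O(n*m) brute-force enumeration
  set.seed(5)
  tc4 <- make_toy_complex(20, c(0, 7, 13, 14, 19), gap = 3.5)
  got <- label_epitopes(tc4$antigen, "A", tc4$antibody_atoms)
  res <- tc4$antigen$chains$A
  want <- vapply(res, function(r) {
    mind <- Inf
    for (ai in seq_len(nrow(r$atoms)))
      for (bi in seq_len(nrow(tc4$antibody_atoms))) {
        d <- sqrt(sum((unlist(r$atoms[ai, c("x", "y", "z")]) -
                         tc4$antibody_atoms[bi, ])^2))
        mind <- min(mind, d)
      }
    as.integer(mind <= 4)
  }, integer(1))
  expect_equal(got, want)

  expect_warning(out <- label_epitopes(tc4$antigen, "A",
                                       matrix(numeric(0), 0, 3)),
                 "empty")
  expect_equal(sum(out), 0)
})

test_that("surface mask is inclusive at the 0.15 boundary", {
  expect_equal(surface_mask(c(0.15, 0.1499, 0, 1)),
               c(TRUE, FALSE, FALSE, TRUE))
})

test_that("the structural feature block is the 14-wide concatenation", {
  st <- make_backbone(rep(-57, 6), rep(-47, 6))
  dssp <- data.frame(chain = "A", resno = 1:6, insert = "", aa = "A",
                     ss = c("H", "H", "E", NA, "-", "T"),
                     asa = c(0, 64.5, 129, 10, 20, 30))
  f <- residue_features(st, "A", dssp)
  expect_equal(ncol(f$dssp_feats), 14)
  expect_equal(rowSums(f$dssp_feats[, 1:9]), rep(1, 6))
  expect_equal(f$dssp_feats[, 10], f$rasa, ignore_attr = TRUE)
  expect_equal(f$dssp_feats[2, 10], 0.5, ignore_attr = TRUE)
  tor <- backbone_torsions(st, "A")
  expect_equal(f$dssp_feats[, 11:14],
               torsion_features(tor$phi, tor$psi), ignore_attr = TRUE)
  expect_equal(f$surface, f$rasa >= 0.15)
})

test_that("feature tables export one row per residue", {
  st <- make_backbone(rep(-57, 4), rep(-47, 4))
  f <- residue_features(st, "A")
  path <- tempfile(fileext = ".tsv")
  df <- write_feature_table(st, "A", f, path, labels = c(0, 1, 1, 0))
  back <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(back), 4)
  expect_equal(back$label, c(0, 1, 1, 0))
  expect_equal(back$index, 0:3)
})
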