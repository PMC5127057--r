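test_that("global_align: identity on trivial cases", {
  al <- global_align("MKVLM", "MKVLM")
  expect_equal(al$identity_pct, 100)
  expect_equal(al$aligned_a, al$aligned_b)

  al2 <- global_align("ACDE", "ACDF", align_scoring(match = 1, mismatch = 0))
  expect_equal(al2$identity_pct, 75)
  expect_equal(al2$n_identical, 3L)
  expect_equal(al2$n_aligned_columns, 4L)

  expect_error(global_align("ACDX1", "ACD"), "invalid")
  expect_error(global_align("", "ACD"), "non-empty")

  # removing gaps restores the inputs
  a <- random_aa(25, 101); b <- random_aa(18, 102)
  al3 <- global_align(a, b)
  expect_equal(gsub("-", "", al3$aligned_a), a)
  expect_equal(gsub("-", "", al3$aligned_b), b)
  expect_equal(nchar(al3$aligned_a), nchar(al3$aligned_b))
})

test_that("global_align scores match the Biostrings oracle on random 30-mers", {
  for (s in 1:12) {
    na <- sample(10:30, 1)
    nb <- sample(10:30, 1)
    a <- random_aa(na, seed = 1000 + s)
    b <- random_aa(nb, seed = 2000 + s)
    al <- global_align(a, b)
    or <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      scoreOnly = TRUE)
    expect_equal(al$score, or, tolerance = 1e-9)
  }
})

test_that("global_align is symmetric in score and identity", {
  a <- random_aa(28, 7); b <- random_aa(22, 8)
  ab <- global_align(a, b)
  ba <- global_align(b, a)
  expect_equal(ab$score, ba$score)
  expect_equal(ab$identity_pct, ba$identity_pct)

  # shorter-sequence denominator option
  al <- global_align(a, b, denominator = "shorter")
  expect_equal(al$identity_pct, 100 * al$n_identical / 22)
})

test_that("P-position labels follow the Schechter-Berger arithmetic", {
  expect_equal(label_p_positions(c(338, 339), 340), c("P3", "P2"))
  expect_equal(label_p_positions(c(375, 376), 380), c("P6", "P5"))
  expect_equal(label_p_positions(c(340, 341), 340), c("P1", "P1'"))
  expect_equal(label_p_positions(c(341, 342), 340), c("P1'", "P2'"))
  expect_error(label_p_positions(c(338, 340), 340), "consecutive")
})

test_that("fragment_mass: reference values, additivity, modifications", {
  expect_equal(fragment_mass("G"), 57.02146 + 18.010565, tolerance = 1e-9)
  # empty span yields the water mass
  expect_equal(fragment_mass("GAV", span = c(2, 1)), 18.010565)
  expect_equal(fragment_mass("GAV", span = c(2, 1), mass_type = "average"),
               18.0153)

  # additivity over any split, to <= 1e-9 Da
  seq <- random_aa(40, seed = 11)
  total <- fragment_mass(seq)
  for (i in c(1, 7, 20, 39)) {
    lhs <- fragment_mass(seq, c(1, i)) + fragment_mass(seq, c(i + 1, 40)) -
      18.010565
    expect_equal(lhs, total, tolerance = 1e-9)
  }

  expect_equal(fragment_mass("C", cys_carbamidomethyl = TRUE) -
                 fragment_mass("C"), 57.02146, tolerance = 1e-9)
  expect_error(fragment_mass("GAV", span = c(1, 4)), "span")
})

test_that("map_cleavage_site localizes a constructed fragment mass", {
  seq <- "MKVLAAGGST"
  rec <- serpin_record("s", seq)
  m4 <- fragment_mass(seq, c(1, 4))
  hits <- map_cleavage_site(rec, m4, "N", tolerance_ppm = 10)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$bond_i, 4L)
  expect_equal(hits$bond_j, 5L)
  expect_equal(hits$error_ppm, 0, tolerance = 1e-9)

  # C-terminal fragments and p-label attachment
  rec2 <- serpin_record("s", seq, rcl_span = c(3, 10), p1_index = 6)
  mC <- fragment_mass(seq, c(6, 10))
  hitsC <- map_cleavage_site(rec2, mC, "C", tolerance_ppm = 10)
  expect_equal(hitsC$bond_i[1], 5L)
  expect_equal(hitsC$p_label_i[1], "P2")
  expect_equal(hitsC$p_label_j[1], "P1")

  # the generating bond always ranks first at 0 ppm, wide tolerance
  for (i in c(2, 5, 8)) {
    m <- fragment_mass(seq, c(1, i))
    h <- map_cleavage_site(rec, m, "N", tolerance_ppm = 5e4)
    expect_equal(h$bond_i[1], i)
    expect_equal(h$error_ppm[1], 0, tolerance = 1e-9)
    expect_true(all(diff(abs(h$error_ppm)) >= 0))
  }

  # degenerate observed mass and no-match cases give empty results
  expect_equal(nrow(map_cleavage_site(rec, 18.010565, "N")), 0L)
  expect_equal(nrow(map_cleavage_site(rec, 1e6, "N", tolerance_ppm = 1)), 0L)

  # restriction to the annotated RCL: bond 2 lies outside rcl_span (3, 10)
  m2 <- fragment_mass(seq, c(1, 2))
  h_all <- map_cleavage_site(rec2, m2, "N", tolerance_ppm = 10)
  h_rcl <- map_cleavage_site(rec2, m2, "N", tolerance_ppm = 10,
                             restrict_to_rcl = TRUE)
  expect_equal(h_all$bond_i, 2L)
  expect_equal(nrow(h_rcl), 0L)
})

test_that("annotate_rcl projects a reference span through the alignment", {
  core <- random_aa(60, seed = 31)
  rcl <- "GAVSGAEAAAVSM"
  ref_seq <- paste0(core, rcl, random_aa(8, seed = 32))
  ref <- serpin_record("ref", ref_seq, rcl_span = c(61, 73), p1_index = 72)
  # query: same sequence with a 5-residue N-terminal extension
  qry <- paste0("MKKLL", ref_seq)
  ann <- annotate_rcl(serpin_record("q", qry), ref)
  expect_equal(ann$rcl_span, c(66, 78))
  expect_equal(ann$p1_index, 77L)

  # hinge heuristic finds the small-residue run inside the RCL
  hinge <- find_hinge(ann)
  expect_false(is.null(hinge))
  expect_true(hinge[1] >= ann$rcl_span[1] && hinge[2] <= ann$rcl_span[2])
  expect_gte(hinge[2] - hinge[1] + 1, 4)

  expect_null(find_hinge("MKWLYERT"))
  expect_error(annotate_rcl(serpin_record("q", qry),
                            serpin_record("r", ref_seq)), "rcl_span")
})
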