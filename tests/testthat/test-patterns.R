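test_that("parse_pattern computes element structure and span bounds", {
  p <- parse_pattern("C-x(2)-C-x(3)-[FW]-x(8)-H-x(3)-H")
  expect_equal(nrow(p), 9L)
  expect_equal(attr(p, "min_span"), 21L)
  expect_equal(attr(p, "max_span"), 21L)

  p2 <- parse_pattern("C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H")
  expect_equal(attr(p2, "min_span"), 21L)
  expect_equal(attr(p2, "max_span"), 25L)

  p3 <- parse_pattern("[FWsgat]")
  expect_setequal(p3$major[[1]], c("F", "W"))
  expect_setequal(p3$exceptional[[1]], c("S", "G", "A", "T"))
})

test_that("parse_pattern rejects malformed or out-of-dialect input", {
  expect_error(parse_pattern("C-{P}-C"), "dialect")
  expect_error(parse_pattern("<C-x-H>"), "dialect")
  expect_error(parse_pattern("C-x(4,2)-C"), "repeat")
  expect_error(parse_pattern("C-[]-C"), "empty")
  expect_error(parse_pattern("C--C"), "empty")
  expect_error(parse_pattern("C-foo-C"), "malformed")
})

test_that("parse/render is a fixed point for every published pattern", {
  for (pat in ovol_patterns()) {
    rendered <- render_pattern(parse_pattern(pat))
    expect_equal(rendered, pat)
    expect_equal(render_pattern(parse_pattern(rendered)), rendered)
  }
})

test_that("scan_pattern finds hand-checkable matches", {
  hits <- scan_pattern("CAACAAAFAAAAAAAAHAAAH", "C-x(2)-C-x(3)-[FW]-x(8)-H-x(3)-H")
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(1L, 21L))

  hits2 <- scan_pattern("ACDECA", "C-x(2)-C")
  expect_equal(c(hits2$start, hits2$end), c(2L, 5L))

  expect_equal(nrow(scan_pattern("AAAA", "C-x-C")), 0L)
})

test_that("X matches wildcards only, never residue elements", {
  expect_equal(nrow(scan_pattern("CXXC", "C-x(2)-C")), 1L)
  expect_equal(nrow(scan_pattern("XAAC", "C-x(2)-C")), 0L)
  expect_equal(nrow(scan_pattern("CXAF", "C-x(2)-[FW]")), 1L)
  expect_equal(nrow(scan_pattern("CXAX", "C-x(2)-[FW]")), 0L)
})

test_that("scanner agrees with the regex enumeration oracle on random cases", {
  set.seed(1)
  n_cases <- 220
  for (i in seq_len(n_cases)) {
    pat <- random_pattern()
    seq <- random_protein(sample(10:50, 1))
    got <- scan_pattern(seq, pat, mode = "all")
    want <- oracle_scan_all(seq, pat)
    expect_equal(nrow(got), nrow(want), info = sprintf("case %d: %s vs %s", i, pat, seq))
    if (nrow(want)) {
      got_o <- got[order(got$start, got$end), ]
      expect_equal(got_o$start, want$start, info = pat)
      expect_equal(got_o$end, want$end, info = pat)
    }
    got_l <- scan_pattern(seq, pat, mode = "leftmost")
    want_l <- oracle_scan_leftmost(seq, pat)
    expect_equal(nrow(got_l), if (is.null(want_l)) 0L else nrow(want_l), info = pat)
    if (nrow(got_l)) {
      expect_equal(got_l$start, want_l$start, info = pat)
      expect_equal(got_l$end, want_l$end, info = pat)
    }
  }
})

test_that("find_tetrad detects four closely spaced motifs and rejects others", {
  motif <- "CAACAAAFAAAAAAAAHAAAH"  # 21 aa, matches the overall pattern
  seq <- paste0(strrep("Q", 100),
                motif, strrep("A", 5),
                motif, strrep("A", 5),
                motif, strrep("A", 5), motif)
  hits <- scan_pattern(seq, ovol_patterns()[["overall"]])
  tet <- find_tetrad(hits)
  expect_equal(nrow(tet), 4L)
  expect_equal(tet$start, c(101L, 127L, 153L, 179L))
  expect_equal(tet$end, c(121L, 147L, 173L, 199L))
  expect_equal(tet$motif, c("I", "II", "III", "IV"))

  expect_equal(nrow(find_tetrad(hits[1:3, ])), 0L)

  far <- paste0(motif, strrep("A", 5), motif, strrep("A", 5), motif,
                strrep("A", 500), motif)
  far_hits <- scan_pattern(far, ovol_patterns()[["overall"]])
  expect_equal(nrow(find_tetrad(far_hits, max_linker = 20)), 0L)
})

test_that("derive_pattern reproduces frequency-threshold classifications", {
  expect_equal(derive_pattern(c("CAAC", "CTTC", "CAGC"),
                              f_major = 0.2, f_wild = 0.5),
               "C-[AT]-x-C")

  # column with F at 0.8 and S,G,A,T at 0.05 each
  inst <- c(rep("F", 16), "S", "G", "A", "T")
  expect_equal(derive_pattern(inst, f_major = 0.2), "[Fsgat]")

  expect_equal(derive_pattern(rep("CAAC", 3)), "C-A-A-C")
})

test_that("derived patterns re-scan their own ungapped instances", {
  for (rep in 1:10) {
    sim <- simulate_family(simulation_config(taxa = 5, id_length = c(30, 60),
                                             p_core = 0.1, p_id = 0.4),
                           seed = rep)
    # motif I instances are gapless and columnwise homologous by construction
    m1 <- dplyr::filter(sim$truth$motifs, motif == "I")
    inst <- substr(sim$records$residues[match(m1$seq_id, sim$records$id)],
                   m1$start, m1$end)
    pat <- derive_pattern(inst)
    parsed <- parse_pattern(pat)
    for (s in inst) {
      hits <- scan_pattern(s, parsed, mode = "all")
      expect_true(any(hits$start == 1 & hits$end == nchar(s)), info = pat)
    }
  }
})

test_that("logo_matrix computes entropy-based information", {
  lm1 <- logo_matrix(rep("C", 50), small_sample_correction = FALSE)
  expect_equal(lm1$information, log2(20), tolerance = 1e-12)

  lm2 <- logo_matrix(ovolution:::AA20, small_sample_correction = FALSE)
  expect_equal(lm2$information, 0)

  lm3 <- logo_matrix(c("C", "C", "C", "H"), small_sample_correction = FALSE)
  expect_equal(lm3$information, log2(20) + 0.75 * log2(0.75) + 0.25 * log2(0.25),
               tolerance = 1e-12)
  expect_equal(lm3$information, 3.5106, tolerance = 1e-4)
  expect_equal(sum(lm3[1, ovolution:::AA20]), 1)

  # small-sample correction subtracts 19/(2 ln2 n)
  lm4 <- logo_matrix(c("C", "C", "C", "H"), small_sample_correction = TRUE)
  expect_equal(lm4$information, lm3$information - 19 / (2 * log(2) * 4),
               tolerance = 1e-12)
})

test_that("logo information decreases with column entropy; gap columns flagged", {
  # increasingly mixed columns
  infos <- vapply(0:10, function(k) {
    col <- c(rep("C", 20 - k), sample(setdiff(ovolution:::AA20, "C"), k, replace = TRUE))
    logo_matrix(col, small_sample_correction = FALSE)$information
  }, 1)
  expect_true(all(diff(infos) <= 1e-9))

  lm <- logo_matrix(c("--", "--", "C-"))
  expect_true(lm$all_gap[2])
  expect_equal(lm$information[2], 0)
})

test_that("a single-instance insertion widens the logo by one column", {
  inst <- c("CAAC-AAH", "CAAC-AAH", "CAACQAAH")
  lm <- logo_matrix(inst)
  expect_equal(nrow(lm), 8L)   # modal instance length 7 + 1 insertion column
  expect_equal(lm$gap[5], 2 / 3)
})
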