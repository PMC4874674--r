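test_that("a constructed amplicon decomposes exactly and idempotently", {
  units <- rep(zfarray:::ZF_UNIT_CONSENSUS_AA, 9)
  seq <- make_amplicon(units)
  a <- segment_array(seq, "s1", "cattle")
  expect_s3_class(a, "zf_array")
  expect_equal(a$n_units, 9L)
  expect_equal(a$allele, "D")
  expect_false(a$partial)
  expect_equal(a$leading_finger_aa, zfarray:::ZF_LEADING_AA)
  expect_identical(reconstruct_array(a), seq)
  # idempotence: decomposing the reconstruction gives the identical result
  b <- segment_array(reconstruct_array(a), "s1", "cattle")
  expect_equal(b$units$aa, a$units$aa)
  expect_equal(b$upstream_flank, a$upstream_flank)
  expect_equal(b$spacer, a$spacer)
})

test_that("a His-mutated unit yields a partial decomposition with warning", {
  units <- rep(zfarray:::ZF_UNIT_CONSENSUS_AA, 9)
  broken <- units[5]
  substring(broken, 18, 18) <- "Y"  # His1 -> Tyr breaks the motif
  units[5] <- broken
  seq <- make_amplicon(units)
  expect_warning(a <- segment_array(seq, "s1"), "partial|interrupted")
  expect_true(a$partial)
  # independent windowed-motif oracle: count windows matching the motif
  aa <- translate_dna(seq, 0)
  oracle_hits <- length(gregexpr("C.{2}C.{12}H.{3,5}H", aa, perl = TRUE)[[1]])
  expect_equal(oracle_hits, 1L + 9L - 1L)  # leading + 8 intact units
})

test_that("no C2H2 motif anywhere is a hard error", {
  expect_error(segment_array(strrep("ACGT", 40), "junk"), "not a ZF array")
})

test_that("contact residues follow the His1 offset rule", {
  # independent re-implementation of the offset rule by direct indexing
  u <- segment_array(make_amplicon(rep(zfarray:::ZF_UNIT_CONSENSUS_AA, 6)),
                     "s")$units[1, ]
  cr <- contact_residues(u)
  chars <- strsplit(u$aa, "")[[1]]
  for (k in c(-9, -5, -2, -1, 2, 3, 6)) {
    idx <- if (k >= 1) u$his1 - (7 - k) else u$his1 - (6 - k)
    expect_equal(unname(cr[as.character(k)]), chars[idx])
  }
})

test_that("the Zif268 finger reproduces its published recognition residues", {
  zif <- substring("PYACPVESCDRRFSRSDELTRHIRIHTGQKP", 4, 31)  # 28-aa window
  anch <- zfarray:::find_c2h2_anchors(zif, relaxed = TRUE)
  cr <- contact_residues(list(aa = zif, his1 = anch$his1))
  expect_equal(unname(cr[c("-1", "2", "3", "6")]), c("R", "D", "E", "R"))
})

test_that("an all-identical unit maps every contact position to that residue", {
  cr <- contact_residues(list(aa = strrep("X", 28), his1 = 18L))
  expect_equal(unname(cr), rep("X", 7))
})

test_that("allele letters map 6-12 to A-G with flagged extensions", {
  expect_equal(assign_allele_label(6:12), c("A", "B", "C", "D", "E", "F", "G"))
  expect_equal(assign_allele_label(9), "D")
  expect_warning(expect_equal(assign_allele_label(5), "A-"), "catalogue")
  expect_warning(expect_equal(assign_allele_label(13), "H"), "catalogue")
})

test_that("amplicon lengths convert to alleles through the 84-bp series", {
  r <- infer_allele_from_amplicon_length(1068, known_n = 6, known_length = 900)
  expect_equal(r$allele, "C")
  expect_equal(r$residual, 0)
  r2 <- infer_allele_from_amplicon_length(1070, 6, 900)
  expect_equal(r2$allele, "C")
  expect_equal(r2$residual, 2)
  # sequential alleles differ by exactly one repeat: step-84 series
  lens <- 900 + 84 * (0:6)
  rr <- infer_allele_from_amplicon_length(lens, 6, 900)
  expect_equal(rr$allele, c("A", "B", "C", "D", "E", "F", "G"))
  expect_equal(rr$residual, rep(0, 7))
  expect_warning(infer_allele_from_amplicon_length(950, 6, 900), "ambiguous")
})

test_that("unit counts are recovered over the full 6-12 allele range", {
  pool <- unit_pool(10, seed = 21)
  set.seed(22)
  for (n in 6:12) {
    seq <- make_amplicon(sample(pool, n, replace = TRUE))
    a <- segment_array(seq, paste0("n", n))
    expect_equal(a$n_units, n)
    expect_identical(reconstruct_array(a), seq)
  }
})
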