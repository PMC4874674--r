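test_that("a clean reading frame is functional with full-length residues", {
  set.seed(51)
  aas <- paste0(sample(setdiff(names(zfarray:::AA_CODON), c("C", "H")), 30,
                       TRUE), collapse = "")
  seq <- reverse_translate(aas)
  rep <- scan_orf(seq, frame = 0)
  expect_equal(rep$classification, "functional")
  expect_equal(rep$n_stops, 0L)
  expect_equal(rep$residues_before_first_stop, 30L)
})

test_that("an inserted stop is located by the codon walk", {
  base <- segment_array(make_amplicon(rep(zfarray:::ZF_UNIT_CONSENSUS_AA, 6)),
                        "b")
  ps <- simulate_pseudogene(base, stops = 10L)
  rep <- scan_orf(ps$seq)
  expect_equal(rep$first_stop_codon, 10L)
  expect_equal(rep$residues_before_first_stop, 9L)
  expect_equal(rep$classification, "disrupted")
  # independent codon-walk oracle over the chosen frame
  f <- rep$frame
  codons <- substring(ps$seq, f + seq(1, nchar(ps$seq) - f - 2, 3),
                      f + seq(3, nchar(ps$seq) - f, 3))
  oracle_stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  expect_equal(rep$stop_codon_indices, oracle_stops)
})

test_that("stop indices always equal '*' positions in the translation", {
  base <- segment_array(make_amplicon(rep(zfarray:::ZF_UNIT_CONSENSUS_AA, 7)),
                        "b")
  ps <- simulate_pseudogene(base, stops = c(5L, 40L, 80L))
  rep <- scan_orf(ps$seq, frame = base$frame)
  aa <- translate_dna(ps$seq, base$frame)
  expect_equal(rep$stop_codon_indices,
               which(strsplit(aa, "")[[1]] == "*"))
  expect_equal(rep$n_stops, 3L)
})

test_that("stops confined to the final two codons stay functional", {
  set.seed(52)
  aas <- paste0(sample(setdiff(names(zfarray:::AA_CODON), c("C", "H")), 20,
                       TRUE), collapse = "")
  seq <- paste0(reverse_translate(aas), "TAA")  # natural terminator
  rep <- scan_orf(seq, frame = 0)
  expect_equal(rep$n_stops, 1L)
  expect_equal(rep$classification, "functional")
})

test_that("auto frame selection minimises the stop count", {
  base <- segment_array(make_amplicon(rep(zfarray:::ZF_UNIT_CONSENSUS_AA, 6)),
                        "b")
  seq <- reconstruct_array(base)
  rep <- scan_orf(seq)
  expect_equal(rep$frame, base$frame)
  expect_equal(rep$n_stops, 0L)
})

test_that("frameshifts are flagged only for non-multiple-of-3 indels", {
  cons <- reverse_translate(zfarray:::ZF_UNIT_CONSENSUS_AA)
  clean <- strrep(cons, 3)
  expect_equal(nrow(detect_frameshift(clean, cons)), 0L)
  # 1-nt deletion inside copy 2
  del1 <- paste0(substring(clean, 1, 130), substring(clean, 132))
  fs <- detect_frameshift(del1, cons)
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$offset, -1L)
  expect_lt(abs(fs$position - 131L), 6L)  # gap placement ambiguity tolerated
  # in-frame 3-nt deletion is silent
  del3 <- paste0(substring(clean, 1, 130), substring(clean, 134))
  expect_equal(nrow(detect_frameshift(del3, cons)), 0L)
  # 2-nt insertion flagged positive
  ins2 <- paste0(substring(clean, 1, 100), "AA", substring(clean, 101))
  fs2 <- detect_frameshift(ins2, cons)
  expect_equal(fs2$offset, 2L)
  # unalignable sequence is a no-call
  set.seed(53)
  junk <- paste0(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  expect_warning(out <- detect_frameshift(junk, cons), "no-call")
  expect_null(out)
})

test_that("planted frameshifts round-trip through the simulator", {
  base <- segment_array(make_amplicon(rep(zfarray:::ZF_UNIT_CONSENSUS_AA, 6)),
                        "b")
  cons <- base$units$nt[1]
  units_start <- nchar(base$upstream_flank) + nchar(base$leading_finger_nt) +
    nchar(base$spacer)
  ps <- simulate_pseudogene(base, frameshifts = tibble::tibble(
    position = units_start + 100L, offset = -1L))
  fs <- detect_frameshift(substring(ps$seq, units_start + 1), cons)
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$offset, -1L)
  # no edits: functional scan
  clean <- simulate_pseudogene(base)
  expect_equal(scan_orf(clean$seq)$classification, "functional")
})
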