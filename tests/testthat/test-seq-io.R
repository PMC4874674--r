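test_that("read_fasta parses records in order, uppercased, validated", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some description", "ACGT", ">y", "acg", "tNN"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("x", "y"))
  expect_equal(recs$description, c("some description", ""))
  expect_equal(recs$seq, c("ACGT", "ACGTNN"))
  # agrees with an independent character-by-character parser
  ref <- reference_fasta_parse(f)
  expect_equal(setNames(recs$seq, recs$id), unlist(ref))
})

test_that("read_fasta rejects empty files, duplicate ids and bad characters", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(c(">a", "ACXT"), f)
  expect_error(read_fasta(f), "non-nucleotide.*a")
})

test_that("FASTA write/read round-trips ids and sequences exactly", {
  set.seed(41)
  recs <- tibble::tibble(
    id = paste0("rec", 1:8),
    description = c("", "d1", "", "x y z", "", "", "q", ""),
    seq = vapply(1:8, function(i)
      paste0(sample(c("A", "C", "G", "T"), 50 + 37 * i, TRUE), collapse = ""),
      character(1)))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$seq, recs$seq)
})

test_that("translation follows the standard code with stops and ambiguity", {
  expect_equal(translate_dna("ATG"), "M")
  expect_equal(translate_dna("TAA"), "*")
  expect_equal(translate_dna("ATGNAA"), "MX")
  expect_equal(nchar(translate_dna(reverse_translate(zfarray:::ZF_UNIT_CONSENSUS_AA))), 28)
  expect_equal(translate_dna("AATGGC", frame = 1), "M")
  expect_error(translate_dna("ATG", frame = 3), "frame")
})

test_that("translation agrees with seqinr on 1000 random codons", {
  set.seed(7)
  codons <- vapply(1:1000, function(i)
    paste0(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""), character(1))
  mine <- vapply(codons, translate_dna, character(1))
  oracle <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(tolower(cd), "")[[1]])
  }, character(1))
  expect_equal(unname(mine), unname(oracle))
})

test_that("global alignment identity is symmetric and counts mismatches", {
  set.seed(13)
  a <- paste0(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  b <- a
  substring(b, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                  substring(a, 50, 50))[1]
  aln <- align_global(a, b)
  expect_equal(aln$percent_identity, 0.99)
  expect_equal(align_global(b, a)$percent_identity, aln$percent_identity)
  expect_equal(align_global(a, a)$percent_identity, 1)
})

test_that("paralog classifier picks the highest-identity reference", {
  set.seed(5)
  base <- paste0(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  near <- base
  substring(near, 10, 10) <- "N"  # not used; build diverged copy instead
  far <- paste0(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  refs <- tibble::tibble(label = c("PRDM9", "PRDM7"), seq = c(far, base))
  cl <- classify_paralog(list(id = "q", seq = base), refs)
  expect_equal(cl$label, "PRDM7")
  expect_equal(cl$percent_identity, 1)
  expect_equal(nrow(cl$table), 2)
  # ties break by reference input order
  refs2 <- tibble::tibble(label = c("first", "second"), seq = c(base, base))
  expect_equal(classify_paralog(list(id = "q", seq = base), refs2)$label,
               "first")
  expect_error(classify_paralog(list(id = "q", seq = base),
                                refs2[0, ]), "reference")
})

test_that("Newick parse/write round-trips topology and lengths", {
  tr <- parse_newick("(A:1,B:2);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))
  q <- parse_newick("((A,B),(C,D));")
  expect_equal(sort(q$tip.label), c("A", "B", "C", "D"))
  # the quartet split AB|CD is present: drop A and B -> C,D remain siblings
  expect_true(ape::is.monophyletic(ape::root(q, "A"), c("C", "D")))
  s <- "((A:0.1,B:0.25):0.05,(C:0.3,D:0.07):0.02);"
  rt <- parse_newick(write_newick(parse_newick(s)))
  expect_true(ape::all.equal.phylo(rt, parse_newick(s),
                                   use.edge.length = TRUE))
  expect_error(parse_newick("((A,B);"), "parenthes|malformed")
  expect_error(parse_newick("(A,B)"), "malformed")
})
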