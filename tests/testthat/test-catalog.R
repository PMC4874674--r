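make_array <- function(unit_aas, id, species = "sp1") {
  segment_array(make_amplicon(unit_aas), id, species)
}

test_that("identical units collapse to one catalogue entry", {
  a <- make_array(rep(zfarray:::ZF_UNIT_CONSENSUS_AA, 9), "a1")
  cat1 <- build_catalog(list(a))
  expect_equal(nrow(cat1$entries), 1L)
  expect_equal(cat1$entries$n_total, 9L)
})

test_that("disjoint arrays give a catalogue of the union size", {
  pool <- unit_pool(8, seed = 31)
  a <- make_array(pool[1:4], "a1", "sp1")
  b <- make_array(pool[5:8], "b1", "sp2")
  cat2 <- build_catalog(list(a, b))
  # set-union oracle over the unit strings
  expect_equal(nrow(cat2$entries),
               length(union(a$units$aa, b$units$aa)))
  # catalogue size never exceeds total unit count
  expect_lte(nrow(cat2$entries), sum(a$n_units, b$n_units))
})

test_that("codes are deterministic and ordered by first appearance", {
  pool <- unit_pool(6, seed = 32)
  arrays <- list(make_array(pool[c(1, 2, 1, 3, 2, 4)], "a1"),
                 make_array(pool[c(5, 6, 1, 2, 3, 4)], "b1"))
  c1 <- build_catalog(arrays)
  c2 <- build_catalog(arrays)
  expect_identical(c1$entries, c2$entries)
  expect_equal(c1$entries$code, seq_len(nrow(c1$entries)))
  # same arrays in reversed list order: same size, codes reassigned
  c3 <- build_catalog(rev(arrays), sort_input = FALSE)
  expect_equal(nrow(c3$entries), nrow(c1$entries))
  expect_false(identical(c3$entries$aa, c1$entries$aa))
})

test_that("schematics report code order and repeated-domain multisets", {
  pool <- unit_pool(6, seed = 33)
  arr <- make_array(pool[c(1, 2, 1, 3, 4, 5)], "a1")
  ct <- build_catalog(list(arr))
  sch <- array_schematic(arr, ct)
  expect_equal(length(sch$codes), 6L)
  expect_equal(sch$codes[1], sch$codes[3])
  expect_equal(unname(sch$repeated[as.character(sch$codes[1])]), 2L)
  arr2 <- make_array(pool, "b1")
  ct2 <- build_catalog(list(arr2))
  expect_length(array_schematic(arr2, ct2)$repeated, 0L)
  # unknown unit is an error
  expect_error(array_schematic(arr2, ct), "absent")
})

test_that("cross-species stats find shared domains and positional diversity", {
  pool <- unit_pool(8, seed = 34)
  a <- make_array(pool[c(1, 1, 2, 3, 4, 5)], "a1", "sheep")
  b <- make_array(pool[c(1, 6, 7, 8, 6, 7)], "b1", "goat")
  ct <- build_catalog(list(a, b))
  st <- cross_species_stats(ct)
  shared_aa <- intersect(a$units$aa, b$units$aa)
  expect_equal(nrow(st$shared), length(shared_aa))
  expect_true(all(st$shared$n_species == 2))
  expect_setequal(st$diversity$position, c(-9, -5, -2, -1, 2, 3, 6))
  # diversity oracle: distinct residues at -1 across entries
  res_m1 <- vapply(ct$entries$aa, function(aa) {
    anch <- zfarray:::find_c2h2_anchors(aa)
    substring(aa, anch$his1 - 7, anch$his1 - 7)
  }, character(1))
  expect_equal(st$diversity$n_residues[st$diversity$position == -1],
               length(unique(res_m1)))
  expect_error(cross_species_stats(build_catalog(list(a))), "two species")
})

test_that("genotype summaries reproduce the ruminant panel tables", {
  panel <- utils::read.delim(system.file("extdata",
                                         "ruminant_prdm9_genotypes.tsv",
                                         package = "zfarray"))
  recs <- genotype_records_from_counts(panel)
  gs <- genotype_summary(recs)
  # panel sizes add up per species
  totals <- gs$heterozygosity
  expect_equal(sort(totals$n_animals[totals$species %in%
    c("Bos taurus", "Bos indicus", "Bos taurus-Bos indicus hybrid",
      "Bos grunniens", "Bos frontalis")]), sort(c(25, 40, 40, 10, 20)))
  expect_equal(totals$n_animals[totals$species == "Capra hircus"], 45)
  expect_equal(totals$n_animals[totals$species == "Ovis aries"], 45)
  # sheep panel: 41 DD homozygotes + 4 CD heterozygotes
  ov <- totals[totals$species == "Ovis aries", ]
  expect_equal(ov$n_het, 4)
  expect_equal(ov$het_fraction, 4 / 45)
  # yak panel: a single AA genotype class with count 10
  yak <- gs$counts[gs$counts$species == "Bos grunniens", ]
  expect_equal(nrow(yak), 1L)
  expect_equal(yak$genotype, "AA")
  expect_equal(yak$n, 10)
})

test_that("all-homozygous panels have zero heterozygosity", {
  recs <- tibble::tibble(animal_id = paste0("x", 1:5), species = "sp",
                         allele1 = "D", allele2 = "D")
  expect_equal(genotype_summary(recs)$heterozygosity$het_fraction, 0)
})
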