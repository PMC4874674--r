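test_that("population simulation is a pure function of its seed", {
  cfg <- population_sim_config(seed = 81)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$genotypes, s2$genotypes)
  s3 <- simulate_population(population_sim_config(seed = 82))
  expect_false(identical(s1$records$seq, s3$records$seq))
})

test_that("simulated genotypes and catalogues round-trip through the pipeline", {
  small <- population_sim_config(
    species = tibble::tibble(
      name = c("spA", "spB"), n_animals = c(6L, 6L),
      freqs = list(c(A = 0.5, D = 0.5), c(C = 0.3, G = 0.7))),
    pool_size = 5L, seed = 83)
  sim <- simulate_population(small)
  arrays <- purrr::map(seq_len(nrow(sim$records)), function(i) {
    segment_array(sim$records$seq[i], sim$records$id[i],
                  sub("_.*$", "", sim$records$id[i]))
  })
  # every haplotype's recovered allele letter matches the simulated one
  truth_allele <- sub("^.*allele=", "", sim$records$description)
  expect_equal(vapply(arrays, function(a) a$allele, character(1)),
               truth_allele)
  # recovered catalogue equals the set of pool domains actually used
  ct <- build_catalog(arrays)
  used <- unique(dplyr::inner_join(
    sim$alleles,
    dplyr::distinct(sim$genotypes |>
      tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
      dplyr::select("species", "allele")),
    by = c("species", "allele")) |>
    dplyr::inner_join(sim$domains, by = c("species", "domain_id")) |>
    dplyr::pull("aa"))
  expect_setequal(ct$entries$aa, used)
})

test_that("zero branch lengths copy the root to every taxon", {
  tr <- example_tree(5)
  tr$edge.length <- tr$edge.length * 0
  s <- simulate_codon_alignment(tr, "M0", list(omega = 1), n_sites = 40,
                                seed = 84)
  cod <- s$alignment$codons
  expect_true(all(apply(cod, 2, function(x) length(unique(x)) == 1L)))
})

test_that("long-branch M0 simulation converges to the stationary law", {
  tr <- parse_newick("(A:30,B:30,C:30);")
  s <- simulate_codon_alignment(tr, "M0", list(omega = 1), n_sites = 4000,
                                kappa = 2, seed = 85)
  counts <- table(factor(s$alignment$codons, levels = sense_codons()))
  gof <- stats::chisq.test(counts, p = rep(1 / 61, 61))
  expect_gt(gof$p.value, 1e-3)
})

test_that("site-class truth matches its mixture proportions", {
  tr <- example_tree(6)
  s <- simulate_codon_alignment(tr, "M2a",
                                list(p0 = 0.5, p1 = 0.3, omega0 = 0.1,
                                     omega2 = 5),
                                n_sites = 500, seed = 86)
  frac_pos <- mean(s$truth$omega > 1)
  expect_lt(abs(frac_pos - 0.2), 0.05)
  expect_equal(sort(unique(s$truth$omega)), c(0.1, 1, 5))
  # no stop codons ever emitted
  expect_false(any(is.na(s$alignment$states)))
})

test_that("unequal-length arrays stack with trailing missing data", {
  pool <- unit_pool(6, seed = 87)
  a6 <- segment_array(make_amplicon(pool[1:6]), "a6", "x")
  a62 <- segment_array(make_amplicon(pool[c(2:6, 1)]), "a62", "x")
  a9 <- segment_array(make_amplicon(pool[c(1:6, 1:3)]), "a9", "y")
  aln <- build_codon_alignment(list(a6, a62, a9))
  expect_equal(ncol(aln$codons), 28 * 9)
  expect_equal(sum(is.na(aln$codons["a6", ])), 28 * 3)
  expect_equal(sum(is.na(aln$codons["a9", ])), 0)
  # column-count oracle and site map coverage
  expect_equal(nrow(aln$site_map), 28 * 9)
  expect_equal(max(aln$site_map$unit), 9)
  expect_error(build_codon_alignment(list(a6, a62, a9),
                                     strict_equal_length = TRUE), "unit count")
  # helix map points the contact offsets at the consensus anchor
  expect_setequal(aln$helix_map$helix_position, c(-9, -5, -2, -1, 2, 3, 6))
})
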