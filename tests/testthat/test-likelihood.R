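test_that("pruning equals exhaustive enumeration on small trees", {
  pi <- uniform_pi()
  trees <- list(parse_newick("(A:0.2,B:0.1,C:0.3);"),
                parse_newick("((A:0.2,B:0.1):0.15,C:0.3,D:0.05);"))
  mixtures <- list(list(o = 0.7, w = 1),
                   list(o = c(0.1, 1), w = c(0.6, 0.4)),
                   list(o = c(0.2, 1, 4), w = c(0.5, 0.3, 0.2)))
  for (tr in trees) {
    s <- simulate_codon_alignment(tr, "M0", list(omega = 0.8),
                                  n_sites = 3, seed = 17)
    for (mix in mixtures) {
      fast <- prune_loglik(s$alignment, tr, kappa = 2.3, omegas = mix$o,
                           class_weights = mix$w, pi = pi)$loglik
      slow <- brute_loglik(s$alignment, tr, 2.3, mix$o, mix$w, pi)
      expect_equal(fast, slow, tolerance = 1e-8)
    }
  }
})

test_that("missing data marginalises exactly like pruning the taxon", {
  pi <- uniform_pi()
  tr <- parse_newick("((A:0.2,B:0.1):0.15,C:0.3,D:0.05);")
  s <- simulate_codon_alignment(tr, "M0", list(omega = 0.5),
                                n_sites = 4, seed = 23)
  cod <- s$alignment$codons
  cod["D", ] <- NA_character_
  with_missing <- prune_loglik(codon_alignment(cod), tr, 2, 1, pi = pi)$loglik
  dropped <- ape::drop.tip(tr, "D")
  without <- prune_loglik(codon_alignment(cod[c("A", "B", "C"), , drop = FALSE]),
                          dropped, 2, 1, pi = pi)$loglik
  expect_equal(with_missing, without, tolerance = 1e-8)
})

test_that("zero total branch length reduces to the stationary density", {
  pi <- uniform_pi()
  tr <- parse_newick("(A:0,B:0,C:0);")
  cod <- matrix(rep(c("ATG", "TGC", "AAA"), each = 3), 3, 3,
                dimnames = list(c("A", "B", "C"), NULL))
  ll <- prune_loglik(codon_alignment(cod), tr, 2, 1, pi = pi)$loglik
  expect_equal(ll, sum(log(pi[c("ATG", "TGC", "AAA")])), tolerance = 1e-10)
})

test_that("a single-class mixture equals the unmixed computation", {
  pi <- uniform_pi()
  tr <- example_tree(5)
  s <- simulate_codon_alignment(tr, "M0", list(omega = 1.2),
                                n_sites = 30, seed = 29)
  a <- prune_loglik(s$alignment, tr, 2, 0.6, class_weights = 1, pi = pi)$loglik
  b <- prune_loglik(s$alignment, tr, 2, c(0.6, 0.6),
                    class_weights = c(0.5, 0.5), pi = pi)$loglik
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("the likelihood is invariant to leaf order and rooting", {
  pi <- uniform_pi()
  tr <- example_tree(6)
  s <- simulate_codon_alignment(tr, "M1a", list(p0 = 0.6, omega0 = 0.2),
                                n_sites = 40, seed = 31)
  base <- prune_loglik(s$alignment, tr, 2, c(0.2, 1),
                       class_weights = c(0.6, 0.4), pi = pi)$loglik
  # permute alignment rows
  perm <- s$alignment$codons[rev(s$alignment$taxa), , drop = FALSE]
  ll_perm <- prune_loglik(codon_alignment(perm), tr, 2, c(0.2, 1),
                          class_weights = c(0.6, 0.4), pi = pi)$loglik
  expect_equal(ll_perm, base, tolerance = 1e-8)
  # re-root at a tip and unroot again elsewhere
  rooted <- ape::root(tr, "t4", resolve.root = TRUE)
  ll_root <- prune_loglik(s$alignment, rooted, 2, c(0.2, 1),
                          class_weights = c(0.6, 0.4), pi = pi)$loglik
  expect_equal(ll_root, base, tolerance = 1e-8)
})

test_that("stop codons are rejected from alignments", {
  cod <- matrix(c("ATG", "TAA", "ATG", "ATG", "ATG", "ATG"), 3, 2,
                dimnames = list(c("A", "B", "C"), NULL))
  expect_error(codon_alignment(cod), "stop")
})

test_that("neighbor joining solves the 3-taxon additive case exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  # 3-point formulas: a = (dAB + dAC - dBC)/2 = 1, b = 1, c = 3
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("neighbor joining recovers a quartet from additive distances", {
  tr0 <- parse_newick("((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.05);")
  d <- ape::cophenetic.phylo(tr0)
  tr <- neighbor_joining(d)
  # brute-force check over the three quartet topologies via split AB|CD
  expect_true(ape::is.monophyletic(ape::root(tr, "A"), c("C", "D")))
  # identical sequences: all distances zero -> all branch lengths zero
  cod <- matrix(rep("ATG", 12), 4, 3, dimnames = list(LETTERS[1:4], NULL))
  d0 <- codon_p_distance(codon_alignment(cod))
  expect_true(all(d0 == 0))
  tr0b <- neighbor_joining(d0)
  expect_true(all(tr0b$edge.length == 0))
})
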