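# R surface over the pruning core: pattern compression, tree bookkeeping.

# compress alignment columns into unique site patterns
site_patterns <- function(alignment) {
  st <- alignment$states
  st[is.na(st)] <- 0L
  key <- apply(st, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(states = st[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, sum(first))),
       site_to_pattern = idx)
}

# postorder edge matrix + consistency checks between tree and alignment
lik_tree_data <- function(alignment, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, alignment$taxa)) {
    stop("tree leaf set does not match alignment taxa", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  tr <- stats::reorder(tree, "postorder")
  row_ord <- match(tr$tip.label, alignment$taxa)
  list(edge = tr$edge, elen = pmax(tr$edge.length, 0),
       nnode = length(tr$tip.label) + tr$Nnode, row_ord = row_ord)
}

#' Phylogenetic log-likelihood of a codon site-class mixture
#'
#' Felsenstein pruning under a mixture of GY94+F3X4 classes sharing kappa
#' and codon frequencies but differing in omega. Missing states integrate
#' over all 61 sense codons. Branch lengths are interpreted in expected
#' substitutions per codon under the mixture-averaged rate (the matrices
#' are jointly rescaled so the weighted expected rate is 1), unless a
#' pre-computed scale `rho` is supplied.
#'
#' @param alignment A `codon_alignment`.
#' @param tree An `ape::phylo` with branch lengths; leaves must match taxa.
#' @param kappa Transition/transversion ratio.
#' @param omegas Numeric vector of per-class dN/dS values.
#' @param class_weights Mixture proportions (same length, sum 1); default a
#'   single class of weight 1.
#' @param pi Codon frequencies; default [f3x4_frequencies()] of the
#'   alignment.
#' @param rho Optional fixed rate-scale factor (used by BEB so the per-class
#'   site likelihoods factor over omega values); `NULL` computes it from the
#'   mixture.
#' @param per_site Also return per-site quantities.
#' @return List with `loglik`, `rho`, and when `per_site = TRUE`,
#'   `site_loglik` (per alignment column) and `class_site_loglik`
#'   (sites x classes matrix of per-class log-likelihoods).
#' @export
prune_loglik <- function(alignment, tree, kappa, omegas,
                         class_weights = NULL, pi = NULL, rho = NULL,
                         per_site = FALSE) {
  stopifnot(inherits(alignment, "codon_alignment"))
  if (is.null(class_weights)) class_weights <- rep(1 / length(omegas), length(omegas))
  stopifnot(length(class_weights) == length(omegas),
            abs(sum(class_weights) - 1) < 1e-6, all(class_weights >= 0),
            all(omegas >= 0), kappa > 0)
  if (is.null(pi)) pi <- f3x4_frequencies(alignment)
  pat <- site_patterns(alignment)
  td <- lik_tree_data(alignment, tree)
  res <- gy94_loglik_cpp(pat$states[td$row_ord, , drop = FALSE],
                         pat$weights, td$edge, td$elen, td$nnode,
                         as.numeric(pi), codon_pair_class(), kappa,
                         as.numeric(omegas), as.numeric(class_weights),
                         rho %||% -1, per_site)
  if (!is.finite(res$loglik)) {
    stop("non-finite log-likelihood (check branch lengths and frequencies)",
         call. = FALSE)
  }
  out <- list(loglik = res$loglik, rho = res$rho)
  if (per_site) {
    out$site_loglik <- as.numeric(res$site_loglik)[pat$site_to_pattern]
    out$class_site_loglik <- res$class_site_loglik[pat$site_to_pattern, ,
                                                   drop = FALSE]
  }
  out
}
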