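# Goldman-Yang codon rate matrix under F3X4 equilibrium frequencies.

#' F3X4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies are counted over the observed
#' codons; the frequency of a sense codon is the product of its three
#' positional nucleotide frequencies, renormalised over the 61 sense codons.
#' A nucleotide absent at some codon position receives a pseudocount of 0.5
#' (with a warning) so no sense codon has frequency zero.
#'
#' @param alignment A `codon_alignment`, or a character vector of codons.
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(alignment) {
  codons <- if (inherits(alignment, "codon_alignment")) {
    as.vector(alignment$codons)
  } else {
    as.vector(alignment)
  }
  codons <- codons[!is.na(codons)]
  stopifnot(length(codons) > 0L)
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, NUCS))
  for (p in 1:3) {
    counts <- table(factor(substring(codons, p, p), levels = NUCS))
    if (any(counts == 0)) {
      warning("nucleotide absent at codon position ", p,
              "; pseudocount 0.5 applied", call. = FALSE)
      counts <- counts + 0.5
    }
    pos_freq[p, ] <- counts / sum(counts)
  }
  cod <- sense_codons()
  pi <- vapply(cod, function(cd) {
    prod(pos_freq[cbind(1:3, match(strsplit(cd, "")[[1]], NUCS))])
  }, numeric(1))
  pi / sum(pi)
}

#' Goldman-Yang (GY94) codon rate matrix
#'
#' Instantaneous rates between sense codons: zero for multi-nucleotide
#' changes; for single-nucleotide changes the rate to codon j is
#' `pi_j * m` with `m` = 1 (synonymous transversion), `kappa` (synonymous
#' transition), `omega` (nonsynonymous transversion) or `kappa * omega`
#' (nonsynonymous transition). Rows sum to zero. With `scale = TRUE` the
#' matrix is rescaled so the expected rate `sum(pi_i * -Q_ii)` equals 1
#' (branch lengths in expected substitutions per codon).
#'
#' @param pi Named 61-vector of codon frequencies (see [f3x4_frequencies()]).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param scale Rescale to unit expected rate.
#' @return List with `Q` (61 x 61), `pi`, and `rate` (the expected rate of
#'   the unscaled matrix, used for mixture-wide scaling).
#' @export
build_rate_model <- function(pi, kappa = 2, omega = 1, scale = TRUE) {
  cod <- sense_codons()
  stopifnot(length(pi) == 61L, abs(sum(pi) - 1) < 1e-8, kappa > 0, omega >= 0)
  pc <- codon_pair_class()
  mult <- matrix(0, 61, 61)
  mult[pc == 1L] <- 1
  mult[pc == 2L] <- kappa
  mult[pc == 3L] <- omega
  mult[pc == 4L] <- kappa * omega
  Q <- mult * matrix(pi, 61, 61, byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (scale) Q <- Q / rate
  dimnames(Q) <- list(cod, cod)
  list(Q = Q, pi = setNames(as.numeric(pi), cod), rate = rate)
}

# transition probability matrix exp(Q t) via eigendecomposition in the
# pi^{1/2}-symmetrised basis (exact for reversible Q); R reference used by
# the simulator and by tests (the fitting core has its own C++ copy)
codon_pmat <- function(Q, pi, t) {
  if (t == 0) return(diag(nrow(Q)))
  sq <- sqrt(pi)
  S <- (sq * Q) %*% diag(1 / sq)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  P <- (1 / sq * e$vectors) %*% (exp(e$values * t) * t(e$vectors)) %*% diag(sq)
  P[P < 0] <- 0
  P / rowSums(P)
}
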