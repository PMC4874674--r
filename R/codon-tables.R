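# Codon state space and substitution-type classification shared by the
# rate model, the simulator and the likelihood core.

NUCS <- c("A", "C", "G", "T")

# cached per-session: 61 sense codons, genetic code, pair classification
.codon_env <- new.env(parent = emptyenv())

#' Sense-codon universe under the standard genetic code
#'
#' Returns the 61 sense codons (stop codons TAA, TAG, TGA excluded) in
#' lexicographic order; this fixed ordering defines the codon state index
#' used throughout the package.
#'
#' @return Character vector of 61 codon strings.
#' @export
sense_codons <- function() {
  if (is.null(.codon_env$codons)) {
    all64 <- apply(expand.grid(NUCS, NUCS, NUCS, stringsAsFactors = FALSE)[, 3:1],
                   1L, paste0, collapse = "")
    all64 <- sort(all64)
    gc <- genetic_code()
    .codon_env$codons <- all64[gc[all64] != "*"]
  }
  .codon_env$codons
}

#' Standard genetic code table
#'
#' @return Named character vector mapping all 64 codons to one-letter amino
#'   acids, with `"*"` for the three stop codons (TAA, TAG, TGA).
#' @export
genetic_code <- function() {
  if (is.null(.codon_env$gc)) {
    gc <- Biostrings::GENETIC_CODE
    stopifnot(length(gc) == 64L, sum(gc == "*") == 3L)
    .codon_env$gc <- setNames(as.character(gc), names(gc))
  }
  .codon_env$gc
}

# 61 x 61 integer matrix classifying single-nucleotide codon pairs:
# 0 = multi-nucleotide change (or identical), 1 = synonymous transversion,
# 2 = synonymous transition, 3 = nonsynonymous transversion,
# 4 = nonsynonymous transition.
codon_pair_class <- function() {
  if (is.null(.codon_env$pairclass)) {
    cod <- sense_codons()
    gc <- genetic_code()
    n <- length(cod)
    mat <- matrix(0L, n, n, dimnames = list(cod, cod))
    split_nt <- strsplit(cod, "")
    is_transition <- function(a, b) {
      (a %in% c("A", "G") && b %in% c("A", "G")) ||
        (a %in% c("C", "T") && b %in% c("C", "T"))
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        diff <- which(split_nt[[i]] != split_nt[[j]])
        if (length(diff) != 1L) next
        ts <- is_transition(split_nt[[i]][diff], split_nt[[j]][diff])
        syn <- gc[[cod[i]]] == gc[[cod[j]]]
        mat[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
      }
    }
    .codon_env$pairclass <- mat
  }
  .codon_env$pairclass
}

# integer state (1..61) for a codon string; NA for anything not a sense codon
codon_state <- function(codons) {
  match(codons, sense_codons())
}
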