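# Fixed reference trees for simulation experiments and examples.

EXAMPLE_TREES <- c(
  "5" = "((a:0.2,b:0.15):0.1,(c:0.2,d:0.1):0.08,e:0.25);",
  "6" = "(((t1:0.15,t2:0.2):0.1,t3:0.25):0.08,(t4:0.18,t5:0.12):0.1,t6:0.3);",
  "8" = "((((t1:0.2,t2:0.25):0.1,(t3:0.2,t4:0.15):0.12):0.08,(t5:0.22,t6:0.18):0.1):0.06,t7:0.3,t8:0.25);",
  "12" = "(t6:0.34,((((t4:0.19,t11:0.24):0.11,t10:0.26):0.21,(t1:0.3,t2:0.27):0.22):0.17,t12:0.2):0.16,((t9:0.2,t8:0.28):0.29,((t7:0.22,t3:0.12):0.19,t5:0.24):0.17):0.25);")

#' Fixed unrooted example trees
#'
#' Deterministic trees used by the package's simulation experiments:
#' branch lengths in expected substitutions per codon, totals in the range
#' typical of cross-species ZF-exon comparisons. The 12-taxon tree matches
#' the scale of a pooled multi-species haplotype panel.
#'
#' @param n_taxa One of 5, 6, 8 or 12.
#' @return An `ape::phylo`.
#' @export
example_tree <- function(n_taxa = 6) {
  key <- as.character(n_taxa)
  if (!key %in% names(EXAMPLE_TREES)) {
    stop("no example tree with ", n_taxa, " taxa (available: ",
         paste(names(EXAMPLE_TREES), collapse = ", "), ")", call. = FALSE)
  }
  parse_newick(EXAMPLE_TREES[[key]])
}
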