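# Unit-stacked codon alignment over decomposed arrays, codon p-distances,
# and the neighbor-joining tree used when no tree is supplied.

#' Build a unit-stacked codon alignment from decomposed arrays
#'
#' Tandem minisatellite units are aligned unit-by-unit from the array start:
#' column (u, k) holds codon k (1..28) of unit u for every taxon. Arrays
#' with fewer units than the longest carry missing data in the absent
#' trailing units (integrated over all 61 sense codons in the likelihood).
#' The conserved leading finger is excluded by default. Any observed stop
#' codon is a hard error: pseudogenes must be excluded upstream.
#'
#' @param arrays List of `zf_array` objects (>= 3).
#' @param include_first_finger Prepend the 23 leading-finger codons (only
#'   possible when all arrays carry one).
#' @param strict_equal_length Require all arrays to have the same unit
#'   count, mirroring analyses restricted to individuals carrying the same
#'   ZF number in both copies.
#' @return A `codon_alignment`: list with `taxa`, `codons` (character
#'   matrix taxa x sites, NA = missing), `states` (integer matrix of codon
#'   states 1..61), `site_map` (tibble: site, unit, offset; unit 0 marks
#'   leading-finger columns) and `helix_map` (tibble: offset,
#'   helix_position for the seven contact positions, from the modal His1
#'   anchor of the input units).
#' @export
build_codon_alignment <- function(arrays, include_first_finger = FALSE,
                                  strict_equal_length = FALSE) {
  stopifnot(length(arrays) >= 3L,
            all(vapply(arrays, inherits, logical(1), "zf_array")))
  ids <- vapply(arrays, function(a) a$record_id, character(1))
  stopifnot(!anyDuplicated(ids))
  n_units <- vapply(arrays, function(a) a$n_units, integer(1))
  if (strict_equal_length && length(unique(n_units)) > 1L) {
    stop("arrays differ in unit count (", paste(sort(unique(n_units)),
         collapse = ", "), ") under strict equal-length mode", call. = FALSE)
  }
  n_max <- max(n_units)
  lead_codons <- 0L
  if (include_first_finger) {
    if (any(vapply(arrays, function(a) !nzchar(a$leading_finger_nt), logical(1)))) {
      stop("include_first_finger = TRUE but some arrays lack a leading finger",
           call. = FALSE)
    }
    lead_codons <- nchar(arrays[[1]]$leading_finger_nt) %/% 3L
  }
  n_sites <- lead_codons + 28L * n_max
  codons <- matrix(NA_character_, length(arrays), n_sites,
                   dimnames = list(ids, NULL))
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    cds <- character(0)
    if (include_first_finger) cds <- split_codons(a$leading_finger_nt)
    cds <- c(cds, unlist(lapply(a$units$nt, split_codons), use.names = FALSE))
    codons[i, seq_along(cds)] <- cds
  }
  states <- matrix(codon_state(codons), nrow(codons), ncol(codons),
                   dimnames = dimnames(codons))
  stop_hit <- !is.na(codons) & is.na(states)
  if (any(stop_hit)) {
    bad <- ids[unique(which(stop_hit, arr.ind = TRUE)[, 1])]
    stop("stop codon observed in record(s): ", paste(bad, collapse = ", "),
         "; exclude pseudogenes before alignment", call. = FALSE)
  }
  site_map <- tibble::tibble(
    site = seq_len(n_sites),
    unit = c(rep(0L, lead_codons), rep(seq_len(n_max), each = 28L)),
    offset = c(seq_len(lead_codons), rep(1:28, n_max)))
  his1 <- unlist(lapply(arrays, function(a) a$units$his1), use.names = FALSE)
  his1 <- his1[!is.na(his1)]
  modal_his1 <- as.integer(names(sort(table(his1), decreasing = TRUE))[1])
  off <- helix_position_offsets(modal_his1)
  helix_map <- tibble::tibble(offset = unname(off),
                              helix_position = as.integer(names(off)))
  structure(list(taxa = ids, codons = codons, states = states,
                 site_map = site_map, helix_map = helix_map),
            class = "codon_alignment")
}

#' Construct a codon alignment directly from codon strings
#'
#' Lower-level constructor used by the simulator and by tests; `codons` is a
#' taxa x sites character matrix of 3-letter codons (NA = missing).
#'
#' @param codons Character matrix with rownames as taxa.
#' @param site_map Optional tibble (site, unit, offset); defaults to unit 1,
#'   offsets 1..n cycled by 28.
#' @return A `codon_alignment`.
#' @export
codon_alignment <- function(codons, site_map = NULL) {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  states <- matrix(codon_state(codons), nrow(codons), ncol(codons),
                   dimnames = dimnames(codons))
  if (any(!is.na(codons) & is.na(states))) {
    stop("stop codon or invalid codon among observed states", call. = FALSE)
  }
  n_sites <- ncol(codons)
  if (is.null(site_map)) {
    site_map <- tibble::tibble(site = seq_len(n_sites),
                               unit = ((seq_len(n_sites) - 1L) %/% 28L) + 1L,
                               offset = ((seq_len(n_sites) - 1L) %% 28L) + 1L)
  }
  structure(list(taxa = rownames(codons), codons = codons, states = states,
                 site_map = site_map,
                 helix_map = tibble::tibble(offset = integer(0),
                                            helix_position = integer(0))),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", ncol(x$codons),
      " codon sites (", sum(is.na(x$codons)), " missing cells)\n", sep = "")
  invisible(x)
}

#' Pairwise codon p-distances
#'
#' Fraction of differing codon sites among sites observed in both taxa.
#'
#' @param alignment A `codon_alignment`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
codon_p_distance <- function(alignment) {
  st <- alignment$states
  n <- nrow(st)
  d <- matrix(0, n, n, dimnames = list(rownames(st), rownames(st)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(st[i, ]) & !is.na(st[j, ])
      d[i, j] <- d[j, i] <- if (any(ok)) mean(st[i, ok] != st[j, ok]) else 0
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (ape backend) with deterministic input order
#' (taxa sorted lexicographically before agglomeration) and negative branch
#' lengths clipped to zero with a warning.
#'
#' @param distances Symmetric numeric matrix with zero diagonal and
#'   dimnames, or a `dist`.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(distances) {
  d <- as.matrix(distances)
  stopifnot(is.numeric(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("neighbor joining requires at least 3 taxa",
                         call. = FALSE)
  stopifnot(all(is.finite(d)), isTRUE(all.equal(d, t(d))),
            all(diag(d) == 0))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clipped to 0", call. = FALSE)
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr
}
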