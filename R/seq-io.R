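# Sequence I/O, translation, pairwise identity and paralog assignment.
# File formats go through Biostrings / ape; the thin wrappers here add the
# validation and the tabular surface the rest of the pipeline expects.

#' Read a nucleotide FASTA file into a tibble
#'
#' One row per record, in file order. Sequences are uppercased and
#' whitespace-stripped on read; only `A`, `C`, `G`, `T`, `N` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, possibly empty)
#'   and `seq` (uppercase nucleotide string).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop("non-nucleotide characters (other than N) in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence in record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = ids, description = desc, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 60 columns. `read_fasta(write_fasta(x, f))` round-trips
#' ids and sequences exactly.
#'
#' @param records Tibble with columns `id`, `seq` and optionally `description`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(setNames(records$seq, headers))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; stops rendered as `"*"`; any codon containing `N`
#' (or other ambiguity) as `"X"`. The trailing partial codon is dropped.
#'
#' @param seq Nucleotide string.
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return Amino-acid string of length `floor((nchar(seq) - frame) / 3)`.
#' @export
translate_dna <- function(seq, frame = 0L) {
  stopifnot(length(seq) == 1L, is.character(seq))
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  seq <- toupper(seq)
  n_codons <- (nchar(seq) - frame) %/% 3L
  if (n_codons < 1L) stop("sequence too short to translate in frame ", frame,
                          call. = FALSE)
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- genetic_code()[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# split a coding sequence into codon strings (trailing partial dropped)
split_codons <- function(seq, frame = 0L) {
  n_codons <- (nchar(seq) - frame) %/% 3L
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  substring(seq, starts, starts + 2L)
}

#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch global alignment with affine gap costs (Biostrings
#' backend). Percent identity is computed over aligned columns, counting a
#' gap-against-residue column as a mismatch (double-gap columns cannot occur
#' in a global pairwise alignment).
#'
#' @param a,b Nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; defaults
#'   +1/-1/-5/-1.
#' @return A list with `aligned_a`, `aligned_b`, `score` and
#'   `percent_identity` (a fraction in \[0, 1\]).
#' @export
align_global <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 5, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  keep <- !(ca == "-" & cb == "-")
  pid <- mean(ca[keep] == cb[keep] & ca[keep] != "-")
  list(aligned_a = pa, aligned_b = pb,
       score = Biostrings::score(aln), percent_identity = pid)
}

#' Assign a query sequence to the closest labelled reference
#'
#' Mirrors the classic "best BLAT/BLAST hit" paralog call with a local
#' global-alignment classifier: the query is aligned to every reference and
#' assigned the label of the reference with the highest percent identity
#' (ties broken by reference input order).
#'
#' @param query A single-row tibble (or list) with `id` and `seq`.
#' @param refs Tibble with columns `label` and `seq`, one row per reference
#'   exemplar (e.g. PRDM9 and PRDM7 ZF-exon references).
#' @param ... Scoring parameters passed to [align_global()].
#' @return A list with `label`, `percent_identity`, and `table`: a tibble
#'   (query, ref, identity, score) of the full identity table, in reference
#'   order.
#' @export
classify_paralog <- function(query, refs, ...) {
  if (is.null(refs) || nrow(refs) == 0L) {
    stop("at least one labelled reference is required", call. = FALSE)
  }
  stopifnot(nzchar(query$seq))
  hits <- purrr::pmap(refs, function(label, seq, ...) {
    aln <- align_global(query$seq, seq, ...)
    tibble::tibble(query = query$id %||% "query", ref = label,
                   identity = aln$percent_identity, score = aln$score)
  })
  tab <- dplyr::bind_rows(hits)
  best <- which.max(tab$identity)  # which.max takes the first on ties
  list(label = tab$ref[best], percent_identity = tab$identity[best],
       table = tab)
}

#' Parse / write Newick trees
#'
#' Thin validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. Missing branch lengths are set to 0 so downstream
#' likelihood code always sees a length on every edge.
#'
#' @param text A Newick string (terminated by `;`).
#' @return An `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    stop("unbalanced parentheses at character ",
         which(depth < 0)[1], call. = FALSE)
  }
  if (depth[length(depth)] != 0 || !grepl(";\\s*$", text)) {
    stop("malformed Newick: unbalanced parentheses or missing ';' at character ",
         nchar(text), call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("could not parse Newick string", call. = FALSE)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) {
    warning("negative branch lengths clipped to 0")
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr
}

#' @rdname parse_newick
#' @param tree An `ape::phylo` tree.
#' @return For `write_newick`, a Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}
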