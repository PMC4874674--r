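# Detection of pseudogenising lesions in ZF-region paralogs: premature
# stop codons and frameshifts relative to a consensus repeat unit.

#' Scan a reading frame for premature stop codons
#'
#' With `frame = "auto"` the frame minimising the stop count is chosen
#' (ties broken by the larger strict C2H2 motif count, then by the lower
#' frame index). A record is classified `disrupted` when any stop occurs
#' before the final two codons (stops in the last two codons are treated as
#' natural terminators). All positions are 1-based codon indices;
#' `residues_before_first_stop` counts amino acids strictly preceding the
#' first stop, and equals the full translated length when no stop exists.
#'
#' @param seq Nucleotide string, length >= 3.
#' @param frame 0, 1, 2 or `"auto"`.
#' @param record_id Label carried into the report.
#' @return A `disruption_report`: list with `record_id`, `frame`,
#'   `stop_codon_indices`, `n_stops`, `first_stop_codon`,
#'   `residues_before_first_stop`, `n_codons`, `frameshift_flags` (empty
#'   tibble; filled by [detect_frameshift()]), `classification`
#'   (`"functional"` or `"disrupted"`) and `low_confidence`.
#' @export
scan_orf <- function(seq, frame = "auto", record_id = "seq") {
  seq <- toupper(gsub("\\s", "", seq))
  stopifnot(nchar(seq) >= 3L)
  frames <- 0:2
  frames <- frames[(nchar(seq) - frames) %/% 3L >= 1L]
  aa_all <- lapply(frames, function(f) translate_dna(seq, f))
  stops_all <- lapply(aa_all, function(a) {
    which(strsplit(a, "")[[1]] == "*")
  })
  n_stop <- lengths(stops_all)
  if (identical(frame, "auto")) {
    cand <- which(n_stop == min(n_stop))
    if (length(cand) > 1L) {
      motifs <- vapply(aa_all[cand],
                       function(a) length(motif_starts(a, C2H2_STRICT)),
                       integer(1))
      cand <- cand[motifs == max(motifs)]
    }
    pick <- cand[1]
  } else {
    stopifnot(frame %in% 0:2)
    pick <- match(frame, frames)
  }
  f <- frames[pick]
  aa <- aa_all[[pick]]
  stops <- stops_all[[pick]]
  n_codons <- nchar(aa)
  premature <- stops[stops <= n_codons - 2L]
  first <- if (length(stops)) min(stops) else NA_integer_
  low_conf <- all(n_stop * 10L > vapply(aa_all, nchar, integer(1)))
  rep <- structure(list(
    record_id = record_id, frame = f,
    stop_codon_indices = stops, n_stops = length(stops),
    first_stop_codon = first,
    residues_before_first_stop = if (is.na(first)) n_codons else first - 1L,
    n_codons = n_codons,
    frameshift_flags = tibble::tibble(position = integer(0), offset = integer(0)),
    classification = if (length(premature)) "disrupted" else "functional",
    low_confidence = low_conf), class = "disruption_report")
  if (low_conf) {
    warning("low confidence: every frame of ", record_id,
            " carries more than 1 stop per 10 codons", call. = FALSE)
  }
  rep
}

#' @export
print.disruption_report <- function(x, ...) {
  cat("<disruption_report> ", x$record_id, ": ", x$classification,
      " (frame ", x$frame, ")\n", sep = "")
  cat("  ", x$n_stops, " stop(s); first at codon ",
      if (is.na(x$first_stop_codon)) "-" else x$first_stop_codon,
      "; residues before first stop: ", x$residues_before_first_stop,
      " of ", x$n_codons, " (1-based codon indices)\n", sep = "")
  if (nrow(x$frameshift_flags)) {
    cat("  frameshifts:", nrow(x$frameshift_flags), "\n")
  }
  invisible(x)
}

#' Detect frameshift-length indels against a consensus repeat unit
#'
#' Aligns the query against tandem copies of the 84-nt consensus unit and
#' flags every indel whose length is not a multiple of 3 (in-frame indels
#' are silent). Offsets are signed: insertions in the query are positive,
#' deletions negative; positions are 1-based query nucleotide coordinates.
#'
#' @param seq Query nucleotide string.
#' @param consensus_unit 84-nt consensus repeat unit.
#' @return Tibble (position, offset) of frameshift flags; zero rows when the
#'   query is in frame throughout. Returns `NULL` with a warning (no-call)
#'   when alignment identity falls below 50%.
#' @export
detect_frameshift <- function(seq, consensus_unit) {
  seq <- toupper(seq)
  consensus_unit <- toupper(consensus_unit)
  stopifnot(nchar(consensus_unit) == 84L)
  n_copies <- ceiling(nchar(seq) / 84) + 1L
  ref <- strrep(consensus_unit, n_copies)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq), Biostrings::DNAString(ref),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- mean(pa == pb & pa != "-")
  if (ident < 0.5) {
    warning("no-call: alignment identity ", round(100 * ident, 1),
            "% below 50%", call. = FALSE)
    return(NULL)
  }
  # walk the alignment, merging runs of gap columns into single indel events
  qpos <- cumsum(pa != "-")
  gap_in_query <- pa == "-"   # deletion relative to consensus
  gap_in_ref <- pb == "-"     # insertion in the query
  events <- tibble::tibble(position = integer(0), offset = integer(0))
  for (g in list(list(mask = gap_in_query, sign = -1L),
                 list(mask = gap_in_ref, sign = +1L))) {
    if (!any(g$mask)) next
    r <- rle(g$mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    events <- dplyr::bind_rows(events, tibble::tibble(
      position = pmax(1L, qpos[starts[runs]]),
      offset = g$sign * r$lengths[runs]))
  }
  events |>
    dplyr::filter(.data$offset %% 3L != 0L) |>
    dplyr::arrange(.data$position)
}
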