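# Segmentation of ZF-domain amplicons into a conserved leading finger plus
# tandem 84-nt C2H2 units, and extraction of the DNA-contact residues.

# C2H2 motif: C-x2-C-x12-H-x(3..5)-H. The relaxed form (C-x(2..4)-C) admits
# the wider Cys spacing seen in some canonical fingers (e.g. Zif268 finger 1)
# and is used for anchor detection outside the strict tandem block.
C2H2_STRICT <- "C.{2}C.{12}H.{3,5}H"
C2H2_RELAXED <- "C.{2,4}C.{12}H.{3,5}H"

#' Segmentation parameters for ZF arrays
#'
#' @param unit_aa Repeat-unit length in amino acids (28 for the 84-bp
#'   PRDM9-type minisatellite unit).
#' @param leading_aa Length of the conserved leading finger (23 aa).
#' @param cys1_offset Preferred 1-based position of Cys1 inside the 28-aa
#'   unit window (unit phase); shifted automatically when the amplicon
#'   boundaries would otherwise truncate a unit.
#' @return A list of class `zf_config`.
#' @export
zf_config <- function(unit_aa = 28L, leading_aa = 23L, cys1_offset = 2L) {
  structure(list(unit_aa = as.integer(unit_aa),
                 leading_aa = as.integer(leading_aa),
                 cys1_offset = as.integer(cys1_offset)),
            class = "zf_config")
}

motif_starts <- function(aa, motif) {
  m <- gregexpr(motif, aa, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# C2H2 anchor positions (Cys1, Cys2, His1, His2) within an amino-acid
# window: first position admitting C-x{2}(-x{2..4} if relaxed)-C-x12-H-x(3..5)-H.
# `at` restricts the search to a fixed Cys1 position. Returns NULL if absent.
find_c2h2_anchors <- function(aa, relaxed = FALSE, at = NULL) {
  n <- nchar(aa)
  ch <- strsplit(aa, "")[[1]]
  spacings <- if (relaxed) 2:4 else 2L
  starts <- if (is.null(at)) seq_len(n) else at
  for (c1 in starts) {
    if (c1 > n || ch[c1] != "C") next
    for (sp in spacings) {
      c2 <- c1 + sp + 1L
      h1 <- c2 + 13L
      if (h1 + 4L > n) next
      if (ch[c2] != "C" || ch[h1] != "H") next
      h2s <- h1 + 4:6
      h2s <- h2s[h2s <= n]
      hit <- h2s[ch[h2s] == "H"]
      if (length(hit)) {
        return(list(cys1 = c1, cys2 = c2, his1 = h1, his2 = hit[1]))
      }
    }
  }
  NULL
}

#' DNA-contact residues of a zinc-finger unit
#'
#' Returns the residues at helix positions -9, -5, -2, -1, 2, 3 and 6
#' (numbering relative to the recognition-helix start; there is no
#' position 0). With `H1` the 1-based index of the first zinc-coordinating
#' histidine, position `k >= 1` maps to `aa[H1 - (7 - k)]` and `k <= -1`
#' to `aa[H1 - (6 - k)]`.
#'
#' @param unit A one-row unit (list or data-frame row) with fields `aa` and
#'   `his1`, as produced by [segment_array()]; alternatively any object with
#'   those two fields.
#' @return Named character vector over positions `-9,-5,-2,-1,2,3,6`.
#' @export
contact_residues <- function(unit) {
  aa <- unit$aa
  his1 <- unit$his1
  stopifnot(is.character(aa), length(his1) == 1L, !is.na(his1))
  idx <- helix_position_offsets(his1)
  if (any(idx < 1L | idx > nchar(aa))) {
    stop("malformed unit: contact index outside [1, ", nchar(aa), "]",
         call. = FALSE)
  }
  setNames(substring(aa, idx, idx), names(idx))
}

# 1-based aa indices of the seven contact positions given the His1 index
helix_position_offsets <- function(his1) {
  ks <- c(-9L, -5L, -2L, -1L, 2L, 3L, 6L)
  idx <- ifelse(ks >= 1L, his1 - (7L - ks), his1 - (6L - ks))
  setNames(as.integer(idx), as.character(ks))
}

#' Decompose a ZF-domain amplicon into leading finger + tandem units
#'
#' Chooses the reading frame maximising the number of non-overlapping strict
#' C2H2 motifs, takes the maximal run of motif hits spaced exactly 28 aa
#' apart as the tandem block, assigns the first motif-bearing 23-aa window
#' before the block as the conserved leading finger, and returns everything
#' else as flanks. Re-concatenating all segments reproduces the input
#' byte-for-byte.
#'
#' @param seq Nucleotide string (an amplicon spanning the ZF minisatellite).
#' @param record_id,species Provenance labels stored on the result.
#' @param config A [zf_config()].
#' @return A `zf_array` object: list with `record_id`, `species`, `frame`,
#'   `upstream_flank`, `leading_finger_nt`, `leading_finger_aa`, `spacer`,
#'   `units` (tibble: `index`, `nt`, `aa`, anchor columns, `contacts`
#'   list-column), `downstream_flank`, `n_units`, `allele`, `partial`.
#' @export
segment_array <- function(seq, record_id = "seq", species = NA_character_,
                          config = zf_config()) {
  seq <- toupper(gsub("\\s", "", seq))
  stopifnot(nchar(seq) >= 3L)
  ua <- config$unit_aa

  aa_by_frame <- lapply(0:2, function(f) {
    if ((nchar(seq) - f) %/% 3L < 1L) return("")
    translate_dna(seq, f)
  })
  n_hits <- vapply(aa_by_frame, function(a) length(motif_starts(a, C2H2_STRICT)),
                   integer(1))
  if (all(n_hits == 0L)) {
    stop("not a ZF array: no C2H2 motif found in any reading frame for ",
         record_id, call. = FALSE)
  }
  frame <- which.max(n_hits) - 1L
  aa <- aa_by_frame[[frame + 1L]]
  starts <- motif_starts(aa, C2H2_STRICT)

  # maximal arithmetic chain of starts spaced exactly unit_aa apart = the
  # tandem block (robust to incidental motif hits at other phases)
  chain_len <- function(s) {
    n <- 0L
    while ((s + ua * n) %in% starts) n <- n + 1L
    n
  }
  heads <- starts[!(starts - ua) %in% starts]
  lens <- vapply(heads, chain_len, integer(1))
  s1 <- heads[which.max(lens)]
  n_units <- max(lens)
  block <- s1 + ua * (seq_len(n_units) - 1L)

  # phase: Cys1 offset inside the 28-aa window, shifted only if the amplicon
  # would truncate the first or last unit
  L <- nchar(aa)
  off_lo <- max(1L, s1 + ua * n_units - L)
  off_hi <- min(config$cys1_offset, s1)
  if (off_lo > off_hi) {
    stop("tandem block does not fit inside the translated sequence for ",
         record_id, call. = FALSE)
  }
  off <- min(max(config$cys1_offset, off_lo), off_hi)
  w1 <- s1 - off + 1L

  # interrupted tandem block: another in-phase strict motif outside the run
  partial <- any(((starts - s1) %% ua == 0L) & !(starts %in% block))

  # leading finger: first relaxed-motif window fully before the tandem block
  lead_start <- NA_integer_
  pre <- substring(aa, 1L, w1 - 1L)
  if (nzchar(pre)) {
    cand <- motif_starts(pre, C2H2_RELAXED)
    cand <- cand[cand + config$leading_aa - 1L <= w1 - 1L]
    cand <- cand[!(cand %in% block)]
    if (length(cand)) lead_start <- cand[1]
  }

  nt_of <- function(p) frame + 3L * (p - 1L) + 1L  # nt start of aa position p
  unit_aa_starts <- w1 + ua * (seq_len(n_units) - 1L)
  unit_nt_starts <- nt_of(unit_aa_starts)

  units <- purrr::map_dfr(seq_len(n_units), function(m) {
    a_start <- unit_aa_starts[m]
    u_aa <- substring(aa, a_start, a_start + ua - 1L)
    u_nt <- substring(seq, unit_nt_starts[m], unit_nt_starts[m] + 3L * ua - 1L)
    anch <- find_c2h2_anchors(u_aa, at = off)
    ok <- !is.null(anch)
    if (!ok) anch <- list(cys1 = NA_integer_, cys2 = NA_integer_,
                          his1 = NA_integer_, his2 = NA_integer_)
    tibble::tibble(index = m, nt = u_nt, aa = u_aa,
                   cys1 = anch$cys1, cys2 = anch$cys2,
                   his1 = anch$his1, his2 = anch$his2,
                   motif_ok = ok)
  })
  if (any(!units$motif_ok)) partial <- TRUE
  units$contacts <- purrr::map(seq_len(n_units), function(m) {
    if (!units$motif_ok[m]) return(setNames(rep(NA_character_, 7L),
                                            c("-9", "-5", "-2", "-1", "2", "3", "6")))
    contact_residues(units[m, ])
  })

  if (!is.na(lead_start)) {
    lead_nt_start <- nt_of(lead_start)
    lead_nt <- substring(seq, lead_nt_start, lead_nt_start + 3L * config$leading_aa - 1L)
    lead_aa <- substring(aa, lead_start, lead_start + config$leading_aa - 1L)
    upstream <- substring(seq, 1L, lead_nt_start - 1L)
    spacer <- substring(seq, lead_nt_start + 3L * config$leading_aa,
                        unit_nt_starts[1] - 1L)
  } else {
    lead_nt <- ""
    lead_aa <- ""
    upstream <- substring(seq, 1L, unit_nt_starts[1] - 1L)
    spacer <- ""
  }
  downstream <- substring(seq, unit_nt_starts[n_units] + 3L * ua)

  out <- structure(list(
    record_id = record_id, species = species, frame = frame,
    upstream_flank = upstream,
    leading_finger_nt = lead_nt, leading_finger_aa = lead_aa,
    spacer = spacer, units = units, downstream_flank = downstream,
    n_units = n_units, allele = assign_allele_label(n_units, warn = FALSE),
    partial = partial), class = "zf_array")
  if (partial) {
    warning("partial decomposition for ", record_id,
            ": tandem block interrupted by a motif failure", call. = FALSE)
  }
  stopifnot(identical(reconstruct_array(out), seq))
  out
}

#' Re-concatenate the segments of a decomposed array
#'
#' @param x A `zf_array`.
#' @return The original nucleotide string, byte-for-byte.
#' @export
reconstruct_array <- function(x) {
  stopifnot(inherits(x, "zf_array"))
  paste0(x$upstream_flank, x$leading_finger_nt, x$spacer,
         paste0(x$units$nt, collapse = ""), x$downstream_flank)
}

#' @export
print.zf_array <- function(x, ...) {
  cat("<zf_array> ", x$record_id,
      if (!is.na(x$species)) paste0(" [", x$species, "]"), "\n", sep = "")
  cat("  frame ", x$frame, "; ", x$n_units, " tandem units (allele ",
      x$allele, ")", if (x$partial) "; PARTIAL", "\n", sep = "")
  cat("  leading finger: ",
      if (nzchar(x$leading_finger_aa)) x$leading_finger_aa else "<none>",
      "\n", sep = "")
  invisible(x)
}

#' Allele letter for a repeat count
#'
#' Length variants with 6-12 tandem fingers are labelled A-G (6 -> A, ...,
#' 12 -> G). Counts outside that catalogue get extension labels (5 -> "A-",
#' 13 -> "H") with a warning.
#'
#' @param n_fingers Integer vector of tandem-unit counts.
#' @param warn Emit a warning for out-of-catalogue counts.
#' @return Character vector of allele letters.
#' @export
assign_allele_label <- function(n_fingers, warn = TRUE) {
  n_fingers <- as.integer(n_fingers)
  out <- character(length(n_fingers))
  in_cat <- n_fingers >= 6L & n_fingers <= 12L
  out[in_cat] <- LETTERS[n_fingers[in_cat] - 5L]
  hi <- !in_cat & n_fingers > 12L
  out[hi] <- LETTERS[pmin(n_fingers[hi] - 5L, 26L)]
  lo <- !in_cat & n_fingers <= 5L
  out[lo] <- paste0("A", strrep("-", 6L - n_fingers[lo]))
  if (warn && any(!in_cat)) {
    warning("repeat count(s) outside the A-G catalogue (6-12 fingers): ",
            paste(n_fingers[!in_cat], collapse = ", "), call. = FALSE)
  }
  out
}

#' Infer an allele letter from an amplicon length
#'
#' Repeat-count alleles differ by whole 84-bp units, so amplicon lengths
#' form an arithmetic series with step 84. Given one calibration point
#' (a known allele's repeat count and amplicon length), the query length is
#' converted to a repeat count by rounding the length difference to the
#' nearest whole unit.
#'
#' @param length_bp Observed amplicon length(s) in bp.
#' @param known_n Repeat count of the calibration allele.
#' @param known_length Amplicon length of the calibration allele in bp.
#' @return Tibble with `length_bp`, `n_fingers`, `allele`, `residual`
#'   (bp left over after the whole-unit fit) and `ambiguous`
#'   (`TRUE` when `|residual| > 10`).
#' @export
infer_allele_from_amplicon_length <- function(length_bp, known_n, known_length) {
  n <- known_n + as.integer(round((length_bp - known_length) / 84))
  residual <- length_bp - (known_length + (n - known_n) * 84L)
  amb <- abs(residual) > 10L
  if (any(amb)) {
    warning("ambiguous genotype: residual exceeds 10 bp for length(s) ",
            paste(length_bp[amb], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(length_bp = length_bp, n_fingers = n,
                 allele = assign_allele_label(n, warn = FALSE),
                 residual = residual, ambiguous = amb)
}
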