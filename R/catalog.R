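# Deduplicated domain catalogue, allele schematics, cross-species sharing,
# positional diversity and genotype summaries.

#' Build a deduplicated ZF-domain catalogue
#'
#' Collapses the tandem units of a set of decomposed arrays onto distinct
#' domain sequences and assigns integer codes 1..K in order of first
#' appearance. Leading fingers are excluded. Identity is exact amino-acid
#' identity of the 28-aa unit by default (synonymous nucleotide changes
#' collapse); `level = "nt"` switches to nucleotide-level identity for
#' DNA-allele style analyses.
#'
#' @param arrays List of `zf_array` objects.
#' @param level `"aa"` (default) or `"nt"`.
#' @param sort_input Sort arrays by (species, record_id) before coding, so
#'   codes do not depend on list order. Set `FALSE` to keep input order.
#' @return A `domain_catalog`: list with tibbles `entries` (code, aa, nt of
#'   first occurrence, n_total), `occurrence` (code, species, n) and
#'   `provenance` (record_id, species, unit_index, code).
#' @export
build_catalog <- function(arrays, level = c("aa", "nt"), sort_input = TRUE) {
  level <- match.arg(level)
  stopifnot(length(arrays) >= 1L,
            all(vapply(arrays, inherits, logical(1), "zf_array")))
  if (sort_input) {
    ord <- order(vapply(arrays, function(a) a$species %||% NA_character_, character(1)),
                 vapply(arrays, function(a) a$record_id, character(1)))
    arrays <- arrays[ord]
  }
  units <- purrr::map_dfr(arrays, function(a) {
    bad <- nchar(a$units$nt) != 84L | nchar(a$units$aa) != 28L
    if (any(bad)) {
      stop("unit(s) of wrong length in ", a$record_id, " at index ",
           paste(a$units$index[bad], collapse = ", "), call. = FALSE)
    }
    tibble::tibble(record_id = a$record_id, species = a$species,
                   unit_index = a$units$index, aa = a$units$aa, nt = a$units$nt)
  })
  key <- if (level == "aa") units$aa else units$nt
  units$code <- match(key, unique(key))
  entries <- units |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(aa = dplyr::first(.data$aa), nt = dplyr::first(.data$nt),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$code)
  occurrence <- units |>
    dplyr::count(.data$code, .data$species, name = "n") |>
    dplyr::arrange(.data$code, .data$species)
  provenance <- units |>
    dplyr::select("record_id", "species", "unit_index", "code")
  structure(list(entries = entries, occurrence = occurrence,
                 provenance = provenance, level = level),
            class = "domain_catalog")
}

#' @export
print.domain_catalog <- function(x, ...) {
  cat("<domain_catalog> ", nrow(x$entries), " distinct domains (",
      x$level, "-level identity) over ",
      length(unique(x$provenance$record_id)), " arrays, ",
      sum(x$entries$n_total), " units\n", sep = "")
  print(head(x$entries, 10))
  invisible(x)
}

#' Coded schematic of one array
#'
#' @param array A `zf_array`.
#' @param catalog A `domain_catalog` containing every unit of `array`.
#' @return List with `codes` (integer vector, one per tandem unit, in array
#'   order) and `repeated` (named integer vector: multiplicities >= 2).
#' @export
array_schematic <- function(array, catalog) {
  stopifnot(inherits(array, "zf_array"), inherits(catalog, "domain_catalog"))
  key <- if (catalog$level == "aa") array$units$aa else array$units$nt
  ref <- if (catalog$level == "aa") catalog$entries$aa else catalog$entries$nt
  codes <- catalog$entries$code[match(key, ref)]
  if (anyNA(codes)) {
    stop("unit(s) of ", array$record_id, " absent from catalogue: index ",
         paste(array$units$index[is.na(codes)], collapse = ", "), call. = FALSE)
  }
  tab <- table(codes)
  repeated <- tab[tab >= 2L]
  list(codes = as.integer(codes),
       repeated = setNames(as.integer(repeated), names(repeated)))
}

#' Cross-species sharing, per-species unique domains, positional diversity
#'
#' @param catalog A `domain_catalog` with at least two species.
#' @return List of tibbles: `shared` (code, n_species, species — domains seen
#'   in two or more species), `unique_counts` (species, n_unique — domains
#'   private to one species), and `diversity` (position, n_residues,
#'   residues) giving the number of distinct amino acids at each of the
#'   seven DNA-contact helix positions across catalogue entries.
#' @export
cross_species_stats <- function(catalog) {
  stopifnot(inherits(catalog, "domain_catalog"))
  occ <- catalog$occurrence
  if (length(unique(occ$species)) < 2L) {
    stop("at least two species are required", call. = FALSE)
  }
  by_code <- occ |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                     species = paste(sort(unique(.data$species)), collapse = ","),
                     .groups = "drop")
  shared <- dplyr::filter(by_code, .data$n_species >= 2L)
  unique_counts <- by_code |>
    dplyr::filter(.data$n_species == 1L) |>
    dplyr::count(.data$species, name = "n_unique")
  contacts <- purrr::map_dfr(seq_len(nrow(catalog$entries)), function(i) {
    anch <- find_c2h2_anchors(catalog$entries$aa[i])
    if (is.null(anch)) return(NULL)
    cr <- contact_residues(list(aa = catalog$entries$aa[i], his1 = anch$his1))
    tibble::tibble(code = catalog$entries$code[i],
                   position = names(cr), residue = unname(cr))
  })
  diversity <- contacts |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(n_residues = dplyr::n_distinct(.data$residue),
                     residues = paste(sort(unique(.data$residue)), collapse = ","),
                     .groups = "drop") |>
    dplyr::mutate(position = as.integer(.data$position)) |>
    dplyr::arrange(.data$position)
  list(shared = shared, unique_counts = unique_counts, diversity = diversity)
}

#' Per-species genotype counts and heterozygosity
#'
#' @param records Tibble of per-animal genotypes with columns `animal_id`,
#'   `species`, `allele1`, `allele2` (allele letters).
#' @return List with `counts`: tibble (species, genotype, n) where genotype
#'   is the alphabetically sorted letter pair, and `heterozygosity`: tibble
#'   (species, n_animals, n_het, het_fraction, het_percent). Rows whose
#'   letters fall outside A-G are counted under `flagged`.
#' @export
genotype_summary <- function(records) {
  stopifnot(nrow(records) >= 1L,
            all(c("animal_id", "species", "allele1", "allele2") %in% names(records)))
  known <- LETTERS[1:7]
  rec <- records |>
    dplyr::mutate(
      g1 = pmin(.data$allele1, .data$allele2),
      g2 = pmax(.data$allele1, .data$allele2),
      genotype = paste0(.data$g1, .data$g2),
      flagged = !(.data$allele1 %in% known) | !(.data$allele2 %in% known),
      het = .data$allele1 != .data$allele2)
  counts <- rec |>
    dplyr::count(.data$species, .data$genotype, .data$flagged, name = "n") |>
    dplyr::arrange(.data$species, .data$genotype)
  heterozygosity <- rec |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_animals = dplyr::n(), n_het = sum(.data$het),
                     .groups = "drop") |>
    dplyr::mutate(het_fraction = .data$n_het / .data$n_animals,
                  het_percent = 100 * .data$het_fraction)
  list(counts = counts, heterozygosity = heterozygosity)
}

#' Expand a genotype count table into per-animal records
#'
#' Convenience for panel tables laid out as one row per species and one
#' column per genotype class (e.g. `AA`, `AB`, ...), as length-variant
#' screens are usually reported.
#'
#' @param tbl Either a tidy table with columns `species`, `genotype`, `n`,
#'   or a wide table with a `species` column and one count column per
#'   genotype class (two allele letters; NA = 0).
#' @return Tibble of per-animal records suitable for [genotype_summary()].
#' @export
genotype_records_from_counts <- function(tbl) {
  stopifnot("species" %in% names(tbl))
  if (all(c("genotype", "n") %in% names(tbl))) {
    long <- dplyr::filter(tbl, !is.na(.data$n) & .data$n > 0L)
  } else {
    classes <- setdiff(names(tbl), c("species", "n_animals"))
    long <- tbl |>
      tidyr::pivot_longer(dplyr::all_of(classes), names_to = "genotype",
                          values_to = "n") |>
      dplyr::filter(!is.na(.data$n) & .data$n > 0L)
  }
  purrr::pmap_dfr(long, function(species, genotype, n, ...) {
    tibble::tibble(
      animal_id = paste0(gsub("\\s", "_", species), "_", genotype, "_", seq_len(n)),
      species = species,
      allele1 = substring(genotype, 1L, 1L),
      allele2 = substring(genotype, 2L, 2L))
  })
}
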