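# End-to-end orchestration: paralog routing -> decomposition -> catalogue ->
# pseudogene scan -> per-species and pooled selection analyses -> report
# bundle with a reproducibility manifest.

#' Pipeline configuration
#'
#' @param input Path(s) to FASTA files, or a records tibble (id,
#'   description, seq) as returned by [read_fasta()] /
#'   [simulate_population()].
#' @param species_map Named character vector of regular expressions: the
#'   first pattern matching a record id assigns its species (names are the
#'   species). Every record must resolve.
#' @param refs Optional tibble (label, seq) of paralog exemplar references;
#'   records whose best hit is labelled `"PRDM7"` (or any label in
#'   `pseudogene_labels`) are routed to the disruption scan only.
#' @param pseudogene_labels Reference labels treated as pseudogene copies.
#' @param tree Optional `ape::phylo` or Newick file path; otherwise NJ +
#'   M0 branch lengths per analysis group.
#' @param models Site models to fit per group.
#' @param thresholds Significance thresholds, listed descending.
#' @param out_dir Output directory for the report bundle (NULL = in-memory
#'   only).
#' @param seed Integer seed (selection stage is deterministic given inputs;
#'   recorded in the manifest).
#' @param strict_equal_length,include_first_finger Passed to
#'   [build_codon_alignment()].
#' @param min_haplotypes Minimum distinct haplotypes for a selection run
#'   (groups below it are reported as insufficient data).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, species_map, refs = NULL,
                            pseudogene_labels = "PRDM7", tree = NULL,
                            models = c("M1a", "M2a", "M7", "M8"),
                            thresholds = c(0.05, 0.01), out_dir = NULL,
                            seed = 1L, strict_equal_length = FALSE,
                            include_first_finger = FALSE,
                            min_haplotypes = 3L) {
  stopifnot(all(thresholds > 0 & thresholds < 1),
            !is.unsorted(rev(thresholds)))
  if (is.character(tree)) tree <- parse_newick(paste(readLines(tree), collapse = ""))
  structure(list(input = input, species_map = species_map, refs = refs,
                 pseudogene_labels = pseudogene_labels, tree = tree,
                 models = models, thresholds = thresholds, out_dir = out_dir,
                 seed = as.integer(seed),
                 strict_equal_length = strict_equal_length,
                 include_first_finger = include_first_finger,
                 min_haplotypes = as.integer(min_haplotypes)),
            class = "pipeline_config")
}

resolve_species <- function(ids, species_map) {
  sp <- rep(NA_character_, length(ids))
  for (nm in names(species_map)) {
    hit <- is.na(sp) & grepl(species_map[[nm]], ids)
    sp[hit] <- nm
  }
  if (anyNA(sp)) {
    stop("unresolvable species for record(s): ",
         paste(ids[is.na(sp)], collapse = ", "), call. = FALSE)
  }
  sp
}

#' Run the full ZF-array analysis pipeline
#'
#' Stage order: paralog assignment (when references are given) ->
#' pseudogene-labelled records to the disruption scan only -> remaining
#' records decomposed -> domain catalogue, schematics, cross-species stats
#' and genotype summary -> selection analyses for each species separately
#' and all species pooled (distinct haplotypes as taxa). A failing record
#' halts its own downstream stages, not the others'.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `records`
#'   (per-record status tibble), `paralog` (identity table), `arrays`,
#'   `catalog`, `schematics`, `cross_species`, `genotypes`, `disruptions`,
#'   `selection` (per-group fits, LRT table, BEB), `lrt_table`, and
#'   `manifest`. When `out_dir` is set, TSV/JSON reports are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- if (is.character(config$input)) {
    dplyr::bind_rows(lapply(config$input, read_fasta))
  } else {
    tibble::as_tibble(config$input)
  }
  if (nrow(records) == 0L) stop("empty input: no records", call. = FALSE)
  records$species <- resolve_species(records$id, config$species_map)
  status <- tibble::tibble(id = records$id, species = records$species,
                           route = "target", stage = "input",
                           note = "")

  # paralog assignment
  paralog_tab <- NULL
  if (!is.null(config$refs)) {
    calls <- purrr::map(seq_len(nrow(records)), function(i) {
      classify_paralog(records[i, ], config$refs)
    })
    paralog_tab <- dplyr::bind_rows(purrr::map(calls, "table"))
    labels <- vapply(calls, `[[`, character(1), "label")
    status$route <- ifelse(labels %in% config$pseudogene_labels,
                           "pseudogene_scan", "target")
  }

  # decomposition
  arrays <- list()
  for (i in seq_len(nrow(records))) {
    if (status$route[i] != "target") next
    arr <- tryCatch(
      suppressWarnings(segment_array(records$seq[i], records$id[i],
                                     records$species[i])),
      error = function(e) conditionMessage(e))
    if (is.character(arr)) {
      status$stage[i] <- "decompose_failed"
      status$note[i] <- arr
    } else {
      status$stage[i] <- "decomposed"
      arrays[[records$id[i]]] <- arr
    }
  }

  catalog <- NULL; schematics <- NULL; cross <- NULL; genotypes <- NULL
  if (length(arrays)) {
    catalog <- build_catalog(arrays)
    schematics <- purrr::map_dfr(arrays, function(a) {
      sch <- array_schematic(a, catalog)
      tibble::tibble(record_id = a$record_id, species = a$species,
                     n_units = a$n_units, allele = a$allele,
                     codes = paste(sch$codes, collapse = "-"),
                     repeated = paste(names(sch$repeated), collapse = ","))
    })
    if (length(unique(catalog$occurrence$species)) >= 2L) {
      cross <- cross_species_stats(catalog)
    }
    # genotypes from paired haplotype records (<animal>_h1 / _h2)
    hap <- grepl("_h[12]$", names(arrays))
    if (any(hap)) {
      gt <- purrr::map_dfr(arrays[hap], function(a) {
        tibble::tibble(animal_id = sub("_h[12]$", "", a$record_id),
                       species = a$species, allele = a$allele)
      }) |>
        dplyr::group_by(.data$animal_id, .data$species) |>
        dplyr::summarise(allele1 = min(.data$allele),
                         allele2 = max(.data$allele),
                         n = dplyr::n(), .groups = "drop")
      gt <- dplyr::filter(gt, .data$n == 2L)
      if (nrow(gt)) {
        genotypes <- genotype_summary(dplyr::select(gt, -"n"))
      }
    }
  }

  # pseudogene scan
  disruptions <- NULL
  scan_idx <- which(status$route == "pseudogene_scan")
  if (length(scan_idx)) {
    consensus <- if (!is.null(catalog)) {
      catalog$entries$nt[which.max(catalog$entries$n_total)]
    } else NULL
    disruptions <- purrr::map_dfr(scan_idx, function(i) {
      rep <- suppressWarnings(scan_orf(records$seq[i], record_id = records$id[i]))
      fs <- if (!is.null(consensus)) {
        suppressWarnings(detect_frameshift(records$seq[i], consensus))
      } else NULL
      n_fs <- if (is.null(fs)) NA_integer_ else nrow(fs)
      tibble::tibble(
        record_id = rep$record_id, species = records$species[i],
        frame = rep$frame, n_stops = rep$n_stops,
        first_stop_codon = rep$first_stop_codon,
        residues_before_first_stop = rep$residues_before_first_stop,
        n_frameshifts = n_fs,
        classification = if (isTRUE(n_fs > 0L)) "disrupted" else rep$classification)
    })
    status$stage[scan_idx] <- "scanned"
  }

  # selection: each species separately, then all pooled
  selection <- list()
  lrt_rows <- list()
  if (length(arrays)) {
    groups <- split(arrays, vapply(arrays, function(a) a$species, character(1)))
    groups[["all"]] <- arrays
    for (g in names(groups)) {
      arrs <- groups[[g]]
      # distinct haplotypes as taxa
      key <- vapply(arrs, function(a) paste0(a$units$nt, collapse = ""),
                    character(1))
      arrs <- arrs[!duplicated(key)]
      if (length(arrs) < config$min_haplotypes) {
        lrt_rows[[g]] <- tibble::tibble(group = g, null_model = NA_character_,
                                        alt_model = NA_character_,
                                        two_delta_l = NA_real_, df = NA_integer_,
                                        p_value = NA_real_, signif = "",
                                        note = "insufficient data")
        next
      }
      aln <- build_codon_alignment(arrs,
                                   include_first_finger = config$include_first_finger,
                                   strict_equal_length = config$strict_equal_length)
      tr <- config$tree
      if (is.null(tr) || !setequal(tr$tip.label, aln$taxa)) {
        tr <- estimate_tree(aln)
      }
      cmp <- compare_site_models(aln, tr, models = config$models)
      beb <- NULL
      sig8 <- cmp$tests |>
        dplyr::filter(.data$alt_model == "M8", .data$p_value < max(config$thresholds))
      if (nrow(sig8) && "M8" %in% names(cmp$fits)) {
        beb <- beb_classify(aln, tr, cmp$fits$M8)
      }
      selection[[g]] <- list(alignment = aln, tree = tr, fits = cmp$fits,
                             tests = cmp$tests, beb = beb)
      lrt_rows[[g]] <- dplyr::mutate(cmp$tests, group = g, note = "",
                                     .before = 1L)
    }
  }
  lrt_table <- dplyr::bind_rows(lrt_rows)

  result <- structure(list(
    records = status, paralog = paralog_tab, arrays = arrays,
    catalog = catalog, schematics = schematics, cross_species = cross,
    genotypes = genotypes, disruptions = disruptions,
    selection = selection, lrt_table = lrt_table,
    config = config), class = "pipeline_result")
  result$manifest <- if (!is.null(config$out_dir)) {
    write_pipeline_bundle(result, config$out_dir)
  } else {
    build_manifest(result, outputs = character(0))
  }
  result
}

build_manifest <- function(result, outputs) {
  cfg <- result$config
  tibble_hash <- function(x) rlang::hash(x)
  list(tool = paste0("zfarray ", as.character(utils::packageVersion("zfarray"))),
       config_hash = tibble_hash(cfg[setdiff(names(cfg), "out_dir")]),
       seed = cfg$seed,
       input_checksums = if (is.character(cfg$input)) {
         as.list(tools::md5sum(cfg$input))
       } else list(records = tibble_hash(tibble::as_tibble(cfg$input))),
       stages = list(
         decomposed = sum(result$records$stage == "decomposed"),
         scanned = sum(result$records$stage == "scanned"),
         failed = sum(result$records$stage == "decompose_failed"),
         selection_groups = names(result$selection)),
       outputs = if (length(outputs)) as.list(tools::md5sum(outputs)) else list())
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  outputs <- character(0)
  outputs <- c(outputs, write_tsv_file(result$records, p("records.tsv")))
  if (!is.null(result$schematics)) {
    outputs <- c(outputs, write_tsv_file(result$schematics, p("decomposition.tsv")))
  }
  if (!is.null(result$catalog)) {
    ent <- result$catalog$entries
    occ <- result$catalog$occurrence |>
      dplyr::group_by(.data$code) |>
      dplyr::summarise(species = paste(.data$species, collapse = ","),
                       n = sum(.data$n), .groups = "drop")
    outputs <- c(outputs, write_tsv_file(
      dplyr::left_join(ent, occ, by = "code"), p("catalog.tsv")))
  }
  if (!is.null(result$genotypes)) {
    outputs <- c(outputs,
                 write_tsv_file(result$genotypes$counts, p("genotype_counts.tsv")),
                 write_tsv_file(result$genotypes$heterozygosity,
                                p("heterozygosity.tsv")))
  }
  if (!is.null(result$disruptions)) {
    outputs <- c(outputs, write_tsv_file(result$disruptions, p("disruption.tsv")))
  }
  if (nrow(result$lrt_table %||% tibble::tibble())) {
    outputs <- c(outputs, write_tsv_file(result$lrt_table, p("lrt.tsv")))
  }
  beb_tabs <- purrr::imap_dfr(result$selection, function(sel, g) {
    if (is.null(sel$beb)) return(NULL)
    dplyr::mutate(sel$beb$sites, group = g, .before = 1L)
  })
  if (nrow(beb_tabs)) {
    outputs <- c(outputs, write_tsv_file(beb_tabs, p("beb.tsv")))
  }
  bundle <- list(lrt = result$lrt_table,
                 records = result$records,
                 heterozygosity = result$genotypes$heterozygosity)
  jsonlite::write_json(bundle, p("bundle.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  outputs <- c(outputs, p("bundle.json"))
  manifest <- build_manifest(result, outputs)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  records:", nrow(x$records), "(",
      sum(x$records$stage == "decomposed"), "decomposed,",
      sum(x$records$stage == "scanned"), "scanned,",
      sum(x$records$stage == "decompose_failed"), "failed )\n")
  if (!is.null(x$catalog)) {
    cat("  catalogue:", nrow(x$catalog$entries), "distinct domains\n")
  }
  if (!is.null(x$lrt_table) && nrow(x$lrt_table)) {
    cat("  selection groups:", paste(unique(x$lrt_table$group), collapse = ", "),
        "\n")
  }
  invisible(x)
}
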