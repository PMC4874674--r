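# broom-style tidiers for the fitted objects.

#' Tidy a site-model fit
#'
#' @param x A `site_model_fit`.
#' @param ... Unused.
#' @return Tibble (term, estimate) over kappa and the model's natural
#'   parameters.
#' @export
tidy.site_model_fit <- function(x, ...) {
  tibble::tibble(term = c("kappa", names(x$parameters)),
                 estimate = c(x$kappa, unlist(x$parameters, use.names = FALSE)))
}

#' Glance at a site-model fit
#'
#' @param x A `site_model_fit`.
#' @param ... Unused.
#' @return One-row tibble: model, logLik, np, n_taxa, n_sites, converged.
#' @export
glance.site_model_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$lnL, np = x$np,
                 n_taxa = x$n_taxa, n_sites = x$n_sites,
                 converged = x$converged)
}

#' Tidy a BEB site classification
#'
#' @param x A `site_classification`.
#' @param ... Unused.
#' @return The per-site tibble (site, unit, offset, helix_position,
#'   p_positive, post_mean_omega, flagged).
#' @export
tidy.site_classification <- function(x, ...) x$sites

#' Tidy a domain catalogue
#'
#' @param x A `domain_catalog`.
#' @param ... Unused.
#' @return Tibble of entries joined with the per-species occurrence counts.
#' @export
tidy.domain_catalog <- function(x, ...) {
  occ <- x$occurrence |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                     species = paste(.data$species, collapse = ","),
                     .groups = "drop")
  dplyr::left_join(x$entries, occ, by = "code")
}

#' Glance at a domain catalogue
#'
#' @param x A `domain_catalog`.
#' @param ... Unused.
#' @return One-row tibble: n_domains, n_units, n_species, n_arrays, level.
#' @export
glance.domain_catalog <- function(x, ...) {
  tibble::tibble(n_domains = nrow(x$entries),
                 n_units = sum(x$entries$n_total),
                 n_species = dplyr::n_distinct(x$occurrence$species),
                 n_arrays = dplyr::n_distinct(x$provenance$record_id),
                 level = x$level)
}
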