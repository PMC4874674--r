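# ggplot2 views of the main result types.

#' Plot a domain catalogue as a species-by-domain occurrence map
#'
#' @param object A `domain_catalog`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.domain_catalog <- function(object, ...) {
  ggplot2::ggplot(object$occurrence,
                  ggplot2::aes(x = .data$code, y = .data$species,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "units") +
    ggplot2::labs(x = "domain code", y = NULL,
                  title = "ZF domain occurrence by species") +
    ggplot2::theme_minimal()
}

#' Plot per-site posterior probabilities of positive selection
#'
#' Sites on DNA-contact helix positions are labelled; the flagging
#' threshold is drawn as a dashed line.
#'
#' @param object A `site_classification`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.site_classification <- function(object, ...) {
  d <- object$sites |>
    dplyr::mutate(contact = !is.na(.data$helix_position))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site, y = .data$p_positive,
                                  fill = .data$contact)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               name = "contact position") +
    ggplot2::labs(x = "codon site", y = "P(omega > 1)",
                  title = paste("BEB site classification under", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot the fitted omega class distribution of a site model
#'
#' @param object A `site_model_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.site_model_fit <- function(object, ...) {
  d <- tibble::tibble(omega = object$omegas, weight = object$weights)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega, y = .data$weight)) +
    ggplot2::geom_col(width = 0.05, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "omega (dN/dS)", y = "class proportion",
                  title = paste("Site-class mixture:", object$model)) +
    ggplot2::theme_minimal()
}
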