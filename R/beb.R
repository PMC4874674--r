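# Bayes empirical Bayes identification of positively selected sites:
# a uniform prior grid over the site-class parameters of M2a or M8, with
# kappa, branch lengths and the rate scale fixed at the MLE, integrating
# the per-site class posteriors over the grid weighted by each grid
# point's data likelihood.

beb_midpoints <- function(lo, hi, n = 10L) lo + (hi - lo) * (2 * seq_len(n) - 1) / (2 * n)

# per-site log-likelihood under a single omega class, at fixed kappa/rho
site_logliks_by_omega <- function(alignment, tree, kappa, omegas, pi, rho) {
  vapply(omegas, function(w) {
    prune_loglik(alignment, tree, kappa, w, class_weights = 1,
                 pi = pi, rho = rho, per_site = TRUE)$site_loglik
  }, numeric(ncol(alignment$codons)))
}

#' Bayes empirical Bayes classification of selected sites
#'
#' For an M2a fit the grid runs over 10 midpoints each for omega0 in (0, 1)
#' and omega2 in (1, 11) and the 45 proportion pairs (p0, p1) on the
#' 10-point triangle grid; for M8 over 10 midpoints each for p0 in (0, 1)
#' and omega_s in (1, 11) with the beta shapes fixed at the MLE. Each site
#' is assigned the posterior probability of the positive-selection class
#' averaged over the grid, weighting grid points by their data likelihood
#' (uniform prior). Sites with posterior probability > `threshold` are
#' flagged and mapped to their ZF helix position where the alignment column
#' falls on a DNA-contact position.
#'
#' @param alignment A `codon_alignment`.
#' @param tree The fixed tree the fit conditioned on.
#' @param fit A converged `site_model_fit` for M2a or M8.
#' @param threshold Posterior-probability cutoff for flagging (default 0.95).
#' @return A `site_classification`: list with `sites` (tibble: site, unit,
#'   offset, helix_position, p_positive, post_mean_omega, flagged), `model`
#'   and `threshold`.
#' @export
beb_classify <- function(alignment, tree, fit, threshold = 0.95) {
  stopifnot(inherits(fit, "site_model_fit"))
  if (!fit$model %in% c("M2a", "M8")) {
    stop("BEB requires an M2a or M8 fit", call. = FALSE)
  }
  if (!fit$converged) {
    stop("fit did not converge; refusing BEB classification", call. = FALSE)
  }
  n_sites <- ncol(alignment$codons)
  pi <- fit$pi
  grid10 <- beb_midpoints(0, 1)
  if (fit$model == "M2a") {
    w0_grid <- beb_midpoints(0, 1)
    w2_grid <- beb_midpoints(1, 11)
    props <- expand.grid(p0 = grid10, p1 = grid10)
    props <- props[props$p0 + props$p1 < 1, ]
    uw <- c(w0_grid, 1, w2_grid)
    L <- site_logliks_by_omega(alignment, tree, fit$kappa, uw, pi, fit$rho)
    idx_w0 <- seq_len(10L); idx_one <- 11L; idx_w2 <- 11L + seq_len(10L)
    combos <- expand.grid(ip = seq_len(nrow(props)), i0 = seq_len(10L),
                          i2 = seq_len(10L))
    logP <- numeric(nrow(combos))
    pos_post <- matrix(0, n_sites, nrow(combos))
    mean_w <- matrix(0, n_sites, nrow(combos))
    for (g in seq_len(nrow(combos))) {
      p0 <- props$p0[combos$ip[g]]; p1 <- props$p1[combos$ip[g]]
      ws <- c(uw[idx_w0[combos$i0[g]]], 1, uw[idx_w2[combos$i2[g]]])
      lw <- log(c(p0, p1, 1 - p0 - p1))
      lmat <- cbind(L[, idx_w0[combos$i0[g]]], L[, idx_one],
                    L[, idx_w2[combos$i2[g]]])
      lmat <- sweep(lmat, 2L, lw, "+")
      mx <- apply(lmat, 1L, max)
      den <- mx + log(rowSums(exp(lmat - mx)))
      logP[g] <- sum(den)
      postk <- exp(lmat - den)
      pos_post[, g] <- postk[, 3L]
      mean_w[, g] <- postk %*% ws
    }
  } else {
    p <- fit$parameters$p; q <- fit$parameters$q
    d <- discretize_beta(p, q)
    p0_grid <- beb_midpoints(0, 1)
    ws_grid <- beb_midpoints(1, 11)
    uw <- c(d$omegas, ws_grid)
    L <- site_logliks_by_omega(alignment, tree, fit$kappa, uw, pi, fit$rho)
    combos <- expand.grid(i0 = seq_len(10L), is = seq_len(10L))
    logP <- numeric(nrow(combos))
    pos_post <- matrix(0, n_sites, nrow(combos))
    mean_w <- matrix(0, n_sites, nrow(combos))
    for (g in seq_len(nrow(combos))) {
      p0 <- p0_grid[combos$i0[g]]
      ws <- c(d$omegas, ws_grid[combos$is[g]])
      lw <- log(c(rep(p0 / 10, 10L), 1 - p0))
      lmat <- cbind(L[, seq_len(10L)], L[, 10L + combos$is[g]])
      lmat <- sweep(lmat, 2L, lw, "+")
      mx <- apply(lmat, 1L, max)
      den <- mx + log(rowSums(exp(lmat - mx)))
      logP[g] <- sum(den)
      postk <- exp(lmat - den)
      pos_post[, g] <- postk[, 11L]
      mean_w[, g] <- postk %*% ws
    }
  }
  gpost <- exp(logP - max(logP))
  gpost <- gpost / sum(gpost)
  p_positive <- as.numeric(pos_post %*% gpost)
  post_mean_omega <- as.numeric(mean_w %*% gpost)

  sites <- alignment$site_map |>
    dplyr::left_join(alignment$helix_map, by = "offset") |>
    dplyr::mutate(p_positive = p_positive,
                  post_mean_omega = post_mean_omega,
                  flagged = p_positive > threshold)
  structure(list(sites = sites, model = fit$model, threshold = threshold),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  n_flag <- sum(x$sites$flagged)
  cat("<site_classification> BEB under ", x$model, ": ", n_flag,
      " of ", nrow(x$sites), " sites flagged at P > ", x$threshold,
      "\n", sep = "")
  if (n_flag) print(dplyr::filter(x$sites, .data$flagged))
  invisible(x)
}

#' Summarise flagged helix positions
#'
#' Aggregates a BEB classification over the seven DNA-contact helix
#' positions: a position counts as positively selected when any alignment
#' column mapping to it is flagged.
#'
#' @param classification A `site_classification`.
#' @return Tibble (helix_position, n_sites, n_flagged, max_p,
#'   max_post_mean_omega) over contact positions only.
#' @export
helix_position_summary <- function(classification) {
  classification$sites |>
    dplyr::filter(!is.na(.data$helix_position)) |>
    dplyr::group_by(.data$helix_position) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     n_flagged = sum(.data$flagged),
                     max_p = max(.data$p_positive),
                     max_post_mean_omega = max(.data$post_mean_omega),
                     .groups = "drop") |>
    dplyr::arrange(.data$helix_position)
}
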