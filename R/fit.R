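# Maximum-likelihood fits of the codon site models M0, M1a, M2a, M7, M8
# with branch lengths fixed, plus likelihood-ratio tests.

SITE_MODELS <- c("M0", "M1a", "M2a", "M7", "M8")
BETA_K <- 10L  # equal-probability beta categories for M7/M8

# box transform: natural value in (lo, hi) <-> unconstrained x
box_fwd <- function(x, lo, hi) lo + (hi - lo) * stats::plogis(x)
box_inv <- function(v, lo, hi) stats::qlogis(pmin(pmax((v - lo) / (hi - lo),
                                                       1e-12), 1 - 1e-12))
# log-scale box for scale-like parameters
lbox_fwd <- function(x, lo, hi) exp(box_fwd(x, log(lo), log(hi)))
lbox_inv <- function(v, lo, hi) box_inv(log(v), log(lo), log(hi))

#' Discretise a beta distribution into equal-probability categories
#'
#' Category k of K gets the quantile midpoint `qbeta((k - 0.5) / K, p, q)`
#' and probability 1/K.
#'
#' @param p,q Beta shape parameters.
#' @param K Number of categories.
#' @return List with `omegas` (K category values) and `weights` (rep(1/K, K)).
#' @export
discretize_beta <- function(p, q, K = BETA_K) {
  stopifnot(p > 0, q > 0, K >= 1L)
  # extreme shapes can trip qbeta's accuracy warning; the midpoint values
  # remain valid category representatives
  list(omegas = suppressWarnings(qbeta((seq_len(K) - 0.5) / K, p, q)),
       weights = rep(1 / K, K))
}

# decode an unconstrained parameter vector into natural parameters and the
# mixture (omegas, weights) for one model
decode_params <- function(model, x) {
  switch(model,
    M0 = {
      kappa <- lbox_fwd(x[1], 0.01, 100)
      omega <- lbox_fwd(x[2], 1e-4, 50)
      list(kappa = kappa, natural = list(omega = omega),
           omegas = omega, weights = 1)
    },
    M1a = {
      kappa <- lbox_fwd(x[1], 0.01, 100)
      p0 <- box_fwd(x[2], 0, 1)
      omega0 <- box_fwd(x[3], 1e-4, 1)
      list(kappa = kappa, natural = list(p0 = p0, omega0 = omega0),
           omegas = c(omega0, 1), weights = c(p0, 1 - p0))
    },
    M2a = {
      kappa <- lbox_fwd(x[1], 0.01, 100)
      v1 <- box_fwd(x[2], 0, 1)
      v2 <- box_fwd(x[3], 0, 1)
      p0 <- v1
      p1 <- (1 - v1) * v2
      omega0 <- box_fwd(x[4], 1e-4, 1)
      omega2 <- box_fwd(x[5], 1, 50)
      list(kappa = kappa,
           natural = list(p0 = p0, p1 = p1, p2 = 1 - p0 - p1,
                          omega0 = omega0, omega2 = omega2),
           omegas = c(omega0, 1, omega2), weights = c(p0, p1, 1 - p0 - p1))
    },
    M7 = {
      kappa <- lbox_fwd(x[1], 0.01, 100)
      p <- lbox_fwd(x[2], 0.005, 99)
      q <- lbox_fwd(x[3], 0.005, 99)
      d <- discretize_beta(p, q)
      list(kappa = kappa, natural = list(p = p, q = q),
           omegas = d$omegas, weights = d$weights)
    },
    M8 = {
      kappa <- lbox_fwd(x[1], 0.01, 100)
      p0 <- box_fwd(x[2], 0, 1)
      p <- lbox_fwd(x[3], 0.005, 99)
      q <- lbox_fwd(x[4], 0.005, 99)
      omega_s <- box_fwd(x[5], 1, 50)
      d <- discretize_beta(p, q)
      list(kappa = kappa,
           natural = list(p0 = p0, p = p, q = q, omega_s = omega_s),
           omegas = c(d$omegas, omega_s),
           weights = c(p0 * d$weights, 1 - p0))
    },
    stop("unknown model: ", model, call. = FALSE))
}

# encode natural parameters (list) back to the unconstrained scale
encode_params <- function(model, kappa, nat) {
  k <- lbox_inv(kappa, 0.01, 100)
  switch(model,
    M0 = c(k, lbox_inv(nat$omega, 1e-4, 50)),
    M1a = c(k, box_inv(nat$p0, 0, 1), box_inv(nat$omega0, 1e-4, 1)),
    M2a = c(k, box_inv(nat$p0, 0, 1),
            box_inv(nat$p1 / max(1 - nat$p0, 1e-12), 0, 1),
            box_inv(nat$omega0, 1e-4, 1), box_inv(nat$omega2, 1, 50)),
    M7 = c(k, lbox_inv(nat$p, 0.005, 99), lbox_inv(nat$q, 0.005, 99)),
    M8 = c(k, box_inv(nat$p0, 0, 1), lbox_inv(nat$p, 0.005, 99),
           lbox_inv(nat$q, 0.005, 99), box_inv(nat$omega_s, 1, 50)))
}

# deterministic default starts (natural scale) per model
default_starts <- function(model, n_starts) {
  base <- switch(model,
    M0 = list(list(kappa = 2, omega = 0.5)),
    M1a = list(list(kappa = 2, p0 = 0.7, omega0 = 0.2)),
    M2a = list(list(kappa = 2, p0 = 0.6, p1 = 0.3, omega0 = 0.2, omega2 = 3)),
    M7 = list(list(kappa = 2, p = 0.5, q = 1.5)),
    M8 = list(list(kappa = 2, p0 = 0.9, p = 0.5, q = 1.5, omega_s = 3)))
  jitters <- switch(model,
    M0 = list(list(kappa = 4, omega = 1.5), list(kappa = 1, omega = 0.1)),
    M1a = list(list(kappa = 4, p0 = 0.4, omega0 = 0.05),
               list(kappa = 1, p0 = 0.9, omega0 = 0.6)),
    M2a = list(list(kappa = 4, p0 = 0.4, p1 = 0.4, omega0 = 0.05, omega2 = 8),
               list(kappa = 1, p0 = 0.8, p1 = 0.1, omega0 = 0.6, omega2 = 1.5)),
    M7 = list(list(kappa = 4, p = 0.2, q = 2), list(kappa = 1, p = 2, q = 2)),
    M8 = list(list(kappa = 4, p0 = 0.7, p = 0.2, q = 2, omega_s = 8),
              list(kappa = 1, p0 = 0.98, p = 2, q = 2, omega_s = 1.5)))
  c(base, jitters)[seq_len(min(n_starts, 3L))]
}

#' Fit a codon site model by maximum likelihood
#'
#' Maximises the pruning log-likelihood over the model's free parameters
#' with branch lengths held fixed at the supplied tree. Optimisation is
#' derivative-free (Nelder-Mead) on box-transformed parameters
#' (omega0 in (1e-4, 1), omega2/omega_s in (1, 50), proportions through a
#' logistic stick-breaking transform, beta shapes in (0.005, 99)), with
#' deterministic multi-start. M7/M8 use a 10-category equal-probability
#' beta discretisation.
#'
#' @param alignment A `codon_alignment`.
#' @param tree `ape::phylo` with fixed branch lengths (expected
#'   substitutions per codon).
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param pi Codon frequencies; default F3X4 from the alignment.
#' @param n_starts Number of optimisation starts (default 3).
#' @param null_fit Optional fit of the nested null model (M1a for M2a, M7
#'   for M8); adds a start embedded at the null optimum, which guarantees
#'   the alternative's likelihood is not driven below the null's.
#' @param reltol Convergence tolerance passed to [stats::optim()].
#' @param maxit Iteration cap per start.
#' @return A `site_model_fit`: list with `model`, `lnL`, `kappa`,
#'   `parameters` (named list of natural parameters), `omegas`, `weights`,
#'   `pi`, `rho`, `np` (free parameter count), `converged`, `tree`,
#'   `n_taxa`, `n_sites`.
#' @export
fit_site_model <- function(alignment, tree, model = "M1a", pi = NULL,
                           n_starts = 3L, null_fit = NULL,
                           reltol = 1e-8, maxit = 1000L) {
  model <- match.arg(model, SITE_MODELS)
  stopifnot(inherits(alignment, "codon_alignment"))
  if (is.null(pi)) pi <- f3x4_frequencies(alignment)
  pat <- site_patterns(alignment)
  td <- lik_tree_data(alignment, tree)
  st <- pat$states[td$row_ord, , drop = FALSE]
  pc <- codon_pair_class()

  negll <- function(x) {
    dec <- tryCatch(decode_params(model, x), error = function(e) NULL)
    if (is.null(dec)) return(1e10)
    res <- tryCatch(
      gy94_loglik_cpp(st, pat$weights, td$edge, td$elen, td$nnode,
                      as.numeric(pi), pc, dec$kappa, dec$omegas,
                      dec$weights, -1, FALSE),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$loglik)) return(1e10)
    -res$loglik
  }

  starts <- lapply(default_starts(model, n_starts), function(s) {
    encode_params(model, s$kappa, s[setdiff(names(s), "kappa")])
  })
  if (!is.null(null_fit)) {
    emb <- embed_null_start(model, null_fit)
    if (!is.null(emb)) starts <- c(starts, list(emb))
  }

  best <- NULL
  for (x0 in starts) {
    opt <- stats::optim(x0, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  dec <- decode_params(model, best$par)
  lik <- gy94_loglik_cpp(st, pat$weights, td$edge, td$elen, td$nnode,
                         as.numeric(pi), pc, dec$kappa, dec$omegas,
                         dec$weights, -1, FALSE)
  structure(list(
    model = model, lnL = -best$value, kappa = dec$kappa,
    parameters = dec$natural, omegas = dec$omegas, weights = dec$weights,
    pi = pi, rho = lik$rho, np = length(best$par),
    converged = best$convergence == 0L, tree = tree,
    n_taxa = length(alignment$taxa), n_sites = ncol(alignment$codons)),
    class = "site_model_fit")
}

# start for an alternative model sitting (almost) on the null optimum
embed_null_start <- function(model, null_fit) {
  if (model == "M2a" && null_fit$model == "M1a") {
    p0 <- null_fit$parameters$p0
    return(encode_params("M2a", null_fit$kappa,
                         list(p0 = p0 * (1 - 1e-7),
                              p1 = (1 - p0) * (1 - 1e-7),
                              omega0 = null_fit$parameters$omega0,
                              omega2 = 1 + 1e-6)))
  }
  if (model == "M8" && null_fit$model == "M7") {
    return(encode_params("M8", null_fit$kappa,
                         list(p0 = 1 - 1e-7, p = null_fit$parameters$p,
                              q = null_fit$parameters$q,
                              omega_s = 1 + 1e-6)))
  }
  NULL
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("<site_model_fit> ", x$model, ": lnL = ", format(x$lnL, digits = 10),
      " (", x$np, " free parameters",
      if (!x$converged) "; NOT converged", ")\n", sep = "")
  cat("  kappa =", round(x$kappa, 4), "\n")
  cat("  ", paste(names(x$parameters), "=",
                  vapply(x$parameters, function(v) format(round(v, 4)),
                         character(1)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test between nested site models
#'
#' `2 * (lnL_alt - lnL_null)` compared to a chi-squared distribution with
#' 2 degrees of freedom (the convention for both the M1a/M2a and M7/M8
#' comparisons; conservative because the null sits on the boundary of the
#' alternative). The statistic is clipped at 0 for reporting.
#'
#' @param null,alt `site_model_fit` objects for a nested pair
#'   (M1a within M2a, or M7 within M8).
#' @return One-row tibble: `null_model`, `alt_model`, `two_delta_l`, `df`,
#'   `p_value`, `signif` (`"**"` p < 0.01, `"*"` p < 0.05, else `""`).
#' @export
lrt <- function(null, alt) {
  stopifnot(inherits(null, "site_model_fit"), inherits(alt, "site_model_fit"))
  nested <- (null$model == "M1a" && alt$model == "M2a") ||
    (null$model == "M7" && alt$model == "M8")
  if (!nested) {
    stop("models not a supported nested pair (M1a/M2a or M7/M8): ",
         null$model, " vs ", alt$model, call. = FALSE)
  }
  raw <- 2 * (alt$lnL - null$lnL)
  if (raw < -1e-4) {
    warning("alternative fit below null (2*dlnL = ", signif(raw, 4),
            "); optimisation likely not converged", call. = FALSE)
  }
  stat <- max(raw, 0)
  p <- pchisq(stat, df = 2, lower.tail = FALSE)
  tibble::tibble(null_model = null$model, alt_model = alt$model,
                 two_delta_l = stat, df = 2L, p_value = p,
                 signif = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
}

#' Fit the standard model ladder and tabulate the LRTs
#'
#' Fits M1a, M2a, M7 and M8 (each alternative seeded from its null) and
#' returns the two likelihood-ratio tests in one table.
#'
#' @inheritParams fit_site_model
#' @param models Models to fit.
#' @return List with `fits` (named list of `site_model_fit`) and `tests`
#'   (tibble of LRT rows).
#' @export
compare_site_models <- function(alignment, tree,
                                models = c("M1a", "M2a", "M7", "M8"),
                                pi = NULL, n_starts = 3L) {
  models <- match.arg(models, SITE_MODELS, several.ok = TRUE)
  if (is.null(pi)) pi <- f3x4_frequencies(alignment)
  fits <- list()
  for (m in models) {
    nf <- switch(m, M2a = fits[["M1a"]], M8 = fits[["M7"]], NULL)
    fits[[m]] <- fit_site_model(alignment, tree, m, pi = pi,
                                n_starts = n_starts, null_fit = nf)
  }
  tests <- list()
  if (all(c("M1a", "M2a") %in% names(fits))) {
    tests <- c(tests, list(lrt(fits$M1a, fits$M2a)))
  }
  if (all(c("M7", "M8") %in% names(fits))) {
    tests <- c(tests, list(lrt(fits$M7, fits$M8)))
  }
  list(fits = fits, tests = dplyr::bind_rows(tests))
}

#' Estimate branch lengths under M0 on a fixed topology
#'
#' Joint maximisation of the M0 likelihood over kappa, omega and all branch
#' lengths (log-scale, L-BFGS-B). Used to set the fixed branch lengths that
#' the site-model fits condition on when no calibrated tree is supplied.
#'
#' @param alignment A `codon_alignment`.
#' @param tree Topology (`ape::phylo`); starting lengths taken from the tree
#'   when present, else 0.1.
#' @param pi Codon frequencies; default F3X4.
#' @return The tree with optimised branch lengths; attributes `kappa`,
#'   `omega`, `lnL` record the M0 optimum.
#' @export
m0_branch_lengths <- function(alignment, tree, pi = NULL) {
  if (is.null(pi)) pi <- f3x4_frequencies(alignment)
  pat <- site_patterns(alignment)
  td <- lik_tree_data(alignment, tree)
  st <- pat$states[td$row_ord, , drop = FALSE]
  pc <- codon_pair_class()
  nedge <- nrow(td$edge)
  b0 <- if (!is.null(tree$edge.length)) pmax(td$elen, 1e-4) else rep(0.1, nedge)

  obj <- function(x) {
    kappa <- exp(x[1]); omega <- exp(x[2]); bl <- exp(x[-(1:2)])
    res <- tryCatch(
      gy94_loglik_cpp(st, pat$weights, td$edge, bl, td$nnode,
                      as.numeric(pi), pc, kappa, omega, 1, -1, FALSE),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$loglik)) return(1e10)
    -res$loglik
  }
  x0 <- c(log(2), log(0.5), log(b0))
  opt <- stats::optim(x0, obj, method = "L-BFGS-B",
                      lower = c(log(0.01), log(1e-4), rep(log(1e-7), nedge)),
                      upper = c(log(100), log(50), rep(log(20), nedge)),
                      control = list(maxit = 500))
  # write optimised lengths back in the postorder tree's edge order
  tr <- stats::reorder(tree, "postorder")
  tr$edge.length <- exp(opt$par[-(1:2)])
  attr(tr, "kappa") <- exp(opt$par[1])
  attr(tr, "omega") <- exp(opt$par[2])
  attr(tr, "lnL") <- -opt$value
  tr
}

#' Default tree for selection analyses
#'
#' Neighbor-joining on codon p-distances followed by M0 branch-length
#' maximum likelihood; the result is the fixed tree the site-model fits
#' condition on. A user-supplied Newick tree should be used instead
#' whenever an externally estimated topology is available.
#'
#' @param alignment A `codon_alignment` with >= 3 taxa.
#' @return An `ape::phylo` with ML branch lengths (see
#'   [m0_branch_lengths()]).
#' @export
estimate_tree <- function(alignment) {
  d <- codon_p_distance(alignment)
  nj <- neighbor_joining(d)
  m0_branch_lengths(alignment, nj)
}
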