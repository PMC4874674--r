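# Shared fixtures: synthetic arrays, small trees, and independent oracles.

# one synthetic amplicon built from explicit parts (flanks, leading finger,
# units given as amino-acid strings)
make_amplicon <- function(unit_aas,
                          upstream = zfarray:::SIM_UPSTREAM,
                          spacer = zfarray:::SIM_SPACER,
                          downstream = zfarray:::SIM_DOWNSTREAM) {
  paste0(upstream, reverse_translate(zfarray:::ZF_LEADING_AA), spacer,
         paste0(vapply(unit_aas, reverse_translate, character(1)),
                collapse = ""),
         downstream)
}

# a pool of valid distinct unit variants derived from the consensus
unit_pool <- function(n, seed = 1) {
  cons <- zfarray:::ZF_UNIT_CONSENSUS_AA
  zfarray:::with_local_seed(seed, {
    pool <- cons
    while (length(pool) < n) {
      pool <- unique(c(pool, zfarray:::mutate_unit(cons, 2L, 5)))
    }
    pool[seq_len(n)]
  })
}

# independent character-by-character FASTA reference parser
reference_fasta_parse <- function(path) {
  lines <- readLines(path)
  recs <- list()
  id <- NULL; buf <- character(0)
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (!is.null(id)) recs[[id]] <- paste0(buf, collapse = "")
      id <- strsplit(substring(ln, 2), "\\s+")[[1]][1]
      buf <- character(0)
    } else {
      buf <- c(buf, toupper(gsub("[ \t]", "", ln)))
    }
  }
  if (!is.null(id)) recs[[id]] <- paste0(buf, collapse = "")
  recs
}

# brute-force mixture likelihood by exhaustive enumeration of all internal
# node states (feasible for <= 4 leaves)
brute_loglik <- function(alignment, tree, kappa, omegas, weights, pi) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  internal <- (ntip + 1):(ntip + tr$Nnode)
  st <- alignment$states[match(tr$tip.label, alignment$taxa), , drop = FALSE]
  models <- lapply(omegas, function(w) build_rate_model(pi, kappa, w, scale = FALSE))
  rho <- sum(weights * vapply(models, `[[`, numeric(1), "rate"))
  total <- 0
  for (site in seq_len(ncol(st))) {
    sl <- 0
    for (k in seq_along(omegas)) {
      P <- lapply(seq_len(nrow(tr$edge)), function(e)
        zfarray:::codon_pmat(models[[k]]$Q / rho, pi, tr$edge.length[e]))
      grid <- do.call(expand.grid, rep(list(1:61), length(internal)))
      lik_k <- 0
      for (g in seq_len(nrow(grid))) {
        state_of <- function(node) {
          if (node <= ntip) st[node, site] else grid[g, match(node, internal)]
        }
        pr <- pi[state_of(tr$edge[nrow(tr$edge), 1])]
        for (e in seq_len(nrow(tr$edge))) {
          b <- state_of(tr$edge[e, 2])
          if (!is.na(b)) pr <- pr * P[[e]][state_of(tr$edge[e, 1]), b]
        }
        lik_k <- lik_k + pr
      }
      sl <- sl + weights[k] * lik_k
    }
    total <- total + log(sl)
  }
  unname(total)
}

uniform_pi <- function() setNames(rep(1 / 61, 61), sense_codons())
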