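# Synthetic-data generators with known ground truth for every pipeline
# stage: diploid ZF-array panels, codon alignments evolved under site-class
# mixtures, and pseudogenised copies with planted lesions.

# Synthetic exemplar sequences satisfying the C2H2 motif (designed for this
# package; not claimed to be real bovine sequences).
# 28-aa tandem unit: Cys1=2, Cys2=5, His1=18, His2=22; contact residues
# -9:G, -5:K, -2:S, -1:R, 2:D, 3:E, 6:R.
ZF_UNIT_CONSENSUS_AA <- "TCGQCGKSFSRSDELQRHQRTHTGEKPY"
# 23-aa conserved leading finger: Cys1=1, Cys2=4, His1=17, His2=21.
ZF_LEADING_AA <- "CAICNQSFSVKANLIRHMRTHSG"

# fixed codon choice for reverse translation (no stops)
AA_CODON <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
              G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
              M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "CGG",
              S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")

# stop-free flanks, all multiples of 3 so the coding frame is 0 throughout
SIM_UPSTREAM <- "ATGGCTTCAGAATCTGGAGCTTCAGGATCC"
SIM_SPACER <- "GGATCTCCTGAAAGTGGAACTGGAGAATCT"
SIM_DOWNSTREAM <- "GGATCCGAAGCTTGGGCCCT"

#' Reverse-translate an amino-acid string with a fixed codon table
#'
#' @param aa Amino-acid string (no stops).
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa) {
  codons <- AA_CODON[strsplit(aa, "")[[1]]]
  if (anyNA(codons)) stop("cannot reverse-translate symbol(s): ",
                          paste(setdiff(strsplit(aa, "")[[1]], names(AA_CODON)),
                                collapse = ", "), call. = FALSE)
  paste0(codons, collapse = "")
}

# run code under a fixed seed without clobbering the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the diploid ZF-array panel simulator
#'
#' Defaults emulate a five-species ruminant panel: repeat-count allele
#' frequencies concentrated per species (one nearly fixed allele in the
#' sheep-like panel, a single allele in the yak-like panel, the widest
#' allele range in the goat-like panel), domain pools mutated from a
#' species consensus with substitutions concentrated at the DNA-contact
#' positions.
#'
#' @param species Tibble with columns `name`, `n_animals`, `freqs`
#'   (list-column: named allele-frequency vectors over letters A-G).
#' @param pool_size Distinct domain variants available per species.
#' @param contact_bias Relative substitution-rate multiplier at helix
#'   positions -1, 2, 3, 6 (>= 1).
#' @param subs_per_domain Mean substitutions separating a pool domain from
#'   the species consensus (Poisson, minimum 1 for non-consensus domains).
#' @param seed Integer seed fixing all draws.
#' @return A list of class `population_sim_config`.
#' @export
population_sim_config <- function(species = NULL, pool_size = 8L,
                                  contact_bias = 5, subs_per_domain = 2,
                                  seed = 1L) {
  if (is.null(species)) {
    species <- tibble::tibble(
      name = c("cattle", "yak", "mithun", "sheep", "goat"),
      n_animals = c(25L, 10L, 20L, 45L, 45L),
      freqs = list(
        c(A = 0.35, B = 0.35, C = 0.20, D = 0.10),
        c(A = 1.0),
        c(A = 0.40, B = 0.60),
        c(C = 0.044, D = 0.956),
        c(C = 0.15, D = 0.20, E = 0.20, F = 0.30, G = 0.15)))
  }
  ok <- vapply(species$freqs, function(f) abs(sum(f) - 1) < 1e-8, logical(1))
  if (!all(ok)) stop("allele frequencies must sum to 1 per species",
                     call. = FALSE)
  stopifnot(contact_bias >= 1, pool_size >= 1L)
  structure(list(species = species, pool_size = as.integer(pool_size),
                 contact_bias = contact_bias,
                 subs_per_domain = subs_per_domain, seed = as.integer(seed)),
            class = "population_sim_config")
}

# mutate a unit consensus: n substitutions at non-anchor positions, biased
# toward the contact positions; substitutions never introduce C or H
mutate_unit <- function(aa, n_subs, contact_bias) {
  ch <- strsplit(aa, "")[[1]]
  anch <- find_c2h2_anchors(aa)
  protected <- c(anch$cys1, anch$cys2, anch$his1, anch$his2)
  contact_idx <- unname(helix_position_offsets(anch$his1)[c("-1", "2", "3", "6")])
  pos_pool <- setdiff(seq_along(ch), protected)
  w <- ifelse(pos_pool %in% contact_idx, contact_bias, 1)
  alphabet <- setdiff(names(AA_CODON), c("C", "H"))
  n_subs <- min(n_subs, length(pos_pool))
  at <- sample(pos_pool, n_subs, prob = w)
  for (p in at) ch[p] <- sample(setdiff(alphabet, ch[p]), 1L)
  paste0(ch, collapse = "")
}

allele_n_units <- function(letter) match(letter, LETTERS[1:7]) + 5L

#' Simulate a diploid multi-species ZF-array panel
#'
#' For each species a domain pool is realised by mutating a species
#' consensus; each allele letter present in the frequency table becomes one
#' fixed haplotype of 6-12 tandem units drawn from the pool; each animal
#' draws two alleles by frequency. Haplotype sequences carry a stop-free
#' upstream flank, the conserved 23-aa leading finger, an internal spacer,
#' the tandem 84-nt units, and a downstream flank, so decomposition can
#' recover every component exactly.
#'
#' @param config A [population_sim_config()].
#' @return List with `records` (tibble id/description/seq, two haplotypes
#'   per animal, FASTA-ready), `genotypes` (animal_id, species, allele1,
#'   allele2), `alleles` (species, allele, n_units, domain ids), `domains`
#'   (species, domain_id, aa, nt), and `config`.
#' @export
simulate_population <- function(config = population_sim_config()) {
  stopifnot(inherits(config, "population_sim_config"))
  with_local_seed(config$seed, {
    lead_nt <- reverse_translate(ZF_LEADING_AA)
    domains <- list(); alleles <- list(); genotypes <- list(); records <- list()
    for (s in seq_len(nrow(config$species))) {
      sp <- config$species$name[s]
      freqs <- config$species$freqs[[s]]
      # species consensus: one fixed substitution off the global consensus
      sp_cons <- mutate_unit(ZF_UNIT_CONSENSUS_AA, 1L, config$contact_bias)
      pool_aa <- c(sp_cons, vapply(seq_len(config$pool_size - 1L), function(i) {
        mutate_unit(sp_cons, max(1L, stats::rpois(1L, config$subs_per_domain)),
                    config$contact_bias)
      }, character(1)))
      pool_aa <- unique(pool_aa)
      pool_nt <- vapply(pool_aa, reverse_translate, character(1))
      domains[[sp]] <- tibble::tibble(species = sp,
                                      domain_id = seq_along(pool_aa),
                                      aa = pool_aa, nt = unname(pool_nt))
      hap <- list()
      for (letter in names(freqs)) {
        n_units <- allele_n_units(letter)
        picks <- sample(length(pool_aa), n_units, replace = TRUE)
        hap[[letter]] <- picks
        alleles[[paste(sp, letter)]] <- tibble::tibble(
          species = sp, allele = letter, n_units = n_units,
          unit_index = seq_len(n_units), domain_id = picks)
      }
      for (a in seq_len(config$species$n_animals[s])) {
        pair <- sample(names(freqs), 2L, replace = TRUE, prob = freqs)
        pair <- sort(pair)
        animal <- sprintf("%s_%03d", sp, a)
        genotypes[[animal]] <- tibble::tibble(
          animal_id = animal, species = sp,
          allele1 = pair[1], allele2 = pair[2])
        for (h in 1:2) {
          units_nt <- paste0(pool_nt[hap[[pair[h]]]], collapse = "")
          records[[paste0(animal, "_h", h)]] <- tibble::tibble(
            id = paste0(animal, "_h", h),
            description = paste0("species=", sp, " allele=", pair[h]),
            seq = paste0(SIM_UPSTREAM, lead_nt, SIM_SPACER, units_nt,
                         SIM_DOWNSTREAM))
        }
      }
    }
    list(records = dplyr::bind_rows(records),
         genotypes = dplyr::bind_rows(genotypes),
         alleles = dplyr::bind_rows(alleles),
         domains = dplyr::bind_rows(domains),
         config = config)
  })
}

#' Mixture of omega classes implied by a site model's natural parameters
#'
#' @param model One of M0, M1a, M2a, M7, M8.
#' @param params Named list of natural parameters (M0: `omega`; M1a: `p0`,
#'   `omega0`; M2a: `p0`, `p1`, `omega0`, `omega2`; M7: `p`, `q`; M8: `p0`,
#'   `p`, `q`, `omega_s`).
#' @return List with `omegas` and `weights`.
#' @export
site_class_mixture <- function(model, params) {
  model <- match.arg(model, SITE_MODELS)
  switch(model,
    M0 = list(omegas = params$omega, weights = 1),
    M1a = list(omegas = c(params$omega0, 1),
               weights = c(params$p0, 1 - params$p0)),
    M2a = list(omegas = c(params$omega0, 1, params$omega2),
               weights = c(params$p0, params$p1, 1 - params$p0 - params$p1)),
    M7 = discretize_beta(params$p, params$q),
    M8 = {
      d <- discretize_beta(params$p, params$q)
      list(omegas = c(d$omegas, params$omega_s),
           weights = c(params$p0 * d$weights, 1 - params$p0))
    })
}

#' Simulate a codon alignment under a GY94 site-class mixture
#'
#' Each site draws an omega class by its mixture proportion; a root codon is
#' drawn from the equilibrium frequencies and evolved down the tree with
#' `exp(Qt)` transition sampling under that class's rate matrix (classes
#' jointly scaled so branch lengths are expected substitutions per codon
#' under the mixture). No stop codon can be emitted: the state space is the
#' 61 sense codons.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param model,params Site model and true natural parameters
#'   (see [site_class_mixture()]).
#' @param n_sites Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default uniform over the 61 sense codons).
#' @param seed Integer seed.
#' @return List with `alignment` (a `codon_alignment`) and `truth`
#'   (tibble: site, class, omega — the positive-selection class is the one
#'   with omega > 1 where the model has one).
#' @export
simulate_codon_alignment <- function(tree, model = "M2a",
                                     params = list(p0 = 0.5, p1 = 0.3,
                                                   omega0 = 0.1, omega2 = 5),
                                     n_sites = 300L, kappa = 2,
                                     pi = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  mix <- site_class_mixture(model, params)
  K <- length(mix$omegas)
  if (is.null(pi)) pi <- setNames(rep(1 / 61, 61), sense_codons())
  with_local_seed(seed, {
    models <- lapply(mix$omegas, function(w)
      build_rate_model(pi, kappa = kappa, omega = w, scale = FALSE))
    rho <- sum(mix$weights * vapply(models, `[[`, numeric(1), "rate"))
    tr <- stats::reorder(tree, "postorder")
    ntip <- length(tr$tip.label)
    edges_pre <- rev(seq_len(nrow(tr$edge)))  # preorder: parents first
    cls <- sample.int(K, n_sites, replace = TRUE, prob = mix$weights)
    root <- tr$edge[nrow(tr$edge), 1]
    node_states <- matrix(NA_integer_, ntip + tr$Nnode, n_sites)
    node_states[root, ] <- sample.int(61L, n_sites, replace = TRUE, prob = pi)
    for (e in edges_pre) {
      par <- tr$edge[e, 1]; chl <- tr$edge[e, 2]
      t_e <- tr$edge.length[e]
      for (k in seq_len(K)) {
        idx <- which(cls == k)
        if (!length(idx)) next
        P <- codon_pmat(models[[k]]$Q / rho, pi, t_e)
        for (s in unique(node_states[par, idx])) {
          at <- idx[node_states[par, idx] == s]
          node_states[chl, at] <- sample.int(61L, length(at), replace = TRUE,
                                             prob = P[s, ])
        }
      }
    }
    cod <- sense_codons()
    codons <- matrix(cod[node_states[seq_len(ntip), , drop = FALSE]],
                     ntip, n_sites, dimnames = list(tr$tip.label, NULL))
    list(alignment = codon_alignment(codons),
         truth = tibble::tibble(site = seq_len(n_sites), class = cls,
                                omega = mix$omegas[cls]))
  })
}

#' Plant disruptive lesions into a decomposed array
#'
#' Substitutes TAA at the requested codon indices (1-based, counted in the
#' array's reading frame over the full sequence, matching [scan_orf()]) and
#' applies frameshift indels at the requested nucleotide positions.
#'
#' @param base A `zf_array` (e.g. one haplotype from
#'   [simulate_population()] after [segment_array()]).
#' @param stops Integer vector of codon indices to replace with TAA.
#' @param frameshifts Tibble or data frame with columns `position`
#'   (1-based nt) and `offset` (in -2, -1, 1, 2; positive inserts that many
#'   `A`s, negative deletes that many bases).
#' @return List with `seq` (the lesioned nucleotide string) and `truth`
#'   (tibble: type, position, offset).
#' @export
simulate_pseudogene <- function(base, stops = integer(0),
                                frameshifts = NULL) {
  stopifnot(inherits(base, "zf_array"))
  seq <- reconstruct_array(base)
  f <- base$frame
  stop_nt <- f + 3L * (stops - 1L) + 1L
  if (any(stop_nt + 2L > nchar(seq)) || any(stops < 1L)) {
    stop("stop codon index outside the sequence", call. = FALSE)
  }
  fs <- if (is.null(frameshifts)) {
    tibble::tibble(position = integer(0), offset = integer(0))
  } else tibble::as_tibble(frameshifts)
  if (nrow(fs) && !all(fs$offset %in% c(-2L, -1L, 1L, 2L))) {
    stop("frameshift offsets must be in {-2, -1, 1, 2}", call. = FALSE)
  }
  spans <- rbind(
    if (length(stops)) cbind(stop_nt, stop_nt + 2L),
    if (nrow(fs)) cbind(fs$position, fs$position + pmax(-fs$offset - 1L, 0L)))
  if (!is.null(spans) && nrow(spans) > 1L) {
    o <- order(spans[, 1])
    if (any(spans[o, 1][-1] <= spans[o, 2][-nrow(spans)])) {
      stop("overlapping edits", call. = FALSE)
    }
  }
  for (p in stop_nt) {
    substring(seq, p, p + 2L) <- "TAA"
  }
  if (nrow(fs)) {
    for (i in order(fs$position, decreasing = TRUE)) {
      p <- fs$position[i]; off <- fs$offset[i]
      if (off > 0L) {
        seq <- paste0(substring(seq, 1L, p), strrep("A", off),
                      substring(seq, p + 1L))
      } else {
        seq <- paste0(substring(seq, 1L, p - 1L),
                      substring(seq, p - off))
      }
    }
  }
  truth <- dplyr::bind_rows(
    tibble::tibble(type = rep("stop", length(stops)),
                   position = as.integer(stops), offset = 0L),
    tibble::tibble(type = rep("frameshift", nrow(fs)),
                   position = as.integer(fs$position),
                   offset = as.integer(fs$offset)))
  list(seq = seq, truth = truth)
}
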