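---
title: "Methods: ZF minisatellite decomposition and codon site-model selection tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ZF minisatellite decomposition and codon site-model selection tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfarray)
```

## The problem

PRDM9 positions meiotic recombination hotspots through a C2H2 zinc-finger
(ZF) array encoded as a minisatellite in a single exon: each finger is an
84-bp / 28-amino-acid unit repeated in tandem, and the residues the fingers
present to the DNA (helix positions -1, 2, 3 and 6, with -9, -5 and -2 also
variable) set the binding specificity. Length variants of the array differ
by whole repeat units, so amplicon sizes form an 84-bp arithmetic series and
repeat counts of 6-12 can be labelled as alleles A-G. Paralogous copies
(PRDM7-like) carry the same 84-bp periodicity but are disabled by premature
stop codons and frameshifts. `zfarray` implements the full analysis chain:
amplicon decomposition, domain cataloguing, genotype summaries, pseudogene
scanning, and codon-model tests of positive selection on the repeat units,
plus a synthetic-data generator with known ground truth for every stage.

## Array decomposition

`segment_array()` works in amino-acid space. The reading frame is the one
maximising the number of strict C2H2 motifs `C-x2-C-x12-H-x(3..5)-H`
(ties go to the lowest frame index). The tandem block is the maximal
arithmetic chain of motif hits spaced exactly 28 residues apart — an
arithmetic chain rather than a consecutive run, so an incidental motif hit
at another phase cannot split the block. Unit windows are phased so Cys1
sits at the same offset in every unit (position 2 by default, shifted only
when the amplicon would truncate a terminal unit). The first relaxed-motif
window (`C-x(2..4)-C`, admitting the wider Cys spacing of canonical fingers
such as Zif268 finger 1) fully preceding the block is taken as the
conserved 23-aa leading finger; the sequence between it and the block is
kept as an explicit spacer segment so that re-concatenating
`upstream + leading + spacer + units + downstream` reproduces the input
byte-for-byte. A motif failure inside the block (for example a mutated
histidine) yields a partial decomposition with a warning flag rather than
an error.

All residue and codon coordinates in reports are 1-based with closed
intervals. Contact residues are read off the His1 anchor: for helix
position $k \ge 1$ the residue is `aa[H1 - (7 - k)]`, for $k \le -1$ it is
`aa[H1 - (6 - k)]`; there is no position 0. This reproduces the published
Zif268 finger-1 recognition residues (-1:R, 2:D, 3:E, 6:R), which is the
package's fixed-point test for the rule.

Domain identity in `build_catalog()` is exact amino-acid identity of the
28-aa unit, collapsing synonymous changes; a nucleotide-level mode
(`level = "nt"`) supports DNA-allele-style analyses. Codes are assigned in
order of first appearance over inputs sorted by (species, record id):
the numbering is deterministic but intentionally not meant to match any
hand-assigned published labels. Heterozygosity is reported as an exact
fraction alongside the percentage.

## Pseudogene scanning

`scan_orf()` reports 1-based stop-codon indices; "residues before the first
stop" counts amino acids strictly preceding it, and equals the full
translated length when there is no stop. With `frame = "auto"` the frame
minimising the stop count is chosen (ties by C2H2 motif count, then lowest
frame). Stops confined to the final two codons are treated as natural
terminators and do not trigger the `disrupted` classification, so ordinary
C-termini are not misclassified. `detect_frameshift()` aligns the query
against tandem copies of an 84-nt consensus unit and flags only indels
whose length is not a multiple of 3; an alignment identity below 50% is a
no-call. Gap placement within homopolymer context is inherently ambiguous,
so flagged positions should be read with a few nucleotides of slack.

## The codon model

Selection on the repeat units is tested with Goldman-Yang (GY94) codon
models over the 61 sense codons. Codon equilibrium frequencies are F3X4
(products of position-specific nucleotide frequencies renormalised over
sense codons; an absent nucleotide at a position receives a 0.5 pseudocount).
Rates are zero for multi-nucleotide changes and otherwise
$q_{ij} = \pi_j \cdot \{1, \kappa, \omega, \kappa\omega\}$ for
(synonymous/nonsynonymous) x (transversion/transition). Site models are
mixtures over $\omega$ classes sharing $\kappa$ and $\pi$:

* **M0**: one $\omega$;
* **M1a**: $\omega_0 < 1$ with weight $p_0$, $\omega_1 = 1$;
* **M2a**: adds $\omega_2 > 1$ with weight $p_2$;
* **M7**: $\omega \sim \mathrm{Beta}(p, q)$;
* **M8**: beta plus a point mass $\omega_s \ge 1$ with weight $1 - p_0$.

The beta is discretised into $K = 10$ equal-probability categories at
quantile midpoints (the category probabilities sum to 1 and the
discretised mean converges to $p/(p+q)$ as $K$ grows).

A single matrix is scaled so its expected rate $\sum_i \pi_i(-q_{ii})$ is 1;
a mixture is scaled by the weight-averaged expected rate across classes, so
branch lengths are expected substitutions per codon under the fitted
mixture rather than per class. Transition probabilities are computed by
eigendecomposition of the reversible generator in the
$\pi^{1/2}$-symmetrised basis — exact and stable for reversible models —
and likelihoods by Felsenstein pruning with per-pattern rescaling
(implemented in C++); missing states (shorter arrays stacked against longer
ones) marginalise over all 61 codons, which is exactly equivalent to
pruning the taxon from the tree at that column. A strict equal-length mode
refuses mixed unit counts for analyses restricted to individuals carrying
the same repeat number.

## Alignment and tree

Because the units are fixed-length tandem repeats, the codon alignment is
built by unit-indexed stacking — column $(u, k)$ is codon $k$ of unit $u$ —
rather than by a general-purpose aligner; the leading conserved finger is
excluded by default (flag to include). When no externally estimated tree is
supplied, the fixed tree is neighbor joining on codon p-distances followed
by joint maximum-likelihood estimation of all branch lengths under M0
(L-BFGS-B on log branch lengths); the site-model fits then condition on
those fixed branch lengths. Negative NJ branch lengths are clipped to zero
with a warning, and agglomeration order is made deterministic by sorting
taxa lexicographically.

## Fitting, tests, BEB

Fits maximise the pruning likelihood over the model's free parameters with
branch lengths fixed, using derivative-free Nelder-Mead on transformed
parameters: $\omega_0 \in (10^{-4}, 1)$ and $\omega_2, \omega_s \in (1, 50)$
through logistic boxes, proportions through logistic stick-breaking, beta
shapes in $(0.005, 99)$ and $\kappa \in (0.01, 100)$ on log scale. Three
deterministic starts are used by default; fitting an alternative model with
`null_fit =` its nested null adds a start embedded at the null optimum
(e.g. M2a at $p_2 \to 0$), which structurally guarantees
$\ln L_{\mathrm{alt}} \ge \ln L_{\mathrm{null}}$ at the optimum.
Convergence is the optimiser's own criterion (relative tolerance $10^{-8}$);
non-convergence returns the best point flagged `converged = FALSE`.

Both likelihood-ratio tests (M1a/M2a, M7/M8) use $2\Delta\ell$ against
$\chi^2_2$, the common codeml convention. Because the null sits on the
boundary of the alternative, the test is conservative; the package
documents this rather than applying a boundary correction, and its null
simulations (below) confirm a type-I error well under the nominal level.
The statistic is clipped at zero for reporting, and stars mark
$p < 0.05$ and $p < 0.01$.

BEB follows the empirical-Bayes construction: with $\kappa$, branch lengths
and the rate scale fixed at the MLE, a uniform prior grid is laid over the
site-class parameters — for M2a, 10 midpoints each for
$\omega_0 \in (0,1)$ and $\omega_2 \in (1,11)$ and the 45-point triangle
grid for $(p_0, p_1)$; for M8, 10 midpoints each for $p_0$ and $\omega_s$
with the beta shapes held at their MLE. Per-site class posteriors are
averaged over the grid weighted by each grid point's data likelihood.
Fixing the rate scale at the MLE mixture lets the per-class site
likelihoods factor over the unique $\omega$ values of the grid, so the
whole grid needs only ~21 (M2a) or ~20 (M8) pruning passes. Sites with
posterior probability of the positive class above 0.95 are flagged and
mapped through the unit/offset bookkeeping to helix position labels where
the column falls on a contact position.

## The synthetic-data generator

`simulate_population()` emulates a diploid multi-species length-variant
panel: per species, a domain pool is realised by mutating a species
consensus (substitutions biased toward contact positions -1, 2, 3, 6 by a
configurable multiplier, default 5; zinc-coordinating anchors are never
touched and substitutions never introduce Cys or His, so every simulated
unit stays a valid C2H2 finger); each allele letter becomes one fixed
haplotype of 6-12 units drawn from the pool; animals draw allele pairs by
the species' frequency table. The default panel has five species with
frequency shapes typical of such screens: one species fixed for a single
short allele, one nearly fixed (95.6% / 4.4%), one with the full C-G range.
Units never contain indels — the 84-bp periodicity is exact — and lesions
exist only where `simulate_pseudogene()` plants them explicitly. The
generator does **not** model unequal crossing-over, concerted-evolution
dynamics, sequencing error or demography, so passing tests demonstrate
correctness of the decomposition/cataloguing machinery on clean
minisatellites, not robustness to assembly artefacts in real amplicons.

`simulate_codon_alignment()` draws a class per site and evolves a root
codon (drawn from $\pi$) down the tree with exact `exp(Qt)` transition
sampling under the same mixture scaling the fitter uses, recording the true
class of every site. All generators are pure functions of (config, seed).

## Experiment sizes and numerical choices

The package's simulation experiments (in the test suite and the acceptance
script) use fixed seeds and these problem sizes, chosen to give stable
statistical conclusions at interactive runtimes:

* decomposition recovery: 200 arrays spanning 6-12 units;
* pruning-vs-enumeration oracle: all tree shapes with up to 4 leaves,
  up to 3 sites, mixtures of 1-3 classes, tolerance $10^{-8}$;
* nesting / LRT sanity: 20 datasets, 5 taxa x 60 codons;
* type-I error of M1a-vs-M2a: 100 null replicates, 6 taxa x 150 codons
  (observed rate 0.03 at nominal 0.05, consistent with the boundary-null
  conservativeness; the acceptance bound is 0.075);
* parameter recovery: 10 replicates at 6 taxa x 500 codons under M2a with
  $p_2 = 0.2, \omega_2 = 5$; $\hat p_2$ within $\pm 0.1$ and
  $\hat\omega_2 > 1$ required in at least 9 of 10;
* BEB recovery: 12 taxa x 200 codons under $p_2 = 0.15, \omega_2 = 8$ —
  the 12-taxon tree mirrors the scale of a pooled multi-species haplotype
  panel, where per-site information is sufficient for high-confidence
  flagging; at least 80% of true positive-class sites must be flagged at
  posterior > 0.95.

Degenerate inputs are handled explicitly: empty FASTA files, duplicate ids
and non-nucleotide characters are errors naming the record; arrays without
any C2H2 motif raise `not a ZF array`; observed stop codons in a selection
alignment are a hard error naming the record (pseudogenes must be routed to
the scan, which the pipeline does automatically); per-species selection
groups with fewer than 3 distinct haplotypes are reported as
"insufficient data" rather than fitted.

## Known limitations

* The paralog classifier is a local global-alignment identity rule over
  user-supplied exemplar references; it does not perform k-mer database
  search, and reference choice determines the labels.
* Codon frequencies are F3X4 only; branch models, branch-site models and
  among-site rate variation in the sense of a gamma alpha are out of scope
  (site-model fits condition on fixed branch lengths).
* The unit-stacked alignment assumes unit homology follows array position
  from the start; arrays related by internal duplications or deletions of
  middle units will be stacked positionally, not by descent.
* Helix-position mapping uses the modal His1 anchor across the input
  units; arrays with heterogeneous anchor offsets map only approximately.
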