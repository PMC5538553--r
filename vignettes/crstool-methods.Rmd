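---
title: "Scoring conserved RNA structures with crstool: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring conserved RNA structures with crstool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crstool)
```

## The problem

A conserved RNA structure (CRS) is a region of a multiple alignment whose
predicted base-pairing pattern is maintained across species. The strongest
comparative evidence for such a structure is *compensatory substitution*:
two alignment columns change together in a way that preserves pairing (for
example GC in one clade, AU in another). `crstool` provides the statistic
that quantifies this evidence for a *given* structure-annotated alignment —
it consumes the output of a structural motif finder, it does not rediscover
motifs — plus the null models and downstream annotation statistics needed to
turn raw scores into calibrated calls.

## The three-model score

For an alignment with consensus structure (pair set $P$, unpaired set $U$) on
a phylogeny $T$, three substitution processes are compared:

* a **structured model**: a reversible 16-state process on ordered
  dinucleotides, applied jointly to the two columns of each pair in $P$;
* a **conserved single-nucleotide model**: a reversible 4-state GTR process;
* a **neutral model**: the conserved model with branch lengths multiplied by
  $\rho > 1$, capturing poorly conserved or misaligned regions.

Every column (or column pair) is scored by its likelihood under Felsenstein's
pruning algorithm, with gaps and ambiguity codes marginalised as missing
data. Writing $\ell$ for log2 likelihoods, the score is

$$\Delta_{cons} = \sum_{(i,j)\in P} w_{ij}\,
  (\ell^{pair}_{ij} - \ell^{cons}_i - \ell^{cons}_j), \qquad
\Delta_{neut} = \sum_{(i,j)\in P} w_{ij}\,
  (\ell^{pair}_{ij} - \ell^{neut}_i - \ell^{neut}_j)
  + \sum_{i\in U} (\ell^{cons}_i - \ell^{neut}_i),$$

$$\text{pscore} = \min(\Delta_{cons}, \Delta_{neut}) \quad \text{(bits)}.$$

The structured model must outscore *both* unstructured alternatives: the
$\Delta_{cons}$ arm guards against conserved-but-unstructured columns, the
$\Delta_{neut}$ arm against poorly conserved regions where the structured
model would beat the conserved model by accident. Unpaired columns cancel
exactly in $\Delta_{cons}$, so evidence for structure can only come from
paired columns; a structure with $P = \emptyset$ can never score positively.

### Model parameterisation

The shipped parameterisation is a deliberate, documented stand-in for a
trained model, built from three transparent ingredients:

* `build_gtr(pi, exch)` — $Q_{ij} = r_{ij}\pi_j$, detailed balance by
  construction, normalised to one expected substitution per unit time.
* `build_pair_model()` — the independence backbone $Q_{16} = Q \oplus Q$
  (Kronecker sum), $\pi_{16} = \pi \otimes \pi$, made structure-aware by a
  stationary bias for the six canonical pairs (default 8 for Watson–Crick,
  3 for GU/UG) and an exchange-rate boost (default 4) between canonical
  pairs, which is what generates compensatory double substitutions.
* `score_models(rho = 3)` — the neutral rate multiplier.

**Rate normalisation of pair models.** Pair models are normalised to an
expected rate of 2 per unit time, i.e. 1 per nucleotide. This is forced by an
exact identity we consider non-negotiable: with no stationary bias and no
exchange boost the pair model must be *exactly* the product of two
single-site processes, so that the pair/single log-odds of any data is
identically zero ("null neutrality"). Normalising the 16-state generator to
rate 1 would silently halve its time scale and break this identity.

### Thermodynamic weights

The weight $w_{ij} \in [0,1]$ emphasises pairs that sit in thermodynamically
stable contexts. For each row, columns $i$ and $j$ are mapped to positions of
that row's ungapped sequence, and the row contributes its equilibrium pairing
probability at those positions (0 if either column is gapped); $w_{ij}$ is
the mean over rows. Pairs gapped in more than half the rows (configurable
`gap_cap`) get weight 0 — an explicit, simple stand-in for a base-pair indel
model.

Pair probabilities come from an inside–outside (McCaskill-style) recursion
over all pseudoknot-free structures under a minimal pair-additive energy
model: each structure's energy is the sum of its pair energies
(GC $-3$, AU $-2$, GU $-1$ in arbitrary units, inverse temperature
$\beta = 1$, minimum hairpin $h = 3$), with no stacking, loop or dangle
terms. The model is intentionally small enough that the dynamic program is
verified against exhaustive structure enumeration for every sequence up to
12 nt; a full nearest-neighbour engine can be substituted by supplying its
probabilities through the same interface. The exterior recursion conditions
on the closest enclosing pair and costs $O(n^4/24)$ in the worst case —
perfectly fine for the few-hundred-nt windows this toolkit targets, and not
intended for whole transcripts.

```{r}
p <- basepair_probabilities("GGGAAACCC")
round(p[1:3, 7:9], 3)  # the hairpin stem dominates
```

## Null models and FDR calibration

The pscore scale depends on the models, the tree and the weights, so
thresholds are calibrated against a null rather than fixed. Two transparent
null modes bracket a full dinucleotide/GC-fitting alignment simulator:

* **shuffle** — jointly permutes alignment columns: per-column conservation
  and gap patterns survive, covariation between the structure's paired
  columns is destroyed. This is the conservative null used in the shipped
  benchmark.
* **evolve** — evolves fresh sequences down the tree under a GTR whose
  stationary GC matches the source alignment, reusing the source gap mask.

`dinucleotide_shuffle()` (Altschul–Erickson Eulerian shuffle) preserves mono-
and dinucleotide counts exactly and is available for sequence-level controls.

`estimate_fdr()` counts, per GC bin and score threshold $t$,
$\mathrm{FDR} = \min(1,\; N_{null}(\ge t) / N_{real}(\ge t))$, with mean and
SD over null replicates, one score per source alignment. GC binning matters
because score distributions shift with base composition; the default bins
(0–0.2–0.4–0.65–0.8–1) single out the common 20–65% GC range.
`calibrate_threshold()` picks the smallest threshold whose pooled estimate
meets a target FDR — the calibration logic a screen would use instead of any
fixed score cutoff.

## Downstream annotation statistics

* `stratified_enrichment()` — midpoint-overlap counts against a feature set,
  stratified by (GC, sequence identity) bins of 100-bp windows; per bin a
  one-sided Z-test $z = (q - np)/\sqrt{np(1-p)}$ with $p$ the feature
  coverage fraction, refused below 1 kb feature coverage, BH-corrected
  across bins; fold enrichment $q/(np)$.
* `conserved_site_fet()` — one-sided exact hypergeometric test for 2×2
  conservation tables, odds ratio $ad/bc$.
* `selection_ratio()` — purifying selection iff both $d_{CRS}/d_{AR}$ and
  $d_{CRS}/d_{Inter}$ fall below 0.95.
* `empirical_pvalue()` / `expression_calls()` — add-one-smoothed rank
  p-values against background loci, expressed at $p < 0.01$.
* `cpm_rle_normalize()` — median-of-ratios size factors, CPM on effective
  library size.
* `call_islands()` — capture-seq read islands: ≥50%-repeat reads removed,
  reads replaced by 150-nt 5'-anchored intervals, overlapping (not abutting)
  unified reads merged per strand, on-target islands tested against the
  off-target count distribution at $p < 0.1$.
* `exosome_sensitivity()` — $s = \max((E_{exo}-E_{ctr})/E_{exo}, 0)$;
  stable $\le 0.25$, unstable $\ge 0.75$.
* `probing_lfc()` / `probing_concordance()` — per-position
  $\log_2(denatured + 5) - \log_2(native + 5)$ on depth-normalised
  termination counts, paired iff lfc $> 1$ (strict); concordance is the
  per-nucleotide fraction of structure-paired positions called paired.

Coordinate conventions are fixed once: BED intervals are 0-based half-open
(abutting intervals do not merge — "overlapping" is taken literally),
alignment columns are 1-based. Sequence identity uses the gap-included
denominator: a column gapped in either row is a mismatch, divided by the full
alignment length; single-row alignments report SI 1 with a warning rather
than NaN.

## The synthetic world

Every generator is a pure function of its seeded configuration
(`sim_config()`), so the whole pipeline is testable offline:

* `simulate_structured_alignment()` evolves paired columns jointly under the
  16-state model (compensatory changes arise from the substitution process
  itself, not post-hoc swaps) and unpaired columns under the 4-state model.
* `simulate_read_counts()` draws negative-binomial counts
  (default mean 50, size 0.3 — overdispersion is the norm in RNA-seq) with
  per-sample scale factors.
* `simulate_probing_counts()` constructs termination counts that satisfy the
  lfc pairing rule with probability $1 -$ `probing_noise` by construction,
  so noise-free profiles give concordance exactly 1.

The shipped benchmark world — fixed before any benchmark was run — is a
balanced 8-leaf tree with branch lengths 0.25, 60-column alignments with 9
base pairs (30% of columns paired), scored with the default models. What a
green benchmark establishes: the statistic separates compensatory covariation
from conservation-preserving column shuffles (AUC ≥ 0.9) and FDR calibration
against that null transfers to realized error. What it does not establish:
performance on real genome alignments with indels, alignment error,
heterogeneous trees, or the paper-scale score distribution — the synthetic
world has no indel evolution (gap masks are copied), no misalignment, and a
stand-in parameterisation.

## Numerical choices and limitations

* Matrix exponentials use the cached eigendecomposition of the
  detailed-balance-symmetrised generator; round-off negatives above
  $-10^{-12}$ are clipped and rows renormalised.
* Distance estimation brackets $t \in [10^{-6}, 20]$ (tolerance $10^{-8}$);
  an optimum at the bracket edge is reported as saturated (`Inf`) with a
  warning. Under Jukes–Cantor the estimate matches the closed form
  $-\tfrac{3}{4}\log(1 - \tfrac{4p}{3})$.
* The enrichment Z-test uses the paper-fixed statistic without continuity
  correction; its agreement with the exact binomial tail (within 10%
  relative error) therefore holds in the large-count regime, which is where
  the test is used — genome-scale counts. The acceptance grid was chosen
  inside that regime by approximation theory, then verified.
* `estimate_fdr` does not enforce monotonicity of FDR in the threshold;
  estimates are reported as measured and clipped to $[0,1]$.
* Partition-function values are unscaled doubles; sequences beyond roughly
  1 kb of strongly pairing sequence could overflow — out of scope for the
  intended window sizes.

## A worked example

```{r}
tree <- read_newick(text = paste0(
  "(((h:0.25,m:0.25):0.25,(c:0.25,d:0.25):0.25):0.25,",
  "((e:0.25,f:0.25):0.25,(g:0.25,i:0.25):0.25):0.25);"))
db <- "....(((((....))))).......((((....))))......................."
cfg <- sim_config(tree, db, seed = 7)
aln <- simulate_structured_alignment(cfg)
res <- pscore(aln, tree)
res

nul <- simulate_null_alignment(aln, tree, "shuffle", seed = 8)
pscore(nul, tree)
```

The structured alignment scores several bits; its column-shuffled control
does not. Scaled to hundreds of alignments, exactly this comparison drives
the FDR calibration in `estimate_fdr()` and the acceptance benchmark in
`tests/testthat/test-acceptance.R`.
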