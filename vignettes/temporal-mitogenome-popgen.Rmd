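---
title: "Temporal mitogenome population genetics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal mitogenome population genetics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mitotempo` compares mitochondrial genome diversity between sample
groups collected at different times — typically an ancient-DNA
collection from archaeological material against a modern reference
panel — and characterises the deeper phylogeographic structure of the
maternal lineage.  This vignette documents the statistical models, the
conventions the implementation commits to, and the reasoning behind the
choices that were genuinely open.

## The analysis model

The data are an equal-length alignment of mitogenome haplotypes over
`{A, C, G, T}` plus missing symbols, with per-sample metadata
(`location`, `era` ∈ modern/ancient, `age_years`).  Analyses operate at
the haplotype level; the mitogenome is treated as a single
non-recombining locus.

### Missing data: pairwise deletion everywhere

`N`, the alignment gap `-`, and every IUPAC ambiguity code are treated
as missing at that site.  All pairwise quantities (nucleotide diversity
π, mean pairwise differences k̄, distance matrices, net divergence)
compare each sequence pair over the sites where *both* are unambiguous,
then rescale: to per-site by dividing by the number of comparable
sites, or to per-locus by further multiplying by the alignment length
L.  Pairwise deletion keeps the full sample size at the cost of mild
heteroscedasticity between pairs; complete deletion would discard most
sites in ancient-DNA panels, where coverage gaps are the norm rather
than the exception.  Gaps are not treated as a fifth state because
indel columns are expected to be removed during alignment curation.

### Haplotype identity under missing data

Two sequences share a haplotype iff they conflict at no site where both
are non-missing.  This compatibility relation is intransitive, so
`collapse_haplotypes()` resolves it greedily in input order: a sequence
joins the first existing haplotype whose *merged profile* (the sitewise
union of its members' observed states) it is compatible with, otherwise
it founds a new haplotype, and the profile then absorbs the new
member's observed states.  The rule is deterministic and order-stable;
with no missing data it reduces to exact identity, which is asserted as
a test invariant.  Alternative rules (complete-linkage compatibility,
nearest-haplotype assignment) change `Nh` by at most the number of
partially missing sequences; the greedy rule matches the common
behaviour of collapsing tools and is documented so results are
reproducible.

### The diversity panel

For each group the panel reports `N`, polymorphic sites `Np` (≥ 2
distinct non-missing states), `Nh`, sites with any missing state `Nm`,
and:

* **π** — mean per-site pairwise difference (per site, so values like
  0.005 for a diverse marine fish);
* **h** — haplotype diversity `N/(N−1) · (1 − Σ pᵢ²)`;
* **θ_W** — Watterson's estimator `Np / a1(N)`, reported *per locus*
  (values of tens for a ~16.7 kb mitogenome), matching the scale such
  studies print alongside per-site π;
* **Tajima's D** — `(k̄ − Np/a1) / sqrt(e1·Np + e2·Np(Np−1))` with k̄
  the per-locus mean pairwise difference under pairwise deletion.  `D`
  is undefined (`NA`) when `Np = 0`, or in the degenerate small-n cases
  where the variance estimate is non-positive.

Significance stars for D use Tajima's beta-distribution approximation
of the null density (two-sided, flagged at p < 0.05).  That
approximation is the standard default when no permutation scheme is
specified; note that the exact finite-sample mean of D under neutrality
is slightly *negative* (≈ −0.1 for n = 20 at moderate θ, confirmed
against an independent coalescent simulator during development), so D
values near zero should not be over-interpreted.

Net divergence between groups, `D_A = d_XY − (d_X + d_Y)/2`, estimates
`2μT` under clean isolation; with a fast-evolving control region a few
percent of saturation loss (Jukes–Cantor, unrejected multiple hits) is
expected at divergences in the 10⁵–10⁶-year range.

### Rarefaction

Expected distinct-haplotype counts at subsample sizes `m = 1..N` are
computed by drawing random sample orderings and counting first
occurrences cumulatively, so one permutation yields every `m` at once.
Default 1,000 replicates; the seed is a required argument.

## Structure tests

**AMOVA.** The pairwise difference-count matrix is used directly as the
squared-distance matrix (for haplotype indicator coding the difference
count *is* a squared Euclidean distance up to a constant that cancels
from every Φ).  Sums of squares follow the standard hierarchical
decomposition (among groups / among populations within groups / within
populations), with the usual unequal-size coefficients for the variance
components.  Permutation nulls follow the conventional scheme:
individuals among all populations for Φ_ST, individuals among
populations within their group for Φ_SC, and whole populations among
groups for Φ_CT.  With all sequences identical the Φ statistics are
reported as `NA` rather than 0/0.

**Diversity permutation test.** Observed statistic `|π_A − π_B|`; the
null re-partitions the pooled samples into the original group sizes.
The pooled order is canonicalised and the smaller group size is the one
resampled, so the p-value is exactly invariant to swapping the group
labels.  Default 10,000 permutations.

**Fisher exact test and the bootstrap clade test.** For 2×2 tables the
two-sided p is the exact enumeration of hypergeometric tables whose
point probability does not exceed the observed one; for 2×k the same
criterion is estimated by Monte Carlo over tables with fixed margins
(default 10⁵ draws, ±0.003 at p ≈ 0.7).  The temporal clade test
subsamples the modern panel without replacement down to the ancient
sample size, recomputes the era × clade Fisher p per bootstrap (default
1,000), and reports the full p distribution plus its mean and
2.5–97.5% interval.  The mean is a documented aggregation choice — no
single-number summary of a bootstrap p distribution is canonical — so
the full vector is always returned.

All permutation/bootstrap p-values use the add-one correction
`(1 + exceedances)/(1 + reps)`, which avoids impossible p = 0 at the
cost of ≤ 1/(reps+1) conservatism.

## Haplotype genealogy

Given a tree over haplotype representatives (an externally estimated
tree is preferred input; a neighbor-joining tree from the difference
matrix is the labelled fallback), ancestral sequences are reconstructed
by the two-pass Fitch algorithm: intersection-else-union upward (one
change per union), then downward resolution to the parent's state when
possible, else the lexicographically smallest member (a deterministic
tie-break).  Missing tip states contribute the full state set, so they
never create spurious changes.  Polytomies are resolved arbitrarily
(deterministically) to binary before the passes; the parsimony score is
unaffected.

The genealogy graph then contracts zero-change edges — merging internal
nodes reconstructed identical to a sampled haplotype into that
haplotype — and expands an edge carrying `m` changes through `m − 1`
unsampled intermediate nodes, so *every edge is one nucleotide change*
and the edge count equals the parsimony score (asserted on every
build).  Note that while the score is invariant to re-rooting the input
tree, the resolved ancestral sequences (and hence fine graph structure)
need not be: equally parsimonious resolutions differ by root-dependent
tie-breaks.  The clade partition is what downstream analyses consume,
and that is stable in practice.

**Clade assignment** removes every maximal chain of unsampled degree-2
nodes carrying at least `min_cut_changes` changes and labels the
resulting components.  The default `"auto"` threshold is the longest
such chain, so one dominant deep split yields exactly two clades
without hard-coding any particular change count.  Minor-clade
structure is sensitive to this threshold and no principled universal
value exists, so the threshold is exposed rather than defaulted for
that use.

## The synthetic-data generator

`sim_config()` defaults encode the temporal sampling design the package
targets: 350 modern samples across 10 locations plus 26 ancient samples
aged 200–750 years; a 16,724-site alignment whose final ~6% plays the
role of the fast control region (5.0·10⁻⁸ vs 3.28·10⁻⁹
substitutions·site⁻¹·year⁻¹); two clades that split 650,000 years ago
and are equally admixed today; exponential growth beginning 8,000 years
ago.

* **Coalescent scaling.** Haploid and maternal: each lineage pair
  coalesces at rate `1/(N_f(t) · generation_time)` per year, so
  `E[T₂] = N_f` generations and `θ = 2 N_f g μ` — the standard
  mitochondrial scaling, kept deliberately consistent with the analytic
  expectations in `expected_summaries()` (`E[S] = θ·a1(n)`,
  `E[π] = θ/L`), which the calibration tests verify by simulation.
  Generation time is an explicit knob (default 1 year) because the
  clock rates are per year.
* **Demography.** `N(t) = N₀ e^{−gt}` back to the growth onset and
  constant at the pre-expansion size earlier.  The default growth rate
  `ln(100)/8000` encodes a hundred-fold post-glacial increase.  Each
  clade receives its present-day mixture share of `N0_f`.
* **Calibration of `N0_f`.** Neither a female effective size nor a
  generation time is observable here, so `N0_f = 4·10⁶` was fixed once
  by a calibration run targeting total nucleotide diversity near 0.005
  with the two-clade structure in place (within-clade diversity a few
  10⁻⁴, between-clade divergence `≈ 2μT ≈ 0.8%`); the acceptance tests
  check the resulting π band rather than the input size.
* **Serial tips.** Tips enter the coalescent at their ages; ancient
  ages default to uniform draws in [200, 750] years.  The two clade
  ancestral lineages merge at exactly the split time; a within-clade
  genealogy deeper than the split is resampled (rejection, counted,
  negligible at the defaults).
* **Mutation.** Poisson counts per branch at the summed partition
  rates; each mutation picks a partition proportionally, a site
  uniformly within it, and a Jukes–Cantor change; repeat hits are
  allowed (finite sites).  JC keeps the analytic oracles exact; it is
  *not* a substitution-model fit to real data.

What the generator does **not** emulate: post-mortem DNA damage and
contamination, sequencing/coverage-driven missingness patterns (use the
missing-data handling tests for that), geographic structure among
modern locations (locations are exchangeable labels, matching the
no-structure regime the AMOVA null calibration needs), selection, and
migration beyond the single admixture event.  Passing tests on
simulated data therefore demonstrate estimator correctness and
calibration under this model, not robustness to aDNA artefacts.

## Numerical and reproducibility choices

* Sites are 0-based half-open internally; all user-facing output is
  1-based.
* Incomparable pairs (no shared unambiguous site) are `NA` in distance
  matrices and excluded from means with a warning; AMOVA imputes them
  with the mean comparable distance rather than dropping samples.
* Every stochastic function takes an explicit seed; the pipeline
  derives per-stage seeds as a deterministic hash of (global seed,
  stage name), so toggling one stage never shifts another's stream.
  Report bundles rerun byte-identically; the manifest records md5s and
  omits machine-specific paths.
* Test problem sizes: oracle equivalence uses ≥200 random alignments
  (N ≤ 20, L ≤ 50) and exhaustive Fitch on ≤ 6-tip trees; calibration
  uses n = 20 with 2,000 constant-size replicates, 500 permutation-test
  and 100 AMOVA null runs; recovery uses 200 two-clade replicates at
  L = 2,000; the signature-pattern check runs 50 replicates at the full
  study scale (376 samples, L = 16,724), where per-clade Tajima's D is
  estimated from hundreds of segregating sites rather than the noisy
  handful a short alignment yields.

## Known limitations

* Φ statistics use raw difference counts; no substitution-model
  correction of distances is offered.
* The Fitch genealogy assumes the input tree is adequate; tree
  uncertainty is not propagated.
* Monte-Carlo Fisher p-values for k > 2 carry ~10⁻³ noise; exact 2×k
  enumeration is not implemented.
* The bootstrap clade test conditions on the clade assignment; clade
  uncertainty is not propagated into its p-values.
* `expected_summaries()` covers only constant-size single-clade
  configurations — it is a validation device, not a general-purpose
  expectation engine.
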