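# mitotempo

Temporal mitochondrial-genome population genetics: did a population
lose genetic diversity over the period spanned by ancient-DNA samples,
and what deeper phylogeographic structure does the maternal lineage
carry?

The package is aimed at studies that combine a modern mitogenome panel
with a smaller set of ancient (archaeological) mitogenomes from the
same species — the motivating setting is a heavily fished marine
species with ~350 modern and ~26 ancient (up to 750-year-old)
sequences.  It provides, behind one consistent missing-data policy
(pairwise deletion):

* **Diversity panel** per population / era / total: polymorphic sites
  `Np`, haplotypes `Nh`, sites with missing data `Nm`, nucleotide
  diversity π (per site), haplotype diversity
  `h = N/(N−1)(1 − Σ pᵢ²)`, Watterson's `θ_W = Np/a1(N)` (per locus),
  and Tajima's `D = (k̄ − Np/a1)/√(e1·Np + e2·Np(Np−1))` with a
  beta-approximation significance flag.
* **Temporal tests**: a permutation test for `|π_modern − π_ancient|`
  (default 10,000 permutations) and a bootstrap-subsampled Fisher exact
  test for shifts in clade frequencies over time (modern panel
  subsampled to the ancient size, default 1,000 bootstraps).
* **Structure**: hierarchical AMOVA (Φ_ST/Φ_SC/Φ_CT with permutation
  nulls, default 1,000) on the pairwise difference matrix.
* **Haplotype genealogy**: Fitch-parsimony reconstruction on a supplied
  (or neighbor-joining fallback) tree, rendered as a graph in which
  every edge is a single nucleotide change; major clades are assigned
  by cutting the longest mutational path.  Net divergence
  `D_A = d_XY − (d_X + d_Y)/2` between clades estimates `2μT`.
* **A serial-sampling coalescent simulator** (two anciently diverged,
  presently admixed clades; post-glacial exponential expansion;
  two-rate control-region/body mutation; heterochronous tips) used for
  calibration and power studies, with analytic expectations for the
  constant-size case.

See `vignettes/temporal-mitogenome-popgen.Rmd` for the models,
conventions and design decisions.

## Worked example

Simulate a small temporal dataset under the default two-clade history
(split 650 kya, hundred-fold expansion from 8 kya) and run the core
analyses:

```r
library(mitotempo)

cfg <- sim_config(n_modern = 60, n_ancient = 8, L = 4000,
                  n_locations = 4)
ds  <- simulate_dataset(cfg, seed = 42)
aln <- ds$alignment

nucleotide_diversity(aln)              # 0.00369
haplotype_diversity(collapse_haplotypes(aln))   # 0.87
tajimas_d(aln)                         # D = 1.77 (p = 0.092)

d   <- pairwise_differences(aln)
gen <- build_haplotype_genealogy(build_nj_tree(d), aln)
gen                                    # 20 haplotype nodes, 46 edges
cl  <- assign_clades(gen)              # 2 clades (cut threshold 28)

diversity_permutation_test(aln,
    aln$ids[aln$meta$era == "modern"],
    aln$ids[aln$meta$era == "ancient"],
    n_perm = 10000, seed = 1)
#> Permutation test: |pi_A - pi_B| = 0.000815 (pi_A = 0.00363, pi_B = 0.00445)
#> p = 0.1124 (10000 permutations, 1123 exceedances)

clade_abundance_test(cl$clades,
    setNames(aln$meta$era, aln$ids), n_boot = 1000, seed = 2)
#> Clade abundance test: 1000 bootstraps of 8 modern samples
#> mean p = 0.8135 (95% interval 0.2821 - 1)
```

Reading: total Tajima's D is positive — the signature of two old,
now-admixed maternal clades inflating intermediate-frequency variation
— while diversity has not changed detectably between eras (permutation
p = 0.11) and clade frequencies are stable over time (mean bootstrap
Fisher p = 0.81).  The genealogy's 46 edges equal its parsimony score;
the auto threshold cut the 28-change path separating the two major
clades.

The same analyses run end-to-end with `run_pipeline()` (or the
`inst/exec/mitotempo` command line), which writes a report bundle
(stats table, AMOVA/permutation/clade-test JSON, GraphML genealogy,
rarefaction TSV) plus a manifest that makes reruns byte-identical.

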