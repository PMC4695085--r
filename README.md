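# symcomm

Analysis of symbiotic and free-living *Symbiodinium* ITS2 amplicon
communities across reef habitat compartments — water column, sediment,
and coral tissue — sampled from two backreef pools with contrasting
thermal regimes. The package is aimed at coral-reef microbial ecologists
who need the full chain from demultiplexed reads to ecological inference
in one reproducible, testable place:

1. **Read QC** — 3' quality trimming at a running-mean threshold of Q25,
   a >6-base homopolymer filter, and IUPAC-aware primer trimming with an
   edit-distance budget of 3.
2. **Hierarchical taxonomy** — clade assignment (A/C/D/F/G) by local
   alignment with Karlin–Altschul e-values (cutoff 1e-20, next-best-clade
   ratio 1e-5); subtype assignment at >97% identity over >90% of the
   reference length, with ties placed at the lowest common ancestor of the
   matched leaves on a clade guide tree (`C_i:52`); greedy de novo
   clustering of novel reads at 97% identity (`C_d:7`).
3. **Community analysis** — Bray-Curtis dissimilarities of square-root
   transformed relative abundances, `d(u,v) = Σ|u−v| / Σ(u+v)`; NMDS
   (Kruskal stress-1, multiple starts); one-way and two-way PERMANOVA with
   sequential sums of squares of the Gower-centered `−d²/2` matrix and
   permutation p-values.
4. **Differential abundance** — a Bayesian Poisson-lognormal GLMM,
   `log λ[s,t] = α[t] + β[t]·I(pool=300) + u[s] + ε[s,t]`, fit by adaptive
   Metropolis-within-Gibbs, with abundances expressed relative to an
   artificial "sum" taxon that absorbs sequencing-depth differences;
   fold-changes with 95% credible limits and Bayesian z-score p-values at
   FDR 0.1.
5. **Spatial autocorrelation** — UTM projection of GPS coordinates and
   one-tailed Mantel tests of geographic versus community distance.
6. **Synthetic data** — truth-known reference databases, communities
   (log-normal library sizes, geometric mean 1,011 × / ÷ 3.8), planted
   between-pool fold-changes, spatial gradients, and error-bearing reads,
   so every stage above is verifiable offline.

## Worked example

```r
library(symcomm)

db <- make_reference_db(seed = 42)            # 20 refs, 5 clades + guide trees
sc <- default_scenario(db, seed = 1)          # two-pool survey design
comm <- simulate_community(sc$design, sc$base_mixture, sc$fold_changes,
                           sc$gradient, sc$depth_params, seed = 2)
comm
#> <sym_counts> 218 samples x 20 taxa, 595,154 reads
#>            300 400
#>   coral     50  50
#>   sediment  30  30
#>   water     28  30

dissimilarity_table(subset_counts(comm, compartment = "water"),
                    n_perm = 999, seed = 1)
#>   subset  n   overall within_pool between_pool        R2 p_value
#> 1  water 58 0.2059203   0.1434286    0.2664033 0.5019138   0.001
```

The water-column pool effect is significant (p = 0.001 at 999
permutations): between-pool pairs are more dissimilar (0.266) than
within-pool pairs (0.143) because of the planted pool-300 fold-changes,
and pool explains half the total sum of squares in this scenario.
Differential abundance on the same subset:

```r
da <- diff_abundance(comm, compartment = "water", q = 0.1, seed = 3,
                     iterations = 4000, burnin = 1500, thin = 3)
head(subset(da, significant,
            select = c(taxon, fold_change, fold_lo, fold_hi, p_value)))
#>   taxon fold_change fold_lo fold_hi   p_value
#> 1    A1      1.3993  1.2123  1.6079 1.121e-05
#> 2    A2      0.2698  0.2242  0.3139 0.000e+00
#> 3    A3      0.4865  0.3955  0.5841 4.219e-15
#> 4    A4      0.5528  0.4220  0.7167 5.801e-05
#> 5    C1      0.1567  0.1370  0.1837 0.000e+00
#> 7    C3      0.6229  0.5120  0.7126 1.235e-06
```

Fold-changes are pool-300 relative to pool-400 abundances (both measured
against the sum taxon). The hundredfold clade-D plant surfaces as
`D1  55.7  [23.2, 80.3]` (compositional renormalization shrinks realized
folds), the suppressed dominant C type as `C1  0.16`, and the remaining
moderate shifts reflect the renormalization of everything else.

An end-to-end run (taxonomy from reads through Mantel tests, with
differential abundance gated on a significant one-way pool effect):

```r
reads <- simulate_reads(comm, db, error_rate = 0.005, seed = 4)
res <- run_pipeline("out/", sc$design, db = db, reads = reads)
```

A thin CLI wrapper for shell use is installed at
`system.file("cli", "symcomm.R", package = "symcomm")` with subcommands
`simulate`, `assign`, `all`, `permanova`, and `mantel`.

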