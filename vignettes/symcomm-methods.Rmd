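---
title: "Methods: hierarchical ITS2 taxonomy and two-pool community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical ITS2 taxonomy and two-pool community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcomm)
```

## Scope

`symcomm` analyses ITS2 amplicon surveys of *Symbiodinium* communities
sampled from three reef habitat compartments — the water column, sediments,
and coral tissue — across two backreef pools with contrasting thermal
regimes (labelled 300, the highly variable pool, and 400, the moderately
variable one). The chain runs from quality-controlled reads to a
sample-by-taxon count table, and from there to beta diversity, ordination,
permutation tests, Bayesian differential abundance, and spatial
autocorrelation. A synthetic generator produces truth-known inputs at every
level so that each stage can be verified without any external download.

## Hierarchical taxonomy assignment

Reads are classified in three tiers.

**Clade.** Each read is aligned locally (Smith–Waterman with affine gaps;
match +1, mismatch −2, gap open −5, gap extend −2) against every reference
of each clade (A, C, D, F, G). Raw scores are converted to e-values with
Karlin–Altschul statistics, `E = K m n exp(-lambda S)`, where `n` is the
total reference length of the clade searched. The defaults
`lambda = 1.23, K = 0.06` were fitted once by moment-matching a Gumbel
distribution to maximal scores of random reads against shuffled reference
sets (`calibrate_evalue()` re-fits them for any database). A read is
assigned to the best clade only when its e-value passes `1e-20` *and* is at
least `1e5`-fold smaller than the next-best clade's. We read the stated
ratio rule as best/next-best ≤ 1e-5, i.e. the winning clade must dominate;
a database hit in a single clade satisfies the ratio trivially. Ambiguous
read bases never score as matches; IUPAC codes in references and primers
match any base in their set.

**Subtype.** Within the assigned clade, qualifying hits must pass the same
e-value cutoff, exceed 97% identity (matches over alignment columns, gaps
counted as mismatches), and span more than 90% of the *reference* length. A
unique best hit labels the read with that reference leaf. Hits are tied when
raw scores agree within a relative `1e-9` and identities agree to four
decimals — a design choice, since "equally matched" needs a concrete
numerical definition — and tied leaves are placed at their
lowest common ancestor on the clade guide tree, labelled `<clade>_i:<node>`.
Guide trees, when not supplied, are built by neighbor-joining on pairwise
global-alignment distances, midpoint-rooted, and internal nodes are numbered
in preorder from 1 so numbering is deterministic.

**De novo.** Reads passing clade assignment but failing every subtype
threshold are clustered greedily within clade at 97% *global* identity
(global rather than local identity — the stricter reading of a 97%
similarity rule): unique sequences are processed in
decreasing abundance with ties broken by the lexicographically smallest read
id, each joining the earliest-founded centroid within threshold or founding
the next cluster, labelled `<clade>_d:<k>` in founding order.

Quality control mirrors a 454-era pipeline: 3' trimming where the trailing
10-base running mean drops below Q25 (window width is a configuration knob;
only the threshold is fixed by convention), discarding reads with
homopolymer runs longer than six bases, and primer trimming by semi-global
edit-distance search allowing three edits, with reads lacking a forward
primer discarded. Upstream vendor steps (dereplication, chimera removal,
denoising) are not reproduced; the synthetic generator emits chimera-free
reads equivalent to post-QC data.

## Community analysis

Counts are converted to relative abundances and square-root transformed, so
dissimilarities reflect dominant and rare taxa alike, then Bray-Curtis
dissimilarities `sum|u-v| / sum(u+v)` are computed between samples.
PERMANOVA partitions the total sum of squares of the Gower-centered matrix
of `-d^2/2` sequentially (Type I), supporting one factor or two crossed
factors with interaction; the two-way design is unbalanced, so term order
matters and defaults to compartment (or species), then pool, then their
interaction. Significance uses free permutation of sample labels with the
`(exceedances + 1)/(n_perm + 1)` correction and 9,999 permutations by
default, enough to resolve p = 1e-4. No strata are imposed, and no
multiple-testing correction is applied across the per-species one-way
tests (fewer than one type I error is expected at ten tests). NMDS
minimizes Kruskal stress-1 via monotone regression (`vegan::monoMDS` as
the engine) over 20 starts — the first the principal-coordinates
configuration, the rest random — declaring convergence when a later start
reproduces the best stress within `1e-6` or matches it under Procrustes
rotation with RMSE below `1e-5`. Taxa are projected into ordinations as
weighted averages for biplots.

## Differential abundance

Within a compartment or species, taxa making up more than 0.1% of the
subset's sequences (strict inequality) are tested; an artificial `sum`
taxon equal to each sample's **pre-filter** depth is appended so the
normalizer reflects true library size. Counts follow a Poisson-lognormal
generalized linear mixed model,

    y[s,t] ~ Poisson(lambda[s,t])
    log lambda[s,t] = alpha[t] + beta[t] * I(pool[s] = 300) + u[s] + eps[s,t]

with a lognormal sample effect `u` (library size) and lognormal
overdispersion `eps`. Priors are Normal(0, 10^2) on fixed effects and
half-Cauchy(2.5) on both standard deviations — weakly informative choices,
exposed in the interface rather than hard-wired. Sampling is adaptive Metropolis-within-Gibbs with elementwise
vectorized proposals and two decorrelating shift moves (`alpha[t]` against
`eps[,t]`, and `u[s]` against `eps[s,]`) that leave the likelihood invariant
and break the strong posterior correlation between intercepts and their
residuals. Proposal scales adapt toward 44% acceptance during burn-in only,
so the post-burn-in chain is a fixed Markov kernel; runs are deterministic
given the seed. Defaults are 15,000 iterations, 5,000 burn-in, thinning 10
(1,000 retained draws); split-R-hat and effective sample sizes are reported
for the pool contrasts.

Per draw, the relative abundance of taxon `t` in pool `p` is
`exp(eta[t,p] - eta[sum,p])` and the pool-300/pool-400 fold-change is their
ratio, summarized by posterior means and 2.5/97.5 percentiles. Significance
uses the Bayesian z-score of the contrast `beta[t] - beta[sum]`
(`p = 2(1 - Phi(|mean|/sd))`) with Benjamini–Hochberg control at FDR 0.1.
Because abundances are compositional, planting an `f`-fold change on a
taxon with baseline share `p` yields a realized fold of `f / (1 + p(f-1))`
after renormalization — a hundredfold rise is only observable for taxa rare
at baseline, which is how the synthetic scenario plants its clade-D effect.

## Spatial autocorrelation

GPS coordinates are projected to universal transverse Mercator (zone taken
from the data centroid; Ofu Island falls in zone 2S) using the standard
ellipsoidal series, with a local equirectangular fallback; over a pool's
~100 m extent the two agree to well under a meter. Geographic distance is
Euclidean on the projected plane, not great-circle. The Mantel statistic is
the Pearson correlation of the lower triangles of the geographic and
community distance matrices, tested by simultaneous row/column permutation
with 999 permutations, one-tailed for positive autocorrelation
(matching the convention of the distance-ecology packages; the tail is
configurable). Samples without
coordinates are dropped from spatial analysis only — field surveys routinely lose GPS
records for a subset of samples, and the community analyses should not
lose them too.

## Synthetic data generator

`make_reference_db()` evolves a random 330-nt ITS2-like root into five
clade ancestors (0.3 expected substitutions/site) and then into leaves
along random coalescent trees scaled to a within-clade divergence of 0.05;
the generating trees ship as guide trees so LCA placements are scoreable.
`default_scenario()` encodes the study system's survey design — water along three
shore-parallel transects (n = 28 and 30 per pool), sediment throughout each
pool (n = 30 each), ten coral species at five colonies per pool — with
compartment-level clade mixtures chosen to emulate the system's typical
patterns
(water dominated by C and A; sediment C, A, D; coral mostly C with D;
read-weighted overall roughly three-quarters clade C), Dirichlet spread
within clades, planted pool-300 fold-changes (a hundredfold clade-D rise
against a rare baseline, moderate two-way shifts in C and A types), and a
0.03/m cross-shore gradient on clade-A taxa. Library sizes are log-normal
with geometric mean 1,011 and geometric standard deviation 3.8.
`simulate_reads()` copies source sequences with independent substitution
errors (default 0.005/base), an optional indel mode to exercise the
homopolymer filter, and optional primer attachment. All generators are
byte-deterministic under a fixed seed.

What the generator does *not* emulate: platform-specific homopolymer error
spectra, chimeras, PCR abundance bias, and intragenomic ITS2 variation.
Passing tests therefore demonstrate correctness of the algorithms under a
clean substitution-error model, not robustness to every artifact of real
pyrosequencing data.

## Verification sizes and numerical choices

The test-suite and acceptance runs use problem sizes chosen to finish in
minutes while keeping the statistical checks at their stated strength:
exhaustive permutation oracles at n ≤ 7; null calibration with 1,000
simulated datasets (n = 20, 199 permutations each) where the rejection rate
at alpha = 0.05 must fall in the binomial 99% band [0.033, 0.069];
differential-abundance recovery over 50 replicates per condition (10
samples/pool, depth ~1,000, 4,000 MCMC iterations — enough for >100
effective draws of every contrast in these designs); and an end-to-end
pipeline run on a reduced design (12 water, 10 sediment, 8 coral samples;
geometric mean depth 150) with full-design statistics exercised separately
on a simulated count table. Degenerate inputs are handled explicitly:
zero-sum samples are dropped with warnings, Bray-Curtis between two empty
samples is an error, ties in permutation statistics count as exceedances
(conservative), and a degenerate posterior with zero contrast variance
yields p = 1 rather than a division error.

## Known limitations

- E-value calibration is Gumbel moment matching, adequate for thresholding
  at 1e-20 but not for precise tail probabilities.
- The single-chain split-R-hat diagnostic can miss multimodality; for
  publication-grade fits run several seeds.
- Sequential (Type I) sums of squares make two-way PERMANOVA results depend
  on term order in unbalanced designs; the order is configurable and both
  crossings can be run.
- The z-score significance rule assumes an approximately Gaussian contrast
  posterior; a posterior-tail-probability flag is the natural alternative
  when that fails.
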