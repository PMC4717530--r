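# phyloniche

Phyloclimatic analysis of macroecological niche evolution in R.

`phyloniche` is for evolutionary ecologists asking how broad-scale
climatic niches evolve across a dated species phylogeny: whether niches
are conserved or labile, whether transitions between them are
directionally asymmetric, and when they happened. It was built around
the analysis of a Madagascan epiphytic orchid clade (~30 species, ~600
georeferenced records, crown age ~5.3 Ma) whose species occupy three
macroecological niches — a hot, seasonally dry north-western lowland
(*A*), a warm, wet aseasonal eastern lowland (*B*), and a cold central
highland (*C*) — but every stage takes generic inputs and ships with a
seeded synthetic-data generator, so the full pipeline runs and is tested
without any external downloads.

The pipeline, stage by stage:

1. **Niche identification.** Occurrence records carrying altitude plus
   the 19 bioclim layers are fuzzy-clustered (fuzzy C-means) on raw
   environmental distances; the number of clusters K = 2..15 and the
   fuzziness exponent m = 1.1..2.0 are selected by a 140-combination
   sweep over seven validity indices (partition coefficient and entropy,
   Xie–Beni, Dunn, Fukuyama–Sugeno, fuzzy hypervolume, average partition
   density), with consensus by "optimal or next-to-optimal" support.
2. **Ordination.** Covariance PCA of the environmental matrix, cluster
   centroids in PC space, Mann–Whitney U tests between clusters on
   PC1/PC2 (with a Kolmogorov–Smirnov normality check motivating the
   rank tests).
3. **Niche models.** A simplified presence–background maximum-entropy
   model per cluster (linear + quadratic features, L1-regularized,
   background = all land cells), bootstrap AUC evaluation (70/30
   splits, removal flag below 0.7), max sensitivity-plus-specificity
   thresholding, Jaccard range overlap, and predicted niche occupancy
   (PNO) profiles — unit-area histograms of a variable weighted by raw
   suitability.
4. **Tip coding.** Species become discrete niche states by majority
   cluster, polymorphic when a second cluster holds ≥ 1/3 of the
   species' localities. The published count table of the study clade is
   packaged (`clade_c_counts()`, `clade_c_coding()`).
5. **Ancestral niches and transition tests.** A 3-state continuous-time
   Markov (Mk) model with Felsenstein pruning over ambiguous tips;
   Metropolis–Hastings MCMC over the six rates q_AB … q_CB with an
   exponential rate prior whose mean is hyper-sampled on (0, 30], a
   rate-proposal window (`ratedev`) of 250, and optional tree-ensemble
   moves; harmonic-mean marginal likelihoods; Bayes factors
   2·Δlog ML comparing the full model against seven constrained models;
   marginal ancestral states; transition counting on the chronogram
   with a clade-support filter (PP > 0.95) and Quaternary (≤ 2.6 Ma)
   binning.
6. **Phylogenetic signal.** Blomberg's K with tip-shuffling permutation
   tests (999 permutations) per trait over a tree ensemble, summarized
   as median K, median p, and the percentage of trees not rejecting the
   null.

## Worked example

```r
library(phyloniche)

## published per-species niche counts -> state frequencies
coding <- clade_c_coding()
state_frequencies(coding)
#>    A    B    C
#>  9.5 11.5 12.0

## synthetic landscape, occurrences, and the validity sweep
grid  <- gen_env_grid(30, seed = 1)
specs <- default_niche_specs(grid)
occ <- gen_occurrences(grid, specs,
                       list(sp1 = list(niche = "A", count = 40),
                            sp2 = list(niche = "B", count = 40),
                            sp3 = list(niche = "C", count = 40)),
                       seed = 2)
sweep <- model_selection_sweep(env_matrix(occ), k_range = 2:6, seed = 3,
                               max_iter = 50)
sweep
#> Validity sweep: 50 combinations (K in 2..6, m in 1.1..2)
#>   PC    (max) optimum at K = 3, m = 1.1
#>   PE    (min) optimum at K = 3, m = 1.1
#>   XB    (min) optimum at K = 3, m = 2.0
#>   Dunn  (max) optimum at K = 3, m = 1.1
#>   FS    (min) optimum at K = 6, m = 1.1
#>   FHV   (min) optimum at K = 4, m = 1.2
#>   APD   (max) optimum at K = 4, m = 1.2
#> Consensus: K = 3, m = 1.1 (supported by 3 index/indices)

## Mk MCMC on a simulated 30-tip chronogram (reduced chain)
tr   <- sim_tree(30, root_age = 5.3, seed = 5)
tips <- sim_discrete_character(tr, sim_q(qAB = 1.5, qAC = 0.15,
                                         qBA = 1.5, qBC = 0.3,
                                         root = "B"), seed = 6)
post <- mk_mcmc(tr, data.frame(species = names(tips),
                               states = unname(tips)),
                "full", generations = 2e5, burnin = 4e4, thin = 100,
                seed = 7)
summary(post)
#> Mk posterior: 1600 samples (200000 generations, burn-in 40000, thin 100)
#>   acceptance rates: rate 0.08, mu 0.85, tree 1.00
#> Posterior rate means (per Ma):
#>     qAB     qAC     qBA     qBC     qCA     qCB
#> 12.8815 17.1580 12.2917 17.5385  3.9975  3.8201
#> Harmonic-mean log marginal likelihood: -24.925 (SE 0.290)
```

The frequency table splits each species evenly over its coded states
(a species coded "A|C" contributes 0.5 to each), so the three niches
end up nearly equally occupied at the species level. The sweep's
consensus (K = 3) recovers the three generating regimes, and the hard
assignment separates them perfectly on this fixture. In the Mk summary,
large posterior means with a log marginal likelihood near the
saturation value are typical for short chains on small trees; the
Bayes-factor machinery (`bayes_factor_table()`,
`reproduce_transition_models()`) compares such chains across
constraint masks.

A single call runs everything end to end on synthetic data:

```r
cfg <- analysis_config(seed = 11,
                       mcmc = list(generations = 2e5, burnin = 4e4,
                                   thin = 100))
run_pipeline(cfg, out_dir = "run1")   # writes CSV/TSV/JSON + manifest
```

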