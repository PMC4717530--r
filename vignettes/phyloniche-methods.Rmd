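---
title: "Models and methods behind phyloniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyloniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phyloniche` implements a phyloclimatic analysis of macroecological niche
evolution for a clade of tropical epiphytes: occurrence records described
by altitude and the 19 bioclim layers are clustered into broad niches,
each niche is characterized by a presence-background suitability model,
species are coded into discrete niche states, and the evolution of those
states is analyzed on dated phylogenies with a continuous-time Markov
model, Bayes-factor model comparison, transition counting, and
phylogenetic-signal tests. This vignette explains each model, the
parameters that matter, and the design decisions taken where the
methodology left genuine choices open.

## Niche identification: fuzzy C-means and the validity sweep

Records are clustered on their **raw** environmental values (WorldClim
v1.4 units: temperature in °C×10, precipitation in mm). Raw units mean
precipitation variables dominate the Euclidean metric; we keep this
behavior as the default because it is what the standard raw-layer
analysis does, and expose standardization to the caller (cluster any
matrix you like, e.g. `scale(X)`).

Fuzzy C-means minimizes
$J=\sum_i\sum_k u_{ik}^m\lVert x_i-c_k\rVert^2$ by alternating membership
and centroid updates. The fuzziness exponent $m>1$ controls how graded
the memberships are; $m\to1^+$ approaches crisp K-means. Memberships are
initialized from a symmetric Dirichlet(1) draw under the run seed, one
start per combination; the sweep's seed policy (sweep seed + combination
index) makes all 140 fits reproducible and independent of execution
order. Iteration stops when the objective decreases by less than `tol`
(default 1e-9) or after `max_iter` (default 200) iterations.

Model selection sweeps $K = 2..15$ against $m = 1.1, 1.2, \dots, 2.0$
(140 combinations) and scores each fit with seven validity indices:
partition coefficient (max), partition entropy (min), Xie-Beni (min),
Dunn (max), Fukuyama-Sugeno (min), fuzzy hypervolume (min) and average
partition density (max). The first four are the classically named
indices; the last three were chosen from the same index family exposed
by the standard fuzzy-clustering toolkits, and the registry is a plain
named vector so alternates can be substituted. "Next to optimal" support
is operationalized as rank ≤ 2 per index; the consensus combination is
the one supported by most indices, with ties broken toward smaller $K$,
then smaller $m$.

The classical MDS step retains every dimension whose eigenvalue exceeds
$10^{-8}\times$ the largest, which makes it distance-preserving for
Euclidean inputs; clustering the MDS configuration or the raw matrix
therefore yields identical hard labels (tested), so nothing downstream
depends on which path is taken.

## Ordination and group tests

The PCA is a covariance-matrix (centered, unscaled) decomposition by
default, matching the raw-layer clustering; correlation-matrix PCA is a
flag. A deterministic sign convention (largest-magnitude loading
positive per component) removes eigenvector sign ambiguity. Cluster
differences along PC1/PC2 are tested with Mann-Whitney U rather than a
t-test because PC scores of pooled, clustered records routinely fail a
Kolmogorov-Smirnov normality check. The U test uses the exact Wilcoxon
distribution when $n_1 n_2 \le 400$ and there are no ties, otherwise a
tie-corrected normal approximation with continuity correction; two-sided
p values are reported. The KS check estimates the normal parameters from
the sample, which biases p upward (Lilliefors effect); the result
carries that caveat explicitly.

## Simplified maximum-entropy niche models

Per niche we fit a presence-background maxent model with **linear and
quadratic features only** — no hinge, product, or threshold classes.
This keeps the objective a concave, analytically transparent function
while retaining curvature in each variable; full parity with the
reference SDM implementation is explicitly out of scope. Features are
min-max standardized over the masked (land) cells; the background is all
masked cells. The penalized objective is
$$\frac{1}{|P|}\sum_{i\in P}\lambda^\top f(x_i)-\log Z(\lambda)
 -\beta\sum_j s_j|\lambda_j|,$$
with per-feature penalty scale $s_j=\max(\mathrm{sd}_P(f_j),0.05)/\sqrt{|P|}$.
The floor at 0.05 prevents infinite weights on features constant across
presences in separable configurations. Optimization is FISTA (proximal
gradient with momentum, function-value restart, backtracking line
search), declared converged when the L1 subgradient optimality residual
drops below 1e-6 in the infinity norm.

Raw output is the normalized maxent distribution over masked cells; the
logistic output is the standard entropy transform
$e^H p/(1+e^H p)$. Evaluation uses rank-based AUC (midrank ties) over
bootstrap 70/30 presence splits — background cells serve as
pseudo-absences because no true absences exist — with a removal flag at
mean AUC < 0.7. Binary maps use the max sensitivity-plus-specificity
threshold over the sorted unique logistic values (ties toward the larger
threshold), and range overlap is reported as Jaccard percentage
(intersection over union), the single symmetric number per pair; an
intersection-over-smaller-range metric is available as an option.
Predicted niche occupancy (PNO) profiles weight a variable's histogram
by raw suitability over 50 bins (bin count exposed); weights are
renormalized to unit mass.

## Tip-state coding

A species' niche state is the majority cluster of its localities, with
any further cluster holding at least one third of the localities added
as a polymorphism; ties include all tied states. The packaged
transcription of the study clade's published count table adopts, for two
digit-grouping-ambiguous rows, the reading that reproduces the published
record total (604), the per-species maximum (148), and the printed
Coding column; under that reading exactly one species conflicts with the
1/3 rule, and the packaged override file reproduces the printed codes
verbatim (the printed codes drive all downstream comparisons).
`apply_coding()` reports every rule/override discrepancy rather than
resolving it silently.

## Mk model, MCMC and Bayes factors

Niche evolution is a 3-state continuous-time Markov model with six free
transition rates (events/Ma); $P(t)=e^{Qt}$ is computed by
eigendecomposition with a Padé fallback for near-defective generators.
The likelihood is Felsenstein pruning with ambiguous tips: a polymorphic
species contributes an indicator partial over its coded states. The root
prior is uniform over the three states — the common Multistate default;
the prior is a config option (the stationary distribution is an
alternative).

The sampler is Metropolis-Hastings with three uniformly chosen move
types: (i) a window perturbation of one random unconstrained rate
(window width `ratedev`, default 250; negative proposals rejected, which
preserves detailed balance), (ii) a window update of the exponential
rate-prior mean $\mu$ on $(0,30]$ (half-width 2 by default), and (iii) a
uniform redraw of the tree index when a posterior tree ensemble is
supplied, which propagates phylogenetic uncertainty. Defaults mirror the
study-scale run: 5,050,000 generations, 50,000 burn-in, thinning 1,000
(≈5,000 retained samples, matching the scale of the tree sample; the
sampling interval itself was a free choice). Chains start all free rates
at 1.0: starts drawn from the prior occasionally land far above the
likelihood peak and then need very long burn-ins, which biases
harmonic-mean estimates on short chains.

Marginal likelihoods use the harmonic-mean estimator (log-sum-exp
stabilized) for comparability with the reference analysis; its standard
error comes from a moving-block bootstrap with 1,000 resamples, which
respects chain autocorrelation. The estimator is known to be
high-variance — that is precisely why burn-in and initialization care
matter above. Bayes factors are $2(\log ML_{full}-\log ML_{constrained})$
with the usual 2–6 / 6–10 / >10 evidence bands. The model family is the
full model, the six single-rate-zero models, and the model with both
rates out of the highland state set to zero.

The phrase "reversible-jump hyperprior" in the reference methodology
conflates two mechanisms; the load-bearing part for model comparison is
the exponential hyperprior with resampled mean, which is what is
implemented. Full reversible-jump averaging over rate-class partitions
is out of scope.

Ancestral states are **marginal** probabilities by the two-pass
(down/up) conditional-likelihood algorithm, computed per posterior
sample at the MRCA of each node's extant tip set on that sample's tree
and averaged; on discordant topologies the MRCA may subsume extra tips,
which is the standard node-mapping compromise. Transition counting
compares modal states along every parent-child edge of the reference
chronogram; a transition's age is the **child** node's age (0 on
terminal branches) — the methodology bins transitions by period without
defining an edge-dating rule, and child-age is the conservative choice
that also makes every terminal-branch transition Quaternary by
construction. The support filter keeps edges whose child clade has
posterior probability above 0.95, terminal branches passing by
convention; the Quaternary boundary is 2.6 Ma.

## Phylogenetic signal

Blomberg's K uses the closed-form ratio of observed to Brownian-expected
mean squared error under the tree's covariance; it is exactly 1 on a
star tree for any trait (an algebraic identity the tests assert).
Significance comes from permuting trait values across tips and comparing
the variance of standardized independent contrasts; low observed
variance indicates signal, and the reported p is one-sided in that
direction (a two-sided option exists; the reference analysis does not
state sidedness). Species traits are per-species medians of the 20
variables plus PC1/PC2 set to the species' cluster centroid score — so
species sharing a cluster share identical PC traits, deliberately
reproducing the tied-trait construction whose over-dispersion drives the
PC1 behavior in the reference results. Per-tree permutation seeds derive
deterministically from the master seed and tree index.

## The synthetic-data generator

Because the study's occurrence coordinates are unpublished, every stage
is exercised on synthetic data whose defaults mirror the study
conditions:

* **Grid**: a smooth altitude field with a central north-south ridge;
  bioclim layers are deterministic functions of altitude, west-east
  position (moisture) and a seasonality driver concentrated in the
  north-west, plus seeded smooth noise. This produces three separable
  regimes — hot/seasonal north-western lowland (A), warm/wet aseasonal
  eastern lowland (B), cold highland ridge (C) — with pairwise centroid
  distances far exceeding within-regime spread, and a lapse-rate-driven
  negative altitude-temperature correlation.
* **Occurrences**: 33 species (30 ingroup-like + 3 outgroup-like) with
  per-species counts drawn from a log-normal matched to the reported
  moments (mean 18.84, SD 28.71, clipped to [1, 148]), primary niches
  in the reported ~125/249/229 occupancy proportions, and four species
  made polymorphic, mirroring the published table's structure.
* **Trees**: pure-birth (Yule) trees rescaled to an exact root age of
  5.3 Ma with ~30 tips, since the study clade best fits a constant-rate,
  no-extinction diversification model; support values are drawn
  Uniform(0.5, 1).
* **Characters**: exact forward simulation by exponential waiting times
  under an arbitrary (possibly absorbing) rate matrix.

What the generator does **not** emulate: spatial autocorrelation beyond
smooth gradients, sampling bias, georeferencing error, or palaeoclimate
layers. Tests passing on this generator demonstrate the statistical
machinery, not robustness to those real-data pathologies.

The asymmetry-recovery experiment simulates the qualitative
transition-rate regime of the study's conclusions — frequent
lowland-lowland exchange, moderate absorption into the highland state,
no transitions back out of it (qAB = qBA = 1.5, qBC = 0.3, qAC = 0.15,
qCA = qCB = 0, root B, per Ma) — chosen once so that lineages shift
between A and B several times over the clade's depth and roughly half
the tips end absorbed in C, leaving all three states represented in a
typical replicate. Recovery runs use reduced chains (5×10⁵ generations)
with a proportionally longer burn-in (20%) than the study-scale run:
short chains need the larger fraction for the harmonic-mean estimator to
be stable. The prior-recovery validation (data-free likelihood) uses a
narrower rate-proposal window (40) than the data analysis default (250),
because that check targets sampler correctness and needs the chain to
mix across the prior's scale, and 999-style window widths tuned for
peaked likelihoods mix poorly over a heavy-tailed prior.

## Numerical choices and degenerate inputs

* FCM: zero point-centroid distances split the membership mass equally
  over the zero-distance centroids; the objective trace is checked
  non-increasing.
* Validity: indices needing centroid separation are NaN at K = 1;
  singular fuzzy covariances flag the hypervolume indices NA; both are
  reported, never raised.
* MDS eigenvalue floor 1e-8 relative; matrices symmetrized before
  decomposition.
* Maxent: features standardized to [0, 1]; penalty floor 0.05 on the
  presence SD; convergence at 1e-6 subgradient residual, hard failure
  with diagnostics at 1e5 iterations.
* Mk: transition matrices are clamped at zero and row-renormalized to
  absorb eigendecomposition round-off (rows sum to 1 within 1e-10);
  pruning partials are rescaled per node to avoid underflow on large
  trees.
* Trees: ultrametricity tolerance 1e-6 Ma; near-ultrametric input is
  repaired by terminal-branch extension with a warning, or rejected in
  strict mode.
* Ties in hard assignment go to the lowest cluster index and are
  counted; ties in max-SSS thresholds go to the larger threshold.

## Problem sizes used by the shipped tests

The test suite runs the full 140-combination sweep on a ~200-record
synthetic table with a reduced iteration cap; exhaustive-enumeration
checks on 4-tip trees; a 500-replicate Brownian calibration of K on a
30-tip tree; the asymmetry-recovery experiment on 20 seeds of 200-tip
trees at 5×10⁵ generations; and prior-recovery chains of 4×10⁶
generations on 4-tip trees. These sizes were chosen as the smallest at
which each check is statistically meaningful.

## Known limitations

* The harmonic-mean marginal-likelihood estimator is retained for
  comparability; a stepping-stone estimator would be the better default
  in new analyses and is deliberately not wired into the comparison
  path here.
* Node mapping across discordant tree samples by MRCA can merge nodes.
* The simplified maxent omits hinge features, clamping and
  extrapolation diagnostics; suitability surfaces are not comparable to
  full reference-implementation output cell-for-cell.
* The full-fidelity reproduction of the study's transition-model table
  requires the archived 5000-tree ensemble (Dryad doi:10.5061/dryad.35935),
  which is not redistributed here.
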