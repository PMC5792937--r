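---
title: "Methods: maximum-entropy SDMs, null models, and phylogenetic niche conservatism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy SDMs, null models, and phylogenetic niche conservatism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phyloniche` tests whether the abiotic niches of related species are
phylogenetically conserved: whether closely related species occupy more
similar environments than distantly related ones. The question arises
naturally in clades of allopatric or parapatric species — for example
Neotropical understorey trees split into geographically restricted clades by
mountain uplift — where niche similarity across a dispersal barrier, versus
niche divergence along environmental gradients, discriminates between
biogeographic scenarios. The pipeline has four statistical stages, each
usable on its own: maximum-entropy species distribution models (SDMs), a
target-group background null model for SDM significance, Hellinger's *I*
niche overlap, and an overlap-versus-patristic-distance correlation test.
This vignette documents the models, their assumptions, the tunable
parameters, and the numerical choices.

## The maximum-entropy SDM

The geographical domain is the set of valid cells of an aligned raster
stack. Given presence localities for one species, the model is the Gibbs
distribution over cells

$$P_\lambda(i) = \frac{\exp(\lambda \cdot f(i))}{\sum_j \exp(\lambda \cdot f(j))},$$

where $f(i)$ is the feature vector of cell $i$. Among all distributions
whose expected features match the empirical presence averages, this family
contains the one of maximum entropy — the distribution closest to uniform
that is consistent with what the presences say about the environment. We fit
$\lambda$ by minimizing the L1-penalized negative presence log-likelihood

$$-\sum_{k=1}^m \lambda \cdot f(x_k) + m \log Z(\lambda)
  + \sum_j \beta_j |\lambda_j|,$$

which relaxes exact moment matching to
$|E_{P_\lambda}[f_j] - \bar f_j| \le \beta_j / m$ and controls overfitting
at small sample sizes. The raw output is $P_\lambda$ itself: a relative
probability of occurrence per cell, summing to 1 over the domain.

**Features.** Continuous layers are rescaled to $[0,1]$ over the valid
cells. In `auto` mode the feature classes depend on the presence count $m$
(linear always; quadratic from $m \ge 10$; hinge from $m \ge 15$; threshold
and product from $m \ge 80$), following the long-standing defaults of the
reference Maxent implementation. Hinge and threshold features use 50 evenly
spaced knots per layer. Categorical layers contribute one 0/1 indicator per
observed category.

**Regularization.** $\beta_j = r \, \beta_{\text{class}} \, s_j / \sqrt m$,
with a global multiplier $r$ (default 1), per-class constants
$\beta_{\text{class}}$ (linear/quadratic/product/threshold 1.0, hinge 0.5,
categorical 0.25), and $s_j$ the presence-sample standard deviation of
feature $j$. Two departures from the plain formula matter in practice and
were adopted after observing degenerate fits:

* $s_j$ is floored at 0.05 (5% of the scaled feature range). A feature
  constant over the presence sample would otherwise carry no penalty at
  all, and if it also separates presences from background its weight
  diverges.
* Hinge and threshold features use $s_j = 1$, i.e. a sample-size-only
  penalty. High-knot hinges are near-zero almost everywhere, their presence
  standard deviations vanish, and under sd-scaled penalties pairs of
  adjacent knots acquire huge compensating weights (we observed
  $\pm 50$ pairs). The reference R port of Maxent regularizes hinge
  features the same way.

**Optimization.** The objective is convex. We use an active-set strategy:
screen the subgradient (KKT) optimality conditions over all features, grow
the support by at most 20 worst violators per round, and solve each
subspace exactly in the split-variable formulation
($\lambda = \lambda^+ - \lambda^-$, both non-negative, box-constrained
L-BFGS), which handles the L1 kink without smoothing. Convergence is
declared when no feature violates the conditions beyond `tolerance`
(default `1e-5`); the iteration cap defaults to 500. The objective trace is
stored and is non-increasing. Weights are bounded at $|\lambda_j| \le 50$;
reaching the bound — or detecting an unpenalized feature whose presence
mean sits on its background extreme — flags the fit as non-converged
(complete separation has no finite optimum). On a 64×64 domain with ~210
features a fit takes a fraction of a second; full KKT convergence at
`1e-5` needs roughly 2000 iterations, while the default cap of 500 reaches
the same objective to six decimals.

**Background.** All valid cells serve as background up to 10,000 cells;
larger domains are subsampled under an explicit seed.

**Model evaluation.** AUC is computed rank-based (Mann–Whitney): the
probability that a random presence cell outscores a random background
cell, ties counting one half.

## The target-group background null model

A high AUC can reflect nothing more than spatially biased collecting
effort. The null model therefore refits the SDM on random localities drawn
from a *target-group background pool* — the unique cells where any member
of a broader reference clade has been collected, sharing the same
collectors, routes and biases as the focal records. For a species with $n$
localities, `R` replicates (default 100) each draw $n$ cells from the pool
without replacement and are fitted and scored exactly like the observed
model (same feature matrix, same penalties; replicates differ only in
their localities). The replicate AUCs are sorted ascending and the
$\lceil 0.95R \rceil$-th value — the 95th element when $R = 100$ — is the
threshold; the observed model is significant only if its AUC is *strictly*
greater. Species own localities are not excluded from the pool (an option
exists). Under the null (species drawn from the pool themselves) the
expected rejection rate is $3/51 \approx 5.9\%$ at $R = 50$, and our
calibration experiments sit inside the binomial envelope of 5%; one
practical caveat found during development is that the observed and
replicate draws must come from one seeded RNG stream — seeding R's
Mersenne-Twister with related integers for the two produced measurable
stream correlations and a spurious excess of rejections.

## Niche overlap and clade summaries

Overlap between two raw suitability surfaces $p, q$ (each summing to 1 on
the shared domain) is Hellinger's

$$I(p, q) = 1 - \tfrac12 \sum_i \left(\sqrt{p_i} - \sqrt{q_i}\right)^2
  \in [0, 1],$$

1 for identical surfaces, 0 for disjoint supports. *I* is computed on raw
(not logistic) output because the metric is defined on probability
distributions. When masks differ, surfaces are restricted to the
intersection of valid cells and renormalized. Clade-level summaries
average *I* within each clade (over its species pairs) and between clade
pairs (over cross pairs); the "±" reported is the standard error of the
mean over pairs (switchable to SD), singleton clades are listed without a
within value.

## The conservatism test

Pairwise *I* is paired with the patristic distance (sum of branch lengths
on the connecting path) for every species pair present in both matrices,
and the Pearson correlation with a two-sided p from the t transform on
$n_{\text{pairs}} - 2$ degrees of freedom is the primary statistic — the
field's customary test, reproduced deliberately. Pairs share species and
are not independent, so this test is anti-conservative: in our synthetic
null experiments it rejects at roughly 10% instead of 5%. The package
therefore also offers a Mantel permutation test (species labels of one
matrix permuted; two-sided on $|r|$;
$p = (1 + \#\{|r_{\text{perm}}| \ge |r_{\text{obs}}|\})/(1 + n_{\text{perm}})$),
which is exactly calibrated, and we recommend reporting it alongside the
Pearson p. By default, species whose SDM fails the null-model test are
excluded before pairing.

Crown and stem ages are read from ultrametric chronograms: a node's age is
the tree depth minus its root distance; the crown age of a tip set is its
MRCA's age, the stem age its MRCA's parent's age; a single tip has a stem
(its attachment node) but no crown. Ultrametricity is accepted within a
relative tolerance of $10^{-6}$ of the depth, absorbing chronogram
rounding.

## Alignment statistics and indel coding

Site classification counts only unambiguous nucleotides (`A,C,G,T`); gaps,
`?` and IUPAC ambiguity codes are treated as missing — the conservative
common convention. A site is constant (≤1 state), parsimony-informative
(≥2 states each in ≥2 taxa) or variable-uninformative. Simple indel coding
turns each distinct internal gap (identical start and end columns) into a
binary character: 1 for taxa with exactly that gap, 0 for taxa with
contiguous determined sequence across the span, `?` for taxa with a
different overlapping gap (homology unclear) or whose terminal missing
region covers the span. Terminal gaps are never coded — they typically
reflect incomplete sequencing rather than evolutionary events. Marker
summaries can restrict counting to taxa with data in every marker so that
markers are comparable, and order rows by informative-site count.

## The synthetic-world generator

Every pipeline stage is testable without downloads against worlds with
known truth:

* **Landscape** — continuous layers are Gaussian-blurred white noise
  rescaled to $[0,1]$ (spatially autocorrelated, like interpolated climate
  surfaces); categorical layers are quantile-sliced smooth fields
  (contiguous patches).
* **Phylogeny** — a pure-birth tree rescaled to unit depth.
* **Niches** — per-species optima evolve by Brownian motion (rate
  $\sigma^2$) along the tree in the first $k$ continuous layers; this
  *creates* the conserved-niche structure the conservatism test is built
  to detect.
* **Occurrences** — cells drawn without replacement with probability
  $\propto \exp(-\lVert e(i) - \mu \rVert^2 / 2\tau^2)$; records at cell
  centers.
* **Pool** — union of all species' occurrence cells (the target-group
  analogue) or a uniform draw.

Defaults, fixed once: 64×64 grid, 4 continuous + 1 categorical layers,
blur SD 6 cells, 16 tips, $k = 2$, $\sigma^2 = 0.1$ (tip SD ≈ 0.32 on the
unit-depth tree — strong differentiation relative to the unit layer
range), $\tau = 0.15$ (niches occupy a modest fraction of the environmental
range, as for habitat specialists), 30 records per species. Everything is
seeded; sub-seeds for each stage derive deterministically from the master
seed, so a world is fully replayable.

What the generator does *not* emulate: collecting bias within the pool,
spatial sampling error in coordinates, non-equilibrium occupancy,
correlated layers mimicking real climate covariance, or
Ornstein–Uhlenbeck (constrained) niche evolution. Passing tests on these
worlds therefore demonstrate correctness of the estimators under the
stated generative model, not robustness to every property of real data.

## Problem sizes and calibration experiments

The packaged experiments use sizes chosen to make the statistical
behaviour measurable while remaining quick to rerun: the null-model
calibration uses a 32×32 world with two continuous layers, a uniform pool
of 300 cells, 200 simulated species of 8 localities each and $R = 50$
replicates (linear features under the auto rule); the conservatism
recovery experiment uses 20 default worlds, and the shuffled-niche null
uses 10 label permutations of each world's overlap matrix — permuting
species labels is distributionally identical to reassigning the evolved
optima to random tips before sampling occurrences, at a fraction of the
cost.

## Known limitations

* With $k = 2$ niche dimensions, the realized Brownian niche configuration
  is itself random: in roughly one world in five the tip optima happen to
  align weakly with phylogeny and the Pearson test cannot reject at
  $\alpha = 0.05$ even though the generative process is conserved. This is
  realization noise, not estimator failure — it persists when $\sigma^2$
  is scaled up, and it mirrors the power limits of real datasets with few
  species.
* The pairwise Pearson conservatism test inherits the anti-conservativeness
  discussed above; treat its p-values as descriptive and lean on the
  Mantel p for inference.
* The Maxent fit at the default 500-iteration cap is numerically at the
  optimum for practical purposes but may not satisfy the strict KKT
  tolerance; `converged` reports that strict status honestly.
* Coordinates are binned on a planar grid; no projection is applied, which
  is adequate at the resolutions the pipeline targets but not for
  high-latitude or continental-scale work.
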