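---
title: "From stratigraphic abundance counts to interaction networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stratigraphic abundance counts to interaction networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cambronet)
```

## The inference problem

A well-preserved fossil Lagerstätte can be censused at fine stratigraphic
resolution: a table of specimen counts per taxon per 10 cm level. If two
species interacted ecologically, their abundances should co-vary through the
section — strongly and positively for a consumer that depends on a single
prey species, weakly and positively for a generalist consumer, and
negatively for competitors (including apparent competitors sharing a
predator). `cambronet` turns that premise into a tested pipeline:

1. partition the section into compositionally homogeneous sub-assemblages
   (biofacies) so that correlations are not driven by facies turnover;
2. estimate statistically corrected pairwise abundance correlations within
   each sub-assemblage and within running stratigraphic windows, and keep
   the significance-filtered correlation network;
3. quantify, per window and per taphonomic trait factor (body type, size
   class, habitat), how strongly differential preservation could have
   rewired each network, and discard high-bias intervals;
4. decompose the correlation distributions into Gaussian components,
   cluster the components across strata into interaction categories, and
   map categories onto interaction types using an agent-based
   resource–prey–predator model with known ground truth;
5. extract majority-rule consensus interactions across strata and compare
   them with independently proposed interactions.

Because no fossil data ship with the package, a synthetic-assemblage
generator with planted interaction structure, planted facies boundaries and
trait-dependent preservation thinning provides ground truth for every
stage; the test suite and the acceptance script run entirely on it.

## Synthetic assemblages

`generate_assemblage()` draws counts as Poisson with log-mean equal to a
per-facies baseline plus a latent Gaussian field whose pairwise correlations
equal the planted values (a Gaussian copula). This gives exact control of
the sign and magnitude of every planted dependency on the correlation
scale, which is the scale on which the downstream categories are defined.
Facies baselines are drawn once per segment from a log-normal prior
(`baseline_meanlog = log(8)`, `baseline_sdlog = 0.8` by default — typical
level counts of a few to tens of specimens, as in densely sampled shale
beds), or supplied explicitly via `facies_profiles` when a controlled
contrast is wanted. Planted classes default to latent correlations 0.8
(specialist-like), 0.4 (generalist-like) and −0.5 (competitive-like).

Preservation is modeled as binomial thinning (`apply_preservation()`):
every specimen fossilizes independently with a per-taxon probability,
mapped from a trait factor by `trait_preservation_map()`. This captures
taphonomic loss as a sampling process; it deliberately does not model
transport or sedimentology, so tests passing on synthetic data say nothing
about spatially structured bias in real sections.

What the generator does **not** emulate: temporal autocorrelation within a
facies (levels are conditionally independent), taxon interactions that
change through time, and abundance-dependent preservation. Real data have
all three; the pipeline's robustness to them is untested here.

## Biofacies detection

`she_analysis()` accumulates levels upward and tracks the decomposition
`H = ln S + ln E` (S = richness, H = Shannon information in nats,
E = exp(H)/S). Within a homogeneous biozone, `ln E` declines roughly
linearly in `ln N`; a boundary is declared when the newest point's residual
from the running segment regression exceeds `break_tolerance` (default 2)
prediction standard errors — the prediction SE, not the raw residual SD,
because the newest point always extrapolates along `ln N` — for two
consecutive levels. Accumulation restarts at the first deviating level.
Candidates are then audited by ANOSIM (`anosim_test()`, Bray–Curtis
dissimilarities via `vegan::vegdist`, seeded label permutations): a
boundary survives only if the two adjacent segments differ at
`alpha = 0.05`. On synthetic sections with a hard compositional change the
consensus localizes the boundary within ±3 levels in well over 80% of
seeds, while iid-multinomial sections produce spurious candidates in under
10%.

## Corrected correlations and networks

Counts are `log(1 + x)`-transformed (variance stabilization; a per-taxon
multiplicative collection bias becomes an additive shift and cancels from
correlations). Taxa occupying fewer than `min_occupancy = 0.25` of the
levels are excluded as numerically rare — too few occurrences support no
robust correlation. The default estimator shrinks the correlation matrix
toward the identity with an analytically chosen intensity (the ratio of the
summed sampling variances of the empirical correlations to their summed
squares, clipped to [0, 1]) and inverts it to partial correlations; plain
Pearson and Spearman estimators remain available
(`corrected_correlations(..., estimator =)`) because the two halves of the
pipeline want different things:

* for **edge significance** (network construction), partial correlations
  remove latent-chain artefacts (X–Y–Z producing a spurious X–Z edge);
* for **interaction categorization**, the marginal (Pearson) scale is the
  one on which the agent-based model's correlations live, and partial
  correlations inside a planted block of mutually correlated species
  compress toward ρ/(1 + (k−2)ρ), destroying the category structure.
  `infer_interactions()` therefore defaults to the Pearson estimator.

P-values come from the Fisher z transform with effective sample size equal
to the number of levels, and Benjamini–Hochberg adjustment across retained
pairs; edges keep pairs with `q <= alpha` (default 0.05). Fisher z assumes
independent levels; the synthetic generator satisfies this, stratigraphic
reality only approximately.

## The agent-based model

`run_abm()` implements a grid-world energy model: 17 prey species graze a
regrowing basal resource on a toroidal lattice, 8 predators (4 specialists
with singleton diets, 4 generalists with 5-prey diets) consume co-located
diet prey, all agents pay a metabolic cost, die at zero energy and
reproduce by fission. Four stabilizers — all ecologically standard — are
required for a 25-species community to persist and to exhibit the
correlation structure the method presumes:

* **Prey self-limitation** (Beverton–Holt scaling of grazing gain by
  `1 + N_s / prey_K`): without it one prey species competitively excludes
  the rest on the shared resource.
* **Predator satiation, probabilistic reproduction and background
  mortality**: these decouple a predator's killing rate from its encounter
  rate (demand-limited consumption), cap its population growth rate and set
  its demographic turnover, so predators track their prey instead of
  overrunning them.
* **Predator territorial interference** (hunting probability
  `1 / (1 + P_s / predator_K)`): keeps predation a perturbation on prey
  dynamics.
* **Immigration** (Poisson, 0.05 individuals per species per step): an
  open marine community receives propagules; local extinction is transient
  rather than absorbing.

A slow AR(1) environmental suitability per prey species
(`env_phi = 0.97`, `env_sd = 0.15`) plants persistent abundance
fluctuations that predators can track. Under the defaults (grid 24,
600 steps of which 100 burn-in), pooled over many runs, mean abundance
correlations order as specialist > generalist > 0 > competition — the
premise that justifies reading fossil correlation categories as
interaction types. In the preference-weighted variant each predator draws a
search image among its diet species with probability proportional to its
preference and succeeds only if that species is locally present; the
correlation with a low-preference prey is then weaker than with the
high-preference prey and weaker than in the unweighted model.

Defaults were fixed once, during model design, at values giving
coexistence and the qualitative correlation ordering; they are study
conditions, not fitting knobs.

## The preservation-bias coefficient

The coefficient answers: *how much has differential preservation rewired
this network?* Its construction has three parts.

1. **Observable.** A dyad-independent ERGM is fit by maximum
   pseudo-likelihood (`fit_ergm()`, exact for these terms): edge intercept
   plus per-category homophily and activity terms for one trait factor.
   The statistic Δ is the fraction of the edges-only deviance explained by
   the attribute block — 0 when the factor says nothing about edge
   placement, approaching 1 when placement is category-determined.
2. **Calibration.** `run_abm_corpus()` pairs each simulated community with
   preservation-degraded copies: every species is assigned a preservation
   category, categories get probabilities spanning perfect to catastrophic
   (the per-case category probabilities and shares are themselves drawn,
   so corpus cases range from untouched to almost entirely degraded), and
   the census is binomially thinned. For each pair, the normalized Hamming
   distance between the degraded and perfect networks measures true
   structural alteration, and Δ of the degraded network measures visible
   category structure. Isotonic regression of distance on Δ
   (`calibrate_bias()`) yields a monotone map.
3. **Application.** `bias_coefficient()` evaluates the map at a fossil
   window's Δ: the result estimates the expected fraction of rewired node
   pairs on a [0, 1] scale, and 0.5 marks the point where half of all
   pairs would differ — the exclusion threshold used by
   `bias_series_and_trim()`, which flags windows where any of the three
   factors exceeds it and reports contiguous flagged margins at the
   section ends as trims.

This realization of an "ERGM + Hamming distance" bias score is a
reconstruction: it is one defensible way to combine those two ingredients
into a [0, 1] coefficient with a structural-alteration interpretation, and
it is validated behaviorally (shuffled-label null median below 0.1,
category-clique construction above 0.5, planted trait-thinned windows
flagged with sensitivity and specificity ≥ 0.8). The same network builder
(plain Pearson, `alpha = 0.05`) must be used for calibration and scoring;
the map does not transfer across estimators. Δ also responds weakly to
network size and density, so coefficients are comparable across windows of
equal design, not across arbitrary networks.

## Categories from Gaussian mixtures

Per stratum (and per running window), `fit_gmm_1d()` decomposes the
correlation values into 1-D Gaussian components: EM with k-means++-style
restarts, a σ floor of 10⁻³ against likelihood collapse, and BIC selection
of the component count (the per-iteration log-likelihood is asserted
non-decreasing). Components pooled across strata and windows are compared
with the Bhattacharyya coefficient — chosen because it is a closed-form
similarity on (μ, σ) — and clustered spectrally: symmetric normalized
affinity, eigenvalue-scaled (diffusion-map) embedding so that noise
directions vanish and one embedding serves every candidate count, k-means,
and the Tibshirani gap statistic with uniform reference draws over the
embedding's bounding box. The cluster count is the smallest candidate
within one reference-SE of the gap maximum (`firstSEmax`): the textbook
one-SE first-crossing rule returns 1 whenever the gap curve dips before
the true count, and the raw maximizer oversplits once clusters are
exhausted. Candidate counts are restricted to 1–4 in the pipeline: a small
number of broad categories is the scientifically meaningful resolution,
and micro-categories destabilize the downstream consensus rule.

Categories are ordered by ascending cluster mean; each category's interval
is the range of its member component means, so values between intervals
remain uncategorized. `category_composition()` reports, for each true
interaction type of labeled ABM correlations, the fraction of that type's
correlations falling in each interval (a type-normalized propensity — raw
counts would be dominated by the ~34:5:1 imbalance of
competition : generalist : specialist pairs that the 17-prey/8-predator
design implies), the raw counts, and the overall in-interval fraction.

## Consensus interactions and controls

`categorize_pairs()` maps significant pairs onto intervals;
`consensus_interactions()` applies the strict majority rule — a pair gets
a consensus category only when its modal category holds in more than half
of the strata where both taxa co-occur, with uncategorized strata counting
against. `compare_to_literature()` treats categories above the lowest as
trophic and the lowest as competitive (no literature reference set exists
for competitive interactions), and splits proposed interactions by whether
either taxon appears in the literature at all.

Two controls guard against habitat driving the correlations:
`habitat_chisq()` (Yates-corrected 2×2 test of edge sign against habitat
identity, aggregated over windows) and `sbm_equitability()` (agglomerative
Bernoulli stochastic-block-model fit, then the block-size-weighted Shannon
equitability of habitat or motility labels across blocks; 1 = even mixing,
0 = single-type blocks).

## Known limitations

* On synthetic sections the strict interval-plus-majority consensus
  recovers essentially all planted specialist-like pairs but only part of
  the generalist-like pairs, whose correlations straddle the boundary
  between adjacent category intervals across strata; the combined
  planted-pair recovery is nearer 60–80% than the specialist-only rate.
  Estimates falling in the gaps between category intervals are treated as
  uncategorized by design.
* The bias coefficient is calibrated under binomial thinning only and for
  the corpus's network design; dependence of Δ on specimen counts is not
  corrected.
* Directionality is never assigned (the networks are undirected), and
  mutualisms or joint environmental dependence cannot be separated from
  trophic signal by abundance correlations alone.

## Problem sizes

The test suite and `scripts/acceptance.R` use desk-scale designs chosen as
the package's own study conditions: 10–24 taxa and 100–480 levels per
synthetic section, 50–100 seeds per recovery or power estimate, 60–80 ABM
runs for correlation pooling, and a calibration corpus of 40 runs × 6
degradation cases (240 pairs). Paper-scale corpora (millions of runs)
remain configuration-only.
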