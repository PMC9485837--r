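---
title: "Methods: floral-trait convergence analysis in North American Silene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: floral-trait convergence analysis in North American Silene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silenemorph)
```

# The scientific question and the analysis it implies

North American *Silene* (section *Physolychnis*) combines a recently evolved
red floral color, large floral morphological variation, widespread polyploidy
and exposure to hummingbird pollinators. A pollination-syndrome view predicts
that species sharing a pollinator class should converge on correlated suites
of floral traits and form distinct clusters in a morphospace. This package
implements the comparative pipeline that interrogates that prediction: encode
floral traits, measure phylogenetic signal, place species in a phylogenetic
PCA morphospace, ask whether color groups differ in morphospace location and
spread, reconstruct the history of floral color, and test whether geography
(range overlap) rather than pollinator-mediated selection explains pairwise
phenotypic disparity.

# Trait coding

Continuous traits (stem length in cm; leaves per node; leaf length, calyx
height, calyx width and petal limb length in mm) are recorded as min/median/max
ranges; the species **median** is the working value, which is why the package
carries the full range and offers a resampling loop (below) to probe the
sensitivity of every downstream result to that choice.

Floral color is binned into three states. White/pink polymorphic species are
coded *pink* because they demonstrably produce petal anthocyanins; a pale
yellow flower is coded *white* (no anthocyanins); orange-pink is *pink* and
orange-red is *red*. The binning is deterministic, idempotent, and
override-able for descriptions outside the built-in vocabulary.

Ordinal floral traits are converted to representative numbers so they can
enter correlation and ordination analyses: tube extension and reproductive
organ exsertion use `below = -1, equal = 0, above = +1`; inflorescence class
uses `one = 1, few = 2, many = 3`. The four-level exsertion trait has an
intermediate `above/equal` category whose published numeric code is not
stated; we place it at `+0.5`, which preserves the category order and keeps
the two extremes at unit distance from `equal`. The encoding map is stored in
the trait table and serialized next to every CSV written, so an analysis can
always be reproduced from its artefacts. Whether `above/equal` was collapsed
with `above` in the published encoding is unknown; the map is a constructor
argument precisely so both conventions can be run.

Species identifiers keep subspecies tokens: *S. laciniata* subspecies are not
monophyletic in the ITS tree, so subspecies are treated as separate records.

# Phylogenetic machinery

Trees are handled as `ape::phylo` objects. The gene tree enters with
substitution-scale branch lengths and is calibrated to time with
penalized-likelihood rate smoothing (`chronopl`, smoothing weight 0 as in the
source analysis). Two root-calibration presets ship with the package:
`asr` (12.39-31.7 Myr) and `ppca` (15.14-26.49 Myr). A tree that is already
clock-like with a single root calibration is simply rescaled into the
admissible age window - the penalized-likelihood search adds nothing there
and the rescale makes the "already ultrametric" case an exact fixed point.
Calibrated trees are always re-checked by an independent ultrametricity test
(max spread of root-to-tip path sums), and zero-length input branches are
perturbed by `1e-8` of tree depth before dating.

The phylogenetic covariance `C` (shared root-to-MRCA path lengths) supports
Pagel's lambda transform, which scales only off-diagonal entries. The largest
admissible lambda is computed from the tree (the value at which the
transformed matrix loses positive semidefiniteness) rather than assumed to be 1.
Brownian-motion simulation draws tip values from `N(0, sigma2 * C)` via a
Cholesky (or eigenvalue, if semidefinite) factor and is the null engine for
the phylogenetic ANOVA.

## Phylogenetic signal

`pagel_lambda()` profiles the BM rate and phylogenetic mean out by GLS and
maximizes the one-trait Gaussian likelihood over lambda on
`[0, lambda_max]`; the reported p-value is a likelihood-ratio test against
`lambda = 0` (chi-squared, 1 df). `blomberg_k()` implements the ratio
statistic `K = (MSE0/MSE) / E[MSE0/MSE]` with the tree-determined expectation
`(tr(C) - n / sum(C^-1)) / (n - 1)`, so `K = 1` is the BM benchmark; its
p-value permutes tip labels and counts permutations whose GLS error is at
most the observed one (one-tailed for signal; the add-one rule keeps the
estimate away from zero). Both statistics are invariant to affine transforms
of the trait.

## Phylogenetic ANOVA

The observed statistic is the ordinary one-way ANOVA F of trait on color
group; classical p-values are wrong under phylogenetic correlation, so the
null distribution is built by simulating BM on the tree - with the
GLS-estimated rate from the observed data - and recomputing F per simulation.
Post-hoc pairwise pooled-variance t statistics use the same simulation null
and are Holm-corrected. The family for Holm correction of the trait
correlation matrices is the upper triangle of each matrix (the published
analysis does not state its family boundaries; one family per matrix is the
most conservative reading that still lets color groups be analysed
separately). Traits constant within a group produce `NA` cells that are
excluded from the family - with only nine red species several ordinal traits
are uniform there.

# Discrete color evolution

Floral color evolves under continuous-time Markov (Mk) models on
{white, pink, red}. The seven-model set comprises ER, SYM, ARD, and four
stepwise models on the ordered chain white-pink-red with direct white-red
changes forbidden. The constraint matrices of the published stepwise variants
are described only in supplementary material we do not consume, so the chain
parameterization here is an explicit interpretation:

* `stepwise_reversible`: white<->pink, pink<->red (4 rates);
* `stepwise_pink_red_irreversible`: red->pink = 0 (3 rates);
* `stepwise_red_white_irreversible`: pink->white = 0 (3 rates);
* `stepwise_red_pink_red_white_irreversible`: both of the above (2 rates).

All matrices are ordinary `mk_model` objects, so any alternative reading can
be supplied without touching package code.

Likelihoods use Felsenstein pruning with per-branch transition matrices
`exp(Qt)` (vectorized eigendecomposition with a scaling-and-squaring
fallback; rows are renormalized and must sum to 1 within 1e-10). Rates are
fitted by multi-start box-constrained quasi-Newton optimization on log-rates
(bounds `1e-8` to `1e3 / tree depth`). Model selection is by AIC
(`2k - 2 lnL`), and every model within 2 AIC units of the best is flagged
"retained", mirroring the published decision rule. The root prior for
fitting and for the stochastic maps is flat over the three states (the
published stochastic mapping fixed the root at equal probabilities; whether
the ML reconstruction used flat or stationary weights is unstated, so both
are available and the flat prior is the default for internal consistency).

Marginal ancestral states are exact per-node conditionals computed by a
down-pass/up-pass (belief propagation; equivalent to the rerooting method).
Stochastic character maps draw the root state from prior x root conditional
likelihood, descend node states conditioned on the parent and the subtree
likelihoods, and fill branch paths by endpoint-conditioned uniformization -
chosen over rejection sampling because short branches that must change state
make rejection arbitrarily slow, while uniformization has bounded work per
draw. Summaries report per-node state frequencies (which must converge to
the marginal ASR; the test suite enforces agreement) and the posterior
distribution of counts of each ordered transition type.

# Morphospace

`phyl_pca()` is a phylogenetic PCA in correlation mode (the covariance-mode
alternative sits behind a flag): lambda is estimated by joint ML over all
traits under multivariate BM; the GLS (phylogenetic) trait means `a` center
the data; the evolutionary covariance
`P = (X - 1a)' C^-1 (X - 1a) / (n - 1)` is converted to a correlation matrix
and eigen-decomposed. Scores are GLS-standardized centered data projected on
the eigenvectors. Two numerical conventions matter downstream:

* the tree covariance is normalized to unit mean diagonal, which makes the
  `lambda = 0` limit coincide *exactly* with a standard PCA of the
  correlation matrix (and makes scores independent of the time units of the
  tree);
* the sign of each component is fixed deterministically (largest-magnitude
  loading positive), so scores are comparable across the 1,000 resampled
  pPCA runs and across permutation replicates.

Encoded ordinal traits enter as numeric columns. That is the published
choice and it is worth a caveat: Pearson-type machinery on 3-point scales is
a coarse approximation, which is one reason the correlation analyses use
Spearman ranks.

Group summaries in score space are the per-color mean and a 95% normal
ellipse from the group's 2x2 score covariance scaled by the chi-squared(2)
0.95 quantile; groups of fewer than three species get a mean but no ellipse.

# Permutation and resampling inference

The bespoke tests compare color groups on component scores with two
statistics: the variance ratio `var(A)/var(B)` and the mean difference.
The null relabels the full color vector across all species (preserving
group sizes); a mode restricted to the two compared groups is available and
documented as a deviation. Significance is the exceedance count in the
configured direction divided by the number of relabelings - the published
counting rule - with an optional add-one variant. The direction is explicit
in the API and never inferred: for variance ratios with red in the numerator
the alternative is "smaller than expected" (the study's hypothesis of low
red variance); mean differences default to two-sided. Whenever the number of
distinct relabelings is at most 20,000 the null is enumerated exhaustively
instead of sampled, which removes Monte-Carlo error from small problems.

The robustness loop re-draws the three floral size traits (calyx height,
calyx width, petal limb length) uniformly between each species' recorded
minimum and maximum - exactly those three; the other continuous traits stay
at their medians - and re-runs the pPCA per dataset, aggregating per-color
group means and variances of the leading scores across datasets. Individual
dataset failures are skipped; more than 5% failures aborts the loop.

# Geography

Occurrence records are cleaned ((0,0) points, invalid coordinates, exact
duplicates, optional bounding box) and thinned greedily in a deterministic
order (latitude then longitude) to a minimum spacing of 1 km by default -
the upstream pipeline's thinning default is not printed, and 1 km matches
the resolution of typical aggregator records.

Ranges are built by projecting points into a spherical Albers equal-area
conic (authalic radius 6371.0072 km; standard parallels at the 1/6 and 5/6
latitude quantiles of the data, the usual parameter rule, since the source
names the projection but not its parameters), buffering each point by 10 km
and taking the union. The published buffer is written as "10 km^2", which is
dimensionally a length in a buffering operation; it is implemented as a
10 km radius and exposed as a parameter. Union and pairwise-intersection
areas of these disc unions are computed *exactly* by tracing uncovered
boundary arcs (Green's theorem), with intersection area obtained as
`area(A) + area(B) - area(A union B)`; the test suite checks this against
closed forms and a grid-rasterization oracle. The overlap index is
`overlap / ((A - overlap) + (B - overlap))`; a pair is sympatric exactly
when overlap is positive (no tolerance band), and identical ranges (zero
denominator) return an infinity sentinel.

Disparity is the absolute score difference per component over all unordered
species pairs. Contrasts use Kruskal-Wallis (via `stats::kruskal.test`),
a two-way aligned-rank-transform ANOVA (cell-mean alignment per effect,
average-tie ranks, factorial ANOVA on the ranks with only the aligned
effect read out), and a rank-transform ANCOVA: ranks of the response
regressed on ranks of the phylogenetic distance, with the sympatry effect
tested by the drop in residual dispersion (F test). The published analysis
used a Wilcoxon-score rank regression; the rank-transform variant here is
the standard Conover-style approximation and degrades to Kruskal-Wallis
when the covariate is constant. Note the statistical caveat inherited from
the design: all n(n-1)/2 pairs enter these tests as observations although
they are not independent; results are reported with that caveat rather than
"fixed", to stay comparable with the published degrees of freedom.

# The synthetic-data generator

The generator exists so every stage is testable with known ground truth and
no downloads. Its defaults emulate the study design: 47 species; a Yule tree
rescaled to a 20 Myr root age (inside the root calibration window); planted
color counts white 20 / pink 18 / red 9; continuous medians evolving by
multivariate BM with `lambda = 0.15` (the empirical per-trait signal is
weak, with lambda estimates around 0.1-0.2); min/max ranges at +/-25% of the
median (the published per-species ranges vary widely and are not printed, so
a single moderate relative width is used); ordinal traits from
latent-threshold BM so their phylogenetic signal is controlled by the same
lambda; all red species polyploid. The planted "convergence" effect pulls
red species' traits toward the red centroid by a contrast factor of 0.3
(trait-level variance ratio about 0.1, the magnitude used for the
power checks). Occurrence clouds are isotropic bivariate normals whose
centers are laid out in blocks of four so that designated pairs are
partially overlapping (centers one spread apart), disjoint (centers far
beyond buffered cloud extents) or nested (shared center, quarter spread);
everything across blocks is allopatric by construction.

What the generator does *not* emulate - and therefore what green tests do
not certify about real data: aggregator record noise (misidentifications,
basis-of-record classes), non-Brownian trait evolution (selection regimes,
bounded traits), gene-tree/species-tree discordance, correlated
trait-color evolution beyond the planted variance contrast, and real range
shapes (real ranges are not unions of Gaussian clouds).

# Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale versions of every
analysis: 1,000 relabelings for permutation p-values, 1,000 resampled pPCA
datasets, 1,000-5,000 stochastic maps, 200-300-tip trees for
parameter-recovery checks, and 50 scenario replicates for power estimates -
sizes at which the Monte-Carlo error of each check is comfortably below the
tolerance being asserted. Matrix solves go through Cholesky factors;
semidefinite covariances fall back to eigenvalue factorization; optimizer
boundaries are always re-checked against the endpoint likelihoods
(`lambda = 0`, `1`, `lambda_max`); and p-value counting rules, tie handling
(average ranks throughout), and sign conventions are fixed and documented
above precisely because permutation and resampling comparisons break if they
float.

# Known limitations

* The rank ANCOVA is the rank-transform (Conover) variant, not
  Wilcoxon-score rank regression; with heavy-tailed responses the two can
  differ.
* Mixed-geometry overlap (disc-union versus rectangle) is not implemented;
  rectangles exist as analytic test geometry.
* The Mk machinery is fixed at three states and has no hidden-rate
  extension; ploidy evolution is displayed in the empirical study but not
  modeled, and is likewise not modeled here.
* Stochastic-map storage keeps full branch paths only for moderate
  simulation counts (`keep_maps`); summaries (node frequencies, transition
  counts) are always kept.
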