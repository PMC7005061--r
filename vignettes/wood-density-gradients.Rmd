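---
title: "Vertical wood-density gradients and biomass bias correction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertical wood-density gradients and biomass bias correction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodgrad)
```

## The problem

Converting a tree volume into dry aboveground biomass (AGB) requires one
number: a wood density (WD, oven-dry mass over fresh volume, g cm⁻³).
Volumes are increasingly cheap to obtain — terrestrial laser scanning
yields whole-tree volumes nondestructively — but the WD used for the
conversion is usually a species average from a database, or a single basal
measurement. Neither reflects the *vertical* variation of WD inside the
tree: in wet tropical forests, dense-wooded shade-tolerant trees tend to
build progressively lighter wood from the stump towards the branch tips,
while light-wooded pioneers hold steady or get denser upward. Because the
decreasing pattern dominates, converting volumes with basal or database WD
systematically overestimates AGB, on the order of 8–10% at the population
level.

`woodgrad` implements the full analysis chain around this problem:
quantifying the vertical gradients from destructive-sampling data,
measuring the conversion bias they induce, and correcting it with the
volume-weighted wood density (VWWD) estimator and a family of linear
prediction models.

## From raw measurements to tree-level quantities

A destructively sampled tree is divided into six vertical compartments:
stump (`Stu`), stem base (`Ste_b`, absent when the lower bole is not
separated from the commercial stem), stem (`Ste`), and large, medium and
small branches (`LB`, `MB`, `SB`). In each compartment two opposite
pith-to-bark wedge samples give, per sample *i*, fresh mass $m_{fi}$ (g),
fresh volume $v_{fi}$ (cm³) and oven-dry mass $m_{di}$ (g), from which

$$WD_i = m_{di}/v_{fi}, \qquad MC_i = (m_{di}-m_{fi})/m_{fi}, \qquad
BV_i = v_{fi}/m_{fi}.$$

The moisture content $MC_i$ is negative by construction (dry mass is below
fresh mass); the implementation validates $MC_c \in (-1, 0]$. Sample
values are averaged *unweighted* into compartment values $WD_c$, $MC_c$,
$BV_c$ — no volume weighting between the two wedges, since the sampling
protocol treats them as equivalent.

Field measurements come in two forms. Parts light enough to weigh
contribute a fresh mass, converted to dry mass by $m \,(1+MC_c)$ and to
fresh volume by $m \, BV_c$. Larger logs are measured geometrically and
treated as truncated cones,

$$V = \frac{\pi h}{3}\left(r_1^2 + r_1 r_2 + r_2^2\right),$$

with dry mass $V \times WD_c$. A third input kind accepts a precomputed
fresh volume directly (e.g. an irregular stump's cross-section area times
height). Summing over logs gives $V_c$ and $AGB_c$; summing over
compartments gives the tree totals $V_{obs}$ and $AGB_{obs}$, the
destructive reference values. All internal units are g, cm, cm³ and
g cm⁻³; any conversion to kg or Mg is left to report time.

## The volume-weighted wood density

The compartment contribution
$VWWD_c = WD_c \times V_c / V_{obs}$
sums to the tree-level estimator

$$VWWD = \frac{\sum_c WD_c V_c}{\sum_c V_c},$$

the volume-weighted mean WD of the tree. When compartment dry masses are
built from volumes ($AGB_c = V_c WD_c$), $V_{obs} \times VWWD = AGB_{obs}$
is an algebraic identity — VWWD is by construction the unbiased converter
of whole-tree volume to biomass, which is what a single database or stump
value is not.

## Ordinating the vertical profiles

Profiles are compared across trees after removing tree-level WD: each row
of the trees × 6 compartment matrix is divided by its mean (default,
`row_mean_ratio`) or centered (`row_center`). Both normalizations are
standard descriptions of "relative profiles"; the ratio form is the
default because it preserves the reading of a profile as percent of the
tree mean, and both are exposed because the choice is genuinely open. A
missing stem base is imputed as the mean of the tree's stump and stem WD —
it is physically intermediate between the two — and flagged; trees with
fewer than five compartments are excluded with a warning rather than
imputed more aggressively.

The ordination is a scaled PCA: eigendecomposition of the correlation
matrix of the normalized profiles (`stats::prcomp` on standardized
columns). Eigenvector sign is arbitrary, so axes are oriented
deterministically: the SB loading on axis 1 is made positive — trees with
relatively dense bases and decreasing profiles then score *negative* on
axis 1 — and the Ste loading on axis 2 positive; further axes pin their
largest-magnitude loading positive. This convention is a choice; it is the
one under which the axis-1 scores correlate negatively with stump WD.

Supplementary variables (stump WD, species database WD, VWWD, DBH, total
and trunk height, crown radius, and the stem morphology index
$Sm = Ht/H$) are correlated with the first two axes by Pearson tests. The
per-tree gradient statistic is the small-branch vs stump difference in
percent of the stump WD, $100\,(WD_{SB}-WD_{Stu})/WD_{Stu}$.

## Bias statistics and the correction-model family

For trees with both an estimate and a reference,
$b_i = 100\,(AGB_{est,i}-AGB_{obs,i})/AGB_{obs,i}$, the bias is
$B = \overline{b_i}$, and the total error is
$CV = 100 \times RSE_{AGB} / \overline{AGB_{obs}}$ with
$RSE_{AGB} = \sqrt{N^{-1}\sum_i (AGB_{est,i}-AGB_{obs,i})^2}$. Two
distinct "residual error" quantities circulate in this analysis and the
package names them apart: `agb_rmse` (the AGB-level RSE above, g) and
`model_rse` (the residual standard error of a VWWD regression, g cm⁻³).

The correction models are ordinary least squares fits of VWWD on cheaply
available predictors:

| model | predictors |
|-------|------------------------|
| m1    | WD_Stu |
| m2    | WD_Stu + DBH |
| m3    | WD_Stu + DBH + Sm |
| m4    | WD_GWD |
| m5    | WD_GWD + DBH |
| m6    | WD_GWD + DBH + Sm |

Fitting is unweighted OLS. AIC is the Gaussian-likelihood value from
`stats::AIC`, which counts the error variance as a parameter; since the
constant is shared across m1–m6, model ranking by ΔAIC does not depend on
that convention. Each fit reports both R² and adjusted R² (at n in the
hundreds they agree to the printed precision). Reference coefficient sets
calibrated on a published Central African destructive campaign (822 trees,
51 species) ship as presets in `vwwd_presets()` and can be applied through
`predict_vwwd()` without any local calibration data.

Model transferability is evaluated by leave-one-site-out cross-validation:
the model is refit on all sites but one and used to predict VWWD — and
from it AGB — for the held-out site, reporting per-site and pooled B and
CV. Both the apparent (fitting-set) and cross-validated error are exposed,
since the apparent version is what a model table reports and the
cross-validated version is what a new site experiences.

## Guild and taxonomic structure

Axis-1 scores are compared across regeneration guilds (pioneer, P;
non-pioneer light-demanding, NPLD; shade-tolerant, ST) by one-way ANOVA
with Tukey HSD post hoc comparisons (`stats::aov`, `stats::TukeyHSD`) and
a compact letter display computed by the insert-and-absorb algorithm.
Species × site structure is quantified by a sequential (type-I) two-way
ANOVA with interaction, restricted to species present in at least three
sites (a species sampled at one or two sites cannot separate species from
site effects); each term's variance fraction is its sum of squares over
the total.

Phylogenetic signal in species-mean axis-1 scores uses Blomberg's K: the
ratio of the observed $MSE_0/MSE$ (tip variance around the phylogenetic
GLS mean over the variance under the tree's covariance structure) to its
Brownian-motion expectation
$\left(\mathrm{tr}\,C - n/\sum C^{-1}\right)/(n-1)$. K ≈ 1 indicates
Brownian-motion-like conservatism, K ≈ 0 no signal; K is invariant to
rescaling branch lengths. Significance is a rank-based tip-randomization
test, $p = (1 + \#\{K_{rand}\ \text{at least as extreme}\})/(n_{rand}+1)$
with 999 shuffles by default. The tail is configurable and defaults to
*lower*: a K smaller than the randomization distribution is read as
overdispersion (related species less similar than chance), the pattern of
interest for profiles that track functional strategy rather than ancestry.
On a star phylogeny (no shared branches, equal depths) K equals 1
identically — the BM expectation collapses onto the observed ratio — so
"no signal" baselines must be read against the tree at hand, not against
a universal 0.

## The synthetic-data generator

There is no public tabular fixture at desk scale for this kind of
campaign, so the package generates one with the statistical structure the
analysis assumes. The generator's defaults are the reference study
conditions and are not tuning knobs:

* 51 species, 822 trees, 6 sites; species mean WD uniform on
  0.22–1.02 g cm⁻³ (the tropical range), guild probabilities shifting
  P → NPLD → ST with increasing WD.
* Vertical profiles linear in compartment rank (an optional quadratic
  term, default 0, accommodates convex variants): the expected total
  stump-to-branch change is `gradient_slope × (wd_pivot − WD_basal)`, so
  dense trees decrease and light trees increase upward. The pair
  `wd_pivot = 0.38`, `gradient_slope = 0.41` was calibrated once, on
  independent seeds, so that the population reproduces the published
  summary pattern — WD decreasing in roughly 83% of trees with a mean
  small-branch vs stump difference near −13% — and then frozen.
* Compartment volumes from a Dirichlet split (concentration 60) around
  (Stu 5%, Ste_b 5%, Ste 55%, LB 20%, MB 10%, SB 5%) of a total-volume
  allometry (≈ 0.7 × the DBH cylinder): dominant-trunk trees typical of
  closed-canopy forest.
* Moisture content uniform on (−0.6, −0.2), so dry mass is always below
  fresh mass; measurement noise is relative lognormal (default 2%) on
  masses, and small Gaussian perturbations on basal WD (0.04), total
  profile change (0.04) and per-compartment WD (0.02 g cm⁻³).
* The stem base is absent with probability 0.15 (its wood folded into the
  stem), exercising the imputation path; an optional additive site
  intercept on basal WD defaults to 0, mirroring a non-significant site
  effect.
* The species phylogeny is a random ultrametric coalescent over the pool,
  *independent of the traits* — a structural stand-in sufficient for
  testing the signal machinery, not a model of real shared ancestry.

What the generator deliberately does not emulate: radial (pith-to-bark)
gradients, 3-D architecture and point clouds, real phylogenetic
correlation of WD, site climate. Consequently, passing tests demonstrate
the correctness and calibration of the *machinery* on data with the
assumed structure; they do not certify the published real-data values,
which require the original campaign data.

Determinism is strict: every generator function derives an independent RNG
substream from the single config seed (per stage and per tree), so any
stage can be rerun in isolation and identical seeds give byte-identical
tables end to end.

## Numerical choices and degenerate inputs

* Exact identities (VWWD conservation, weight sums) are tested at 1e−12
  relative; eigendecomposition agreement at 1e−8.
* Constant profile columns abort the PCA with the column named, rather
  than silently dropping it.
* A dry mass exceeding its fresh mass is a warning by default (field data
  contain such records) and an error under `strict = TRUE`.
* Missing stump is a hard error in `tree_totals()` — stump WD is required
  downstream — as is `Ht > H`.
* Rank-deficient model designs raise a collinearity error naming the
  model; cross-validation refuses a fold whose training set is smaller
  than the parameter count, naming the site.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run entirely on generated data:
500–1,000 trees for the conservation and bias-removal experiments, 200
replicates of n = 800 for coefficient-recovery coverage, 50 random 20 × 6
matrices for the PCA oracle, 200 Brownian simulations on a 50-tip tree
plus 100 null replicates at 199 randomizations for the K calibration, and
the full 822-tree reference configuration for the end-to-end pipeline.
These sizes give stable Monte-Carlo behaviour for every claim the package
makes while keeping a complete run in the order of a minute.

## Known limitations

* The generator's profile model is linear in compartment rank; real
  profiles include convex and non-monotone shapes that only enter through
  the optional quadratic term and noise.
* Volume allometry and compartment fractions are coarse; they are
  adequate for the estimator algebra (which is exact regardless) and for
  bias structure, not for studying volume models themselves.
* `lookup_wd_gwd()` resolves species by exact id only; genus-level
  fallbacks are intentionally unsupported (a user-supplied constant is
  the only fallback), because silent taxonomic fuzziness is a known
  source of WD error.
* The phylogenetic-signal test operates on species means, as the
  species-level analysis prescribes; within-species variance is not
  propagated into K.
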