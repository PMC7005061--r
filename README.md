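# woodgrad

Vertical wood-density gradients and bias-corrected tree biomass
estimation.

## The problem

Dry aboveground biomass (AGB) of a tree is its volume times a wood
density (WD, oven-dry mass / fresh volume, g·cm⁻³). Whole-tree volumes
are now obtainable nondestructively (terrestrial laser scanning), but the
WD used for the conversion is almost always a species average from a
global database or a single basal measurement — and WD is not constant
inside a tree. In wet tropical forests, dense-wooded shade-tolerant trees
build progressively lighter wood from the stump to the branch tips, while
light-wooded pioneers stay flat or get denser upward. Because decreasing
profiles dominate, converting volumes with basal or database WD
overestimates AGB by roughly 8–10% at the population level.

`woodgrad` is for researchers working with destructive-sampling
campaigns or LiDAR-derived tree volumes who need to quantify that bias
and remove it. The core quantity is the **volume-weighted wood density**

VWWD = Σ_c WD_c·V_c / Σ_c V_c

over the six vertical compartments (stump, stem base, stem, large /
medium / small branches). V_obs × VWWD equals the reference AGB_obs by
construction, making VWWD the unbiased converter — and VWWD is highly
predictable from cheap measurements via linear models

m1: VWWD = a + b·WD_Stu   …   m5: VWWD = a + b·WD_GWD + c·DBH   (etc.)

whose published reference coefficients ship with the package. Around this
core, the package provides the laboratory/field processing chain (wedge
samples, weighed and coned logs, truncated-cone volumes), the scaled-PCA
ordination of relative vertical profiles with supplementary-variable
correlations, bias (B) and total-error (CV) statistics with
leave-one-site-out cross-validation, guild ANOVA with Tukey HSD,
species × site variance partitioning, Blomberg's K with a
tip-randomization test, and a synthetic-data generator emulating a
multi-site destructive campaign (822 trees, 51 species, 6 sites by
default).

## Worked example

```r
library(woodgrad)

cfg  <- sim_config(n_trees = 300, n_species = 20, seed = 7)
dat  <- simulate_dataset(cfg)                     # species, trees, samples, logs
proc <- process_field_data(dat$samples, dat$logs, dat$trees)
trees <- proc$trees
trees$WD_GWD <- lookup_wd_gwd(trees, dat$species)

# how biased is conversion with the species database WD?
bias_report(trees$V_obs * trees$WD_GWD, trees$AGB_obs)
#> AGB bias report (n = 300)
#>   B (mean rel. error): +6.85% (sd 11.25%)
#>   AGB RMSE: 467187.6 g, MAGB_obs: 2575514.3 g, CV: 18.1%

# calibrate the stump-WD correction model and look at the residual bias
fit_vwwd_model("m1", trees)
#> VWWD correction model m1 (n = 300)
#>          term estimate        se       t           p
#> 1 (Intercept) 0.085965 0.0054063  15.901  1.1973e-41
#> 2      WD_Stu 0.788743 0.0078743 100.167 1.6566e-231
#>   R2 = 0.971 (adj 0.971), RSE = 0.0315 g cm-3, AIC = -1219.9
#>   AGB bias B = +0.37%, CV = 11.6%

# ordinate the vertical profiles; axis 1 is the gradient direction
pca <- run_pca(build_profile_matrix(proc$compartments))
supplementary_correlations(pca, trees)[1:3, c("variable", "r_axis1", "sig_axis1")]
#>   variable    r_axis1 sig_axis1
#> 1   WD_Stu -0.7691895       ***
#> 2   WD_GWD -0.7505996       ***
#> 3     VWWD -0.7046217       ***

# or skip local calibration entirely and use the published preset
predict_vwwd("m5", data.frame(WD_GWD = 0.6, DBH = 50))
#> [1] 0.549244
```

Reading the output: converting volumes with database WD inflates AGB by
+6.9% on this population (B), with an 18.1% total error (CV). The m1
model predicts VWWD from stump WD alone (R² = 0.97) and cuts the
conversion bias to +0.4%. The strong negative correlation between axis-1
scores and stump WD (r = −0.77) is the structural fact the correction
models exploit: the denser a tree's base, the more its WD decreases
upward.

`run_pipeline(sim_config(seed = 1), out_dir = "run")` executes the whole
chain (simulate → process → convert → PCA → model fits → cross-validation
→ guild/taxonomic analyses) and writes every table as CSV plus
`report.json` and a digest manifest.

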