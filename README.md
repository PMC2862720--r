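# ihcquant

Quantitative analysis of chromogenic immunohistochemistry (IHC) micrographs
and statistical validation of a multiplexed microchannel staining platform
against conventional whole-section scoring.

Immunohistochemistry reads out protein expression in tissue by staining
antibody-bound sites with a brown chromogen (DAB) over a blue hematoxylin
counterstain. Scoring is traditionally ordinal and subjective. This package
implements the computational side of a microfluidic multiplexed IHC
workflow for breast-cancer biomarkers (ER, HER2, PR, Ki-67): colour-based
segmentation of micrographs, a continuous expression statistic,
translation of clinical scores onto a common ordinal scale, the agreement
statistics used to compare two scoring methods, and a physical simulation
of antibody transport in a reaction microchannel. Everything is exercisable
on synthetic data with exact ground truth, so the full pipeline is testable
without access to patient material.

It is aimed at researchers building or validating quantitative IHC
pipelines, and at anyone needing tidy, oracle-tested implementations of
attribute-agreement statistics (Kendall's W, Cohen's/Fleiss' kappa, exact
binomial concordance intervals).

## The model

**Segmentation.** Each pixel class — stained cell part (SP), non-stained
counterstained cell part (NSP), background (BG) — gets a Gaussian mixture
colour model over RGB:

    f(x; λ) = Σ_{j=1}^{C} p_j N(x; μ_j, Σ_j),   Σ_j p_j = 1,

with component counts C = 5 (SP), 10 (NSP) and 2 (BG). Parameters
λ = {p_j, μ_j, Σ_j} are estimated by expectation-maximization; pixels are
then assigned by Bayes' rule,

    P(class c | x) ∝ π_c f_c(x),

taking the maximum-posterior class (ties broken SP > NSP > BG).

**Expression statistic.** For a segmented field,

    staining ratio   r = |SP| / (|SP| + |NSP|)
    staining intensity s = mean over SP of a stain signal in [0, 1]
    expression level  E = r · s,

averaged over at least five 400x fields per reaction channel.

**Agreement statistics.** Two scoring methods over n cases are compared
with Kendall's coefficient of concordance W (mid-ranks, tie-corrected)
and its chi-square test χ² = m(n−1)W, unweighted Cohen's κ, and percent
concordance with an exact Clopper–Pearson 95% CI. Latin-square designs
decouple biomarker order from channel position in reproducibility runs.

**Transport simulation.** Antibody binding in the reaction channel is
modelled as 2-D advection–diffusion with Langmuir kinetics at the reactive
tissue wall, dB/dt = k_on·C_wall·(R_T − B) − k_off·B, solved by explicit
upwind finite differences with exact discrete mass accounting.

## Worked example

```r
library(ihcquant)

# train class colour models on synthetic labeled fields
train  <- lapply(1:3, function(i) generate_ihc_field(image_gen_config(seed = 100 + i)))
models <- train_class_models(train, seed = 1)
models
#> <class_model_set: C = (SP 5, NSP 10, BG 2), priors = (0.333, 0.333, 0.333)>

# quantify a channel of five fields generated with 30% stained cells
fields  <- lapply(1:5, function(i)
  generate_ihc_field(image_gen_config(fraction_stained = 0.3, seed = i)))
channel <- quantify_fields(fields, models)
channel
#>   n_fields mean_ratio mean_intensity mean_expression magnification
#> 1        5      0.371          0.627           0.233          400x
```

The channel mean expression 0.233 recovers the generator's ground truth
(0.2326, the mean of the five per-field truth products) to three decimals:
the per-field staining ratios (0.330–0.392) track the generated stained
area, and the intensity ≈ 0.627 is the mean darkness of the brown SP
pixels. Agreement between two scoring methods works the same way:

```r
ratings <- generate_paired_ratings(
  rating_gen_config(n_cases = 105, agreement = 0.95, seed = 2))
concordance_report(ratings)
#>   biomarker   n      W  chi2  kappa concordance_pct ci_lo ci_hi p_w_fmt
#> 1       all 105 0.9639 200.5 0.9317           95.24 89.24 98.44 <0.0001
```

With 95% copy probability between methods the report shows near-perfect
concordance: W = 0.964 (χ² = 2·104·W = 200.5, p < 0.0001), κ = 0.93, and
95.2% raw concordance with an exact 95% CI of 89.2–98.4%.

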