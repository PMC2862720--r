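---
title: "Methods: colour-model segmentation, expression quantification and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour-model segmentation, expression quantification and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

## Scope and model

`ihcquant` covers the computational chain of a multiplexed microchannel
IHC workflow: synthetic micrograph generation with exact ground truth,
Gaussian-mixture colour modelling with EM, Bayesian pixel classification
into stained cells (SP), counterstained cells (NSP) and background (BG),
the expression statistic (staining ratio times mean staining intensity),
clinical score translation to a common four-level ordinal scale, the
attribute-agreement statistics used to compare two scoring methods, and a
finite-difference simulation of antibody transport and surface binding in
a reaction microchannel.

The segmentation model assumes pixel colours within a class are i.i.d.
draws from a class-specific Gaussian mixture in RGB, ignoring spatial
correlation. That is adequate when the three colour populations (DAB
brown, hematoxylin blue, near-white background) are well separated, which
chromogenic IHC is designed to achieve; it degrades for faint stains or
heavy colour overlap, where a spatial prior or stain unmixing would be
needed (out of scope here).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| mixture components `C` (SP/NSP/BG) | 5 / 10 / 2 | – | conventional counts for the three colour populations; NSP needs the most modes (chromatin texture and stain gradations), BG the fewest |
| class priors | 1/3 each | – | no prior preference among classes; configurable and recorded with the model |
| EM tolerance `tol` | 1e-6 | relative log-likelihood | below colour-quantization noise; iterations cap at 500 |
| covariance ridge `reg` | 1e-3 | (0–255 colour units)² | prevents singular fits on quantized byte data |
| staining signal | `"darkness"` | in [0, 1] | `1 − luminance/255` is parameter-free and monotone in stain darkness; `"dab_od"` (optical-density projection on the Ruifrok–Johnston DAB vector) is available when hematoxylin bleed-through into SP matters |
| `min_fields` | 5 | fields/channel | matches the acquisition convention of at least five random 400× fields per channel |
| cell counting | 8-connectivity, `min_size_px = 30` | px | a 30 px blob at 400× is below a plausible nucleus; border components are counted |
| binding defaults | D = 4e-11 m²/s, k_on = 1e3 m³ mol⁻¹ s⁻¹, k_off = 1e-4 s⁻¹, R_T = 1e-8 mol/m², C0 = 7e-5 mol/m³ | SI | IgG-scale diffusivity and antibody-typical affinity; with a 100 µm channel these give k_on·R_T·h/D ≈ 25, i.e. the transport-limited regime that motivates flowing incubation |

## The synthetic generator

The generator is first-class, tested code, not a fixture. It emulates the
three colour populations of a DAB/hematoxylin field: cells are rendered as
(possibly overlapping) disks, a chosen fraction of them stained; overlaps
are resolved by draw order with stained cells drawn last, so the label
mask — and hence the recorded staining-ratio truth — is exact by
construction. Default colour mixtures centre SP near RGB (140, 90, 60),
NSP near (120, 120, 180) and BG near (235, 230, 235), each multi-modal to
mimic the multi-modal class distributions of real stains; additive i.i.d.
Gaussian channel noise (sd 4 by default) then stresses the classifier.
These are generator choices, not measurements.

What the generator does **not** emulate: out-of-focus blur, shading and
glare gradients, stain colocalization within a cell, membranous vs nuclear
staining patterns, tissue architecture, and fatty or detached tissue.
Passing the recovery tests therefore shows the pipeline is correct and
well-conditioned on colour-separable fields; it does not certify
performance on real micrographs, whose colour overlap is worse.

Paired ordinal ratings are generated as: method A drawn from a 4-category
marginal (default 0.4/0.3/0.2/0.1, a realistic negative-skewed clinical
mix); method B copies A with probability `agreement` and otherwise draws
from a confusion kernel (default: A's marginals, i.e. independent
disagreement).

## Numerical choices

* All densities and posteriors are computed in log space with Cholesky
  factorizations; with 3×3 covariances on byte data, linear-space
  products underflow routinely.
* EM is initialized by k-means seeding under the caller's seed; every
  randomized function takes an explicit seed and restores the RNG state,
  so no global state leaks.
* Classification ties break in the fixed order SP > NSP > BG —
  deterministic, and biased toward detecting staining.
* Fields with zero cell area are rejected (error classed
  `ihcquant_empty_field`), not zero-scored, so empty fields cannot dilute
  channel means; a field whose cells are all unstained scores 0 via the
  zero-SP intensity rule.
* Kendall's W uses within-rater mid-ranks with the standard tie
  correction; a rater with constant scores makes W degenerate and errors
  rather than returning a misleading value.
* An Allred composite score of 1 cannot occur (minimum positive composite
  is 2) and is rejected loudly.
* The transport solver checks the diffusion, CFL, reaction and
  wall-uptake stability limits before running and errors with a suggested
  `dt`. Adsorbed mass is withdrawn from the adjacent fluid cell, so the
  discrete scheme conserves mass identically; the reported mass-balance
  error is a round-off diagnostic.

## Open design choices

* **Intensity scalar.** "Average intensity in SP" admits several
  readings; the default is normalized darkness (parameter-free, monotone);
  the DAB optical-density alternative is selectable and both are recorded
  in output metadata.
* **Class priors.** Uniform by default; classification is invariant to
  rescaling priors by a positive constant, and the posterior reduces to
  the priors when the class models coincide (both tested).
* **Concordance CI.** Clopper–Pearson exact, chosen over asymptotic
  intervals because channel-level n can be small (eight needle-biopsy
  cases); the method name travels with the result.
* **Kappa.** Unweighted Cohen's κ for two methods, with Fleiss' κ also
  provided; the two differ (Fleiss pools marginals) and both are
  oracle-tested.
* **Levene's test** uses the classic group-mean centring (not the
  Brown–Forsythe median variant), delegated to `car::leveneTest`.
* **Latin squares.** The published order-4 slide sequence is a Latin
  square of pairwise swaps, not a strict rotation; both that fixed square
  (`style = "paper4"`) and a true cyclic construction (`style =
  "cyclic"`) are provided.
* **Static-vs-flow comparison window.** Flow at one-tenth analyte
  concentration matches full-strength static incubation only once the
  static column becomes depletion-limited; the package compares at a
  600 s incubation (at 80 s a sealed 100 µm column still holds most of
  its analyte), scanning mean velocities of 1e-4 to 8e-4 m/s.

## Problem sizes

Defaults keep every computation at desk scale: 128×128 px fields
(96×96 in the recovery grids), ≤ 20 000 training pixels per class,
5 000-point EM recovery fixtures, 105-case rating sets, and a 40×16
transport grid (step ≈ 0.05 s, 80–600 s horizons). These sizes were chosen
so that the statistical targets (e.g. staining-ratio MAE ≤ 0.03 across
stained fractions 0–1) are comfortably resolvable, and all tests and the
acceptance script rerun in minutes on one CPU.

## Known limitations

* No model selection over `C`; the component counts are fixed by
  convention and must be revisited for other stains.
* No shading/glare correction, colour normalization across scanners, or
  spatial regularization of labels.
* The expression statistic is semi-quantitative: it is monotone in stain
  abundance but not an absolute protein concentration.
* The transport model is a 2-D longitudinal section with plug or
  plane-Poiseuille flow; it captures the depletion-layer mechanism but
  not 3-D corner flows, channel deformation, or binding-site
  heterogeneity, and its rate constants are order-of-magnitude defaults.
  Its acceptance checks are property-based (conservation, monotonicity,
  limiting solutions), not curve matching.
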