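---
title: "Quantifying inhibitory synaptic coverage of cortical neurons"
author: "synapcover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inhibitory synaptic coverage of cortical neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapcover)
```

## The measurement problem

Inhibitory (GABAergic) synapses on the perikarya of cortical layer-5
pyramidal neurons can be visualised by double immunofluorescence: a
neurofilament stain delineates the soma (red channel) and GAD 65/67 marks
inhibitory presynaptic terminals as bright puncta (green channel).  The
quantity of interest is the *inhibitory synaptic coverage*

$$C' = \frac{N_s}{A(d)},$$

the number of GAD+ puncta overlapping the neuronal membrane, $N_s$,
divided by the area of the segmented neuron, $A(d)$, in µm².  Counting
puncta rather than summing punctum area avoids the ill-posed problem of
delineating the boundary of a diffraction-limited synapse.  Neuron size is
measured alongside as the area enclosed by the segmented boundary plus the
area of the boundary itself.

The computation splits into three parts:

1. **Soma segmentation** of the normalized red channel: threshold (Otsu by
   default), a small despeckling opening, morphological closing, hole
   filling, removal of components below a minimum soma area, retention of
   the largest surviving component.  The boundary is the 8-connected
   outline of the retained object; the interior is the object minus its
   boundary.
2. **Punctum detection** in the normalized green channel: light Gaussian
   smoothing, white top-hat background suppression, thresholding, and a
   local-maximum watershed that assigns one object per intensity peak;
   objects outside an admissible pixel-area range are discarded.
3. **Combination**: a punctum counts toward $N_s$ (once) if its mask
   intersects the membrane band, the boundary dilated by a half-width of
   0.5 µm on both sides.  $A(d)$ is taken as interior plus boundary area.

On the semantics of $A(d)$: the method's source defines it as "the area of
the segmented neuron" while printing coverage "per µm² neuronal membrane".
This package uses the full segmented area (interior + boundary, identical
to the neuron-size definition) and carries the per-µm² unit string; the
ambiguity is intrinsic to the published description and is surfaced here
rather than hidden.

## Intensity normalization

Post-mortem material varies in time in formalin, post-mortem interval and
tissue pH, all of which shift absolute fluorescence intensity.  Each
channel is therefore rescaled so that its 1st percentile maps to 0 and an
upper anchor percentile maps to 1, with clipping.  For the soma channel
the upper anchor is the 99th percentile.  For punctate channels it is the
99.9th: puncta occupy well under 1% of pixels, so a 99th-percentile anchor
would land *inside* the punctum intensity distribution, saturate punctum
cores into flat plateaus, and irreversibly merge neighbouring puncta
(about one punctum in ten was lost this way in noise-free simulations
during development).  Percentile rescaling makes downstream measurements
invariant to multiplicative intensity drift in the clipping-free regime,
which the test suite verifies over scale factors 0.7–1.3.

## Quality control

Images are deleted (but retained in the bookkeeping, with status) for four
reasons, evaluated in priority order:

| status | test | default threshold |
|---|---|---|
| `poor_contrast` | raw red-channel robust contrast (p99 − p1) | < 0.15 full scale |
| `two_neurons` | components above the minimum soma area | ≥ 2 |
| `multi_process` | solidity of the retained component | < 0.80 |
| `incorrect_neuron` | no component reaches the minimum soma area | 100 µm² |

The QC report enforces conservation: reason counts sum to the deletion
total, and retained + deleted equals photographed.  The published
deletion-reason breakdown this emulates is itself internally inconsistent
(the listed reasons sum to fewer than the stated deletions), so the
package enforces the invariant rather than reproducing the inconsistency.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pixel_size` | 0.2 (always explicit) | µm/px | plausible for a 60× / 1.4 NA confocal acquisition; never silently defaulted at the pipeline level |
| `r_open_um` | 0.2 | µm | removes isolated suprathreshold noise pixels; a solid soma is unaffected |
| `r_close_um` | 0.6 | µm | bridges small gaps in the neurofilament signal |
| `min_soma_area_um2` | 100 | µm² | well below genuine layer-5 somata (~400–530 µm²), above debris |
| `punctum threshold` | 0.22 | normalized intensity | ~10 SD above smoothed background noise at default noise levels |
| `r_tophat_um` | 1.2 | µm | twice the largest punctum radius: flat background removed, puncta untouched |
| `blur_sigma_px` | 0.4 | px | sub-punctum smoothing; detection was equally accurate without it, kept for robustness to pixel noise |
| `ws_tolerance` | 0.01 | intensity | smallest saddle depth still separating two planted peaks of unequal brightness |
| `min/max punctum area` | 3 px / area of 1.5 µm disc | px | excludes noise specks and aggregates |
| `band_halfwidth_um` (counting) | 0.5 | µm | operationalises "overlapping the membrane" at pixel resolution |
| `contrast_min`, `solidity_min` | 0.15, 0.80 | — | QC deletion thresholds |

The watershed is applied to the whole suprathreshold top-hat surface, not
only to components exceeding the maximum punctum area: at membrane
densities of 0.25–0.40 puncta/µm² of soma, neighbouring puncta routinely
touch, and a merged *pair* (~20 px) never exceeds the single-punctum area
cap, so splitting only oversize components would systematically undercount.
For isolated puncta the two formulations coincide.

## The synthetic image generator

Real tissue imagery for this assay is not publicly deposited, so the
package ships a generator that plants exact ground truth:

* an irregular convex-ish polygon (8–12 vertices, radial jitter 0.25,
  rescaled to the requested area exactly before rasterization)
  approximates a pyramidal soma profile; rasterized area converges to the
  requested area as pixels shrink (verified at 0.4/0.2/0.1 µm/px);
* exactly `round(coverage × soma_area)` Gaussian puncta (FWHM 0.5 µm,
  peak brightness uniform on 0.6–1.0) with centroids uniform on the
  membrane band (half-width 0.6 µm) under a minimum centre separation of
  1.2 × FWHM ≈ 2.8σ;
* a DAPI nuclear disc, per-case multiplicative intensity drift (uniform
  0.6–1.4) exercising the normalization, additive Gaussian noise
  (SD 0.03 of full scale), and clipping;
* degenerate variants exhibiting each QC defect.

Two generator choices deserve justification because they were driven by a
resolvability analysis rather than taken from any published value.  First,
the punctum FWHM is 0.5 µm and the minimum centre separation 0.6 µm: two
Gaussians of unequal brightness (0.6 vs 1.0) separated by less than ~2.8σ
present a single intensity maximum, so no detector could recover the
planted count at tighter packing — and the membrane band's random
sequential adsorption capacity at the published densities caps the
separation at about 0.6 µm anyway.  Second, when a draw approaches that
packing limit (large soma × high coverage), the placement relaxes the
separation by 15% steps rather than failing: the planted count stays
exact; a few pairs pack tighter.  Per-neuron soma areas and coverages are
drawn from ±2 SD symmetrically truncated normals around the case means,
which preserves the planted group means exactly while avoiding unpackable
extremes.  The placement band (±0.6 µm) is marginally wider than the
counting band (±0.5 µm); a punctum centred at the placement edge still
extends into the counting band, so planted membrane puncta remain
countable.

What the generator does **not** emulate: point-spread-function physics,
photobleaching, z-structure, dendritic/axonal synapses, spatially
structured background (lipofuscin, vessels), or segmentation ambiguity
from genuinely overlapping cells.  Passing recovery tests therefore shows
that the algorithm is correct and well-calibrated *under the stated image
model*, not that it would achieve the same absolute accuracy on tissue.
Group *contrasts* are more robust than absolute values: a detector bias
that is multiplicative and common to both groups cancels in a percent
difference, which is exactly how the simulated experiments are scored.

## The synthetic cohort and its statistics

Cohort tables (47 MS cases: 21 HLA-DRB1\*15 carriers, 26 non-carriers;
10 controls) are drawn per stratum from a Gaussian copula: neuronal
density is the latent factor and each correlated variable loads on it
with latent Pearson correlation $\rho = 2\sin(\pi r_s/6)$, the exact
relation for which a bivariate Gaussian copula has population Spearman
$r_s$.  The one-factor structure is positive definite for any targets
with $|\rho| < 1$, and infeasible configurations are rejected by name.
Marker expressions and fibrinogen use log-normal marginals (non-negative,
right-skewed); density, age and post-mortem interval are Gaussian, with
moments seeded from the published group tables (SDs back-computed from
SEM × √n where printed, otherwise a quarter of the printed range).  Sex
is Bernoulli with the published proportions.  The fibrinogen–density
association has no published magnitude; it defaults to a configurable
r = −0.3 (negative, per the prior literature on fibrinogen and neuronal
loss).

Note one deliberate property of sample Spearman correlations: at n = 26
the expectation of the sample statistic is attenuated by roughly 0.02
below the population value (a classical small-sample property, not a
planting error); recovery checks therefore compare means over many
replicates against the target with a ±0.03 margin.

Statistical analyses mirror the published workflow: Spearman rank
correlations (exact permutation null for n ≤ 10 without ties, t
approximation otherwise); ordinary least squares with age, sex and
post-mortem interval (plus fibrinogen where relevant) as covariates and
z-scored outcome and predictor, so coefficients are standardized betas;
outcomes are log-transformed when a Shapiro–Wilk statistic below 0.95 on
the raw but not the logged values indicates skew, and the decision is
recorded per model.  No multiple-testing correction is applied, mirroring
the source analysis (α = 0.05, two-sided); results tables carry n and the
transform so readers can apply their own.  Whether the original method
thresholded images per image or per case is unstated; this implementation
thresholds per image.

## Problem sizes and reproducibility

Every stochastic step takes an explicit integer seed and is
bit-reproducible given it; the pipeline writes a manifest with a config
hash so a run can be reproduced exactly.  The simulated recovery
experiments use 10 MS-like + 7 control-like cases of 30 neurons for the
coverage contrast (averaged over 12 seeds in the acceptance script, 3 in
the test suite) and 30 neurons per group over 20 seeds for the
neuron-size contrasts; correlation recovery uses 1000 replicate cohorts.
These sizes give Monte-Carlo standard errors an order of magnitude below
the acceptance margins while keeping a full run on a single CPU in the
minutes range.

## Known limitations

* The segmentation pipeline is a classical parametric one; it will not
  match a hand-optimised or learned segmenter on difficult tissue.
* Absolute punctum counts undercount by ~1–2% at the highest simulated
  densities (touching puncta whose intensity maxima merge); contrasts are
  unaffected because the bias is common to groups.
* DAB quantification assumes the standard haematoxylin/DAB stain vectors;
  heavily counterstained or unevenly illuminated slides would need a
  re-estimated stain matrix.
* The cohort generator plants rank correlations and marginal moments; it
  does not model spatial structure, lesion topography, or case-level
  missingness patterns beyond the configured variables.
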