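---
title: "Quantifying neurofilament and synaptic-marker signal in dendritic spines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurofilament and synaptic-marker signal in dendritic spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stedspine)
```

## The measurement problem

Neurofilaments (NF) — the intermediate-filament triplet NFL, NFM, NFH —
are classically axonal proteins, but they also occur as short oligomers in
dendritic spines. Asking whether their postsynaptic abundance tracks
synaptic traits (postsynaptic strength via homer immunolabel, presynaptic
activity via synaptotagmin-1 uptake) requires quantifying faint, punctate
STED signal inside micron-scale spine ROIs, across many imaging sessions,
and correlating it with a second channel's signal in the same spines.

`stedspine` implements that measurement chain for photon-counting
STED/confocal images:

1. **Masking.** Each manually segmented spine ROI is intersected with a
   channel-appropriate *second mask*: a fixed 4-count background threshold
   for NF STED channels, or an automatic Otsu threshold (computed on the
   integer count histogram) for synaptic-marker STED channels. Images are
   first cleared of extreme bright spots by clipping the top 0.01% of the
   count histogram. Spines crossed by bright axonal NF filaments are
   excluded, since their signal cannot be attributed to the postsynapse.
2. **Quantification.** For each spine, the masked area ($A$, in
   µm² at the 30 nm pixel size) and mean intensity ($\bar I$, counts) give
   the *amount* $Q = A \cdot \bar I$, which equals the pixel area times the
   summed masked counts. Per-spine NF area also feeds an occupancy summary
   (fraction of spines with more than 0.1 µm² of signal, strict
   inequality) and its cumulative distribution.
3. **Standardization and correlation.** Amounts are z-standardized within
   each experimental round, $z = (x - \mu_{\text{round}}) /
   \sigma_{\text{round}}$, pooled, and the NF-versus-marker association is
   summarized by the Spearman rank correlation $\rho$ with a two-sided
   p-value and the conventional interpretation bands ($|\rho| < 0.3$
   negligible, 0.3–0.5 low, 0.5–0.7 moderate, $\ge 0.7$ high).
   Standardizing before pooling makes $\rho$ exactly invariant to
   round-specific positive affine distortions of the raw amounts
   (staining efficiency, laser power, detector gain), which is the
   pipeline's core robustness property and is asserted in the tests.
4. **Colocalization and unmixing.** Channel pairs are compared by the
   Pearson correlation over non-zero masked pixels (after offsetting each
   image's minimum to zero), per compartment (spine, axon, or a cell-level
   confocal mask built by 90%-of-max clipping, 8×8 median filtering, and
   Otsu). Bleed-through between the two STED dye channels is removed by
   linear spectral unmixing with a 2×2 mixing matrix estimated from
   single-color reference samples, solved per pixel as nonnegative least
   squares so that unmixed images remain valid count images.

## The synthetic-scene generator

Raw imaging data for this kind of study is typically available only on
request, so every stage is validated against synthetic scenes with known
ground truth. `scene_config()` + `build_scene()` place horizontal dendrite
shafts carrying spine polygons (heads of 0.3–1 µm diameter on short necks;
no size cutoff, mirroring how spines are identified morphologically) and
thin axonal tracks; `render_channels()` renders photon counts per channel:

- emitter densities blurred by isotropic Gaussian PSFs
  ($\sigma = \mathrm{FWHM}/2.355$; defaults 60 nm STED, 250 nm confocal —
  typical instrument figures, since imaging hardware specifications do not
  pin down a PSF);
- Poisson readout over a uniform background (default 1.5 counts/pixel, so
  the 4-count threshold is meaningful: a background pixel exceeds it with
  probability ≈ 0.066);
- per-spine NF signal as 1–5 point emitters in the head whose summed
  intensity is proportional to the true amount — emulating the oligomeric
  puncta STED resolves at postsynapses — and one marker punctum per head;
- bright line emitters along axons (default 12 counts at the filament
  core, which reproduces an axon/spine intensity enrichment at the top of
  the 1.1–2.5× range reported for NF immunolabels);
- multiplicative per-round gains drawn from [0.7, 1.4], so that per-round
  standardization is both necessary and exactly sufficient;
- optionally, forward spectral mixing of the two STED channels by a known
  matrix.

True per-spine (NF, marker) amount pairs have log-normal marginals
(default meanlog $\log 400$, sdlog 0.6 — a few hundred detected photons
per spine with severalfold biological spread) coupled by a Gaussian
copula. The latent Pearson correlation $r$ is chosen from the requested
Spearman correlation $\rho_S$ via the bivariate-normal identity
$\rho_S = (6/\pi)\arcsin(r/2)$, so the generator's population Spearman
equals the requested value exactly; calibration tests confirm the sample
Spearman is unbiased to within ±0.01 across seeds.

A configurable fraction of spines (default 10%) is deliberately crossed by
a bright axon track; the `crossed_by_axon` flag is computed geometrically
and provides ground truth for the exclusion rule. An occupancy mode
(`p_occupied`, `nf_fill`) renders NF in only a Bernoulli subset of spines,
giving a known occupancy probability for validating the 0.1 µm² summary.

### What the generator does and does not emulate

It reproduces the features the pipeline's correctness depends on: photon
statistics, PSF blur, punctate sub-resolution signal, round effects,
bleed-through, background, and axon-crossing confounds. It does not model
3D structure, antibody labeling stochasticity beyond Poisson counts,
fluorophore blinking or drift, or inhibitory-synapse morphologies. Passing
tests therefore demonstrate that the *computational* chain recovers known
truth under realistic imaging statistics — not that any biological
conclusion about real tissue is reproduced.

## Numerical and interpretation choices

Several processing conventions are stated loosely in common protocol
descriptions; the package fixes them explicitly and exposes the
alternatives:

- *"saturated to 0.01% their highest intensity"* is read as clipping the
  top $10^{-4}$ quantile of the histogram (`tail_fraction = 1e-4`);
  clipping at 0.01% of the maximum value would erase essentially all
  signal and is rejected as implausible.
- *"saturating 90%"* for the cell-level confocal mask is read as clipping
  at 0.9 × max before median filtering (`saturate_level`).
- The *8-pixel median filter* is an 8×8 square window (even-sized windows
  use offsets −4…+3 and the lower median, keeping counts integer).
- The 4-count NF threshold is inclusive (a 4-count pixel is signal); the
  Otsu mask rule is strict (`pixel > threshold`), matching common
  implementations; ties in the between-class variance break toward the
  smallest threshold.
- Non-zero-pixel Pearson uses the `either_nonzero` inclusion policy by
  default (a pixel is kept if either channel is non-zero there), which
  retains anticorrelated signal; `both_nonzero` is available.
- $\sigma$ in the standardization is the sample (n−1) standard deviation
  (`sd_type = "sample"`); rounds with fewer than two spines or zero
  variance are dropped with a warning.
- Interpretation bands are applied to $|\rho|$; the boundary cases 0.3,
  0.5, 0.7 belong to the higher band.
- Spearman p-values are two-sided: exact permutation enumeration for
  n ≤ 9, the $t$ approximation on n − 2 degrees of freedom otherwise. No
  multiple-testing correction is applied across isoforms.
- The exclusion rule's parameters (`overlap_fraction = 0.1` of spine
  pixels on axonal-bright pixels, `bright_quantile = 0.95`) formalize a
  judgement made by eye on real data; their defaults are validated against
  simulator ground truth (≥ 99% agreement in the test conditions).
- Amounts are quantified on the saturated image, consistent with the
  masking order (saturation precedes thresholding).
- Pixel-grid conventions are fixed once: 0-based `(row, col)` coordinates,
  pixel centres at integer coordinates, even-odd rule for polygon
  rasterization. ImageJ ROI files ((x, y) order, corner-based, half-pixel
  offset) are normalized on read and write.

## Validation design and problem sizes

The test suite validates each primitive against an independent oracle
(exhaustive between-class-variance search for Otsu; explicit
filter-and-correlate and mid-rank computations for the correlation
statistics; analytic areas for rasterization; per-pixel matrix algebra for
mixing) and the whole chain against generator ground truth. End-to-end
recovery uses scenes of 800 spines (1600×1600 px) across 3 rounds with
distinct gains, 20 seeds per generative level
$\rho_S \in \{0.3, 0.5, 0.65\}$ — spanning the range of correlations
reported for NF isoforms versus synaptic markers — asserting the mean
recovered $\rho$ within ±0.06 of truth. Occupancy uses 150-spine scenes at
$P(\text{area} > 0.1\,µm^2) = 0.7$ over 10 seeds, compared at three
binomial standard errors (pooled), plus a per-seed check against each
seed's realized occupancy. Threshold masking of Poisson counts removes a
little low-tail signal, so recovered correlations sit a few hundredths
below the generative value; this attenuation is inherent to count
thresholding and is well inside the asserted bounds.

## A worked run

```{r example, eval = FALSE}
cfg <- scene_config(n_spines = 100, rho_spearman_true = 0.5, seed = 7)
res <- run_spine_pipeline(cfg)
res$correlation$result
res$occupancy$fraction

# persist the scene and a figure/table report
write_scene_fixture(res$scene, "fixture", channels = res$channels)
report_results("report", quants = res$quants_nf,
               correlations = res$correlation$result,
               scatter = res$correlation$scatter)
```

## Known limitations

- Scenes are 2D; overlap of presynaptic terminals with spines in the focal
  volume is only emulated through the axon-crossing mechanism.
- The Otsu second mask can zero genuinely dim marker puncta, creating ties
  at zero amount; this mildly attenuates rank correlations (see above).
- Spectral unmixing supports exactly two channels; chromatic registration
  is assumed (shared depletion line).
- Spine segmentation itself is out of scope: ROIs come from files (or the
  generator), mirroring manual morphological segmentation.
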