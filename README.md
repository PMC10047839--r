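# stedspine

Quantification of neurofilament (NF) and synaptic-marker signal in
dendritic spines from multicolor STED/confocal photon-counting images.

Neurofilaments — the NFL/NFM/NFH triplet — occur as short oligomers at
postsynapses, and their abundance there appears to track synaptic traits.
Measuring that requires a careful chain: masked intensity quantification of
faint punctate STED signal inside manually segmented spine ROIs, exclusion
of spines confounded by bright axonal filaments, normalization across
imaging sessions, and rank correlation against a synaptic marker imaged in
a second channel. `stedspine` implements that chain, plus a synthetic-scene
generator with exact ground truth so every stage can be validated without
access to raw microscopy data.

## The core computation

For each spine ROI, the channel image is masked by the intersection of the
ROI with a *second mask* — counts ≥ 4 for NF STED channels, or an Otsu
threshold on the integer count histogram for synaptic-marker channels,
after clipping the top 0.01% of the histogram — and summarized by the
amount metric

    Q = A · Ī   (ROI area × ROI mean intensity = pixel area × Σ counts)

Amounts are z-standardized within each experimental round,
`z = (x − μ_round)/σ_round`, pooled, and associated by the Spearman rank
correlation ρ with interpretation bands (0.3–0.5 low, 0.5–0.7 moderate).
Standardization makes ρ exactly invariant to per-round positive affine
distortions (staining, laser, detector differences). Colocalization is the
Pearson correlation over non-zero masked pixels; two-channel spectral
bleed-through is removed by per-pixel nonnegative least-squares unmixing
with a mixing matrix estimated from single-color references.

The synthetic generator couples per-spine (NF, marker) amounts through a
Gaussian copula with log-normal marginals; the latent correlation is set
from the requested Spearman value via `ρ_S = (6/π)·asin(r/2)`, so the
population rank correlation of the ground truth is known exactly.

## Worked example

```r
library(stedspine)

cfg <- scene_config(n_spines = 100, rho_spearman_true = 0.5, seed = 7)
res <- run_spine_pipeline(cfg)

res$scene
#> <spine_scene> 640x640 px, 100 spines (11 crossed), 14 axon tracks, 3 rounds, rho_true = 0.5

res$correlation$result
#> # A tibble: 1 × 6
#>   isoform marker   rho     p_value n_spines band
#>   <chr>   <chr>  <dbl>       <dbl>    <int> <chr>
#> 1 NF      marker 0.518 0.000000165       90 moderate
```

The scene simulates 100 spines on dendrite shafts across 3 experimental
rounds with distinct gains; 11 spines are deliberately crossed by bright
axon tracks. The pipeline renders the photon-count channels, builds the
4-count and Otsu masks, excludes 10 spines it detects as axon-crossed,
quantifies NF and marker amounts per spine, standardizes by round and
pools. The recovered ρ = 0.518 (n = 90 spines after exclusion) is the
rank association between the two channels' amounts — close to the
generative ρ = 0.5, and classified "moderate" by the conventional bands.
`res$occupancy` summarizes the fraction of spines with more than 0.1 µm²
of NF signal, and `report_results()` writes the standard tables and
figures (ECDF of spine NF area, standardized scatter with ρ annotation,
colocalization bars ± SEM).

A thin command-line runner is included:

```sh
Rscript inst/scripts/run_pipeline.R --out run1 --seed 7 --n-spines 100 --rho 0.5
```

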