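# myohisto

Quantification pipeline for dystrophic muscle histopathology, written for
studies of dystrophin-deficient (mdx-type) mouse models where degeneration,
regeneration and fibrosis must be scored reproducibly from whole-slide
images and RT-qPCR plates. It is aimed at imaging-facility and muscle-lab
analysts who want the scoring logic of such studies as tested, scriptable R
functions rather than one-off slide-viewer scripts.

## What it computes

From laminin + DAPI immunofluorescence:

- **Fibre segmentation** — interior-seeded watershed on the laminin ridge
  landscape (deterministic; the label-map contract accepts any upstream
  segmenter).
- **Morphometry** — area, perimeter, circularity `4πA/P²`, and the minimum
  Feret diameter `min_θ w(θ)` by rotating callipers on the convex hull;
  fibres with circularity < 0.3 (oblique/longitudinal sections) are
  excluded before statistics.
- **Centronucleated fibres (%CNF)** — each nucleus is assigned to the fibre
  under its centroid; its distance to the fibre border is the exact
  Euclidean distance transform at that point; a fibre is CNF when some
  nucleus lies deeper than `0.3·√(A/π)`.

From brightfield slides, via Beer–Lambert colour deconvolution
(`OD = −log10(I/I0)`, densities = OD through the inverse stain matrix):

- **Collagen fraction** (Sirius Red / Fast Green): thresholded Sirius Red
  density over tissue area.
- **Myonecrosis** (H&E): infiltrate foci by local nuclear density plus
  fragmented-sarcoplasm fibres, as a percentage of tissue.

From marker channels: IgM⁺ fibre fraction, eMyHC⁺ fibres/mm²,
PDGFRA⁺ (FAP) cell fraction, damage/repair/healthy region classification
(F4/80 + eMyHC), and region-normalized p-SMAD2 scores.

From qPCR plates: dilution-series standard curves with efficiency
`E = 10^(−1/slope) − 1`, relative quantities, geNorm stability `M`,
pairwise variation `V(n/n+1)`, normalization factors and group fold
changes.

A built-in synthetic-slide generator (`generate_phantom()`,
`phantom_preset()`) produces ground-truthed fields — fibre tessellation,
controlled CNF fraction, lesions, collagen, marker identities, matched
brightfield renderings — so the entire pipeline is testable without any
external data.

## Worked example

```r
library(myohisto)
ph  <- generate_phantom(phantom_spec(
  fiber_minferet_mean_um = 30, cnf_fraction = 0.6,
  collagen_fraction = 0.2, necrotic_fraction = 0.15,
  igm_positive_fraction = 0.1, emyhc_count_per_mm2 = 25,
  pdgfra_positive_fraction = 0.25,
  psmad2_class_positivity = c(damage = .6, repair = .3, healthy = .05),
  seed = 11))
res <- analyze_slide(ph$channels, ph$brightfield)
t(res$metrics)
#> n_fibers           400.0000
#> n_retained         400.0000
#> mean_min_feret_um   30.1561
#> sd_min_feret_um      5.2080
#> tissue_area_mm2      0.4597
#> cnf_percent         60.2500
#> n_cnf              241.0000
#> igm_fiber_fraction   0.1000
#> emyhc_per_mm2       23.9295
#> fap_cell_fraction    0.2500
#> psmad2_healthy       0.0586
#> psmad2_damage        0.5919
#> psmad2_repair        0.3083
#> collagen_percent    20.0000
#> necrotic_percent    13.8954
```

Each generated condition (60% CNF, 30 µm mean calibre, 20% collagen, 15%
necrosis, 10% IgM⁺, 25 eMyHC⁺/mm², 25% FAPs, p-SMAD2 positivity
0.6/0.3/0.05 by region) is recovered by the full detection path — no ground
truth is consulted during analysis.

Study orchestration: `run_pipeline()` takes a YAML/list config (sample
sheet + stage parameters + qPCR block), tolerates per-sample stage
failures, writes per-sample metrics, per-group mean ± SD summaries and a
manifest with a config hash and seed. A thin CLI lives at
`inst/scripts/myohisto-cli.R` (`simulate`, `run`, `qpcr`).

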