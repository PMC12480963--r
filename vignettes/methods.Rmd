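---
title: "Quantifying dystrophic muscle histopathology: models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dystrophic muscle histopathology: models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`myohisto` implements the quantification side of a muscle-histopathology
study of dystrophin-deficient (mdx-type) mice: how badly a muscle is
degenerating (myonecrosis, IgM uptake), how actively it regenerates
(centronucleated fibres, eMyHC⁺ fibres, fibre calibre), and how far it has
progressed to fibrosis (Sirius Red collagen fraction, FAP expansion,
TGF-β signalling readouts), plus RT-qPCR relative quantification. This
vignette explains each model, the tunable parameters, and the design
decisions taken where the underlying procedure left genuine freedom.

## Fibre segmentation

Muscle fibres appear in a laminin immunofluorescence image as dark convex
interiors separated by a thin bright basal-lamina band. Detection here is a
classical, fully deterministic interior-seeded watershed: smooth the laminin
channel (`smoothing_sigma_um`, default 1 µm), threshold the ridge (Otsu by
default, a fixed threshold for exact reproducibility), take the enclosed
low-laminin basins as fibre interiors, and split any basins merged by leaky
boundaries with a watershed on the Euclidean distance map. Boundary-band
pixels belong to background (label 0). Learned segmentation models would
slot in behind the same input/output contract — a calibrated laminin channel
in, an integer label map out — but are out of scope: the quantification
logic downstream is independent of how the label map was produced.

Fibres touching the image border have censored shapes; they are flagged and
excluded from morphometry by default (`exclude_border = FALSE` restores
them). Fibres below `min_fiber_area_um2` (default 80 µm², roughly a 10 µm
calibre fibre) are treated as segmentation debris.

## Morphometry and the circularity filter

The minimum Feret diameter — the smallest distance between two parallel
supporting lines — is the standard calibre measure for transverse fibre
sections because it is insensitive to oblique sectioning. It is computed by
rotating callipers on the convex hull: the minimum width is always attained
perpendicular to a hull edge, so scanning hull edges is exact, and an
exhaustive 0.1° rotation scan is used as the test oracle. Masks are
converted to hull polygons of pixel-corner vertices first, which makes a
single pixel a unit square rather than a degenerate point.

Circularity is the classical `4πA/P²`. The perimeter estimator matters: raw
8-connected pixel contours overestimate staircase boundaries, biasing
circularity low and distorting the exclusion cutoff, so the boundary contour
is smoothed with a 3-point moving average before summing segment lengths.
Fibres with circularity strictly below 0.3 are excluded (reason
"circularity") before any CNF or size statistic — this removes
longitudinally/obliquely sectioned profiles. The cutoff is applied as a
strict inequality, so a fibre at exactly 0.3 is retained. Whether the
upstream tooling's "circularity" included a solidity correction is not
documented anywhere we could rely on; the classical form is used and the
choice is flagged here.

## Centronucleation

Each DAPI nucleus is assigned to the fibre whose label lies under its
centroid (centroid-based assignment is robust to nucleus-segmentation noise
at fibre edges). Its distance to the fibre border is the exact Euclidean
distance transform of the fibre's pixel set evaluated at the centroid pixel
— verified against a brute-force minimum-distance oracle, equality to
machine precision.

No published cutoff defines "internal": the pipeline defaults to a relative
rule, internal iff distance > 0.3·r_eq with r_eq = √(area/π), chosen so a
subsarcolemmal (peripheral-rim) nucleus can never classify as internal,
while truly central nuclei (the synthetic ground truth places them deeper
than 0.5·r_eq) are recovered with margin. An absolute rule
(`list(absolute_um = d0)`) is exposed for parity with script-constant
implementations; on phantoms of homogeneous fibre size the two rules agree
within 2 percentage points. A fibre is a CNF if it contains ≥ 1 internal
nucleus; the percentage is over retained (filter-surviving) fibres.

## Colour deconvolution and slide scores

Brightfield stains follow the Beer–Lambert model: per channel,
`OD_c = -log10(I_c / I0_c)`, and the OD of a pixel is the linear mix of unit
stain absorption vectors weighted by local stain densities
(Ruifrok–Johnston). Deconvolution inverts the 3×3 stain matrix (a 2-stain
model is completed with the unit cross product as a residual channel);
negative densities are clipped with the clip fraction reported, since a
large clip fraction is the signature of a wrong stain model. The stain
vectors shipped as defaults (Sirius Red/Fast Green, and the classical H&E
pair) are configuration, not measurements — override them per dataset with
`stain_model()` or a YAML file (`inst/extdata/*.yaml`).

Collagen scoring thresholds the Sirius Red density channel within tissue
and reports collagen area / tissue area. The Otsu threshold is floored at
`min_od` (default 0.15 OD): on a collagen-free section the Sirius Red
channel contains only noise, and an unguarded Otsu would split that noise
into spurious "collagen". The floor is the one numerical guard in the
module; a fixed-threshold mode exists for exact reproducibility.

Myonecrosis is scored on H&E as infiltrate plus degeneration: (i) tissue
whose local haematoxylin-positive area fraction in a 20 µm disc exceeds
`density_threshold`, default 0.45 — about half the nuclear coverage of a
packed mononuclear infiltrate, i.e. a half-maximum edge criterion that
places the focus boundary where local density crosses the midpoint between
infiltrated and normal tissue; and (ii) fibres whose interior eosin density
has a coefficient of variation above 0.6 (fragmented sarcoplasm), when a
fibre map is supplied. Tissue detection on brightfield uses a fixed
summed-OD threshold (0.15) rather than Otsu because glass/cytoplasm/nuclei
make the histogram tri-modal.

## Marker scores and region classification

Fluorescence positivity thresholds default to Otsu within tissue, with one
deliberate degenerate-input convention: a constant channel thresholds at 0,
so an all-zero marker scores no positives and a saturated one scores
everything positive. A fibre is marker-positive when more than
`min_positive_area_fraction` (default 0.3) of its interior is positive —
sarcoplasmic markers like IgM and eMyHC stain whole fibres, and the 0.3
floor tolerates edge bleed. Cells (for PDGFRA⁺ FAP scoring) are positive by
the mean intensity in a 4 µm disc around the nucleus centroid.

The damage / repair / healthy partition is operational, since no published
boundary definition exists: damage = tissue where the local F4/80-positive
area fraction (20 µm disc) exceeds 0.5; repair = remaining tissue within
25 µm of an eMyHC⁺ fibre; healthy = the rest; precedence
damage > repair > healthy, and the three classes always partition the
tissue mask. "Locally normalized" p-SMAD2 scoring is interpreted as
positive-area fraction within each class; classes with zero area report
missing, never 0. All radii and thresholds are config-exposed rather than
presented as anyone's published constants.

## qPCR quantification

Standard curves are least-squares fits of mean Ct against log10 relative
input over a ≥ 3-point dilution series; amplification efficiency is
`E = 10^(−1/slope) − 1` (slope −3.3219 ⇔ 100%). Quantities invert the
curve; technical replicates are aggregated by geometric mean on the
quantity scale because Ct is log-scale. geNorm stability is
`M_j = mean_k sd_samples(log2 q_j/q_k)` with log2 ratios as in the original
description; ranking is by iterative exclusion of the highest-M gene, and
pairwise variation `V(n/n+1)` measures what the (n+1)-th gene adds to the
normalization factor. Normalization factors are geometric means of the
reference-gene quantities rescaled to overall geometric mean 1 — both a
single-reference mode (e.g. Hprt alone) and the multi-reference geNorm mode
are first-class, since practice mixes them. Fold changes are ratios of
group geometric means to the control group. The dilution range and the
replicate-aggregation rule are implementation defaults, documented here,
not inherited values.

## The synthetic-slide generator

Every stage is validated against phantoms with exact ground truth, because
the original tissue slides behind any such study are rarely deposited. The
generator emulates: a tessellation of convex-ish fibres (seeded region
growing on a jittered grid with per-fibre lognormal growth weights — not a
plain Voronoi, so the minimum-Feret distribution can be imposed directly;
the grid spacing is calibrated so the realized interior hull widths match
the requested mean, within ~3% across the preset range), a laminin boundary
band of set thickness, peripheral nuclei within ~3 px of the band and
central nuclei at the interior distance-map maximum for a controlled CNF
fraction, marker identities (IgM⁺ fibres, smallest-calibre eMyHC⁺ fibres,
PDGFRA⁺ interstitial cells), infiltrate lesions and collagen deposits hit
at the requested tissue fractions exactly (pixel-count construction), and
brightfield renderings produced through the same Beer–Lambert forward model
the analysis inverts. Nuclei are placed with a minimum centre separation
(7 px) because real nuclei are solid bodies and two coincident disks would
be one DAPI object. Fluorescence noise is Gaussian with SD = mean/SNR, a
desk-scale stand-in for shot noise; brightfield gets 8-bit quantization
plus mild Gaussian read noise. The fluorescence stack and the two
brightfield slides represent serial sections of one block, so lesion
hypercellularity appears in H&E haematoxylin but not in DAPI, keeping the
CNF ground truth exact.

All randomness descends from one integer seed through fixed sub-streams
(geometry, nuclei, marker identity, density fields, noise), so a spec
reproduces bit-identical output. Presets `wt`, `mdx_3m`, `mdx_6m`,
`mdx_12m` encode the canonical age/genotype trends (CNF 0 / 0.60 / 0.55 /
0.50 — wild-type muscle shows no centronucleation, so the wt preset pins it
to exactly 0; collagen rising with age in the dystrophic presets; necrosis
and IgM peaking early; smaller dystrophic fibre calibre), with
around 300–450 fibres per field at 1 µm/px.

What the phantoms do *not* emulate — scanner artefacts (vignetting,
stitching), 3-D tissue context, fibre-type heterogeneity, true stain
chemistry variation, realistic nucleus shapes — bounds what passing tests
show: they demonstrate that the quantification logic is correct and stable
under the stated noise model, not that segmentation would reach the same
accuracy on arbitrary real slides.

## Problem sizes and numerical choices

Tests run phantoms of ~120 fibres (340² px) for module checks and the full
preset geometry (~300–450 fibres, 700–860² px) for the end-to-end
recovery checks; the deconvolution round trip uses 10⁵ random mixtures and
the geometry oracles 200 polygons / 50 masks. Ties in the watershed are
resolved deterministically by the underlying implementation; degenerate
(collinear) regions report their maximum extent with a flag rather than a
zero width; circularity values pushed above 1 by discretization are clipped
and flagged. Pixel-corner polygon coordinates are exported 0-based (x
right, y down) in pixel units with the calibration in properties, which
keeps GeoJSON round trips lossless.

## Worked example

```{r, eval = FALSE}
library(myohisto)
ph <- generate_phantom(phantom_preset("mdx_3m", seed = 1))
res <- analyze_slide(ph$channels, ph$brightfield)
t(res$metrics)
```

## Known limitations

Segmentation is tuned for transverse sections with continuous laminin;
heavily disrupted boundaries (late-stage necrotic foci) will merge fibres.
The myonecrosis score implements the two operational components of the
standard definition (infiltrate density, fragmented sarcoplasm), not a full
SOP. Inferential statistics (ANOVA families, KS tests on circularity
distributions) are deliberately not reimplemented: the pipeline exports
tidy per-sample and per-group tables for standard statistics environments.
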