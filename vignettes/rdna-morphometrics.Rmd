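---
title: "Quantifying rDNA spatial organization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rDNA spatial organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnamorph)
library(dplyr)
```

## The measurement problem

The ribosomal DNA (rDNA) of fission yeast sits in two tandem arrays at
the ends of chromosome 3 and is transcribed inside the nucleolus.  A
live two-channel assay marks it with GapR-GFP, a bacterial DNA-binding
protein whose fluorescence highlights DNA (and the rDNA especially),
while Nhp2-mCherry delimits the nucleolar compartment.  From a 3D
two-channel stack the pipeline derives, per cell:

* **rDNA volume ratio** — voxels of the GFP mask inside the nucleolar
  mask, divided by total GFP-mask (nuclear) voxels;
* **rDNA mean GFP intensity ratio** — mean GFP over the rDNA object
  divided by mean GFP over the nucleus (dimensionless, so detector gain
  cancels);
* **mCherry volume ratio** — nucleolar mask volume over nuclear mask
  volume;
* **rDNA extension** — the physical distance (micrometres) between the
  intensity-weighted midpoints of the rDNA object and of bulk
  chromatin.

Condensation of the arrays shrinks the volume ratio and raises the
intensity ratio (fluorophores packed closer); expansion does the
opposite on volume while transcriptional activation can raise both.

## The segmentation model

Each z-slice is background subtracted with a **white top-hat**
(grayscale opening under a flat 25-pixel square subtracted from the
image), which removes any structure wider than the structuring element
— including constant offsets and linear shading — while preserving the
nucleus, whose lateral diameter (~2.6 µm ≈ 24 px at 0.11 µm/px) is
just below the element.  This is why the structuring-element size is
not a free knob: it must exceed the nucleus.  Slices are then smoothed
with a Gaussian (σ = 1 px, kernel truncated at 3σ, unit mass).  Both
filters use replicate boundary handling, so the top-hat cannot
manufacture halos at the frame edge.

Masks come from a **full-histogram 3D Otsu threshold** per channel:
the threshold maximizing between-class variance over the pooled voxel
histogram, with voxels *strictly above* as foreground.  When the
histogram has at most 256 distinct values every value is a candidate
(the search is exhaustive); ties — which occur when the histogram has
an empty gap between classes — resolve to the centre of the maximizing
interval, keeping the threshold away from either class edge.

The compartments obey set identities that are asserted, not assumed:
`rdna = nucleus ∩ nucleolus`, `bulk = nucleus \ nucleolus`.  A cell
whose intersection is empty is flagged `no_rdna_object` with zero
ratios rather than silently dropped.

Cells with two nuclei (post-mitotic) are excluded; the remaining G2
population is staged by cell length into early/mid/late tertiles.  The
boundary takes `round(0.33 n)` cells at each extreme, and cells tied
across a boundary all go to the less extreme class, so an
all-equal-length population is entirely mid G2.  Outliers in ratio
distributions are removed by Tukey fences (1.5 × IQR, quartiles by
linear interpolation — R's type 7 — the single quartile convention
used everywhere in the package).

## Screen hit calling

Per-cell records are filtered (retain nuclear mean GFP > 750 AU and
nuclear GFP volume in [10, 200] voxels, inclusive — the stated purpose
is removing empty-well artifacts, which have *low* intensity, so the
filter is a retention rule; a `direction = "drop"` flag preserves the
literal alternative for audit).  Wells with fewer than 30 cells are
dropped; each strain's two mated-duplicate well medians are averaged;
strains missing a replicate are excluded and listed rather than called
on a single well.

Thresholds are anchored on the wild-type strain imaged on eight
control plates: the centre is the mean of the eight per-plate medians,
the high cut adds one third of their interquartile range, the low cut
subtracts one quarter.  (An alternative reading of the source material
uses ±0.33/0.25 standard deviations; `threshold_mode = "sd"` provides
it, but the IQR fractions 1/3 and 1/4 are the documented default.)  A
strain is a **high** hit only when *both* volume and intensity
summaries exceed the high cuts, **low** only when both fall below the
low cuts — the conjunction guards against single-metric excursions.
With only eight control medians the sample IQR is itself noisy, so
these deliberately liberal thresholds can admit an occasional
borderline call; the synthetic screen plants its effects at three
IQRs, far outside that ambiguity.

## SGA Torin1-resistance scoring

Colony densities from grid measurement assign empty positions small or
negative values, so every negative density and the lowest 5% of
positive densities (rank-based, per plate and condition) are floored
to 1 ("no growth") before the log2 Torin1/DMSO fold change is taken.
A double mutant is **sensitive** below −10 (growth reduced more than a
thousandfold) and **resistant** at or above it (the tie goes to
resistant, since sensitivity is defined strictly).  A candidate gene
is **essential for resistance** when its deletion sensitizes ≥3 of the
5 Torin1-resistant RPL queries, and a **repressor of resistance** when
it confers resistance on ≥2 of the 3 sensitive control queries;
unmeasured pairs never vote.

## FRAP normalization

Each trace is background corrected with an extracellular ROI and
divided per frame by the same correction of a reference compartment —
the whole cell for free GFP-NLS, the whole nucleus for GapR-GFP —
which cancels acquisition photobleaching and detector gain.  The
series is then rescaled so the pre-bleach mean (all frames strictly
before the bleach frame) equals 1; both the raw ratio and the rescaled
series are returned since conventions differ.  No kinetic model is
fitted: the recovered fraction is summarized by the mean of the final
10% of frames, appropriate when acquisition extends far past the
recovery half-time.  Traces on different time bases are pooled by
linear interpolation onto the first trace's base.

## What the synthetic data emulate — and what they do not

The generators exist so every stage is testable against known ground
truth without instruments.

**Scenes** (`sim_scene`).  One nucleus is rendered as an ellipsoidal
chromatin body (semi-axes 8 × 12 × 12 voxels at 0.3 µm z-steps and
0.11 µm pixels) with the nucleolus centred on the nuclear surface —
fission-yeast nucleoli sit at the nuclear periphery.  Three rendering
conventions matter and are deliberate:

* the nucleolar interior carries *background* GFP except the rDNA —
  GapR-GFP binds DNA and the nucleolar interior is DNA-poor; without
  this the GFP mask would swallow the whole nucleolus and the rDNA
  volume ratio would degenerate to the mCherry ratio;
* the rDNA focus grows from the nucleolus–chromatin **contact point**,
  where the arrays connect to the rest of chromosome 3;
* a thin (2.5 px) chromatin-depleted shell separates bulk chromatin
  from the nucleolar compartment, as around real nucleoli.  Without
  it, chromatin blur crossing the nucleolar boundary is scored as
  rDNA — a one-sided error that inflates small fractions by tens of
  percent.

Default intensity levels are 10 (background), 100 (chromatin), 115
(rDNA foci) and 150 (mCherry nucleolus), with Gaussian noise σ = 18
AU, i.e. a signal-to-noise ratio of 5 for the chromatin signal —
deliberately at the low end of what the property tests must tolerate.
The target rDNA fraction is defined against the DNA-occupied (GFP
mask) nuclear volume, the same denominator the pipeline measures; if
the requested fraction exceeds the default nucleolus, the nucleolus
shifts inward and enlarges, and an impossible request (nucleolar
compartment exceeding the DNA-occupied volume) errors.  Rendering is
binary voxelization by default (`supersample` enables sub-voxel
coverage rendering; binary turns out kinder to threshold-based
segmentation because boundary voxels take class values rather than
intermediate ones).

Not modelled: the point-spread function, optical aberrations, detector
statistics beyond optional Poisson noise, and z-blur (slices are
independent, matching the pipeline's slice-wise preprocessing).
Passing tests therefore demonstrate the *logic* of the measurement —
segmentation, ratio formation, staging, calling — not robustness to
optical artifacts absent from the model.

**Screen tables** (`sim_screen_tables`).  96 strains in mated
duplicate across 8 plates, ~40 cells per well, with the artifacts the
filters exist for: low-intensity/extreme-volume records in every well
and one 29-cell well.  Wild-type control wells carry per-plate batch
offsets (SD 0.03 on the volume ratio, 0.25 on the intensity ratio),
centred across the campaign; they are what gives the control IQR its
width.  Planted high/low strains shift both metrics by a multiple
(default 3) of the realized control IQR.  Mutant wells do not share
the batch offsets — the generator isolates the calling logic from the
batch-correction problem, which the pipeline does not attempt to
solve.

**SGA plates** (`sim_sga_plates`).  DMSO densities near 2000 with
Torin1 densities of exactly 1 for sensitive pairs and ≥55% of DMSO for
resistant pairs.  DMSO draws for sensitive pairs come from the upper
part of the distribution so that the rank-based no-growth floor lands
only where it cannot flip a fold change — the property that makes
exact truth recovery provable rather than probabilistic.  A truth map
with fewer planted no-growth pairs than the floor converts (e.g.
all-resistant) triggers a warning, and only the gene-level claims
survive in that regime.

**FRAP traces** (`sim_frap_traces`).  Ideal recovery
`I(t) = b + m(1-b)(1-exp(-(t-t0)/tau))` with per-cell detector gain,
shared slow acquisition bleaching, camera offset, and 2% Gaussian
noise — exactly the nuisances the normalization must cancel.

## Numerical choices and degenerate inputs

* Quartiles: linear interpolation (type 7) everywhere; verified against
  a direct order-statistic oracle in the tests.
* Otsu on a constant volume: an error ("degenerate histogram"), not an
  empty mask.
* Fewer than 4 values in the outlier filter: pass-through with a
  warning.
* `floor_densities` is idempotent and preserves `NA` (unmeasured).
* Copy-number equivalence is boundary-inclusive at exactly 10%.
* Problem sizes in the test-suite and acceptance script — 64³-scale
  voxel scenes, 96-strain screens, 110-gene SGA panels, 100-frame
  traces — were chosen as the smallest sizes at which every planted
  structure (tertiles, sparse wells, vote rules) is non-trivially
  exercised.

## Known limitations

* The pipeline segments nuclei per field or per provided cell mask; it
  does not segment cells from transmitted light, so staging requires
  externally supplied cell lengths (the generator provides them).
* The Otsu threshold sits, for background-dominated fields, slightly
  above the half-height of the chromatin edge; masks are accordingly a
  fraction of a voxel conservative.  Ratios are robust to this because
  numerator and denominator move together.
* Batch effects across plates are sampled by the repeated controls but
  not corrected in mutant wells; the hit thresholds inherit the
  controls' realized spread.
* No time-lapse tracking, deconvolution, or chromatic registration.
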