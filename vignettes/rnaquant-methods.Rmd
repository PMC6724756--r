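---
title: "Methods: per-cell quantification of multiplex RNAscope images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell quantification of multiplex RNAscope images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaquant)
```

## The problem and the model

Multiplex RNAscope renders each hybridized transcript (or amplified
cluster) as a diffraction-limited fluorescent punctum. Quantifying such an
image per cell requires three decisions: what is a cell, what is a
punctum, and when is a cell "positive" for a probe. This package fixes
those decisions as follows.

**A cell is a dilated nucleus.** The DAPI channel anchors every cell: the
smoothed image (Gaussian, σ configurable, default 1 px) is thresholded
globally with Otsu's method, touching nuclei are split by watershed on the
negated distance transform of the mask, and each nucleus mask is expanded
by 3 px into a *territory*. Expansion is nearest-nucleus assignment under
the Euclidean metric with ties broken toward the lower label id, not
per-label morphological dilation — this guarantees territories are
pairwise disjoint, so every focus has at most one owner and per-cell
counts are well defined. The approximation deliberately ignores
cytoplasmic extent beyond 3 px: transcripts in distal dendrites or axons
are invisible to it, and transcripts from processes crossing a territory
are mis-attributed to it. The approach is therefore reliable where
expression clusters at the cell body and unreliable where it is diffuse.

**A punctum is a prominent maximum.** Probe channels are smoothed with a
Gaussian of σ = 1 px and maxima are extracted under a *noise tolerance*
(topographic prominence) criterion: a regional maximum `m` of value `v` is
accepted iff no path starting at `m` over pixels with values
`> v - tolerance` reaches a pixel with value `> v`. Equivalently, `m` must
stand at least `tolerance` above the highest saddle that connects it to
higher ground. Two conventions complete the rule:

* *Reference level.* A maximum with no higher ground anywhere (the global
  maximum in particular) takes the image minimum as its reference level.
  Without this convention a constant image, or an image whose total relief
  is below the tolerance, would still report one focus; with it, both
  report none. A corollary worth knowing: a bright uniform patch (e.g. an
  optical aberration) still contributes exactly one maximum — its top
  stands the full patch height above the floor under any prominence
  definition. Aberrant areas should be excluded with region masks, which
  is also how the original imaging studies handle them.
* *Plateaus.* A connected set of equal-valued pixels forming a regional
  maximum yields one focus at its centroid, rounded half-up. Equal-height
  maxima never suppress one another.

The tolerance is per channel and per sample: staining intensity varies
between probes and experiments, so it is a user-set input, applied to the
*filtered* image (filtering scales a Gaussian spot of width `s` by
`s²/(s²+σ²)`). The detector has no separate absolute intensity floor; a
dim but prominent maximum counts.

**A cell is positive at ≥ 3 foci.** Focus counts per territory are
thresholded at 3 (configurable, identical for all channels). Foci on
background pixels are *strays*: excluded from every cell but reported, so
the conservation identity `sum(per-cell counts) + strays = total foci`
always holds and is asserted in the QC report.

## Region summaries and the applicability rule

All region statistics derive from the positivity flags alone:

* `percent_positive(A)` uses **all** DAPI-defined cells of the region as
  the denominator (the heatmap quantity);
* the conditional percentage `(A|B)` uses B-positive cells as the
  denominator and is reported as missing — never 0 — when the region has
  no B-positive cell;
* co-expression classes are the full power set of channels (8 classes for
  3 channels, including "none"), and class counts sum to the cell count.

Per-cell quantification is *not applied* where it would mislead:
regions whose mean focus count over all DAPI-defined cells is below
4 dots/cell for the queried channel, and regions whose cell bodies cannot
be separated. The mean is taken over all cells, not only positive ones —
the rule is a signal-abundance gate, and conditioning on positives would
make sparse regions look abundant. Separability is assessed by the
fraction of labelled area held by objects larger than an area ceiling
(default twice the median object area; in dense tissue pass an expected
nucleus area times a small factor — the median itself is inflated once
most objects are fusions). Excluded entries appear as explicit
"not quantified" markers in the heatmap table, with the failed criterion
named.

When several slices per region are available, percentages are computed
per slice and averaged afterwards (mean ± SEM across images), not pooled
before computation; pooling would weight slices by their cell counts.

## The synthetic tissue simulator

The simulator provides ground truth for every stage; every claim the test
suite makes about recovery is a claim about these scenes, so their
construction matters.

* **Nuclei** are disks with a smooth radial falloff
  (`I = A·(1 − (d/r)²)²` complement), placed by rejection sampling under a
  minimum center spacing. Radii are normal (default mean 16 px, sd 1,
  truncated at 3 px) — at the ~0.25–0.3 µm/px sampling of a 40× confocal
  plane this is a nucleus of roughly 8–10 µm diameter. Spacing below the
  diameter produces touching nuclei; spacing far below it produces the
  fused, "too dense to separate" regime. Pixel size is a free parameter of
  the study design, not a claim about any particular instrument.
* **Counts** per cell follow either a zero-inflated Poisson
  (`π` structural zeros, Poisson mean `λ` otherwise; defaults π = 0.2,
  λ = 5, spanning negative and positive cells at the ≥ 3 threshold) or a
  degenerate law planting exactly `k` spots (for scenes with exactly known
  means). The closed-form ZIP tail `P(K ≥ k)` is exported (`zip_tail()`)
  as the analytic reference.
* **Puncta** are 2-D Gaussian kernels (default amplitude 120, σ = 1.5 px)
  at integer pixel positions inside the owning nucleus, at least 8 px
  apart within a cell so that planted spots remain resolvable after
  σ = 1 filtering at a tolerance of half the amplitude. If a drawn count
  exceeds what the cell can hold at that spacing, the remainder is placed
  without the spacing constraint — the recorded count always equals the
  planted count, so the count law is exact even when optical resolvability
  is not. Overlapping (unresolvable) puncta are a real feature of dense
  biological data that the simulator's defaults deliberately avoid:
  passing recovery tests show the pipeline is correct on resolvable
  scenes, not that real merged spots are countable.
* **Background and noise** are a uniform offset (default 20) plus additive
  Gaussian noise (default sd 8), clipped at zero and quantized to 16-bit
  integers. The default punctum SNR (amplitude/noise = 15) is an easy,
  well-stained regime. There is no Poisson shot noise, no optical
  sectioning, no photobleaching; tolerance semantics are easiest to reason
  about under additive noise.
* **Aberrations and strays**: uniform bright rectangles emulate optical
  aberrations; extracellular "stray" puncta (a configurable Poisson rate)
  exercise the background-focus path.

Identical configuration and seed give bit-identical scenes; the simulator
restores the session RNG state.

## Numerical and design choices

* **Thresholding guard.** Otsu always returns *some* split, even of pure
  noise; unguarded, a signal-free image segments into a large noise
  component. The threshold is therefore accepted only when its
  between-class variance fraction (Otsu's effectiveness measure) exceeds
  0.75 — a unimodal Gaussian histogram caps near 0.64, nuclei over
  background measure ≳ 0.85 across simulated densities — otherwise the
  image is declared all-background. This is what makes "blank image →
  zero nuclei" well defined.
* **Watershed seeds** merge below a distance-map depth of 1 px
  (`seed_tolerance`); round touching nuclei split at their waist without
  fragmenting single nuclei. Components below `min_area` (rule of thumb:
  ~25% of expected nucleus area) are removed, and labels are renumbered
  contiguously; each label is 8-connected.
* **Maxima search** is a single descending-order union-find sweep
  (C++), resolving each candidate maximum at the saddle where its
  component merges into higher ground; a per-maximum flood search — the
  definition itself — serves as the exhaustive oracle in tests, and the
  two agree exactly on random images including integer-valued ones with
  ties and plateaus.
* **Coordinates** are 1-based (row, column) everywhere, including CSV
  outputs — the R convention; mixing 0-based files with 1-based in-memory
  indexing invites off-by-one errors.
* **Determinism.** Row orders, tie-breaks (lower label id, half-up
  rounding) and CSV/JSON formatting are fixed, so identical inputs and
  configuration produce byte-identical outputs; the QC report records
  every parameter needed to reproduce a run.
* **Single planes only.** Multi-sample or volumetric TIFF pages are
  rejected rather than silently projected.

Problem sizes in the test-suite and acceptance runs — 448–512 px scenes
with 50 nuclei for recovery, 128 px scenes for the conservation sweep,
32×32 images for oracle equivalence, ~1000 pooled cells for
distributional checks — were chosen as the smallest scenes that leave the
statistical assertions well-powered (3-standard-error bands on means and
tails).

## The sag metric

For current-clamp sweeps of a hyperpolarizing step (protocol: 5 s,
−70 pA from −50 mV), sweeps are averaged pointwise (typically 5–10) and

`sag = V_steady − V_min`

where `V_min` is the trace minimum within the first second after stimulus
onset and `V_steady` the mean over the final 500 ms (configurable) of the
stimulus epoch; "final steady state" has no standard width, so the window
is a declared parameter. No smoothing is applied before the minimum
search beyond sweep averaging. Sag is invariant to constant offsets,
non-negative for traces that relax upward after the trough, and exactly
zero for flat traces. Group statistics across animals are out of scope.

## Known limitations

* Counts are per cell body; dendritic/axonal transcripts are unobserved
  and crossing processes can contaminate territories.
* The detector does not split merged (sub-resolution) puncta; in high
  expression regimes counts saturate and the ≥ 3 positivity call is the
  robust quantity, not the raw count.
* Detection tolerances are not estimated from the data; they are
  experiment-specific inputs.
* The simulator validates the pipeline's logic, not instrument realism:
  no PSF model, no shot noise, no 3-D structure.
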