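---
title: "Methods: dual-scale boundary segmentation and sector thickness analysis of macular OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-scale boundary segmentation and sector thickness analysis of macular OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retilayers)
```

## Scope and data model

`retilayers` analyses macular spectral-domain OCT raster volumes: stacks of
B-scans, each a depth-by-width reflectivity image, covering a 6 x 6 mm field
centred on the fovea. The reference protocol is 128 B-scans of 512 A-scans at
18,000 A-scans/s (`acquisition_time_s()` gives 3.6 s for the raster, 3.7 s
with the 0.1 s galvanometer overhead), with 480 axial samples at 3.5 um/px.
The axial pixel budget and pitch are device configuration; only the optical
axial resolution (6 um) is physics, and it enters the package as an
informational header field.

Volumes are stored as plain multi-page 16-bit TIFF files (one page per
B-scan) with a JSON sidecar header — an open, lossless, inspectable stand-in
for vendor containers, which this package deliberately does not parse. All
depth coordinates are 0-based sub-pixel positions in `[0, n_depth)`, with z
growing from the vitreous toward the choroid; the B-scan index grows
inferior to superior and the A-scan index nasal to temporal for right eyes
(mirrored for left).

## Boundary segmentation

### Edge model

Each boundary is an axial intensity transition of known polarity (e.g. the
ILM is dark-to-bright, Bruch's membrane bright-to-dark). A B-scan's edge
score combines derivative-of-Gaussian responses at two axial scales,

E(z, x) = w g_fine(z, x) + (1 - w) g_coarse(z, x),

with each response sign-flipped so the expected polarity is positive and
clamped at zero. Defaults: sigma_fine = 1.5 px, sigma_coarse = 6 px,
w = 0.6. The fine scale localizes; the coarse scale accumulates contrast
across speckle and carries the tracer over low-contrast stretches. Kernels
are normalized so an ideal unit step scores 1, which makes edge scores
commensurate with intensity contrasts and gives the smoothness penalty an
interpretable unit. Whether the two scales should combine by weighted sum,
product, or coarse-to-fine refinement is an open design choice; the weighted
sum is exactly solvable, easy to reason about, and is what this package
commits to.

### Exact tracing

A boundary in one B-scan is the path {z_x} maximizing

sum_x E(z_x, x) - lambda sum_x |z_x - z_{x+1}|

over a per-column search band. The maximum is found exactly by dynamic
programming; the L1 transition cost admits a two-pass (forward/backward)
max-transform, so each column costs O(n_depth) rather than O(n_depth^2), and
ties break toward the shallower node for determinism. A unit test and an
acceptance block compare the tracer against exhaustive path enumeration on
thousands of random small instances.

`lambda` is stated per pixel of axial step for the reference 512-column /
6-mm sampling and internally scaled with lateral sampling density: a path's
total |dz| across a physical feature (the foveal pit, say) does not depend
on how finely it is sampled, while its edge reward grows with column count,
so a fixed lambda would make the same tissue look "stiffer" at coarser
sampling. The default lambda = 0.3 follows the pit (slope about 0.4 px per
column at full sampling, cost 0.12 versus edge scores of 0.15-0.5) while
suppressing speckle-driven jitter.

Sub-pixel refinement runs after tracing, on a *finer* derivative response
(sigma = 1 px by default) than the tracing map: the chosen node is
re-centred on the local argmax within +/-2 px and a parabola through three
samples gives the offset. The coarse component of the tracing map merges the
closely spaced outer boundaries (ELM, EZ, OS/RPE lie 4-6 px apart) into one
blob, which would bias a peak fit on the combined map by up to a pixel; at
sigma = 1 px the three peaks are resolved. The final depth adds 0.5 px
because an edge-map row z measures the derivative at the pixel centre
z + 0.5.

### Hierarchy and search bands

Boundaries are traced highest-contrast first, each banding the next:

1. ILM over the full depth (the vitreoretinal interface is the strongest
   dark-to-bright transition).
2. BM below ILM + 100 um (minimum plausible retinal thickness).
3. OS/RPE, then EZ, in absolute-depth bands 10-32 um and 34-48 um above the
   traced BM — the photoreceptor/RPE band geometry varies far less than
   inner-retinal geometry, and fractional bands would shift with the foveal
   pit.
4. The remaining inner boundaries (2-6) top-down within fractional bands of
   the ILM-EZ span, clipped by their already-traced neighbours with a
   minimum separation of 1 px. Fractional bands are invariant to overall
   tissue scaling and wide enough to cover the collapse of the inner layers
   toward the ILM at the pit.

After each trace the boundary's rows (+/-2 px) are zeroed on its polarity's
maps so later boundaries cannot lock onto an already-claimed edge. Ordering
is finally enforced by a monotone clamp (refinement can nudge neighbours by
under a pixel); the `boundary_set` constructor independently verifies it.
Columns whose ILM edge response falls below 0.05 (no detectable retina:
blinks, clipped or empty A-scans) are marked invalid for all nine surfaces.

At the pit centre the inner boundaries genuinely lose contrast — layers
thinner than the blur cannot produce separable edges — so per-surface errors
there are structural for any gradient-based method. They are confined to a
few percent of the field and the acceptance budget (mean absolute error
<= 0.5 px noise-free, <= 2 px at heavy speckle) absorbs them.

## Thickness, fovea, sectors

Thickness between two surfaces is their depth difference times the axial
pitch; the eight sublayer maps sum to the total map to floating-point
precision by construction, and the suite asserts it. The fovea is the
minimum of the total-thickness map after Gaussian smoothing with sigma
0.25 mm (anisotropic pixel pitch handled explicitly: 6/512 mm in x,
6/128 mm in y), searched within the central 3 mm square, refined by a
per-axis quadratic fit, with ties broken toward the scan centre. A pit
contrast below 5 um flags the fix as low-confidence rather than failing:
a pitless map still yields a central minimum, and downstream QC decides.

Sector summaries use the ETDRS layout — rings of 1, 3 and 6 mm diameter,
the two outer rings split into quadrants by the 45-degree diagonals — which
the package adopts as the universal convention for macular OCT; the grid is
fully configurable in case a study used other sector dimensions. Pixel
membership is by lateral pixel-centre point. Quadrant labels resolve
laterality from the header: the +x half is temporal for right eyes and nasal
for left eyes.

## Quality-control indices

The four indices operationalize verbal definitions; their exact vendor
formulas are unpublished, so each is configurable and the defaults are
validated on phantoms.

* **Signal strength (q_score, 0-100)**: the volume's intensities are split
  by an Otsu threshold; with S and B the class means, the score is a
  logistic in S / max(B, 0.01), with midpoint 3 and scale 0.5. The raw
  ratio S/B is invariant under global attenuation, which would let a blink
  score like a clean scan — the fixed noise floor in the denominator is what
  makes attenuation visible. Zero-variance volumes score 0. The score is
  invariant to B-scan order by construction.
* **ILM indicator**: each B-scan's traced ILM is split into 16 lateral
  windows; the indicator is the minimum window mean of the edge score at the
  traced ILM across the whole scan. Blinks zero it locally. Unlike q_score
  it is *not* permutation-invariant in spirit: it localizes the worst
  window. Default threshold 0.1 (about a quarter of the clean-phantom
  value).
* **Validity count**: the count and fraction of (B-scan, A-scan) positions
  where any surface is invalid or within 2 px of the axial window limits —
  the clipping detector. Threshold: 5% of the field.
* **Motion indicators**: the minimum Pearson correlation, over consecutive
  B-scan pairs, of the RNFL (1-2) and total (1-9) thickness profiles.
  Thickness is shift-invariant, so a pure axial jump is *not* flagged until
  it clips content or disrupts tracing — consistent with using the index as
  a segmentation-failure detector; blinks destroy both correlations.
  Profiles are smoothed laterally (31-column moving average) before
  correlating so the index measures scan-to-scan consistency of thickness
  structure, not per-column tracing jitter. The minimum (not the mean) is
  used because blinks and jumps are localized. Zero-variance pairs are
  skipped; an all-flat volume reports the indicator as missing.

`apply_exclusions()` re-evaluates reports against thresholds and reports
exclusions both per volume (eye) and per subject, since imaging is per-eye
while cohort exclusions are often per-participant.

## The phantom generator

Because no study data ship with the package, every end-to-end claim is
tested on synthetic volumes with known ground truth. A phantom is:

1. **Geometry.** Nine boundary surfaces from baseline offsets (100, 140,
   190, 220, 250, 320, 335, 355, 375 um — a plausible 275 um macula) plus
   three smooth plane-wave perturbations: an *additive displacement* of all
   surfaces together (20 um, 3 mm wavelength — globe curvature and tilt;
   thickness-neutral), a *multiplicative thickness modulation* (3 um at
   boundary 9 — a diffuse lateral thickness gradient), and an *RNFL
   texture* shifting boundaries 2-5 together (10 um, 4 mm — nerve-fibre
   bundle variation that moves RNFL thickness without changing total
   thickness). The amplitudes are deliberate: the thickness modulation is
   kept small because any background total-thickness gradient displaces the
   true smoothed minimum away from the pit centre (at 3 um the shift stays
   under a pixel pitch), while the motion indicator draws its lateral
   signal mainly from the thickness-neutral RNFL texture.
2. **Fovea.** A Gaussian pit (depth 120 um, sigma 0.6 mm): the ILM
   descends by the pit depth while boundaries 2-5 compress between the
   displaced ILM and boundary 5, which stays fixed — inner layers vanish at
   the centre and the total map dips by the pit depth, so the fovea is
   recoverable from the total-thickness minimum, as in real anatomy.
   Specs whose pit would cross boundaries are rejected.
3. **Appearance.** Piecewise-constant reflectivities per compartment
   (box-averaged within pixels), exponential signal decay below BM (60 um
   length — OCT signal fades beneath the RPE; without it the volume is
   mostly bright choroid and any global contrast score misbehaves), axial
   Gaussian PSF of sigma 0.75 px (6 um FWHM at 3.5 um/px — the device's
   stated optical resolution), and multiplicative gamma speckle with mean 1
   (shape 50 by default; 30 is the heavy-noise test point), the standard
   OCT noise model. Generation is bit-reproducible given the seed, and the
   ground truth never depends on the seed.
4. **Artifacts.** Blinks multiply a B-scan range by 0.02; axial motion
   shifts all B-scans from an index onward (volume and truth together,
   vitreous fill); clipping displaces a requested fraction of field
   positions until even the ILM leaves the axial window, so clipped columns
   carry no retinal signal. Each maps onto the QC index designed to catch
   it.

What a green phantom suite does **not** establish: performance on real
pathology (drusen, fluid, haemorrhage), vessel shadows, media opacity, or
vendor-specific intensity statistics. The phantom's layers are locally
homogeneous and its perturbations smooth; real eyes are neither. The
acceptance tests quantify the method on the stated synthetic world only.

## Batch engine and throughput model

`run_batch()` mirrors a remote-repository workflow: per row, fetch a copy
into a private scratch directory, segment, extract derived rows (81 sector
summaries per volume: 9 sectors x 9 layer pairs, plus the QC report),
delete the copy — even on failure. Consent-withdrawn rows are skipped
before fetching; corrupt volumes are recorded (`failed_corrupt`) rather
than raised, and processed + failed + skipped always equals the manifest
size. The unit of parallelism is the row and rows share no state, so
derived CSVs are identical whatever the worker count; the suite diffs runs
at 1, 2 and 4 forked workers. The success percentage rounds half-up to two
decimals.

`estimate_days()` is the campaign model: `per_set_s * n_sets /
((n_logins - n_reserved) * efficiency * 86400)`. At 128 s per set, 134,611
sets and 12 logins with one reserved for transfers, it gives 18.1 days at
full efficiency and about 27.9 at 65% — the arithmetic the package's
worked-example tests pin down, together with `data_size_tb()` (97.8 MB x
134,642 sets is 13.2 TB) and `success_percentage()` (134,611 of 134,642 is
99.98%).

## Numerical and testing choices

* 16-bit quantization bounds the volume round-trip error at 1/65535; the
  TIFF codec is a minimal baseline implementation (uncompressed, one strip
  per page) because the installed R stack has no TIFF reader, and it only
  promises to read what the package writes.
* DP ties toward the shallower node; brute-force comparisons use continuous
  random scores, where ties have probability zero.
* The parabola in sub-pixel refinement is only trusted where the
  three-point stencil is concave; offsets clamp to +/-0.5 px.
* The fovea-recovery acceptance block runs `locate_fovea()` on thickness
  maps built from ground-truth surfaces: it isolates the localization
  operator at full lateral resolution within its time budget, while
  segmentation accuracy is budgeted separately (and the unit suite also
  runs the full segment-then-locate path on two phantoms).
* Heavy tests scale down: randomized-ordering and noise-monotonicity
  phantoms use 8 x 200 x 192 volumes; the error-budget and QC acceptance
  blocks use the full 128 x 480 x 512 protocol, where one volume segments
  in well under a minute on one CPU.

## Known limitations

* Search-band defaults encode macular geometry; optic-nerve-head scans or
  severely distorted retinas would need a different configuration.
* No cross-B-scan regularization: motion artifacts are detected by QC, not
  corrected by smoothing, matching the design intent of the motion
  indices.
* The q_score scale is calibrated on phantoms; mapping it onto any
  particular device's signal-strength scale would need real reference
  scans.
* Choroidal boundaries, pathology detection and vendor file formats are out
  of scope.
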