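# retilayers

Layer segmentation and thickness analysis for macular spectral-domain OCT
raster volumes, built for cohort-scale batch processing.

Population imaging studies collect OCT volumes by the tens of thousands;
manual grading does not scale, so retinal thickness must come from fast,
fully automated segmentation plus quality control that flags the scans no
algorithm should be trusted on. `retilayers` implements that pipeline for
6 × 6 mm macular rasters (128 B-scans × 512 A-scans as the reference
protocol): it segments nine intraretinal boundaries per B-scan, locates the
fovea, reports ETDRS sector thickness for the whole retina and its eight
sublayers, computes four scan-quality indices, and runs manifests of volumes
through a fetch → segment → extract → delete batch engine with parallel
workers. A synthetic phantom generator with known ground truth makes the
whole pipeline testable without study data.

## The method

Each boundary is an axial intensity transition of known polarity. A B-scan's
edge score combines derivative-of-Gaussian responses at two axial scales,

```
E(z, x) = w · g_fine(z, x) + (1 − w) · g_coarse(z, x)
```

sign-flipped so the expected polarity is positive and clamped at zero
(defaults: σ_fine = 1.5 px, σ_coarse = 6 px, w = 0.6). A boundary is the
path {z_x} that exactly maximizes

```
Σ_x E(z_x, x) − λ Σ_x |z_x − z_{x+1}|
```

found by dynamic programming (the L1 transition admits a linear-time
max-transform), with sub-pixel refinement by a parabolic fit on a finer
response. The nine boundaries are traced hierarchically — ILM, then Bruch's
membrane, then the photoreceptor boundaries (OS/RPE, EZ) above BM, then the
inner boundaries banded by their traced neighbours — so surface ordering
holds by construction. The quality indices are a logistic signal-strength
score (`q_score`), the minimum localized ILM edge strength
(`ilm_indicator`), the fraction of clipped/invalid A-scan positions
(`validity_count`), and the worst inter-B-scan correlation of RNFL and total
thickness profiles (`motion_indicators`). See the methods vignette
(`vignettes/retilayers-methods.Rmd`) for assumptions, parameters and design
rationale.

## Worked example

```r
library(retilayers)

# a 6 x 6 mm macular phantom with a 120 um foveal pit and speckle noise
spec <- phantom_spec(seed = 42)
phantom <- generate_phantom(spec)

acquisition_time_s(spec$protocol, overhead_s = 0.1)
#> [1] 3.740889

# segment the nine boundaries, locate the fovea, summarise the ETDRS sectors
bs <- segment_volume(phantom$volume)
fovea <- locate_fovea(thickness_map(bs, 1, 9))
round(fovea, 3)
#>  x_mm  y_mm
#> 3.008 3.005

sectors <- sector_summary(thickness_map(bs, 1, 9), sector_grid(fovea))
sectors[, c("sector", "mean_um", "sd_um", "valid_fraction")]
#>           sector  mean_um     sd_um valid_fraction
#> 1        central 172.2679 10.364709              1
#> 2 inner_superior 245.3718 21.842463              1
#> 3 inner_inferior 246.2694 22.317708              1
#> 4    inner_nasal 247.1227 22.519503              1
#> 5 inner_temporal 246.0038 22.275321              1
#> 6 outer_superior 274.5314  2.603991              1
#> 7 outer_inferior 274.4134  2.430603              1
#> 8    outer_nasal 274.4465  2.228501              1
#> 9 outer_temporal 275.1947  2.353868              1

# how close is the segmentation to the known truth?
round(mean(abs(bs$depths_px - phantom$truth$boundaries_px)), 2)
#> [1] 0.52

qc_report(phantom$volume, bs)
#> QC report [phantom, right eye]
#>   q_score           100.0  [pass]
#>   ilm_indicator     0.395  [pass]
#>   validity         0.0000  [pass]
#>   motion (rnfl/total) 0.894 / 0.924  [pass]
#>   excluded: FALSE
```

The phantom's pit sits at (3, 3) mm and is recovered to well under a pixel
pitch; the thin central sector (~172 µm versus ~275 µm in the outer ring) is
the foveal depression; the mean boundary error of ~0.5 px (~1.8 µm) is
dominated by speckle jitter. QC passes all four indices, so the volume would
be retained in a cohort analysis.

Batch processing takes a CSV manifest (`volume_path, subject_id, laterality,
consent`):

```r
res <- run_batch("manifest.csv", workspace = "scratch", out_dir = "derived",
                 n_workers = 4)
```

which writes `results.csv` (statuses, timings), `sectors.csv` (81 rows per
volume: 9 sectors × 9 layer pairs), `qc.csv` and a JSON-lines log, and
prints the success percentage. Campaign-scale planning helpers:
`estimate_days(throughput_model(...))` and `data_size_tb(...)`.

A thin command-line wrapper ships at `inst/cli/retilayers.R`
(`phantom`, `segment`, `qc`, `batch` subcommands).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a small phantom cohort (clean, blink-affected and clipped
volumes at the full raster size), runs it through write/read → segmentation
→ thickness/sector extraction → QC → batch, prints the cohort QC outcome and
the campaign accounting models, and writes the (empty) acceptance-target
JSON to `--out`.
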