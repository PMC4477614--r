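# aeropheno

Plot-level phenotyping of low-nitrogen stress in maize trials from
low-altitude multispectral imagery.

Breeding for low-N tolerance means scoring hundreds of small two-row plots
— replicated hybrids under a ladder of ammonium-nitrate rates — for canopy
vigor and senescence. A UAV-mounted green/red/NIR camera can survey the
whole trial in one flight at ~60 mm/pixel, but the raw frames are a long way
from phenotypes. aeropheno implements the full chain:

1. **Imaging** — demosaic the color-filter-array frames (Bayer-like tiling
   with NIR in place of blue), convert digital numbers to reflectance with
   an empirical-line calibration (fixed gains or estimated from a reference
   panel), and mosaic frames by absolute position with nearest-center
   blending.
2. **Extraction** — derive per-row regions of interest from the trial
   layout, separate vegetation from soil with a per-row Otsu NDVI cutoff,
   and pool vegetation reflectances per plot.
3. **Indices** — per plot: NDVI = (R_NIR − R_red)/(R_NIR + R_red); the
   nitrogen stress index NSI = 1 − NDVI_i/NDVI_m (NDVI_m = mean NDVI at the
   highest, reference N rate); green fraction GF (hue ∈ [60°, 180°]) and
   greener fraction GGF (hue ∈ [80°, 180°]) from plot RGB photographs; and
   the crop senescence index CSI = 100 (GF − GGF)/GF.
4. **Field statistics** — whole-field NDVI mean/min/max/SD/CV, a
   moving-window CV map, and polygonized high-variability zones for trial
   placement.
5. **Analysis** — a continuous two-segment ("broken-stick") least-squares
   fit of senescence against N rate with grid-searched breakpoint; Pearson
   correlations (t-based p, Fisher-z CI) between indices and grain yield
   within N-rate strata; and hybrid tolerance ranking by mean NSI at low N.
6. **Synthetic trial generator** — a split-plot 10 hybrids × 6 N rates
   {0, 10, 20, 40, 80, 160} kg/ha × 3 blocks layout, a nitrogen-response
   model with known ground truth, rendered CFA frames and plot-level RGB
   images, so the entire pipeline can be validated against known answers
   without flight data.

The methods vignette (`vignettes/low-n-phenotyping.Rmd`) documents the
models, the tunable parameters and the design decisions.

## Worked example

Simulate a 48-plot demo trial (4 hybrids × 6 rates × 2 blocks), render and
process its imagery, and analyze the result — one call:

```r
library(aeropheno)
cfg <- validate_config(list(
  seed = 1,
  paths = list(out_dir = "demo_run"),
  design = list(n_hybrids = 4, reps = 2),
  sensor = list(frame_width = 1024, frame_height = 512),
  scene  = list(rgb_width = 32, rgb_height = 32)))
run_pipeline(cfg)
cat(readLines("demo_run/report.txt"), sep = "\n")
```

```
aeropheno analysis report
=========================
plots: 48   reference rate: 160 kg/ha

Senescence broken-stick response (CSI ~ N rate):
  breakpoint 40 kg/ha; slopes -0.4992 / -0.05003 %/kg; rss 0.1543

Correlations with grain yield:
  ndvi   all    r= 0.853 *** (n=48)
  ndvi   low    r= 0.861 *** (n=16)
  ndvi   high   r= 0.353 NS  (n=16)
  nsi    all    r=-0.853 *** (n=48)
  nsi    low    r=-0.861 *** (n=16)
  nsi    high   r=-0.353 NS  (n=16)
  csi    all    r=-0.887 *** (n=48)
  csi    low    r=-0.795 *** (n=16)
  csi    high   r=-0.599 *   (n=16)

Low-N tolerance ranking (mean NSI at low rates, ascending):
   1. H01 (tolerant) mean NSI 0.422
   2. H02 (tolerant) mean NSI 0.465
   3. H03 (sensitive) mean NSI 0.518
   4. H04 (sensitive) mean NSI 0.565
```

Reading the report: the senescence index declines steeply (−0.50 %/kg)
up to the 40 kg/ha breakpoint and then flattens (−0.05 %/kg) — N supply
beyond that rate no longer delays senescence much. Canopy–yield
correlations are strong and significant under low N but collapse at high N,
where the canopy saturates and other factors limit yield. The stress index
separates the tolerant hybrids (lower NSI at low N) from the sensitive
ones. The run directory also holds the calibrated mosaic
(`field_mosaic.tif` + world file), the per-plot index table
(`indices.csv`), ROI geometries (`roi.geojson`), field-variability outputs
and a `manifest.json` with parameters, seeds and artifact checksums;
re-running with the same config reproduces every artifact bit for bit.

Individual stages are plain functions (`generate_layout()`,
`render_multispectral()`, `demosaic_cfa()`, `calibrate()`,
`mosaic_frames()`, `auto_rows()`, `extract_spectra()`,
`build_index_table()`, `fit_broken_stick()`, `pearson()`, ...), and
`inst/scripts/aeropheno` wraps the pipeline for shell use:

```sh
Rscript inst/scripts/aeropheno run --config demo.yaml --seed 1
```

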