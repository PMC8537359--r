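# cytoquench

Semiquantitative detection of cytosolic cytochrome c — an apoptosis
readout — from two-channel confocal images of cells loaded with carbon
quantum dots (CQDs).

CQDs accumulate in the cytosol and emit blue fluorescence (~440 nm).
Cytochrome c released from mitochondria during early apoptosis absorbs in
that emission band and quenches the dots (inner filter effect), so under
acquisition settings held identical across samples, dimmer cytoplasm means
more cytosolic cytochrome c. `cytoquench` implements the full analysis as
a reusable, tested pipeline for anyone who wants to quantify or simulate
this readout:

* **synthetic scenes** — fields of elliptical cells with one nucleus each,
  a DRAQ5-like nuclear channel and a CQD channel whose cytoplasmic
  brightness is attenuated by a monotone quench function
  `q(c) = 1/(1 + K c)` (Stern–Volmer, pluggable) of cytochrome c
  concentration, with full ground truth;
* **segmentation** — Otsu/fixed threshold masks, nuclei as seeds,
  multi-source geodesic region growing (compiled, deterministic
  smaller-label tie-break), and mask subtraction yielding cytoplasm-only
  labels ("cells without nuclei");
* **quantification** — area and mean CQD intensity of every cytoplasm
  object, pooled across the images of each experimental group;
* **statistics** — each treated group versus control: Welch t test,
  Wilcoxon–Mann–Whitney, and KS normality with a Monte-Carlo Lilliefors
  null, plus shared-bin histogram data for stacked distribution plots;
* **spectroscopy** — relative quantum yield
  `phi_x = phi_st (A_x/A_st)(Abs_st/Abs_x)(eta_x/eta_st)^2` against a
  quinine bisulphate standard (phi = 0.54), quench-curve fitting,
  stepwise quench time courses, emission/absorbance spectral overlap and
  photostability drift.

## Worked example

The `analysis/` scripts run the whole study in four numbered stages
(simulate → segment/quantify → statistics → spectroscopy). Bulky
intermediates (TIFF scenes, per-cell records) go to `scratch/run/`; small
result tables land in `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_segment_quantify.R
Rscript analysis/03_group_stats.R
Rscript analysis/04_spectroscopy.R
```

Stage 1 simulates five groups — control plus two doses each of etoposide
(ETO25/ETO50) and staurosporine (STAU25/STAU50) — as 3 images x 50 cells
per group at 1024 x 1024, with cytosolic cytochrome c of 0, 5, 15, 10 and
25 µM mapped through the calibration to quench factors:

```
  control  cytc =    0 uM -> quench factor q = 1.000
  ETO25    cytc =    5 uM -> quench factor q = 0.833
  ETO50    cytc =   15 uM -> quench factor q = 0.625
  STAU25   cytc =   10 uM -> quench factor q = 0.714
  STAU50   cytc =   25 uM -> quench factor q = 0.500
```

Stage 3 prints the group comparison (this exact table, seed 101):

```
   group   n    mean       p_t    p_mww p_ks_normal p_ks_classical significant
 control 150 21303.9  1.00e+00 1.00e+00       0.797          0.965       FALSE
   ETO25 150 17950.6  9.89e-86 1.75e-49       0.934          0.992        TRUE
   ETO50 150 13921.2 2.85e-156 1.08e-50       0.711          0.940        TRUE
  STAU25 150 15542.2 3.36e-137 1.08e-50       0.377          0.789        TRUE
  STAU50 150 11351.6 3.20e-175 1.08e-50       0.799          0.965        TRUE
```

Read it as: all 150 measured cells per group; control compared against
itself gives p = 1 by construction; every treated group's mean cytoplasmic
CQD intensity is reduced (more quenching at higher quencher
concentration: STAU50 < ETO50 < STAU25 < ETO25 < control) and the
reduction is overwhelmingly significant by both the t and rank tests,
while none of the per-group distributions departs from normality. Stage 4
prints the benchtop-side numbers on synthetic traces:

```
Quantum yield: 0.111 (11.1%)
Stern-Volmer K: 0.0391 per uM (half quench at 25.6 uM)
Emission peak shift at 100 uM: +30 nm
Time-course segment means: 900.8 642.9 499.6 408.2
  step drops: -257.9 -143.2 -91.4
Emission/absorbance overlap: 0.892
Photostability: slope 0.0007508 a.u./s, p = 0.315 -> no significant drift
```

The same thing programmatically, in one call:

```r
library(cytoquench)
cfg <- default_run_config(seed = 101, output_dir = "scratch/demo")
manifest <- run_pipeline(cfg, write_images = FALSE)
manifest$table
```

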