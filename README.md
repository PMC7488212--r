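# cfhier — connective-field convergence along the visual hierarchy

`cfhier` is an R package for asking a directional question about the visual
cortex: **does information converge or diverge between V1 and extrastriate
areas, and how does that change along the visual hierarchy?** It is aimed at
visual-neuroscience groups analyzing retinotopic fMRI (stimulus-driven or
resting state) who want the full pipeline — connective-field fitting, the
convergence statistic, and exact small-sample inference — validated
end-to-end on synthetic cortex with known ground truth.

## The model

A **connective field** (CF) predicts a target voxel's BOLD series from the
cortical surface of a source area with a circular Gaussian of center `v0`
(a source unit) and size `σ` (mm geodesic distance):

    ŷ(t) = g · Σᵢ wᵢ sᵢ(t),   wᵢ ∝ exp(−d(v0, i)² / 2σ²),  Σ wᵢ = 1,  g ≥ 0

fitted by exhaustive search over all source units and the size grid
`0.0001, 0.2, 0.4, …, 10 mm`, keeping voxels with variance explained
≥ 20%, σ > 0.0001 mm (point CFs are one-on-one connections, not fields),
and target eccentricity in 0.5°–7.5°. CF sizes corrected for ipsilateral
representations are **sampling extents** (SE); the per-area summary is
their VE-weighted median. The headline statistic is the **convergence
magnitude**

    CM(x) = SE(V1 → x) − SE(x → V1)     [mm; > 0 ⇒ convergence]

and its per-subject OLS slope over hierarchy levels (V1 0, V2 1, V3 2,
hV4 3, LO 3.5, TO 5.5), compared within and between groups with *exact*
Wilcoxon signed-rank / rank-sum tests (Bonferroni 3 for streams, 9 for
areas).

## Worked example

Simulate an 8-control / 6-patient stimulus-run study under the default
group regimes (control: convergence rising 1.61 mm per hierarchy level;
patient: flat slope with a V1–V3d offset), run the whole pipeline, and
report:

```r
library(cfhier)
cfg <- run_config(seed = 42L)   # 8 controls, 6 patients, stimulus condition
res <- run_pipeline(cfg)
report_results(res, seed = 1)
subset(res$slope_tests, stream == "both")
```

which prints (abridged):

```
Convergence magnitude (mm), median +/- SE of median:
  control  V2     2.00 +/- 0.07 (n = 8)
  control  V3d    2.80 +/- 0.05 (n = 8)
  control  TO     7.80 +/- 0.17 (n = 8)
  patient  V3d    4.10 +/- 0.13 (n = 6)
  patient  TO     1.50 +/- 0.14 (n = 6)
Hierarchy slope (mm/level), median +/- SE of median:
  control  both       1.31 +/- 0.05 (n = 8)
  patient  both      -0.15 +/- 0.03 (n = 6)

 stream         comparison            method  W        p_raw p_corrected
   both       control_vs_0    signed_rank_mc 36 0.0074899251  0.02246978
   both       patient_vs_0 signed_rank_exact  0 0.0312500000  0.09375000
   both control_vs_patient       rank_sum_mc 84 0.0006699933  0.00200998
```

Reading it: control convergence magnitudes rise with hierarchy level
(median slope 1.31 mm/level, corrected p = 0.022), the patient cohort is
flat (corrected p = 0.094 — with n = 6 and Bonferroni 3 the signed-rank
test *cannot* fall below 0.05, a discreteness fact worth knowing), the
groups differ (corrected p = 0.002), and the patient regime's planted
V1–V3d offset is visible (patient 4.10 mm vs control 2.80 mm). The
`_mc` method tags mark tie-handling by seeded Monte-Carlo permutation —
quantized size estimates produce tied slopes.

The command-line interface mirrors the pipeline
(`simulate`, `preprocess`, `fit`, `analyze`, `run-all`, `stats`, `report`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/cfhier", package = "cfhier"))')
Rscript $CLI simulate --group control --condition stimulus --seed 1 --out out/
Rscript $CLI stats --design group_compare --w 80 --n1 8 --n2 6 --correction 3
```

## Layout

- `R/` — mesh + retinotopy generators, bar-stimulus/pRF forward model,
  stimulus and resting-state simulators, preprocessing, CF fitting,
  convergence aggregation, exact tests, IO and CLI.
- `vignettes/cfhier-methods.Rmd` — models, assumptions, parameter choices,
  and what the synthetic validation does and does not establish.
- `tests/testthat/` — unit, property, and acceptance tests (fixtures are
  generated in code).
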