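---
title: "Connective-field convergence along the visual hierarchy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connective-field convergence along the visual hierarchy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cfhier)
```

## The question and the statistic

Visual cortical areas exchange information in both directions. A *connective
field* (CF) describes the patch of cortical surface in a source area whose
pooled activity best predicts a single target voxel's BOLD time series: a
circular Gaussian, folded over the source surface, with center $v_0$ (a
source unit) and size $\sigma$ in millimetres of geodesic distance,

$$\hat{y}_t(\text{target}) = g \sum_i w_i\, s_i(t), \qquad
  w_i \propto \exp\!\left(-\frac{d(v_0, i)^2}{2\sigma^2}\right),
  \quad \sum_i w_i = 1,$$

with non-negative gain $g$ fitted by least squares. If the CFs of V1-to-area-x
fits are larger than those of area-x-to-V1 fits, information *converges* going
up the hierarchy. The package's headline statistic is the **convergence
magnitude**

$$\mathrm{CM}(x) = \mathrm{SE}(\mathrm{V1} \to x) - \mathrm{SE}(x \to \mathrm{V1}),$$

the difference of VE-weighted-median *sampling extents* (CF sizes corrected
for ipsilateral representations), and its ordinary-least-squares slope over
hierarchy levels (V1 = 0, V2 = 1, V3 = 2, hV4 = 3, LO = 3.5, TO = 5.5),
fitted per subject over both streams together, the dorsal stream
(V2d, V3d, TO), and the ventral stream (V2v, V3v, hV4, LO).

## Fitting procedure

`fit_cf()` performs an exhaustive search: every source unit is a candidate
$v_0$ and $\sigma$ ranges over the fixed grid 0.0001, 0.2, 0.4, ..., 10 mm
(51 values). The 0.0001 mm value is a point-CF sentinel: at realistic
inter-unit spacing it puts all weight on a single unit, i.e. a one-on-one
connection rather than a connective field, and such fits are excluded from
summaries. Variance explained is floored at zero
($\mathrm{VE} = \max(0, 1 - \mathrm{RSS}/\mathrm{TSS})$, columns centered),
and ties are broken toward smaller $\sigma$, then smaller $v_0$ index, so
results are bit-reproducible. Voxels enter the summaries when
$\mathrm{VE} \ge 0.20$ (inclusive), $\sigma > 0.0001$ mm, and the target's
retinotopic eccentricity lies in $[0.5, 7.5]$ degrees (both bounds
inclusive; the *target* map supplies the eccentricity). The per-area summary
is the VE-weighted **lower** median (no interpolation) of sampling extents;
with equal weights this is the lower ordinary median. Composite V2 and V3
summaries pool the d/v fit tables (union of rows), not the two sub-medians.

Geodesic distances are shortest paths on the mesh edge graph with Euclidean
edge lengths (Dijkstra, restricted to the region), the standard surrogate
for exact polyhedral geodesics at millimetre scale; distance matrices are
cached per (mesh hash, region).

**Sampling extent.** The ipsilateral correction is a named, swappable policy.
The built-in `truncated_rms` policy computes the weighted RMS geodesic
distance from $v_0$ over contralateral source units only and rescales by the
all-units RMS: $\mathrm{SE} = \sigma \cdot \mathrm{RMS}_{contra} /
\mathrm{RMS}_{all}$, so $\mathrm{SE} = \sigma$ exactly when no ipsilateral
unit carries weight. This is a documented stand-in, not a reimplementation
of any previously published correction; its outputs should not be presented
as replicating one.

## Preprocessing

Stimulus runs are **only** linearly detrended: a 0.01–0.1 Hz bandpass would
remove the stimulus-locked response itself (a bar sweep takes 24 s, i.e.
0.042 Hz, but onset/offset transients and sweep harmonics fall outside the
band). Resting-state runs are detrended and then bandpass filtered to
0.01–0.1 Hz with a zero-phase frequency-domain mask: gain 1 inside the band,
raised-cosine transitions of width 0.005 Hz outside it, DC removed. The mask
is real and symmetric, hence exactly zero phase; a forward–backward IIR
filter would be an acceptable alternative but offers no advantage at these
run lengths. `preprocess_run()` dispatches on the run's condition tag.

## Exact inference

Group comparisons use the two-sided Wilcoxon rank-sum test and within-group
slope tests the one-sample signed-rank test, both with *exact* null
distributions built by dynamic programming (subset rank-sum counts; sign
assignments of ranks). The two-sided p-value is twice the smaller tail,
capped at 1 — the most common convention. Ties use midranks with a seeded
Monte-Carlo permutation fallback ($10^5$ draws), because tie-aware exact
enumeration is instance specific. Bonferroni correction uses factor 3 for
the three stream comparisons and 9 for the nine area comparisons. Spearman
correlations (bias audit) use midranks with an exact permutation p-value up
to $n = 8$ and a t-approximation beyond.

A consequence of discreteness worth stating: with six subjects the smallest
attainable signed-rank p-value is $2/2^6 = 0.031$, so after Bonferroni
correction by 3 a six-subject group can never reach $p_c < 0.05$. Patient
"non-significance" in the validation experiments is therefore structural —
a property of the design, not evidence of a flat slope on its own. The
bias audit compares direction differences of median VE, included-voxel
count, point-CF proportion, and mean target eccentricity between groups
(Bonferroni over the four variables) and, only where a difference is found,
computes the Spearman correlation between that variable and the convergence
magnitude.

## The synthetic world

The generator exists so that every downstream stage can be validated against
known ground truth; its defaults are a *stated world*, chosen once.

**Geometry.** Flat, regular triangulated patches, one unit per vertex.
Extrastriate patches use 1 mm spacing; the V1 patch uses 13×13 vertices at
2 mm spacing (24 mm extent). The wide V1 patch is essential: a Gaussian
kernel wider than the patch is unidentifiable (the VE profile over $\sigma$
becomes flat and noise picks the argmax), and forward widths reach the
10 mm grid maximum. The 1 mm extrastriate spacing is needed to resolve
backward kernels near 1 mm. Real cortical surfaces are folded, but the CF
model consumes only geodesic distances, which flat patches exercise fully.

**Retinotopy.** Log-eccentricity runs linearly along one patch axis and
polar angle along the other; all areas share the same coverage
(0.5–7.5 degrees by default) so that retinotopic correspondence between
areas is well defined. Units are contralateral unless an explicit
ipsilateral margin strip is requested (used to exercise the sampling-extent
correction).

**Stimulus runs.** A drifting-bar aperture movie (8 degree radius, 2 degree
bar = radius/4, 16 steps of 1 degree per sweep, 1.5 s steps, 4 orientations
× 2 directions = 128 frames) drives each V1 unit through an isotropic 2D
Gaussian pRF (size $0.5 + 0.2\,\mathrm{ecc}$ degrees, a conventional V1
size–eccentricity relation). Each extrastriate unit's neural drive is the
normalized Gaussian-kernel-weighted sum of V1 drives, centered on its
retinotopically corresponding V1 unit, with the area's *forward* width —
exactly the CF generative model, so noiseless recovery is exact. V1 series
mix in a *feedback* component, $(1-f)\cdot\text{feedforward} +
f\cdot\text{backward-kernel-pooled extrastriate drive}$ with $f = 0.2$: the
minimal scheme that makes both fit directions informative. All neural
series pass through a canonical double-gamma HRF (peak 6 s, undershoot
16 s, ratio 1/6 — configurable; nothing in the analysis depends on the
exact shape) and are sampled at TR 1.5 s.

**Resting-state runs.** 240 volumes at TR 2 s. A spatially smooth
(Gaussian-kernel-mixed grid field, 1 degree scale), temporally AR(1) and
low-pass (< 0.1 Hz) latent field over visual-field coordinates is sampled
at each unit's visual-field position. Each area mixes the *shared* field
with an independent area-local field of identical construction (local
variance share 0.3): without the local component, corresponding units in
different areas would be exact copies and every fit would collapse to a
point CF — a degenerate world. Series then propagate through the
direction-specific kernels with a coupling share of 0.5 (resting activity
is not dominated by a feedforward drive, so the propagated component is
given more weight than the stimulus-condition feedback fraction).

**Group regimes.** The control regime sets the forward-minus-backward
kernel width difference to 1.61 mm per hierarchy level (backward width
1 mm everywhere); the patient regime is flat (slope 0) with a single
V1–V3d offset of 4.45 mm. Subjects are realizations with kernel widths
jittered by N(0, 0.3 mm²), truncated at 0.15 mm. All regime constants are
overridable.

**Noise.** After global rescaling of the clean signal to unit RMS, units
receive white Gaussian noise (default sd 0.25) and a random linear drift
(slope uniform in ±0.5 over the run). The default noise level was fixed
once, with two considerations: (i) it leaves the estimator in its
identifiable regime — CF size estimation under source noise is *attenuated*
(wide kernels shrink because the VE profile flattens near the patch scale;
narrow kernels inflate because pooling averages source noise out of the
regressor), and at noise sd 0.5 the recovered hierarchy slope drops to
roughly 65% of truth, whereas at 0.25 the median recovered slope is within
about 17% of the generator value; (ii) it yields median VE around 0.9,
the upper range of per-voxel fit quality reported for stimulus-driven CF
analyses of this design. The attenuation at higher noise is a real property
of the estimator, not of the generator, and anyone reusing the generator at
higher noise should expect compressed slopes rather than unbiased ones.

**What the generator does not emulate** (hence what a green test does not
establish): folded cortical geometry, physiological (structured, non-white)
noise, motion, inter-subject anatomical variability, hemodynamic
variability across areas, and any nonlinearity between neural drive and
BOLD. Validation here shows the *pipeline* recovers the *stated* generative
structure; it cannot certify behavior under artifacts it never sees.

## Validation experiments shipped with the package

* **Oracle equivalence** — DP-built rank-sum and signed-rank nulls equal
  brute-force enumeration; Dijkstra geodesics equal a Floyd–Warshall oracle.
* **Noiseless recovery** — with on-grid generating widths, 252 target units
  recover $\sigma$ exactly and reach VE = 1 to 1e-6. On-grid widths matter:
  an off-grid width (say 4.22 mm) is recovered at the nearest grid value
  with VE ≈ 0.99998, so "VE = 1" is only meaningful on-grid.
* **Regime separation** — over 20 replicate cohort pairs at default noise,
  control cohorts (n = 8) show a significantly positive both-streams slope
  (corrected signed-rank p < 0.05) and patient cohorts (n = 6) do not;
  the median recovered control slope stays within 25% of 1.61 mm/level.
* **Null symmetry** — with identical kernels in both directions, identical
  patch geometry, and zero noise, the mean resting-state convergence
  magnitude over 40 seeds is within ±0.1 mm of zero for every area
  (per-seed SD ≈ 0.2 mm; 40 seeds were chosen a priori so the experiment
  has the power its tolerance implies).

## Degenerate inputs and numerical corner cases

Zero-variance targets are flagged and excluded rather than fitted. An
all-ipsilateral CF support is an error (the sampling extent is undefined).
A band incompatible with the sampling rate is rejected naming the Nyquist
frequency. Empty selections produce NA summaries, and a stream with fewer
than two distinct hierarchy levels refuses to fit a slope. The bootstrap
standard error of the median (used only for reporting, $10^4$ seeded
resamples) is NA for single-value groups. Every generator is a pure
function of its seed; reruns of the pipeline with the same configuration
produce byte-identical TSV outputs.
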