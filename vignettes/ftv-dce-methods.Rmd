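---
title: "Functional tumor volume from DCE MRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional tumor volume from DCE MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftvdce)
```

## The problem

Neoadjuvant systemic therapy (NAST) for triple-negative breast cancer is
given before surgery; roughly half of patients reach a pathologic complete
response (pCR), and the rest face markedly worse outcomes. An imaging
marker that separates the two groups *during* treatment would let
non-responders be redirected early. Dynamic contrast-enhanced (DCE) MRI
captures contrast wash-in and wash-out kinetics voxel by voxel, and
volume-style summaries of the enhancing tumor are natural candidates for
such a marker. This package implements that analysis chain: voxel-wise
enhancement maps, tumor volumetrics, and a threshold grid search that picks
the volume definition with the best discrimination.

## Enhancement maps

Each patient-timepoint is a 4D series $S(\mathbf{x}, t)$ with at least one
pre-contrast phase ($t \le 0$) and post-injection phases near 1, 2.5, and
7 minutes. Because the acquisition samples every 8–15 s, nominal phases are
resolved to the nearest acquired timestamp (`select_phase()`); pre-contrast
requests resolve to the last phase before injection.

Per voxel, with $S_E$, $S_P$, $S_L$ the early, pre-contrast, and late
intensities:

* **percentage enhancement** $\mathrm{PE} = (S_E - S_P)/S_P \times 100$,
  the relative wash-in amplitude, undefined (flagged invalid, never an
  error) where $S_P \le 0$;
* **signal enhancement ratio** $\mathrm{SER} = (S_E - S_P)/(S_L - S_P)$,
  large where contrast washes out fast — the signature of aggressive tumor
  vasculature.

Two SER edge cases need a policy the formulas do not give:

* voxels that do not enhance early ($S_E \le S_P$) are marked invalid —
  an enhancement ratio of noise over noise carries no information;
* voxels that enhance early but return to baseline by the late phase have a
  vanishing denominator. They are *exactly* the fast-washout tissue SER is
  meant to flag, so they get the cap `SER_CAP = 10` — above the top of the
  threshold grid (2.0), so they pass every SER threshold — with
  `valid = TRUE`. "Vanishing" means $S_L - S_P \le \varepsilon$ with
  $\varepsilon = 10^{-6}\times$ the study's intensity dynamic range.

Invalid voxels can never enter a downstream volume count. Both maps are
ratios, so they are invariant under global intensity scaling; the tests
exploit this.

## Volumetrics

With the three orthogonal tumor diameters (anteroposterior, craniocaudal,
transverse, in cm) measured on a subtraction image:

* $\mathrm{LD}$ = the largest diameter;
* $\mathrm{TV} = \frac{4}{3}\pi \frac{AP}{2}\frac{CC}{2}\frac{TR}{2}$, the
  ellipsoid through those diameters;
* $\mathrm{ETV}$ = voxel volume $\times$ number of segmented voxels;
* $\mathrm{FTV}(\theta_{PE}, \theta_{SER})$ = voxel volume $\times$ number
  of segmented, valid voxels with $\mathrm{PE} > \theta_{PE}$ **and**
  $\mathrm{SER} > \theta_{SER}$.

Two deliberate readings:

* **"Above threshold" is strict.** The grid includes $(0, 0)$; a non-strict
  rule would count non-enhancing $\mathrm{PE} = 0$ voxels in an
  "enhancement-defined" volume.
* **Voxel volume uses the slice increment, not the slice thickness.**
  Overlapping-slice protocols (3.0 mm slices every 1.5 mm) advance the grid
  by the increment; using thickness would double every volume. Spacing is
  given in mm and converted to cm³ once, at the ETV/FTV boundary.

Relative changes $\%X/\mathrm{BL} = (X - \mathrm{BL})/\mathrm{BL} \times
100$ are undefined when the baseline value is 0 — a complete response at
C2/C4 is expected ($-100\%$), but a zero baseline leaves no denominator, so
the change propagates as missing rather than raising an error, and such
patients are dropped (with a logged count) only from the cells where it
happens.

Masks drawn generously can be tightened with `refine_mask_histogram()`,
which keeps the voxels above an Otsu threshold computed over the masked
subtraction intensities. The threshold search is exact over the observed
sample (every distinct value is a candidate cut, maximizing between-class
variance) rather than a 256-bin approximation, so the refined set is
reproducible and testable against brute force; constant histograms return
the mask unchanged. On synthetic data the masks delineate the enhancing
tumor exactly, so the demo analyses run with `refine = FALSE` — refinement
exists to trim over-inclusive manual contours on real images, and applying
it to an exact mask would only bite into the tumor.

## Threshold grid search

The grid is fixed: PE from 0% to 220% in 5% steps (45 values), SER from 0
to 2 in 0.05 steps (41 values), 1845 pairs; SER values are stored as
integer hundredths so every grid value is exact at two decimals.
`ftv_grid()` computes all pairs by binning each voxel once (how many PE and
SER thresholds lie strictly below its values) and accumulating a reverse 2D
cumulative histogram — contractually identical, and verified in tests, to
evaluating `ftv()` pair by pair.

For each measurement kind (FTV per early phase at BL, C2, C4, and the
relative changes), `auc_surface()` computes the cohort AUC at every pair
and `select_optimal()` picks the maximizing pair. Ties at the maximum take
the minimum PE-and-SER pair; when the tied set has no componentwise
minimum, the lexicographic (PE first, then SER) minimum is used — it
coincides with the componentwise rule whenever one exists, and the full tie
set is logged. Cells where every patient has the same value (e.g. both
thresholds above every voxel) evaluate to 0.5 under the tie convention of
the Mann–Whitney AUC estimator, so the surface has no undefined cells from
ties.

## Statistics

* **AUC**: the Mann–Whitney estimator $U/(n_1 n_0)$, ties counted ½. The
  positive class is non-pCR (residual disease) with higher-is-positive
  orientation for both raw volumes and relative changes — non-pCR patients
  have larger on-treatment volumes *and* less-negative changes — so
  reported AUCs follow the $\ge 0.5$ convention without taking
  $\max(A, 1-A)$.
* **CI and p for AUC**: DeLong's nonparametric variance from placement
  values; normal CI clipped to $[0,1]$; two-sided test of AUC $= 0.5$.
  Perfect separation degenerates the variance to zero: the CI collapses to
  a point and the result is flagged rather than silently inventing width.
* **Group comparisons**: Mann–Whitney via the standard rank-sum machinery —
  exact enumeration when the combined sample is $\le 20$ with no ties
  (where enumeration is cheap and exactness free), otherwise the normal
  approximation with tie and continuity corrections.
* **Best cutoff**: Youden's $J$ over observed scores, smallest maximizer on
  ties, for determinism.
* **Categorical tables**: Freeman–Halton (r×c) Fisher's exact test via the
  network algorithm; tables with totals beyond the enumeration budget must
  opt into Monte-Carlo estimation explicitly.

## The synthetic cohort generator

No public DCE dataset accompanies this analysis, so the generator is a
first-class, tested module. It emulates the study conditions: a 49% pCR
rate; phases at $-10$, 60, 150, 420 s; axis-aligned ellipsoidal tumors on a
uniform background (axis-aligned so the diameter ground truth is exact and
TV analytically checkable); per-voxel kinetics
$S(t) = S_0(1 + A\,w(t))$ with $w$ rising linearly to 1 at the 1-minute
phase and decaying linearly to $1 - W$ at the late phase; and additive
Gaussian intensity noise.

Parameter defaults, chosen once:

* **shrinkage** (multiplicative volume factors vs baseline): pCR 0.35 at
  C2 and 0.02 at C4; non-pCR 0.75 and 0.45. Response lives here — the pCR
  arm's enhancing volume nearly vanishes by C4 (complete response with an
  empty mask is allowed and exercised).
* **kinetics**: $A \sim U(0.5, 2)$ (PE 50–200%), $W \sim U(0.2, 1)$,
  *identical in both arms*. Giving the non-pCR arm hotter kinetics would
  let baseline FTV separate the arms — the emulated cohort's baseline
  measurements do not discriminate, so response status must not leave a
  baseline signature.
* **geometry**: $64^3$ voxels at 1.5 mm isotropic spacing, baseline
  semi-axes $\sim N(14, 3^2)$ mm (longest diameter ≈ 2.8 cm, matching the
  emulated cohort's median); tumors are checked to fit the grid.
* **noise**: SD 2 on a pre-contrast level of 100 — high-SNR subtraction
  imaging. Additive Gaussian rather than Rician: at this SNR the
  difference is negligible and the Gaussian keeps the zero-noise limit an
  exact closed form, which the tests rely on. With `noise_sd = 0`, PE
  inside the tumor is exactly $100A$, SER exactly $1/(1-W)$ (capped at
  complete wash-out), and FTV at $(0,0)$ exactly the true enhancing volume.

Everything derives from one seed; the same configuration and seed give a
byte-identical cohort. What the phantom does *not* emulate: anatomy and
heterogeneous background parenchyma, pharmacokinetic (Tofts-type) kinetics,
motion, coil inhomogeneity, and inter-reader segmentation variability. A
passing suite therefore demonstrates the computational chain is correct and
recovers known ground truth — not that the thresholds selected on real
images would transfer.

## Problem sizes

The test suite runs cohorts of 4–16 patients on 16×16×12 grids (seconds);
the full-scale analysis scripts and the acceptance script use the default
$n = 100$, $64^3$ configuration, generated patient-by-patient so only one
patient's volumes are ever in memory (about a minute on one core). The
in-sample optimism of maximizing AUC over 1845 pairs is visible in the
synthetic results (C4 AUC near 1 at these effect sizes) and is quantified
only via the synthetic-recovery checks; no cross-validation is attempted,
matching the analysis being reproduced.

## Known limitations

* LD/TV diameters are taken from mask bounding boxes for synthetic data;
  caliper measurement on real images is accepted as input, not automated.
* The C2-vs-C4 comparison tests the *value distributions* of the two
  timepoints against each other; comparing correlated AUCs directly would
  need a paired-ROC test, which the reproduced analysis did not specify.
* Whether ETV voxel counting should use the manual or refined mask is
  exposed as `refine =`; the default (`TRUE`) refines, and synthetic runs
  disable it as discussed above.
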