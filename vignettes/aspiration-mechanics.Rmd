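---
title: "Measuring and classifying zygote viability from aspiration mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and classifying zygote viability from aspiration mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryomech)
```

## The measurement and the model

A one-cell embryo held at a micropipette is exposed to a suction step
(holding pressure −0.03 psi, step −0.345 psi by default) and the depth
to which it is drawn into the pipette is recorded at 75 frames per
second. The depth trace shows three regimes: an instant elongation, an
exponential settling, and a slow constant-rate creep. The smallest
lumped network reproducing all three is the modified Zener model — an
equilibrium spring $k_0$ in parallel with a Maxwell arm ($k_1$,
$\eta_1$), in series with a dashpot $\eta_0$:

$$x(t) = \frac{F_0}{k_0}
  - \frac{F_0 k_1}{k_0 (k_0 + k_1)} e^{-t/\tau} + \frac{F_0 t}{\eta_0},
  \qquad \tau = \frac{\eta_1 (k_0 + k_1)}{k_0 k_1}.$$

$F_0 = |\Delta p| \, \pi (d/2)^2$ is the net force of the pressure step
through the pipette opening (diameter $d$; 40 µm mouse, 70 µm human).
We use the *net* step (step minus holding pressure): the embryo is
already equilibrated at the holding pressure when the step arrives.
Simpler models each miss one regime — Maxwell has no exponential,
Kelvin–Voigt no instant jump, Zener no constant-rate tail — and the
five-parameter two-arm Wiechert adds little; `compare_models()` makes
this argument quantitatively on any trace.

Three conventions worth stating explicitly:

* **Labels.** $k_0$ is the equilibrium (parallel) spring that sets the
  settled depth $F_0/k_0$; $k_1$ is the Maxwell-arm spring that sets
  the instant jump $F_0/(k_0+k_1)$; $\eta_1$ the arm dashpot; $\eta_0$
  the series dashpot (late-time creep rate $F_0/\eta_0$). Aspiration
  depth is positive into the pipette regardless of the suction sign.
* **Five-parameter model.** The network (equilibrium spring plus two
  Maxwell arms) has an exact biexponential creep obtained by Laplace
  inversion of its compliance; we implement that exact form rather
  than an arm-by-arm approximation, so the closed form agrees with
  direct ODE integration of the network to machine-level tolerance for
  all five models.
* **Verification.** `creep_ode_oracle()` integrates the network's
  force-balance equations with a stiff solver using the internal
  dashpot strains as state variables; no analytic solution enters it.
  Tests require closed form and oracle to agree to better than 1e-8
  relative.

## Fitting

`fit_trace()` minimises the residual sum of squares with
Levenberg–Marquardt, parameterised in $\log$ space (positivity without
active bounds; log-parameters are clamped at $e^{\pm 300}$ so no LM
trial step can overflow). Initial values come from the data: the
late-time slope gives $\eta_0$, the late-time intercept $k_0$, the
initial jump $k_1$, and a log-linear fit of the detrended residual the
time constant; eight log-spaced rescalings of that guess serve as a
fallback multi-start. Convergence: relative tolerances 1e-12, at most
500 iterations; non-convergence is reported (`converged = FALSE`) with
the best parameters found.

`compare_models()` additionally enforces the nesting logic of the
model family: every model here is a limit of a richer one
(Kelvin–Voigt and Maxwell are $k_1\!\to\!\infty$ and $k_0\!\to\!0$
limits of Zener; Zener is the $\eta_0\!\to\!\infty$ limit of the
modified Zener and the $k_2\!\to\!0$ limit of the Wiechert). If a
richer model ever fits worse than its nested special case, it is
refitted from the nested solution embedded in its parameter space,
which removes local-optimum artefacts from the comparison table.

**Identifiability.** At the human viable center
($k_1=0.30$, $\eta_1=0.59$, $k_0=0.12$ in N/m, N·s/m), $\tau = 6.9$ s.
A trace must cover roughly $3\tau$ for $k_0$ and $\eta_0$ to separate
from the unsettled exponential: a Cramér–Rao analysis at 0.1 µm noise
and 75 Hz gives a 14.5% floor on the relative error of $k_0$ for a
5-s window, dropping to 1.5% at 10 s. The recovery studies in the
tests and the acceptance script therefore use 21-s traces (and 8-s
videos, where the tracker's noise level is lower); with those window
lengths the median recovery error is below 0.5% per parameter.

## Synthetic data: what it emulates, and what not

The generators define the study conditions used throughout the tests.

* **Cohorts** (`cohort_spec()`, `sample_cohort()`). Viable embryos are
  log-normal around the reference viable centers (human
  $k_1=0.30, \eta_1=0.59, k_0=0.12$; mouse $0.17, 1.3, 0.06$) with
  15% multiplicative spread — a tight cluster. Non-viable embryos have
  no typical phenotype: a 50/50 mixture of a "too stiff" (centers
  ×1.8) and a "too soft" (×0.55) component with 40% spread, the factor
  applied jointly to $k_1, \eta_1, k_0$ so that an embryo is stiff or
  soft as a whole. $\eta_0$ is drawn from one shared distribution for
  both classes (center 10 N·s/m human, 5 mouse — values chosen once so
  the constant-rate tail is visible but not dominant in a measurement
  window; no reference value exists for $\eta_0$) and is therefore
  uninformative for viability by construction. Cell-cycle intervals
  are tight normals around $(c_1, c_2, c_3) = (0.20, 11.32, 2.91)$ h
  for viable embryos and a wide uniform band (0.3–3× center) for
  non-viable ones. Blastocyst labels equal the mechanical class
  flipped with probability 0.1 (`label_noise`), so classification is
  hard but learnable. Default size 80 viable / 120 non-viable — the
  n = 200 reference size of the evaluation studies, with a
  study-like viable fraction.
* **Traces** are the closed form plus i.i.d. Gaussian depth noise.
* **Videos** are soft-edged grayscale scenes: dark horizontal pipette
  walls entering from one side, a disk-shaped embryo at the opening,
  and a tongue with a hemispherical leading cap whose position follows
  the supplied motion; 0.5 µm/px, additive pixel noise. The fixture
  draws a small pre-step tongue, as the holding pressure does in the
  real protocol; the frame in which the step is commanded supplies the
  depth zero, so extracted depths include the instant jump.
* **Confocal stacks** contain a smooth cortical ring at 95% of the
  cell radius plus Gaussian granule puncta on the same annulus, with
  per-slice $e^{-k/\lambda}$ attenuation to exercise the contrast
  normalisation.

None of these model optics (no point-spread function, no shading, no
debris), multi-embryo scenes, or cryopreservation effects. Passing
tests therefore demonstrate correctness of the algorithms under the
stated noise models, not robustness to every artefact of real
microscopy.

## Tracking

`detect_pipette()` smooths (σ = 2 px), binarises with Otsu's
threshold, finds the wall rows as long dark runs touching the entry
border, and refines the opening column as the termination corner of
the wall edge lines on a Canny edge map (the dark-run length itself is
not used, because the embryo body can sit flush against the wall ends).
`track_edge()` cuts a template around the leading edge in frame 1,
restricted to the lumen rows and shrunk to stay clear of the static
pipette mouth, and matches it per frame by normalised cross-correlation
along the pipette axis. Subpixel refinement evaluates the correlation
at linearly interpolated fractional shifts (0.2 px grid) around the
integer peak before the final parabolic step — plain three-point
interpolation showed ~0.1 px pixel-locking bias. Frames whose peak
correlation falls below 0.6 are flagged and bridged by linear
interpolation (at most 3 consecutive; more is an error). On noiseless
renders the tracker is accurate to ~0.01 px RMS; with pixel noise,
well below the 0.5 px the round-trip studies assume.

## Classification

Features are z-scored per training fold; tuning, standardisation and
model fitting never see test-fold rows (a corrupted test row provably
leaves other out-of-fold scores unchanged — this is tested). The RBF
kernel is $\exp(-\lVert u-v\rVert^2 / 2\sigma^2)$; `tune_hyperparams()`
maximises stratified 10-fold CV accuracy over a log-spaced grid with
ties broken toward smaller cost, then larger σ (the smoother model).
`mc_cross_validate()` repeats stratified 10-fold CV with reshuffled
folds, pools each repetition's out-of-fold decision values into one
ROC and one PR curve (pooling keeps thresholds coherent across folds),
and reports across-repetition means and s.d. ROC/PR construction
groups tied scores into a single threshold; the trapezoidal ROC AUC is
then exactly the Mann–Whitney statistic, which the tests verify by
brute-force pair counting. Null calibration is done with a fresh label
permutation per repetition; re-using one permutation across all
repetitions concentrates at that permutation's chance association
rather than at 0.5.

`forward_feature_select()` re-tunes hyperparameters for every
candidate set and evaluates candidates within a step on the *same*
fold assignments (a paired design — the dominant noise term, fold
composition, cancels from the comparison). Even so, ranking a
*conditionally* near-null real feature above a spurious association of
a truly class-independent one is sample-limited: with the joint
stiff/soft mixture, the third mechanical feature adds almost no
conditional signal at n = 200, and the class-independent $\eta_0$ is
ranked last in about 80% of cohorts, not essentially always. This is a
property of the cohort model, not of the selection procedure's noise
(the mis-ranking reproduces across evaluation seeds on the same
cohort).

## Granule scoring

Each slice is rescaled by its 1st–99th percentiles to [0, 1]
(percentile rescaling is the package's reading of "contrast
adjustment"; it makes the score invariant to affine intensity changes
and removes depth attenuation), the stack is max-projected (granules
are sparse bright puncta; mean projection is available), the cell is
located by Otsu → hole-filled largest component → Canny → circle
Hough, and the intensity profile is read along the circumference at
95% of the cell radius with a band of width 10% of the radius
(7 radii spanning [0.90R, 1.00R], bilinear interpolation, one angular
sample per circumference pixel). The profile's mean tracks granule
brightness, its s.d. angular granularity. The Hough votes only along
the gradient direction toward increasing intensity, so for a bright
cell on a dark background only the outer boundary votes at the center
— interior ring edges scatter their votes — and detection fails loudly
(never a default geometry) if the peak's vote mass is below a fraction
of the circumference. The annulus is the *centered* reading of the
band ("width 10%" centered at 0.95R), configurable.

## Statistics

Every test returns a `test_report` that records the convention used:
Wilcoxon rank-sum exact by enumeration for $n_x+n_y \le 20$ without
ties, else tie- and continuity-corrected normal approximation; KS
exact for $n_x n_y \le 400$ without ties; Pearson χ² with Yates
correction by default on 2×2 tables (and a warning when an expected
count is below 5); pooled-variance two-proportion z (whose square is
the uncorrected 2×2 χ²); Lilliefors with a seeded Monte-Carlo null
next to the analytic approximation; Welch t by default with a pooled
option. Counts available only as percentages (74%/24% of 55 transfers →
41/55 vs 13/55; 67% of 282 vs 70% of 35) are reconstructed with
rounding and used as consistency checks, not exact fixtures.

## Problem sizes

The bundled studies use: 100 parameter draws for the ODE oracle; 100
replicate 21-s traces for noisy recovery; 100 traces × 5 models for
model comparison; cohorts of n = 200 for null calibration (100
permutations) and feature selection (100 cohorts); one noiseless 5-s
and five noisy 8-s videos for tracking; 100 punctate/smooth render
pairs for granule scoring. These sizes give stable statistics while
keeping a full run in the minutes range on a single CPU.

## Known limitations

* Parameter recovery degrades sharply when the trace is much shorter
  than $3\tau$; the fitter does not currently warn about this.
* The pipette detector assumes roughly horizontal walls touching the
  entry border and a single embryo.
* The cell locator expects one dominant, roughly circular cell.
* Forward selection reports the full AUC path but does not itself pick
  "the" optimal feature count; read it off the plateau.
* Cohort realism is limited to what the mixture model encodes; in
  particular the stiff/soft factor acts jointly on all mechanical
  features, so conditional feature information is lower than if the
  classes separated independently per feature.
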