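# embryomech

Viability of a fertilized egg can be read out, within hours of
fertilization, from how the embryo deforms under gentle suction.
`embryomech` implements that analysis chain for micropipette-aspiration
measurements of one-cell (2PN) embryos: it models the aspiration-depth
creep response with lumped viscoelastic networks, extracts the depth
time series from bright-field video, classifies embryos as
viable/non-viable (blastocyst-forming or not) from their fitted
mechanical parameters with an RBF-kernel SVM, scores cortical-granule
retention in confocal z-stacks, and provides the two-sample statistical
tests these comparisons use. Because raw measurements of this kind are
rarely shared, the package also ships seeded generators for every input
it consumes — embryo cohorts, aspiration traces, aspiration videos and
confocal stacks — so the whole pipeline is exercised end-to-end on
synthetic data with known ground truth.

It is aimed at researchers in embryo biomechanics and at developers of
non-invasive embryo-selection methods who want a tested, reusable
reference implementation of this analysis.

## The model

The embryo's bulk creep response to a pressure step is described by a
modified Zener (standard linear solid) model: an equilibrium spring
`k0` in parallel with a Maxwell arm (spring `k1`, dashpot `η1`), in
series with an extra dashpot `η0`. For a step force
`F0 = |Δp|·π·(d/2)²` (pipette inner diameter `d`), the aspiration depth
is

    x(t) = F0/k0 − F0·k1/(k0(k0+k1)) · exp(−t/τ) + F0·t/η0,
    τ = η1(k0+k1)/(k0·k1)

an instant elongation `F0/(k0+k1)`, an exponential settling toward
`F0/k0`, and a constant-rate tail `F0/η0`. Maxwell, Kelvin–Voigt,
Zener and a two-arm Wiechert variant are implemented alongside for
model comparison, each validated against direct numerical integration
of the spring–dashpot network. Parameters are estimated by
Levenberg–Marquardt least squares in log space with data-driven
initialization.

The classifier follows the measurement protocol end to end: z-scored features
(`k1`, `log η1`, `k0`, optionally cell-cycle intervals `c1`–`c3`),
an SVM with RBF kernel tuned by stratified 10-fold cross-validation,
Monte-Carlo repeated CV with pooled out-of-fold ROC/PR curves, and
greedy forward feature selection.

## Worked example

Fit a simulated human-zygote measurement and cross-validate a
viability classifier on a synthetic cohort:

```r
library(embryomech)

## one aspiration measurement (70-um pipette, -0.03 / -0.345 psi)
pro <- pressure_protocol(-0.03, -0.345, 70e-6)
emb <- visco_params(k0 = 0.12, k1 = 0.30, eta1 = 0.59, eta0 = 10)
tr  <- render_trace(emb, pro, noise_sd = 1e-7, duration = 21, seed = 42)
fit_trace(tr, pro)
#> <fit_result> model = modified_zener  rms = 9.92e-08  converged = TRUE
#> <visco_params>  k0=0.12, k1=0.3, eta1=0.5903, eta0=10.01

## a 200-embryo synthetic cohort, mechanics-only classifier
coh   <- sample_cohort(cohort_spec("human", seed = 1))
fm    <- feature_matrix(coh, c("k1", "log_eta1", "k0"))
tuned <- tune_hyperparams(fm$X, fm$y, seed = 1)
mc    <- mc_cross_validate(fm$X, fm$y, tuned$cost, tuned$sigma,
                           n_mc = 100, seed = 2)
round(c(AUC_ROC = mc$auc_roc_mean, AUC_PR = mc$auc_pr_mean), 3)
#> AUC_ROC  AUC_PR
#>   0.880    0.852
operating_points(mc$curves, "specificity", target = 0.95)
#> at >=95% specificity: sensitivity 0.76, precision 0.93
```

The fitted parameters recover the generating ones to a fraction of a
percent (the residual 9.9e-8 m is the injected 0.1-µm measurement
noise), and the cross-validated AUCs quantify how well mechanics alone
separates embryos that will form blastocysts from those that arrest in
this synthetic cohort.

The same pattern works for the imaging branches:

```r
## aspiration video: holding tongue, then the creep response after frame 5
t     <- (0:380 - 5) / 75
motion <- 3e-6 + ifelse(t > 0, creep(pmax(t, 0), "modified_zener", emb,
                                     step_force(pro)), 0)
video <- render_video(motion, video_scene(), seed = 3)
trace <- to_trace(track_edge(video), 0.5e-6, 75, onset_frame = 5, pro)

stack <- render_confocal(n_puncta = 40, n_slices = 8, seed = 4)
score_stack(stack)    # cortical-granule profile mean and s.d.
```

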