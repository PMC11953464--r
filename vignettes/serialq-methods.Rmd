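---
title: "Models and methods behind serialq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serialq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`serialq` studies a single scientific question end to end: when two
sensorimotor tasks overlap in time, where in the brain is task
information processed serially rather than in parallel, and does that
serial queuing explain the behavioral psychological refractory period
(PRP)? This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the synthetic experiments can
show.

## The behavioral model

Reaction times decompose into three stages: perceptual (P), central
response selection (C) and motor execution (M), each gamma distributed.
The first response time on any trial is `P1 + C1 + M1`. Under the serial
(bottleneck) model the second task's central stage cannot start before
the first task's central stage has finished:

```
RT2 = max(P2, P1 + C1 - SOA) + C2 + M2
```

measured from the second stimulus. The parallel variant removes the
`max` coupling. `simulate_behavior()` records every stage draw and the
realized central postponement per trial as ground truth.

**Defaults and why.** `stage_model()` uses P = 0.100 s, C = 0.835 s,
M = 0.131 s. These are calibrated so that (i) the single-task mean RT is
1.066 s, the regime reported for eight-alternative arbitrary mappings;
(ii) because the two tasks share perceptual statistics, the mean central
postponement at the short 300 ms SOA is `E[C] − SOA = 0.535 s`, which
reproduces a second-task RT near 1.60 s at the short SOA and near the
single-task RT at the long 1500 ms SOA. Response selection carries the
bulk of the RT, consistent with selection duration scaling in the number
of alternatives. Coefficients of variation default to 0.25 for C and 0.1
for P and M (selection carries most RT variability); the between-subject
lognormal scale on C has sd 0.25, giving a realistic ±200 ms spread of
subject mean RTs and, consequently, of PRP magnitudes — the spread that
individual-differences correlations rely on. Response accuracy is
Bernoulli(0.9) per response; only fully correct trials enter analyses.

## The experimental design generator

`design_spec()` encodes the protocol: TR 199 ms, 1600 volumes (318.4 s)
per run, 10 runs of 48 trials (8 per condition: two single-task and four
dual-task conditions crossing task order with 300/1500 ms SOAs), 8
stimulus–response mappings per task balanced exactly within every
condition and run, 7.96 s pre-run and 9.96 s post-run rest.

Inter-trial intervals run from second-stimulus *offset* (stimulus
duration 0.2 s) to the next first-stimulus onset — with that reading the
48-trial run fits its 318.4 s duration, which no other reading permits.
ITIs follow a truncated decaying-exponential law restricted to the TR
grid on [3.98, 11.144] s, with the rate solved numerically (by
`uniroot`) so the theoretical mean is exactly 5.4 s. Stimulus onsets are
quantized to the TR grid (our convention; it makes the shape-free basis
exact). A sampled ITI vector that would overflow the run is re-drawn a
bounded number of times, then reported as a packing error naming the
run; the re-draw slightly truncates the upper tail of the ITI *sum* but
leaves the marginal law intact.

## Region models and BOLD synthesis

Five region families translate trials into neural boxcars:
stimulus-locked sensory events of fixed duration (auditory, visual); a
central region (MD) whose boxcar spans each task's central stage —
serialized across tasks under the bottleneck model; motor regions (M1,
FEF) spanning their modality's selection-plus-execution window, i.e.
co-timed with selection; and a hypothetical execution-only family
(`exec`) locked to the motor stage, used as the contrast class in the
quartile diagnostics. The manual motor region optionally receives a
negative (suppression) boxcar during the oculomotor task.

Each region holds one unit-normalized Gaussian weight vector per
stimulus–response mapping; an event drives voxel v with amplitude
`a · (1 + g · w[mapping, v])`. Voxel trains are convolved with the
region's double-gamma HRF at TR resolution with *fractional bin
overlap*, so sub-TR event timing survives sampling. Noise is AR(1)
(marginal sd 0.3% signal, lag-1 coefficient 0.3), plus random
Legendre-polynomial drift and shared sinusoidal nuisance components,
mapped to scanner units around a per-voxel baseline.

**SNR honesty.** The defaults (pattern gain g = 2, noise sd 0.3%) were
fixed once, from pilot forward simulations, so that time-resolved
decoding peaks near 50% accuracy. Real 7T data of this kind decodes
closer to 20–35%; the generator is deliberately cleaner so that
desk-scale recovery experiments (12–100 subjects, 2–4 runs each) have
the statistical resolution that the original 26-subject, 10-run study
achieved by volume. Passing recovery tests therefore demonstrates
correctness of the estimation chain, not attainable effect sizes on
noisier real data.

## Estimation chain

* **Scaling.** Each voxel is divided by its temporal mean × 100, so
  betas read as percent signal change.
* **Designs.** Whole-event regressors convolve delta or boxcar trains
  with the double-gamma HRF. The shape-free basis places one indicator
  per post-onset lag, 69 lags by default (≈13.5 s at TR 199 ms,
  matching a 69-estimate deconvolution window); overlapping trials sum.
  Incorrect trials get their own set; drift is Legendre order 3 plus an
  intercept per run; external censor vectors delete rows before any
  estimation.
* **Prewhitening.** OLS residuals give a lag-1 autocorrelation per voxel
  (within runs); data and design are quasi-differenced (first row scaled
  by `sqrt(1 − rho²)`) and refitted. This AR(1) feasible-GLS replaces
  full ARMA restricted-maximum-likelihood — a documented simplification;
  the ROI-pooled coefficient is the default for multi-voxel fits (one
  factorization, multi-RHS), per-voxel whitening is available. Normal
  equations are solved by Cholesky with a pivoted-QR fallback that
  diagnoses genuine rank deficiency by column; all-zero columns (empty
  groups, truncated lags) are excluded and reported as `NA` betas.
* **Trial-wise estimation.** Whole-event per-trial betas are fitted
  jointly per run (dual conditions and incorrect trials as pooled
  regressors). Trial-wise timecourses use the least-squares-sum scheme:
  per target trial, one FIR set for that trial, one shared set for the
  remaining same-condition trials, one shared set per other condition,
  plus nuisance. Overlapping *single-trial* indicator sets make the
  all-trials-separate system exactly rank deficient on the TR grid —
  the degeneracy the pooled scheme exists to avoid; on non-overlapping
  designs the two coincide exactly (a test asserts this).

## Latency estimation

ROI-mean condition timecourses are curve-fitted with a cubic smoothing
spline (smoothing by generalized cross-validation); decoding-accuracy
timecourses, being noisier, with a fixed-baseline single gamma (baseline
= the 12.5% chance rate). Peak latency is the argmax on a 10 ms grid
with parabolic refinement; onset latency is the earliest ascending
crossing of baseline + 10% of peak amplitude before the peak; FWHM is
the half-amplitude width. Because deconvolved timecourses carry slow
baseline wander, latency baselines are re-anchored to the fitted curve's
mean over the first 0.8 s (a pre-response window) — without this, onset
estimates at desk-scale trial counts are unusable. Thresholds are
measured relative to the curve's baseline (0 for percent signal; chance
for accuracy curves), resolving the ambiguity of a "10% of maximum"
rule.

Raw (TR-sampled) second-task timecourses are aligned by the largest TR
multiple not exceeding the SOA — the floor rule, giving 199 ms and
1393 ms shifts for the 300/1500 ms SOAs — while fitted curves shift by
the exact SOA. Rounding instead of flooring would give 1592 ms for the
long SOA, contradicting the published shifts; hence the floor.

In the double-gamma formula both exponent constants use the natural
logarithm and the exponential's denominator is `f² / (8 ln 2 · p)` —
the unique reading for which each lobe peaks at its nominal
time-to-peak with unit height, verified analytically in the tests.
Default parameters when unfitted: A = 1, p1 = 5 s, f1 = 5 s, p2 = 14 s,
f2 = 9 s, dip = 0.3.

## Decoding

Feature selection takes the top-k voxels by activation t (or by the
minimum t across the two tasks, for multimodal regions); k defaults to
50, ties break by voxel index. The classifier is eight one-vs-rest
L2-regularized logistic regressions with penalty 25 on the summed
log-loss (intercept unpenalized), fitted by Newton iteration —
deterministic, and cross-checked against glmnet's equivalent objective
in the tests. Features are z-scored with training-fold statistics only.
"Leave-one-out" is implemented leave-one-*run*-out, which guarantees the
train/test independence the procedure exists for; prediction is the
argmax of decision values with ties to the lowest label. Folds whose
training set lacks a mapping class are skipped with a warning rather
than silently mixing data. For single-task time-resolved decoding the
fold containing the tested trial never contributes to training; for
dual-task testing the single-task training set is independent by design.
Task orders are pooled by unweighted pointwise averaging of accuracy
curves.

## The serial-queuing recovery experiment

`serial_queue_experiment()` is the computational core: simulate subjects
(default 12, each with four runs of the study's 48-trial timing),
estimate training patterns and LSS timecourses in the MD region, decode
time-resolved, align second-task curves by the exact SOA, fit gammas,
and compare. The group-level postponement estimate comes from gamma fits
of *group-mean* accuracy curves (as group-averaged timecourses are
fitted in this literature), with each subject's curves
amplitude-normalized by their own fitted gains before averaging.
Normalization matters: subjects with slower central stages contribute
both larger postponements and larger decoding bumps, so an unnormalized
group average is amplitude-weighted toward late shifts and overstates
the postponement — the second-task curve carries this amplitude–latency
coupling twice (through its shift and its duration) while the
single-task reference carries it once. Per-subject fits remain free and
un-normalized and feed the individual-differences correlation between
behavioral PRP and recovered second-task onset shift. Subject central-stage scales are drawn as
permuted lognormal quantiles by default, so the realized injected mean
postponement matches the population value instead of fluctuating with
the subject sample — a standard variance-reduction device that keeps
recovery error separate from sampling error. Under the parallel model
the same pipeline recovers a near-zero shift, which is the null control.

Note one property the experiment shares with its real counterpart: the
decoding peak-latency shift overestimates the injected mean
postponement by one to two hundred milliseconds, because trials with
longer central stages produce both later and stronger evidence, so the
accuracy average is evidence-weighted toward late shifts; the
second-task curve carries this coupling through both its shift and its
duration. Amplitude-normalized averaging removes the between-subject
part of the coupling; the within-trial part is irreducible at the
accuracy level and should be kept in mind when reading recovered
postponements — the behavioral refractory effect is the sharper
estimate of the underlying delay.

## Quartile-RT diagnostics

Correct single-task trials are binned into RT quartiles by rank (counts
within one of each other, ties by trial order), a four-set FIR model
estimates per-quartile timecourses, and spline fits give per-quartile
latency metrics. The classifier between duration-scaling
(selection-like) and pure-shift (execution-like) profiles uses the
quartile regression slope of peak amplitude normalized by mean
amplitude: scaling the event duration grows the response roughly in
proportion, while translating it leaves amplitude unchanged. Pilot
simulations showed this growth signature separates the two families
about four standard deviations apart at default SNR, whereas
onset/peak-latency ratios — the intuitive discriminator — are far too
noisy at desk-scale trial counts; the decision threshold 0.08 is the
equal-error boundary from those pilots. Latency slopes are returned as
corroborating evidence, and the group-level acceptance checks assert
the latency signatures (peak-latency quartile effect with relatively
stable onsets for selection-like regions; onset effects for
execution-locked regions). `quartile_experiment()` pools both
single-task conditions in one model and uses four runs per subject
(8 trials per quartile per task; the original protocol yields 20).

## Granger causality

Trial-wise timecourses are multi-trial segments: lagged predictors never
cross trial boundaries, per-segment means are removed, and the VAR order
is chosen by AIC (default search to order 10, maximum-likelihood
residual covariances). Pairwise-conditional causality is the
time-domain log-ratio of reduced (source lags omitted, all other
channels retained) to full residual variance — equal in population to
state-space formulations for VAR processes, and guaranteed non-negative
here because both models use the same ML divisor. A closed form anchors
the tests: for a unit-variance white source driving a target with
coefficient c, the causality converges to `log(1 + c²)`.

## Group statistics

Paired t (Cohen's d from difference scores), one-way within-subject
ANOVA (`F(k−1, (k−1)(n−1))`, partial eta squared
`SS_effect / (SS_effect + SS_error)`, no sphericity correction by
default), Pearson correlation, Benjamini–Hochberg step-up FDR, and the
JZS Bayes factor for the one-sample/paired t with Cauchy scale
`sqrt(2)/2`, integrated numerically and cross-checked against brute
quadrature. The two-condition ANOVA equals the squared paired t, which
the tests assert as an algebraic identity.

## Problem sizes and limitations

The packaged experiments run at desk scale: 12 subjects × 4 runs for
serial-queuing recovery, 100 subjects × 4 runs for quartile
discrimination, single subjects × 3 runs for the pipeline demo. The
generator omits head motion, physiological waveforms and acquisition
artifacts (nuisance enters only as regressors); onsets are TR-locked by
convention; HRF fitting operates on ROI means, not per voxel; decoding
is linear only. FIR windows truncate the late undershoot of responses,
which leaks structured error into overlapping trials' estimates exactly
as in real rapid designs — it averages out with trial count, and is the
main reason quartile metrics need several trials per bin. Conclusions
about real data should rest on the method implementations, not on the
synthetic effect sizes.
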