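---
title: "Models and methods in vischange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in vischange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vischange)
```

`vischange` implements the computational core of a head-fixed mouse visual
change-detection experiment: a generative simulator of the task, the
descriptive behavioral statistics, a Gaussian-process model of the
momentary lick hazard, and the imaging-side regression analyses that relate
stimulus fluctuations to mesoscale calcium signals. This vignette explains
the models, their assumptions, the tunable parameters, and the design
choices made where the methods left genuine freedom.

## The task and its simulator

A drifting grating's temporal frequency (TF) is redrawn every 50 ms. On
noisy trials (70%), log2 TF is drawn i.i.d. from a normal distribution with
mean 0 and SD 0.25 octaves, so TF itself is lognormal with geometric mean
1 Hz; on the remaining 30% the TF is held at 1 Hz. After a block-dependent
delay the mean TF steps up to one of the change magnitudes
{1.25, 1.35, 1.5, 2, 4} Hz (1 Hz marks no-change trials). Change times are
an offset (3 s in early blocks, 10.5 s in late blocks, swapped with
probability 0.1) plus an exponential draw with mean 4 s truncated at 5 s.
Truncation is implemented by rejection (redraw until the draw is at most
5 s) rather than capping, so the change-time density carries no atom at the
upper bound. Trials begin after a pre-stimulus delay of 3 s plus an
exponential with mean 0.5 s. Licks within 150 ms of the change are
refractory (never rewarded); a first lick in (0.15, 2.15] s after the
change is a hit, and a trial with no qualifying lick by 2.15 s is a miss.
We read the task's "2-s response window" as this refractory-shifted
interval, which reconciles it with the 2.15-s miss deadline. A consequence
worth noting: an agent that licks deterministically one sample (50 ms)
after the change scores *refractory*, not hit.

Change times are snapped up to the next 50-ms boundary so that the change
coincides with a stimulus sample; reaction times are measured from the
snapped time. Licks are represented continuously for reaction-time
statistics and assigned to the 50-ms sample containing them for model
fitting. Each trial is generated from a counter-based substream of the
master seed, so trial *i* is reproducible regardless of batch size. Wheel
aborts are off by default (the simulator emulates a stationary, compliant
mouse) and can be enabled in `task_config()`.

No-change and no-noise degrees of freedom interact: on no-noise trials the
stimulus is constant both before *and* after the change (the noise-free
reading of the protocol), and change magnitudes are sampled uniformly
because the original magnitude mix is not dictated by the generative rules.
The early-probe variant with a 4-s offset used in a minority of the
original sessions is not simulated; all sessions use matched offsets.

The synthetic lick agent is the recovery oracle for the hazard model: its
per-sample log-odds are a bias plus filter outputs (linear in the recent
stimulus history) plus a time gain, exactly the additive structure the GP
model assumes, and the hazard is clipped to [1e-6, 1 - 1e-6] to keep
log-likelihoods finite. The synthetic fluorescence generator convolves the
frame-resampled stimulus and a movement trace with finite kernels and an
exponential indicator kernel, and (in two-channel mode) multiplies both
channels by a shared artifact; it emulates the *linear* response structure
the imaging regressions assume, plus optional rectification in tests. What
passing tests on these fixtures shows is that the estimators are correct
under their own assumptions -- not that real widefield data are linear,
stationary, or free of shared noise beyond a multiplicative hemodynamic
component.

## Behavioral statistics

Psychometric curves use exact Clopper-Pearson 95% binomial intervals
(chosen for exactness at small n; the original analysis used a routine with
the same behavior). Early, abort, and refractory trials never enter the
denominators. Chronometric and lick-triggered-average intervals are simple
percentile bootstraps (0.025/0.975 quantiles of 2000 seeded resamples).
Discrete hazard rates divide events in 1-s bins by the trials still at
risk at the bin start, excluding trials whose early lick, change, or abort
precedes the bin. The lick-triggered average pads histories shorter than
the 2.5-s window with the baseline mean (exclusion is available as an
option); it pools licks across sessions by default.

The train/validation/test split takes `round(0.6 N)` training trials per
stratum and halves the remainder, giving any odd trial to validation; this
rounding rule reproduces the published partition of 14,944 trials into
(8,966, 2,989, 2,989). Strata smaller than 3 go wholly to training with a
warning.

## The GP lick-hazard model

Time is discretized into the task's 50-ms samples. A trial is a run of
Bernoulli outcomes that ends at the first lick, so the trial likelihood is
the product of conditional terms, and a dataset of trials flattens into
independent per-sample terms (every retained sample already conditions on
survival). The log-odds of licking at sample *i* is a latent function
f(x_i) of the input x_i = (stimulus history over the Q = 50 preceding
samples, time since stimulus onset, block), with a GP prior and a constant
mean m0 (initialized at -5 because licks are rare; trainable).

The covariance is a sum of a stimulus part and a time part, so the
posterior log-odds decompose exactly into stimulus- and time-driven
components. The stimulus part is a Matern 5/2 kernel on phi = s'W, where W
is a Q x D filter matrix; the filter scale absorbs the lengthscale, which
is fixed at 1. The time part is a Matern 5/2 kernel on monotonically
warped time t_w = t + sum_k a_k tanh(b_k t + c_k) (J = 5 terms);
non-negativity of a and b -- enforced by softplus reparameterization --
guarantees an invertible warp, which the stationary kernel needs. Each
kernel part splits into a population component and block-specific
components active only when both inputs share a block. Warp parameters are
shared across blocks; only the variances and time lengthscale are
per-component.

Inference is stochastic variational: M inducing points carry a Gaussian
q(u) (mean plus lower-triangular covariance factor), and the evidence
lower bound -- expected Bernoulli log-likelihood minus KL terms, with the
minibatch data term rescaled by N over the batch size -- is maximized with
Adam. All gradients are analytic matrix expressions (verified against
finite differences in the test suite); the variational expectations of the
Bernoulli log-likelihood use 20-point Gauss-Hermite quadrature, which is
deterministic and exact enough that training needs no likelihood
sampling. Prediction uses 500 Monte Carlo draws from the posterior
(inducing values plus independent per-sample conditional noise; full
within-trial covariance is an option we did not take, trading exactness of
joint trial statistics for linear cost).

The filter matrix carries a mean-field Gaussian variational posterior
whose columns have zero-mean Gaussian priors with gamma-distributed
precisions (shape 2, rate 0.05 -- broad, mean 40, favoring high
precisions). The precisions get conjugate gamma updates in closed form
(the optimal variational family for this conditional); the filter means
and log-SDs get reparameterized stochastic gradients. Columns that do not
help prediction are shrunk toward zero (automatic relevance
determination). Prediction fixes W at its posterior mean.

Two numerical points matter in practice. First, the kernel depends on phi
only through distances, so W is identified only up to rotation of its
active columns; the ARD prior breaks the tie slowly, and
`principal_filters()` reports the rotation-invariant singular directions.
Second, the learning rate is held constant for the first half of training
and annealed exponentially to `lr_decay` times its value over the second
half: without annealing, stochastic-gradient noise keeps pruned columns at
a noise floor instead of letting them collapse. The filter means are
additionally Polyak-averaged over the final fifth of training, and columns
whose posterior-mean norm remains below their posterior width
(`||m_d||^2 < Q * mean(s_d^2)`) are zeroed at the end -- such columns are
dominated by prior noise rather than data support, the same logic by
which relevance-vector methods discard basis functions.

Inducing inputs are initialized by k-means within blocks (medoids -- the
nearest actual sample to each centroid -- so their stimulus histories stay
realistic under any later filter projection), stored in raw input space,
and re-projected through the current filters and warp at every step; their
raw-space locations are otherwise fixed. Training stops at a step cap or
when the validation predictive log-likelihood stops improving by 1e-4 nats
per trial over 20 evaluations. The default "desk" profile (M = 64, D = 8,
2,048-sample minibatches, 3,000-4,000 steps) fits roughly 3,000-trial
synthetic sessions in minutes on one CPU; the "full" profile (M = 450
with 150 per block, D = 15, 12,000-sample minibatches, learning rate
0.001) preserves the full-scale settings. The test suite and the
reproduction script use the desk profile with a single seed; the
generator-side statistics use 1e4-2e5 draws.

## Widefield analyses

Hemodynamic correction interpolates the 405-nm reference channel to the
470-nm frame times (mean of the neighboring frames), takes the channel
ratio, and normalizes by its session mean -- removing any multiplicative
fluctuation common to both channels exactly. The low-cut filter is an
order-2 Butterworth high-pass at 0.00333 Hz applied forward-backward (the
original analysis names only the cut-off), with the DC offset restored and
the trace normalized by its session SD.

Stimulus values are resampled to imaging frames as duration-weighted means
of overlapping monitor frames. Event alignment takes the frame whose
exposure interval contains the event as lag 0 (boundary ties to the
earlier frame) and subtracts the mean over 480 ms (stimulus and change
onsets) or 2000 ms (licks) before the event.

The lagged regression fits, independently per lag on a 0-2-s grid,
`f(t) - f(0) = a_t + s b_t` on valid baseline frames (at least 1 s before
early licks or wheel movement, before the change); self-correction forces
the lag-0 slope to zero, and the grid retains the lag-0 anchor for
transparency. Requested lags are mapped to the nearest integer frame
offsets. The expectation analysis adds a block indicator and its
interaction with the stimulus. Coefficient time courses are summarized by
`b(t) = b_max (1 - exp(-t/tau_r))^z exp(-t/tau_d)`, fitted by bounded
Levenberg-Marquardt with random restarts; latency is the first time the
fit reaches half of its maximum absolute value and half-decay the time
from the maximum to the half crossing, not determined if absent within
4 s.

Binned responses compare frames following fast (above +1.5 SD) and slow
(below -1.5 SD) stimulus samples against a +/-0.5-SD reference bin, using
the *empirical* SD of the resampled per-frame values -- resampling shrinks
the variance below the generator's 0.25 octaves, and thresholds in
observed units keep the stated Gaussian tail occupancies.

The ridge deconvolution builds lagged design blocks (stimulus over the
past 2 s; movement traces over the past 2 s and 0.52 s into the future,
lag 0 counted once in the past block; licks 0.68 s past to 0.52 s future;
categorical change onsets per magnitude over 2 s), scales every column but
the intercept by its SD, and solves the closed-form ridge system over 36
penalties log-spaced between 1e-2 and 1e5 with 5 contiguous
cross-validation folds computed on the masked sample sequence. The
intercept is never regularized; coefficients are unscaled before
reporting, and change-mode coefficients are reported relative to the
no-change (1-Hz) block.

## Two-photon neuropil correction

ROI and surround traces are detrended by a centered rolling 10th
percentile over 4,000 frames (truncated at the edges). The correction
models both detrended traces as sharing a common neuropil signal:
`roi = alpha * n + e1`, `surround = n + e2`, with errors following an
asymmetric Student-t -- a piecewise t with shared scale, 30 degrees of
freedom on the left tail (near-Gaussian) and 1 on the right
(Cauchy-like), density-continuous at the location with a closed-form
normalizer. The heavy right tail absorbs large positive calcium
transients, preventing the contamination estimate from inflating for
densely active cells. The exact density, scale linkage, and optimizer of
the original implementation are not documented; this parametrization and
the estimation scheme are this package's reconstruction. Estimation
alternates damped vectorized Newton updates of the per-frame neuropil
signal with bounded quasi-Newton updates of (alpha, scales), from
n = surround and alpha = 0.7, until the log-likelihood gains less than
1e-6 per frame; alpha is bounded to [0, 2] on physical grounds.

## Known limitations

The simulator draws stimulus noise i.i.d. per 50-ms sample and does not
model monitor timing, reward hardware, or wheel biomechanics. The hazard
model's replicate sampler uses diagonal conditional noise within trials,
and by default censors (rather than scoring as misses) no-lick replicates
of trials whose recorded trace was truncated by the subject's own lick
before the miss deadline; comparisons against generative ground truth are
cleanest on full-length stimulus traces.
Fits at the desk profile recover planted filters up to the rotation
ambiguity discussed above; on real data, filter shapes should be read
through `principal_filters()`. The imaging analyses operate on traces --
image registration, ROI segmentation, and video processing are upstream
concerns out of scope here.
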