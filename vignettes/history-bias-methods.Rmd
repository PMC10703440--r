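---
title: "Modeling adaptive history biases and their motor-cortical signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling adaptive history biases and their motor-cortical signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, the synthetic-data generator, the
numerical choices and the known limitations of `histbias`. It is the
package's methodological reference; the README shows the quick-start
workflow.

## The behavioral model

An observer categorises a noisy motion stimulus as up or down. The
probability of an up-choice on trial $t$ is

$$P(c_t = +1 \mid \tilde{s}_t, h_t) = \gamma + (1-\gamma-\lambda)\,
g\!\left(\delta(h_t) + \alpha \tilde{s}_t\right), \qquad
g(x) = \frac{1}{1+e^{-x}},$$

with signed stimulus strength $\tilde{s}$ (motion coherence as a fraction,
times category $\pm 1$), sensitivity $\alpha$, and lapse rates $\gamma$
(floor) and $\lambda$ (distance of the ceiling from 1). The offset

$$\delta(h_t) = \delta' + \sum_{k=1}^{2n} \omega_k h_{k,t}$$

combines a constant bias $\delta'$ with a linear kernel over the history
vector $h_t = (c_{t-1},\dots,c_{t-n}, z_{t-1},\dots,z_{t-n})$: the previous
$n$ choices followed by the previous $n$ stimulus categories, coded
up $=+1$, down $=-1$. A zero-coherence stimulus carries no direction
signal, so its category code $z$ is 0 — while the *choice* made on such a
trial still enters the choice kernel. Positive kernel weights favour
repeating; the sign of $\delta(h_t)$ is a bias toward up. History is reset
at block boundaries (blocks are separated by pauses and possible
environment changes), so lags reaching before a block's first trial are
coded 0.

### Fitting

The likelihood is fully specified, so the package maximises it directly:
bounded quasi-Newton (`L-BFGS-B`) with analytic gradients and multiple
jittered restarts (5 by default for final fits, fewer inside
cross-validation where the landscape is re-fit many times). Box
constraints: $\gamma, \lambda \in [0, 0.45]$ (hence
$\gamma + \lambda \le 0.9$), $\delta' \in [-5, 5]$,
$\alpha \in [0, 50]$, $\omega_k \in [-5, 5]$. Choice probabilities are
clipped at $10^{-10}$ inside the log-likelihood so a single mispredicted
trial cannot produce $-\infty$. When a table spans several sessions, one
slope per session is fitted (other parameters shared) and the reported
$\alpha$ is their mean; this absorbs slow day-to-day sensitivity drifts
without letting them contaminate the history kernel. Non-convergence after
all restarts is flagged on the returned object rather than raised.

A caveat worth knowing: with free lapse parameters the ML estimate of the
slope is biased upward in finite samples whenever the psychometric function
does not saturate within the tested coherence range (the likelihood is
nearly flat along a lapse–slope ridge). The estimator is consistent — the
package's recovery tests show the bias vanishing by $2\times 10^5$ trials —
but at $10^4$ trials slope errors of a few percent are expected, and at
$\sim 600$ trials kernels fitted together with a *non-saturating* slope
inherit some of that bias. Kernel estimates under the package's default,
saturating sensitivity are unbiased at 594 trials per environment (checked
over 50 simulated subjects).

### Model-order selection and cross-fitted bias

The number of lags $n$ is chosen per subject and environment by block-wise
cross-validation: with six blocks, six folds, each holding out one block;
models with $n = 0,\dots,7$ (`max_lag` configurable) are fitted on the
training blocks and scored by held-out log-likelihood, averaged over folds;
the argmax wins, with exact ties resolved toward the smaller $n$. A
selected order of 0 in exactly one of the two structured environments is
replaced by 1 for the behavioral analyses; order 0 in both flags the
subject as non-adapting and marks it for exclusion.

Single-trial biases are *cross-fitted*: $\delta(h_t)$ for the trials of
block $b$ is evaluated with $\delta'$ and $\omega$ fitted on the other
blocks, so the estimates never see the data they will later predict.
Biases are then binned into terciles per subject, pooled across
environments (the binning is used for a pooled neural contrast, and pooling
keeps the bin boundaries comparable across environments); ties at a bin
boundary are assigned stably by trial order.

## The synthetic-data generator

The generator is the ground-truth store for every recovery test. Its
defaults are the study-design conditions:

- three environments defined by the stimulus-category repetition
  probability: 0.8 (repetitive), 0.5 (neutral), 0.2 (alternating);
  first-order symmetric Markov chains, independent across blocks, first
  category of a block uniform;
- blocks of 99 trials, six blocks per environment, two consecutive blocks
  per nominal session;
- coherences $\{0, 0.03, 0.09, 0.27, 0.81\}$ balanced within block: nine
  cells (four signed coherences × two directions, plus the direction-less
  0 level) × 11 trials. Because the Markov chain fixes the direction
  sequence, exact 44/44 direction counts cannot be guaranteed; within each
  direction the four coherences are dealt as evenly as the realised counts
  allow and any remainder is drawn without replacement from the level set.
  Any block-length remainder beyond full cells goes to the 0% level.

Agent choices are drawn from the behavioral model itself, using the
agent's *own* sampled choices in its history. The default agent repeats
the previous stimulus category in the repetitive environment
($\omega^{stim}_1 = +0.6$), alternates it in the alternating environment
($-0.4$), keeps a small repetition tendency in neutral ($+0.15$) and a
weak, environment-independent choice kernel ($+0.1$), with
$\gamma = \lambda = 0.05$, $\delta' = 0$ and $\alpha = 9$. The sensitivity
was set so that performance saturates at the highest coherence and is near
threshold at 9% — the regime the task design targets — which also makes
all model parameters identifiable. These values were fixed once as
realistic effect sizes; they are deliberately not tuned per analysis.

Lateralization epochs (one per trial, $-0.55$ to $1.5$ s around evidence
onset in 25-ms steps, coded relative to the hand mapping to up-choices so
that more negative = toward up) are built as

$$y_i(t) = q\, c^{prev}_i k(t) + r(t)\,\big(a\,\tilde{s}_i + b\,\delta_i\big)
+ \varepsilon_{i}(t),$$

with a previous-choice rebound kernel $k(t)$ (a positive bump spanning the
pre-evidence baseline and decaying linearly to zero by 0.3 s after onset;
the real rebound's exact shape is unknown, only its confinement to the
early trial, so a simple configurable ramp-down is used), an evidence ramp
$r(t)$ rising linearly from 0 at onset to 1 at evidence offset (0.75 s)
and holding, and i.i.d. Gaussian noise. Defaults $a = b = -1$, $q = 1$,
$\sigma = 1$: both couplings negative (toward the up hand for up evidence
or up bias), signal-to-noise low at the single trial but clear in
averages, as in real beta-band data.

What the generator does *not* emulate: oscillatory structure and 1/f
background (epochs are amplitude time courses, not spectra), temporally
correlated noise, reaction-time variability (the ramp is stimulus-locked
and identical across trials), between-subject variability in coupling
strengths, and any nonstationarity within blocks. Passing recovery tests
therefore demonstrates correctness of the estimators under the model's own
assumptions, not robustness to every property of real MEG data.

## Neural read-outs

**Build-up window.** The window used for ramp-slope quantification is
derived from a trial-averaged build-up trace by a continuous two-segment
("hinge") least-squares fit, $y(t) = b_0 + b_1 t + b_2 \max(0, t-\tau)$,
with the breakpoint $\tau$ searched over the observed timepoints inside
the evidence interval; the window runs from $\tau + 0.25$ s to the time of
the signal minimum minus 0.05 s. The buffers keep the window inside the
linear portion of the ramp. Ties in the breakpoint search resolve to the
earliest candidate, and a fit whose optimum sits at the grid boundary — or
that improves on a single line by essentially nothing — is flagged
degenerate. On real data with the standard settings this rule reproduces a
window of (0.58, 0.8475) s from a breakpoint at 0.33 s and a minimum at
0.8975 s. The window should be computed once, on a high-trial-count
average, and then reused — fitting it per subsample makes the breakpoint
an extra noise source, and for traces whose ramp starts exactly at the
interval edge the per-sample fit is degenerate by construction.

**Rebound removal.** The previous-choice rebound template is the
trial-averaged epoch coded by the previous choice, normalised to unit
norm; removal is the orthogonal projection $y^* = y - (y^\top r)\,r$,
idempotent with $y^{*\top} r = 0$ to machine precision.

**Choice-balanced subsampling.** Within each outer bias bin, every one of
1000 draws keeps all minority-choice trials plus an equal-size random
subset of majority-choice trials (without replacement); epochs are
averaged within draws and then across draws. Bins where either choice has
fewer than 10 trials are excluded (and logged) rather than balanced on a
handful of trials. The low-bin average is sign-flipped and combined with
the high-bin average, giving a trace whose negative deflections are
lateralization toward the bias direction; its OLS slope inside the
build-up window is the headline "bias-locked ramp slope". Validation runs
this machinery in a neutral environment, where the bias is independent of
the current stimulus; in structured environments the adaptive bias
genuinely predicts the upcoming stimulus, so a stimulus-driven component
in the bias-locked trace is expected there, not a test failure.

**Single-trial regressions.** Amplitude at each timepoint, the mean over
the baseline window ($-0.35$ to $-0.10$ s; no coherence regressor, since
evidence has not yet appeared), and local slopes in sliding 200-ms windows
are each regressed on z-scored signed coherence and z-scored bias, with the
outcome z-scored across trials within subject (one consistent scope for
all analyses). The slope regression is fitted separately for current up
and down responses and the coefficient traces averaged; all three traces
are returned, flagged, since the appropriate combination is a judgement
call. Degenerate inputs — constant outcomes, collinear regressors — raise
errors rather than silently producing z-scored garbage.

## Statistics

One-sample permutation tests flip signs of per-subject values
($p = (1 + \#\{null \ge obs\})/(N+1)$, $N = 10{,}000$ by default,
reducible). The 1-D cluster test thresholds per-timepoint one-sample $t$
statistics at the two-tailed $p<0.05$ critical value (configurable; the
threshold choice trades sensitivity for broad versus focal effects, it
does not affect error control), forms maximal contiguous same-sign runs,
and compares summed-$t$ cluster masses against the permutation null of the
maximum absolute mass. Rayleigh's test uses
$z = n\bar{R}^2$ with the standard series approximation for $p$; the
paired Hotelling $T^2$ uses the exact $F$ transform. Calibration of all
of these (type-I error, family-wise error) is part of the test suite.

## Problem sizes used in validation

The recovery suite simulates at the design's own scale wherever that is
informative: generator calibration on $>10^4$ trials per environment;
parameter recovery as 50 repetitions of a 10,000-trial fit plus 50
subjects at 594 trials; model-order selection over 50 subjects per true
order $n \in \{0,1,2\}$ with `max_lag = 3` (the selection rule is
identical for larger `max_lag`; restricting the grid keeps the 1,200
cross-validated fits cheap without changing what is being tested); 100
simulation repetitions for the confound-removal and bias-coupling power
checks; 200–400 repetitions at $N = 1000$ permutations for the
statistical calibration checks. The end-to-end pipeline test runs two
subjects at three blocks per environment — enough to exercise every stage
and the determinism contract.

## Known limitations

- The slope/lapse identifiability issue above: absolute slope estimates at
  realistic trial counts carry a small upward bias when the psychometric
  function is far from saturation; kernel weights are robust.
- The cross-validated weights used for single-trial biases are fitted per
  fold; subjects with very few blocks get noisy fold fits (at least two
  blocks are required, six are intended).
- The bilinear window rule assumes a single kink followed by a clean
  minimum; multi-phase build-ups will be summarised poorly (the degenerate
  flag catches only the extreme cases).
- `hotelling_paired` and `rayleigh_test` are asymptotic; at very small n
  prefer the permutation machinery.
- The pipeline driver is synthetic-first: real datasets enter through
  `read_trials()`/`read_epochs()` and the stage functions, not through
  `run_pipeline()`.
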