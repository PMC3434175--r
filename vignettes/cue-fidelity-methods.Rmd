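---
title: "Models and methods: psychometric thresholds, Quick pooling and heave-simulation fidelity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuepool)
```

## The problem this package addresses

Fidelity of a simulated environment (a flight simulator, here) is most
usefully defined against *human performance*, not physical realism: a cue is
worth rendering if it is detectable, if it improves task performance, or if
it supports transferable learning. `cuepool` implements the three
quantitative chains such an evaluation needs — forced-choice detection
thresholds with a cue-pooling analysis, closed-loop tracking performance
with within-subject factorial statistics, and a pre/post transfer
comparison with a learning-curve inclusion rule — together with the
mechanistic simulators (ideal observers, heave flight dynamics, synthetic
pilots) needed to exercise every step without human subjects.

## Weibull psychometric functions and the 81% threshold

In a two-alternative forced-choice task (was the motion up or down?), the
probability of a correct categorisation rises from the 50% chance floor to
1 as the signed control input `Xc` grows in magnitude. We model it with the
Weibull form

$$p(x) = A + (B - A)\left(1 - e^{-(x/x_0)^m}\right),$$

with the asymptotes fixed at chance ($A = 0.5$) and perfect performance
($B = 1$). The scale $x_0$ carries the units of the stimulus (collective
inches); the dimensionless slope $m$ reflects decision reliability. At
$x = x_0$ the curve passes through $A + (B-A)(1 - 1/e) \approx 0.816$,
which is why the conventional threshold criterion is the 81%-correct point;
`threshold_at()` solves it in closed form and `fit_psychometric()` reports
it alongside the raw parameters.

Fitting choices, made here because no standard is universal:

* **Objective**: binomial maximum likelihood over independent trials, not
  least squares on proportions — it weights levels by their trial counts
  and is the standard for modern psychophysics fitting.
* **Optimiser**: a deterministic coarse log-spaced grid over $(x_0, m)$
  followed by Nelder–Mead refinement on the log scale. No randomness, so
  fits never need a seed.
* **Pooling up/down**: equivalent up and down levels are pooled onto
  $|x|$ by default (`pool_updown = TRUE`); direction-specific asymmetries
  can be tested first with `paired_compare()`.
* **Degenerate data**: all-correct, all-incorrect, or chance-level-everywhere
  tables have no interior maximum-likelihood solution; these raise a typed
  error carrying the per-level summary instead of returning a meaningless
  fit. Levels left with no valid trials (after discarding `"none"`
  responses) are dropped with a warning.

## The Quick pooling model

When two redundant cues (audio and kinematic motion, say) are present at
once, the bimodal threshold $T_{am}$ is compared with the unimodal
thresholds $T_a, T_m$ by replotting it in *threshold units*,
$u = T_{am}/T_a$, $v = T_{am}/T_m$. The Minkowski (Quick pooling) model
says pooled thresholds sit on the unit contour

$$u^k + v^k = 1,$$

and the exponent $k$ diagnoses the integration architecture: $k = 1$ for
linear (early) summation of the signals, $k = 2$ for optimal
reliability-weighted integration, $k \approx 4$ for probability summation
over independent channel decisions, and $k \to \infty$ when the cues are
not combined at all. Equivalently, the combined threshold for unimodal
thresholds $T_i$ is $T = (\sum_i T_i^{-k})^{-1/k}$
(`predict_combined_threshold()`).

`k_from_triple()` solves one subject's triple exactly by bisection (the
left side of the contour equation is strictly decreasing in $k$ when both
ratios are below one). For a group, `fit_pooling()` minimises the squared
*radial* residuals $\sum_j ((u_j^k + v_j^k)^{1/k} - 1)^2$ — chosen because
it is symmetric in the two cues and reduces to the exact single-subject
root. Whether a published group exponent was obtained this way or by
averaging per-subject exponents is typically not stated; the radial group
objective is this package's choice. The search interval is $k \in
[0.1, 64]$; anything above 8 is reported as the `independence` regime,
since "no combination" is not numerically representable. Subjects showing
no facilitation at all ($u, v \ge 1$) make $k$ undefined; the strict
default refuses them by name, and `strict = FALSE` keeps them (pulling the
fit toward independence).

## Mechanistic observers: what the synthetic data emulate

No raw behavioural data exist to re-analyse, so the package generates
trial tables from observer mechanisms chosen to *realise* each pooling
regime exactly (`observer_spec()`):

* **optimal_gaussian** — per-cue Gaussian-noise estimates combined by
  inverse-variance weighting; combined noise obeys
  $1/\sigma_c^2 = 1/\sigma_a^2 + 1/\sigma_m^2$, hence Euclidean threshold
  combination ($k = 2$).
* **linear_late_noise** — channel outputs $g_i x$ summed into a single
  decision variable with one late noise source. Unimodal thresholds are
  $\propto 1/g_i$ and the bimodal one satisfies $1/T = 1/T_a + 1/T_m$
  ($k = 1$). A late (post-summation) noise source is essential: summing
  channels with independent noise would itself be optimal and give $k=2$.
* **probability_summation** — each channel independently detects with
  Weibull probability $1 - e^{-(|x|/s_i)^{m}}$ and reports the true
  stimulus sign; the observer answers with any detecting channel's report
  (audio wins ties — immaterial for accuracy) and guesses otherwise. The
  OR rule over Weibull channels with exponent $m$ yields $k = m$.

The default noise levels are calibrated so the unimodal 81% thresholds
land at 0.27 (audio) and 0.21 (motion) control-input units — the
magnitudes reported for a representative subject — i.e.
$\sigma = T/\Phi^{-1}(0.81)$; for the probability-summation kind the same
$\sigma$s are mapped to channel scales preserving those thresholds, so all
mechanisms are comparable at identical settings. This is a calibration
choice, not an inference about human channel noise. Cohorts
(`make_cohort()`) spread the $\sigma$s log-normally across subjects
(default SD 0.15, a plausible between-subject threshold spread).

Levels of exactly zero are accepted as catch trials: no signal is
presented and correctness is scored against a randomly designated nominal
direction, so long-run accuracy is 50% — this anchors the chance floor
empirically.

What these generators deliberately do **not** emulate: lapses and
attention drift, response bias, learning within a session, reaction times,
and vestibular temporal dynamics. Passing recovery tests therefore shows
the *analysis chain* is correct and well-calibrated, not that human data
would be this clean; with real data one should expect wider bands and a
possible lapse-rate correction (out of scope here). One consequence
visible in the tests: fitting the Weibull to the Gaussian-mechanism
psychometrics on the fixed 0.1–0.5 level grid is a mild model mismatch
that biases the recovered group exponent upward by a few hundredths —
within all the recovery bands used.

## The heave model and its cue channels

The flight dynamics are the standard single-axis heave law

$$\dot w = Z_w w + Z_0 X_c, \qquad \dot h = w,$$

with input gain $Z_0 = 4.8$ fixed and damping $Z_w = -0.1$ (sluggish,
"difficult": time constant 10 s) or $-0.5$ ("easy": 2 s). The model is
integrated with fixed-step RK4 at `dt = 0.01` s (0.02 s in the closed-loop
pilot runs, where the controller holds its output over each step); the
constant-input closed form $w(t) = (-Z_0/Z_w)X_c(1 - e^{Z_w t})$ is
reproduced to better than $10^{-6}$ relative error. The model units of
$Z_0$ are treated as configuration — accelerations are reported both in
model units and, through the motion channel, in g.

Two cue channels are derived from the state (`cue_channels()`):

* **audio**: level linear in `Xc`, spanning 3 dB (86–89 dB(A)) over the
  full collective travel, base 87.5 dB(A). The travel defaults to
  ±1.5 in, so the calibration is realisable and typical tracking inputs
  stay within range. `static` mode pins the level at the base;
  `substitute` changes only the carrier label (a different sound with
  identical behaviour).
* **motion platform**: the model acceleration scaled by
  `motion_gain / Z0` so a unit-`Xc` step peaks at 0.04 g, delayed by
  80 ms (8 samples at the default step; non-multiple delays shift to the
  nearest sample with a warning), with an optional first-order high-pass
  washout stub (off by default — realistic washout design is a separate
  subject).

Target paths are sums of six sinusoids with frequencies spanning
0.2–0.5 rad/s; amplitudes (uniform 0.5–1.5 ft) and phases are seeded
draws, since only the frequency range is published. The same seed always
reproduces the same path.

## The synthetic pilot

`fly_tracking_run()` closes the loop with a deliberately simple
human-like controller: the collective command is
`kp * error + kd * (target rate − own-velocity estimate)`, computed from
measurements delayed by a 0.2 s visuomotor lag, with Gaussian visual noise
(SD 0.1 ft) on the height, and clamped to the collective travel. The cue
flags act through the state estimate, which is the mechanism under study:

* motion platform **on**: velocity feedback at the short kinematic latency
  (80 ms) with small noise (SD 0.05 ft/s);
* **off**: velocity inferred by differencing the delayed noisy visual
  height over 0.15 s — noisier and more sluggish, which destabilises the
  weakly damped difficult dynamics in particular;
* an informative turbine sound improves the velocity estimate only in
  proportion to `audio_weight` (default 0: an untrained pilot ignores it —
  matching the finding that audio cues contribute only after training);
* the error beep is exposed as a flag with no effect at its default gain,
  matching its observed null contribution.

Gains were fixed once at `kp = 0.6`, `kd = 0.1` so that the closed loop is
comfortably stable under easy dynamics and marginally damped under
difficult dynamics — the regime in which the quality of the velocity
estimate visibly matters, as in the experiments. The properties asserted
in tests are qualitative by design (easy < hard error; motion cue helps,
decisively so under difficult dynamics; audio ineffective pre-training):
the pilot is invented plumbing, and no numeric agreement with human
tracking scores is claimed. `direct_inverse` is an idealised pilot that
inverts the plant from the target derivatives and anchors the zero of the
error metric. Divergence (error beyond a bound) raises an error rather
than returning a score.

## Tracking statistics

Performance is the **median absolute error** between target and flown
height (robust to brief excursions). For the 2×2×2×2 within-subject
design (error beep `e`, turbine `t`, motion `m`, difficulty `d`),
`main_effects()` averages each factor over all other cells within subject,
then across subjects, reporting `mean(level 0) − mean(level 1)` — the
error reduction from switching the factor on. `rm_anova()` computes, per
factor, $F = MS_{\text{factor}} / MS_{\text{factor} \times
\text{subject}}$ on subject×level cell means with df $(1, n-1)$ —
algebraically $t^2$ of the paired comparison for a single factor, verified
in the tests against `aov()`'s within-subject stratum and calibrated to a
5% type-I rate under a null simulation. Unbalanced or incomplete designs
are refused, never imputed. Post-hoc comparisons use `paired_compare()`
with sidedness always explicit; no multiple-testing correction is applied
by default (matching the uncorrected post-hocs of the study design), and
`p.adjust()` is available for a Holm option.

The transfer analysis includes only participants who actually learned:
`learning_filter()` fits a least-squares line to the mean error over the
four training phases and requires the predicted first-to-last improvement
to reach 0.15 ft.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10-subject cohorts at
500 trials/level (2000 for the probability-summation mechanism, whose
thresholds are noisier), 50-seed regime-recovery sweeps, 200-replication
parameter-recovery checks, 1000-replication type-I calibration, and
40–60 s tracking runs at `dt = 0.02` s — sizes chosen so each full
analysis runs in seconds to a few minutes on one core while leaving the
Monte-Carlo error well below the tolerances asserted. Root solving uses
`uniroot` at tolerance 1e-13; the group pooling fit uses `optimize` at
1e-10; threshold inversion is closed-form.

## A worked example

```{r example}
cfg <- exp1_config(seed = 1, n_subjects = 6, trials_per_level = 300)
rep <- run_experiment1_replica(cfg)
rep
head(rep$thresholds)
```

## Known limitations

* The observers and pilot are mechanistic stand-ins; none of the human
  inferential statistics of the original study (its F, t and p values, the
  group exponent 2.1, the 0.74→0.39 ft training gain) can be reproduced
  without the raw behavioural data, and the package does not attempt to.
* Thresholds carry no per-subject confidence intervals (group SEM-style
  summaries only); no lapse-rate parameter; no adaptive staircases.
* The motion washout is a first-order stub, not a platform-workspace
  design; no audio synthesis or playback is modelled.
* The pooling group fit weights all subjects equally; weighting by
  threshold standard errors would need per-subject interval estimates.
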