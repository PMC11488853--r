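---
title: "Single-trial decision-variable analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial decision-variable analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

dvtrace implements an analysis pipeline for resolving the drift-diffusion
decision variable (DV) on single trials of a reaction-time motion
discrimination task: a behavioral race model, a synthetic neural population
whose spiking is driven by the latent DV, coding-direction estimators that
render single-trial population signals, closed-form diffusion diagnostics
for those signals, and leverage/mediation statistics linking them to choice
and reaction time. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic data do and do not
establish.

## The behavioral model

Decisions are modeled as a race between two accumulators, one integrating
momentary evidence for the leftward (contraversive) choice and one for the
rightward choice. At each step of size $dt$ the pair of momentary-evidence
samples is bivariate Normal with means $\pm\kappa(C + C_0)\,dt$ (positive
signed coherence $C$ denotes leftward motion), variance $dt$ per
accumulator (unit variance per second, so an unbounded accumulator reaches
variance 1 after one second), and correlation $\rho = -\sqrt{0.5}$ — the
accumulators share half their variance. The first accumulator to reach its
positive bound determines the choice and the decision time. Bounds collapse
linearly, $B(t) = B_0 - \alpha t$, clipped at $0.01\,B_0$ so they remain
positive; the collapse plays the role of an urgency signal. Reaction time
adds a non-decision time, parameterized either as a single Gaussian
$N(\mu_{nd}, \sigma_{nd})$ (used when fitting) or split into a fixed 200 ms
pre-integration latency plus a Gaussian post-termination latency
$N(117, 39)$ ms truncated at zero (used when simulating; the split means
sum to $\mu_{nd}$). During the post-termination interval the DV holds the
value it attained at termination. Trials still undecided at the 5 s
simulation horizon are resolved to the accumulator closest to its bound.

The reference parameter set (`ddm_params_monkey("M")`) is
$\kappa = 13.37$, $B_0 = 1.03$, $\alpha = 0.4199$, $\mu_{nd} = 0.317$,
$\sigma_{nd} = 0.039$, $C_0 = -0.0144$; the default signed-coherence set is
$\pm\{0, 3.2, 6.4, 12.8, 25.6, 51.2\}\%$.

### First-passage solver

`fpt_solve()` propagates the joint density of the two accumulators in
discrete time with absorbing collapsing bounds. In rotated coordinates
$u = x + y$, $v = x - y$ the correlated increments become independent, so
each time step is a pair of one-dimensional Gaussian convolutions. Three
numerical choices matter:

* kernels are cell-integrated Gaussians with the discretization variance
  $h^2/12$ subtracted (moment matching), and edge mass is clamped rather
  than lost, so total probability is conserved to machine precision at
  every step;
* cells straddling a bound are absorbed fractionally (uniform within-cell
  density), which removes the $O(h)$ absorption bias of cell-wise
  absorption;
* a Broadie–Glasserman continuity correction,
  $0.5826\,(\sqrt{dt} - \sqrt{dt_{ref}})$ subtracted from the bound, makes
  coarse-step solves consistent with the 1 ms Euler simulator
  ($dt_{ref} = 0.001$).

The state space is truncated at `state_floor` (default $-2.5$ evidence
units) with clamping; paths that deep essentially never return to a bound.
With these corrections the solver agrees with a $10^5$-trial Monte-Carlo
simulation to a Kolmogorov–Smirnov distance below 0.01 per choice and to a
few times $10^{-3}$ in choice probability, and its conditional mean
decision time is within ~2 ms of the simulator across grid settings
(`dt` from 1 to 12.5 ms, `h` from 0.02 to 0.09).

### Fitting

`fit_ddm()` maximizes the likelihood of (choice, RT) pairs; the predicted
RT density is the first-passage density convolved with the Gaussian
non-decision time. $\rho$ is fixed. The search is multi-start Nelder–Mead
(five starts, the first from a logistic fit of the choice function) over
$(\log\kappa, \log B_0, \log\alpha, C_0)$, with $(\mu_{nd}, \sigma_{nd})$
profiled out by a warm-started inner optimization — they enter only
through a cheap convolution. Starts run on a coarse solver grid
($dt = 12.5$ ms, $h = 0.09$) and the best solution is polished on two
finer grids ($dt = 7.5$ then 5 ms). Trials with RT above 2.3 s (a
sub-percent tail under the collapsing bound at the reference parameters)
enter the likelihood as right-censored observations — their contribution
is the probability of responding later than the cap, with choice
marginalized — so the solver horizon stays short without biasing the fit
(an improperly truncated likelihood would reward parameters that push
probability mass past the cap); densities are floored at $10^{-10}$. Non-convergence of the final stage is
flagged, never silent. On 20,000 simulated trials this recovers $\kappa$
to a few percent and $\mu_{nd}$ to a few milliseconds.

## The synthetic population

`generate_decision_session()` produces the study conditions the analyses
assume, with ground truth retained (labels, coupling weights, latent DV
paths). Defaults describe a session resembling the recordings the pipeline
is aimed at: 135 neurons, of which 14.5% are Tin_con (response field on
the contralateral choice target), 7.2% Tin_ips, 4.2% Min_left and 2.5%
Min_right (direction-selective), the remainder untuned.

* **Tin neurons** fire at `baseline_rate` (12 sp/s) plus
  `dv_gain` (15 sp/s per evidence unit, jittered $\pm 40\%$ per neuron)
  times the DV of their accumulator, delayed to begin 200 ms after motion
  onset, plus an evidence-independent urgency ramp. The urgency slope
  defaults to `dv_gain * alpha_collapse`, the firing-rate equivalent of
  the collapsing bound: rates on contraversive trials then terminate at a
  common level (saccade-aligned convergence) and the 0% coherence average
  rises. Tin neurons whose response field matches the chosen target also
  receive a perisaccadic buildup (`peri_gain`, 12 sp/s over the last
  180 ms), as target-selective parietal neurons do.
* **Min neurons** follow the boxcar-smoothed (50 ms, causal) momentary
  evidence with a 100 ms latency, at `min_gain` (1 sp/s per unit of
  smoothed evidence) on top of a 15 sp/s baseline, plus a large
  non-selective visual onset transient (latency 40 ms). They are
  coherence-dependent and do not converge at the saccade. Critically, by
  default they read the *same* evidence stream the DV integrates (the DV
  "hears" each evidence sample 100 ms after the Min neurons do), so an
  integrator signature appears in Min-to-Tin correlations;
  `min_coupled = FALSE` substitutes a coherence-matched, trial-shuffled
  stream as the control condition.
* **Other neurons** fire at baseline; a config switch (`other_dv_gain`)
  can couple them to the DV, but the default leaves them DV-free — the
  generative model for decision-related covariability outside the labeled
  classes is unknown, so the default is the null.
* **Shared noise**: one Gaussian latent, piecewise constant over 50 ms
  blocks and common to all neurons, with amplitude calibrated in closed
  form so that residual spike counts in 200 ms windows correlate at
  `noise_r` = 0.09 for baseline-rate pairs.

Rates are rectified at zero (a warning fires if more than half the time
bins rectify) and spikes are drawn as inhomogeneous Poisson at 5 ms rate
resolution with uniform jitter within bins, from 300 ms before motion
onset to 150 ms after the saccade. Passive-viewing sessions show only
$\pm 51.2\%$ coherence for 500 ms with no choice; delayed-saccade sessions
place a target at one of eight locations and give Tin neurons
visual/delay/perisaccadic selectivity at their preferred location.

Generator calibration was anchored to summary properties reported for the
recordings this pipeline emulates (mean session size near 135 neurons,
category fractions, pairwise noise correlation near 0.09, a When-decoder
AUC near 0.84, near-identical choice accuracy of the When and What
decoders); it was then frozen. What passing tests on these data show is
that the *estimators* behave as designed when their assumptions hold.
Real recordings differ in ways the generator does not emulate — non-Poisson
spiking, heterogeneous tuning and latencies, rate nonstationarities,
richer correlation structure, undetected task-related neurons — so
agreement here does not certify performance on real data.

## Signals and coding directions

Spikes are binned at 1 ms and smoothed with a 50 ms boxcar whose window at
time $t$ spans $t-24$ to $t+25$ ms (an 80 ms truncated Gaussian with
$\sigma \approx 26$ ms is available for display). Censoring is strict: for
motion-aligned decision data every sample within 100 ms of the saccade is
missing (`NA`), any boxcar window touching a censored sample is itself
censored, and no analysis reads censored samples. Neurons are standardized
by their firing-rate mean and s.d. in the 200–600 ms epoch; silent neurons
are excluded and forced to zero weight. A coding direction is a per-neuron
weight vector; the single-trial signal is the projection
$S_i(t) = \sum_n w_n s_{i,n}(t)$.

Five coding directions are implemented: ramp regression (lasso at
$\lambda = 0.005$ onto $-1 \to +1$ ramps spanning 200 ms after motion
onset to 50 ms before saccade, left-choice trials), the first PC of the
per-coherence trial-averaged standardized rates (200 ms to 600 ms or 100 ms
before the coherence's median RT, whichever is shorter), the Tin_con
average ($1/N$ weights), a logistic choice decoder (What; 50 ms bins,
lasso $\lambda = 0.01$, even/odd trial split by parity, the 450 ms bin
defining the fixed direction), and a saccade-time decoder (When; 25 ms raw
spike counts, labels 1 within 150 ms of the saccade, left-choice trials).
Sign conventions are "leftward/contraversive = positive" throughout. The
When direction's choice accuracy uses the sign of the detrended signal
(grand-mean subtraction at each time), rendered with the standard 50 ms
boxcar. Trials longer than 2 s are excluded from When training so the
design matrix stays bounded; they are a small tail.

## Diffusion diagnostics

For an unbounded Wiener process started at $t_0$ and averaged over boxcar
windows of width $w$, the window means satisfy
$\mathrm{Var}(M_i) = \tau_i - w/6$ and, for non-overlapping windows,
$\mathrm{Cov}(M_i, M_j) = \tau_i$ (with $\tau$ the window center in
diffusion time); the general case is the double integral
$w^{-2}\iint \min((s-t_0)_+, (u-t_0)_+)\,ds\,du$, evaluated by midpoint
quadrature when windows overlap or straddle the origin. These forms are
validated in the test suite against a $10^5$-path Monte-Carlo oracle
(maximum correlation discrepancy below 0.01) — that validation is part of
the suite, not optional. The default layout is six 51 ms windows starting
at 226 ms after motion onset with the diffusion origin at 200 ms, so the
first sample sits at 26 ms of diffusion time and the predicted normalized
variances are $1 : 3.91 : 6.83 : \dots$ — the stated closed forms, not the
rougher "doubling and tripling" description, are authoritative. As
$w \to 0$ the correlation approaches $\sqrt{\tau_i/\tau_j}$; at $w = 1$ ms
the residual deviation is $\approx (w/12)(1/\tau_1 + 1/\tau_2) \sim
2.5\times 10^{-3}$, so the limit is verified at $w = 0.25$ ms together
with the shrinkage of the deviation.

Empirically, detrended and baseline-corrected single-trial signals at the
weakest motion strengths give a variance curve (normalized to the first
sample) and autocorrelation matrix; bootstrap standard errors use 500
resamples respecting the coherence composition. Because spiking and other
nuisance variance inflate the diagonal, a scalar $\phi \le 1$ multiplies
the empirical variances before normalization,
$r_{ij}(\phi) = C_{ij}/(\phi\sqrt{C_{ii}C_{jj}})$, and is found by bounded
minimization of the squared Fisher-z difference from theory (tolerance
$10^{-4}$; boundary solutions flagged). On synthetic data a planted
diffusion fraction $f$ is recovered as $\hat\phi \approx f$.

## Leverage and mediation

Leverage analyses use 50 ms boxcar samples every 25 ms over 0.2–0.5 s plus
a later sample at 0.55 s, restricted to $|C| \le 6.4\%$ and
$0.67 < RT < 2$ s; signals are detrended per signed coherence and RTs
residualized per coherence and choice. The complete-case trial set (a
trial enters only if all samples survive censoring) is shared by all
coding directions. Choice leverage $\beta_1(t)$ comes from a logistic
regression with one intercept per signed coherence; the mediated
$\beta_1^*(t)$ adds the 0.55 s sample; both are normalized by the standard
error of $\beta_1(t)$. RT leverage is the Pearson correlation (left-choice
trials), mediated by the partial correlation given the later sample,
computed by regression residualization. The summaries at $t = 0.4$ s are
$\xi_{RT} = 1 - r_{partial}^2/r^2$ (undefined unless the simple
correlation is negative) and the piecewise
$\xi_{Ch} = 1 - \beta_1^*/\beta_1$ (1 if $\beta_1^* \le 0$; undefined if
$\beta_1 \le 0$; undefined cases are marked, never coerced to zero).
Logistic separation triggers a flag. Inference: trial bootstrap for
standard errors; a null that permutes the mediator within signed-coherence
groups (preserving per-coherence counts exactly), with the headline
p-value the permutation probability that a null $\xi$ reaches the
observed one — the Wilcoxon rank-sum comparison of the bootstrap and null
$\xi$ distributions is also reported, but it is anti-conservative when
the true effect is near zero (each distribution concentrates around a
dataset-specific value, so any realized spurious mediation registers as a
difference); a random-coding-direction null (permuting PC1 weights); and
a trial-shuffle null. The ceiling analysis
feeds the latent DV, observed through 17 noisy instantiations with
pairwise noise correlation 0.09 and marginal noise s.d. of 1 evidence unit
(chosen to give a signal-to-noise ratio comparable to a small Tin pool;
the noiseless limit recovers essentially complete mediation, though not
exactly 1 at finite n because the RT–state relation is nonlinear and the
partial correlation is linear).

Choice-leverage trials include both choices (the logistic model requires
both outcomes) with the same RT window; the left-choice restriction
applies to the RT branch only.

## Min-neuron analyses

Direction-selective neurons are identified from passive viewing: a
fivefold rate increase over the pre-onset baseline within the first 80 ms
(the baseline window is the 200 ms before motion onset, and the criterion
is applied to 25 ms binned rates), a rate-of-rise criterion
(max forward difference in the first 80 ms exceeding any pre-onset rise),
and a leftward-vs-rightward AUC above 0.6 (or below 0.4) in either the
0.15–0.3 s or 0.3–0.5 s epoch; Tin-labeled neurons and
preference-switchers are excluded. Latency is estimated by CUSUM: the
cumulative left-minus-right count difference (25 ms bins; correct trials,
RT > 450 ms, $|C| > 10\%$) is fit with a dog-leg (flat at zero, then
linear) by 1 ms grid search over the breakpoint with the closed-form
least-squares slope; degenerate (selectivity-free) inputs are flagged.
The Min-to-Tin map correlates the standardized residual Min difference at
$t_x$ with the Tin_con signal at $t_y$ (25 ms bins, trials with
RT ≥ 0.55 s, per-bin z-scoring, pre-onset baseline subtracted); the
statistic $\langle\rho_{ROI1}\rangle - \langle\rho_{ROI2}\rangle$
($t_x > 100$ ms, $t_y > 200$ ms, above vs. below the diagonal) is tested
against 200 trial-order shuffles with a z-test, with an alternative ROI2
($t_x < 100$, $t_y < 200$) also reported. The per-trial summary $\psi$
(mean Min difference over 0.1–0.4 s) is correlated with per-coherence
z-scored RT on contraversive choices with RT ≥ 0.5 s, tested one-tailed
against $\rho \ge 0$.

## Problem sizes and reproducibility

The test suite runs on sessions of 40–135 neurons and 400–2000 trials,
with bootstrap and permutation counts of 60–300 in unit tests; the
acceptance checks use the sizes their definitions state ($10^6$ increment
pairs, a 20,000-trial refit, $10^5$ Wiener paths, 5,000-trial $\phi$
recovery, 400-trial CUSUM recovery, 200-shuffle ROI nulls). All
randomness flows through explicit integer seeds; `run_pipeline()` derives
per-stage substreams from one master seed so stage-level reruns reproduce
exactly.

## Known limitations

The solver's accuracy budget is tuned for the reference parameter regime
(bounds near 1, drifts below ~8 s$^{-1}$); extreme parameter values may
need a larger `state_floor` or finer grids. The fit drops the RT tail
above 2.3 s. The generator's "other" neurons are decision-free by default,
which understates the decodable information in real populations; its
Poisson spiking understates real overdispersion, so $\phi$ on real data
would sit further below 1 than in the synthetic checks. Passive and
delayed-saccade generators are deliberately minimal — they exist to give
the classifiers something with known ground truth, not to model those
tasks fully.
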