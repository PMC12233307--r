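---
title: "Models and methods behind gazeddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gazeddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazeddm analyses binary context-dependent decisions in which two option
images occupy lateral areas of interest (AOIs) on a screen and may
disappear before the choice is reported, so that part of the deliberation
happens while the participant fixates *empty* locations (the
look-at-nothing situation). This vignette explains the models the package
implements, the choices made where the design was genuinely open, and what
the synthetic-data generator does and does not emulate.

## The experimental structure being modelled

A trial presents a verbal context, then two images left and right of
fixation (Stimulus-On, 4 s by default, 2 s in the short-observation
variant). At the GO signal the images disappear (or stay, in the
always-visible control), and the participant presses the left or right
button within a 4 s response window, then rates confidence (C), reward
(R), interest (I) and complexity (CM) on a 0–10 scale. Three analysis
intervals matter throughout: `SOn` (stimulus onset to GO), `SOffUD` (GO to
the button press) and `SOffPD` (press to the end of the response window).
All intervals are half-open `[start, end)` in trial-relative milliseconds,
with 0 at stimulus onset.

Trials are discarded when the decision time is negative, absent, or
strictly greater than 4000 ms; exactly 4000 ms is kept, reading "longer
than 4 s" literally.

## From gaze samples to metrics

`extract_dwells()` labels each sample by the AOI containing it (AOI =
image frame padded by 25 px; the empty frame left after stimulus offset is
the same target region as the image), merges same-side runs across
off-AOI gaps up to `max_gap_ms` (default 80 ms, a saccade-scale gap), and
drops dwells shorter than `min_dwell_ms` (default 100 ms, a conventional
minimum fixation duration — the underlying eye-tracking literature offers
no single criterion, so both are exposed). A dwell ends one sample period
after its last sample, so an isolated sample carries one period of dwell
time.

Per interval, `compute_trial_metrics()` sums per-side dwell time (clipped
to the interval), the number of changes of target (#CoT: adjacent dwell
pairs with different sides, counted in the interval where the *second*
dwell starts, so a change crossing a boundary is attributed to where the
new fixation begins) and its frequency fCoT = #CoT divided by the interval
length in seconds. The psychometric regressor is the regularised log
looking-time ratio `log((T_R + eps)/(T_L + eps))` with `eps` one sample
period (16.7 ms at 60 Hz) — the smallest measurable dwell — so a trial
with one side never fixated stays finite.

## Choice versus looking time

Per participant and interval, trials are ranked by log looking-time ratio
and split into four equal-count bins (remainder to the lower bins). Each
bin contributes its median log-ratio (robust to the heavy tails the log
ratio produces when one side dominates) and its fraction of right-button
presses. A two-parameter logistic

$$P_R = \frac{1}{1 + e^{-(\beta_0 + \beta_1\,x)}}$$

is fitted to the four points by binomial maximum likelihood (IRLS), which
weights bins by trial count; a least-squares alternative would ignore the
binomial variance structure. Under complete separation the slope is capped
(default 25) and flagged. Right is coded as the *button*, not the image
side, which is why the motor-reversal variant yields negative slopes.

Significance per participant uses a shuffle test: the four (proportion,
count) pairs are permuted across the four bin positions, the curve is
refitted, and the observed slope is compared with the shuffle
distribution (10,000 sampled shuffles by default; since only 4! = 24
orderings exist, the implementation fits each ordering once and samples
ordering indices, and an exact enumeration mode is available). The
p-value uses the add-one correction (1 + ties)/(N + 1) so it is never 0,
and the significance flag is the 95th-percentile criterion. The
discreteness of 24 orderings makes the test conservative: its true
type-I rate is at most about 1/24 ≈ 0.042, which the calibration test and
the acceptance script confirm empirically.

Group-level inference is a one-sample t-test of the per-participant
slopes, accompanied by the JZS Bayes factor (Cauchy prior on the
standardized effect, scale √2/2 by default — the modern default;
reported Bayes factors in the motivating literature do not state their
prior scale, so only order-of-magnitude agreement is meaningful).
Decision-time distributions are compared with the two-sample
Kolmogorov–Smirnov test.

## Cognitive factors

Per participant and interval, ordinary least squares link the gaze
metrics to the z-scored ratings:

* proportion of interval time on the selected option ~ C + R + I + CM +
  R×I + R×CM + I×CM, with interactions computed as products of the
  z-scored main effects (the order of z-scoring versus multiplication is
  open; products of z-scores keep every column on a comparable scale);
  the proportion response stays on its natural 0–1 scale,
* z-scored #CoT (and fCoT) ~ C + R + I + CM.

Group significance is a t-test of each coefficient across participants,
uncorrected for multiple comparisons by default (matching common
reporting practice; a Benjamini–Hochberg option exists in
`group_coefficient_tests()`). Participants with too few complete trials
(12 for the 8-parameter model, 8 for the 5-parameter ones) or a
rank-deficient design are reported, never silently dropped.

## Diffusion models of choice and confidence

Evidence x(t) starts at 0 and evolves as dx = μ dt + σ dW until it hits
±θ; the first crossing fixes the choice and the decision time. In the
*parallel* reading μ is the constant value difference between the
options. In the *sequential* (gaze-gated) reading the drift is the value
of the currently attended option (μ₁ while option 1 is attended, −μ₂
while option 2 is), so evidence accrues for one option at a time,
following the fixation sequence.

Two closed-form confidence readouts follow:

* parallel: g(t) = Φ(θ / σ(t)) with Φ the standard normal CDF. The noise
  scale σ(t) is implemented as σ√t — the standard deviation the
  accumulated diffusion noise actually reaches at time t, which is the
  standard result in the bounded-accumulation confidence literature; a
  linear σ·t variant is exposed as a sensitivity switch because the
  printed form is typographically ambiguous. Confidence depends on
  decision time only and decreases in it.
* sequential: g(Δt₁, Δt₂) = 1 / (1 + exp(−2 μ₀ (Δt₁ − Δt₂)/σ²)), using
  the small-value approximation Δxᵢ ≈ μ₀ tᵢ. It depends only on the
  difference of attention times, is exactly ½ at balance, and satisfies
  g(Δ) + g(−Δ) = 1. (The approximation step sits in mild tension with
  μ₁ = μ₀/2; the printed equations are followed as printed.)

The three *observation models* that are actually fitted to reported
confidence are linear in the per-trial attention times of the selected
(Δt₁) and non-selected (Δt₂) option:

| model | prediction |
|---|---|
| parallel | α₀ + α₁ / (Δt₁ + Δt₂) |
| sequential | α₀ + α₁ (Δt₁ − Δt₂) |
| hybrid | α₀ + α₁ (Δt₁ − Δt₂) + α₂ / (Δt₁ + Δt₂) |

Models are named, never numbered, throughout the package: the source
material numbers them inconsistently between its equations and its figure
captions, and names are unambiguous.

**Which span do Δt₁/Δt₂ cover?** This is not fixed by the source
analyses. The package's default is the GO-to-decision span (`SOffUD`),
configurable to include Stimulus-On. Two reasons. First, the
inverse-total-time term is the parallel model's decision-time signature,
and the data summary it is compared against is confidence *as a function
of decision time*; the deliberation-to-commitment span is that time
scale (roughly 0.3–4 s). Second, once a mandatory 4 s stimulus
presentation is added to every trial the total observation time is
pinned near 4–8 s, 1/(Δt₁+Δt₂) becomes nearly constant, and no method —
ours or anyone's — can distinguish a model containing that term from one
without it; the comparison would be decided by the complexity penalty
alone.

## Model scoring and random-effects selection

Each observation model is a linear-Gaussian regression of normalized
confidence y = C/10 on its predictors, so its log model evidence (free
energy) is available exactly in conjugate form — the package computes it
in closed form rather than through a variational scheme, whose bound
would be tight here anyway. Defaults: predictors standardized per
participant (so one prior scale is comparable across models), Gaussian
prior of scale 5 on the coefficients, and a conjugate inverse-gamma noise
prior (a = b = 10⁻³) under which the coefficient prior scales with the
residual SD and the marginal is multivariate t. A fixed-noise variant
exists mainly so the evidence can be checked against brute-force
quadrature in the tests. Trials with zero total attention time are
dropped (and counted) for models with an inverse term.

The participants × models evidence matrix enters random-effects Bayesian
model selection: model identity is a random effect with a Dirichlet
population distribution, updated by the standard fixed-point scheme
(posterior assignments u ∝ exp(F + ψ(α) − ψ(Σα)); α = α₀ + Σu) with
prior α₀ = (1,1,1), tolerance 10⁻⁶ on the α update, and a 10⁴ iteration
cap. Reported quantities: the *model frequency* (the Dirichlet mean
α/Σα — note that with N participants and this prior its ceiling is
(N+1)/(N+3), about 0.91 at N = 20, even when every participant is
attributed to one model) and the *exceedance probability* (the posterior
probability that a model is the most frequent), estimated from 10⁶
seeded Dirichlet draws. Only within-participant evidence differences
matter: adding a constant to a participant's row leaves the result
unchanged, which the tests assert.

`model_recovery()` closes the loop: cohorts are generated under each
model, inverted with all three, and the exceedance winner recorded — a
3×3 confusion matrix that is diagonal in the strong-signal regime.

## What the synthetic generator emulates

Per trial: two option values drawn from N(0.7, 0.45²) in drift units
(1/s), an alternating attention schedule with gamma dwells (mean 700 ms,
shape 4, 40 ms saccade gaps), a gaze stream at 60 Hz with 20 px jitter
around the attended AOI centre and invalid samples in the gaps, a
bounded diffusion from the GO signal (σ = 0.8, θ = 1.2, Euler step 1 ms)
whose drift is gaze-gated under the sequential and hybrid generative
models, and ratings on 0–10. Defaults were calibrated once against the
behavioral summary statistics of the emulated paradigm — decision times
averaging ≈1.4 s with a long tail inside the 4 s window, and roughly 1.3
target alternations per second during stimulus viewing — and then left
alone.

Choices of note:

* *Both options are appetitive on average.* Under gaze-gated drift the
  attended option's value drives the accumulator, so when both values
  are positive, looking longer at a side pushes evidence toward it; this
  single assumption produces the looking-time/choice coupling without
  any extra attentional-discounting parameter. Under the parallel
  generative model the drift is the constant value difference and gaze
  does not influence choice.
* *Accumulation starts at GO.* The deliberation the decision time
  measures is the post-GO one; a trial whose accumulator never crosses
  within the response window is emitted as a non-response (`button =
  "none"`), and such trials carry no ratings.
* *Confidence* is the configured observation model evaluated at the true
  attention times, clipped to [0, 1], plus reporting noise (SD 0.05),
  rounded onto the rating scale. Reward, interest and complexity load on
  a per-trial difficulty latent (minus the absolute value difference,
  z-scored) with a shared appraisal noise term, so they correlate with
  each other and with difficulty without driving gaze.
* *Ground truth is a separate table* (`truth`) so downstream stages can
  never read it accidentally; the analysis re-extracts attention times
  from the gaze streams.
* The motor-reversal variant reuses the same gaze and decision process
  and flips the button; the short-observation variant shortens
  Stimulus-On to 2 s.
* Stated trial and block durations in the source material do not
  reconcile exactly with the stated phase durations, so every phase
  duration is an explicit configuration field rather than a derived
  quantity.

What it deliberately does not emulate: saccade kinematics,
microsaccades, smooth pursuit, blinks beyond validity flags, pupil
dynamics, calibration drift, and any semantic content of the images or
contexts. Passing tests on this generator therefore show that the
pipeline recovers the structure it assumes — gaze-gated accumulation,
linear confidence readouts, gamma dwells — not that real data satisfy
those assumptions.

One honest corollary of the confidence scale: with the headline
coefficients (α₀ = 0.5, α₁ = 0.15 /s, α₂ = 0.3 s) the fastest decisions
push the model confidence past the top of the scale, where it saturates,
exactly as a bounded rating scale saturates for a maximally confident
participant. That censoring attenuates a naive uncensored refit of α₂.
The parameter-recovery suite therefore checks coefficient recovery in a
non-saturating regime (α₀ = 0.3, α₁ = 0.05, α₂ = 0.05), where pooled
estimates land within two standard errors of the generating values,
while model *selection* — which is what the saturating regime is used
for — remains unambiguous there (the hybrid generative cohort is won by
the hybrid model with exceedance probability 1 at 20 × 80).

## Numerical choices

* Euler–Maruyama step 1 ms; 8 s simulation horizon; a warning fires when
  the step is coarse relative to (θ/σ)².
* Logistic fits run through `glm.fit` (binomial IRLS) on the four binned
  points; permutation refits reuse the same fast path.
* The JZS Bayes factor integrates the scale-mixture representation with
  `integrate()` and is tested to 1% against a dense noncentral-t grid.
* Evidence computations use Cholesky factorizations; a singular Gram
  matrix is an explicit error.
* Exceedance probabilities are Monte-Carlo with a recorded seed;
  frequencies are exact Dirichlet means.
* A single user-facing seed expands into per-stage seeds by a fixed
  affine-mod-prime rule (`stage_seed`), so any stage can be rerun in
  isolation; all derived seeds stay below 2³¹.
* Test and example problem sizes: cohorts of 6–20 participants × 30–80
  trials, 1,200–1,500 diffusion replicates for first-passage checks, and
  2,000 null participants for the permutation calibration — sizes at
  which the Monte-Carlo error bands used in the assertions are
  comfortably tight.

## Known limitations

* The dwell segmentation is position-based (AOI membership), not
  velocity-based; fast within-AOI saccades are invisible to it.
* The two-stage summary-statistics approach (per-participant fits,
  group t-tests) ignores per-participant estimation uncertainty;
  hierarchical variants are out of scope.
* The confidence observation models are linear and unclipped at fit
  time; a tobit-style censored likelihood would treat scale-top reports
  more faithfully.
* Exact Bayes-factor and free-energy *values* from other software will
  differ (prior scales and noise models are rarely reported); the
  selection outcome, not the evidence values, is the reproducible
  quantity.
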