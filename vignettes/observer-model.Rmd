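---
title: "Dynamic Bayesian observers and the time-order effect: models, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Bayesian observers and the time-order effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toebayes)
```

This vignette is the package's own account of its science: the generative
observer models, the fitting and model-selection machinery, what the
synthetic-data generator does and does not emulate, and the choices we made
where the design was genuinely open.

## The perceptual model

At each stimulus presentation the observer holds a Gaussian belief over the
latent stimulus feature, summarized by its mean $\mu$ and learning rate
$\tau$ (the posterior precision is $\pi_u/\tau$, where $\pi_u$ is the
sensory precision). Before assimilating the next stimulus the belief is
convolved with a *prior of sameness* — a Gaussian transition of precision
$\pi_x$ expressing that consecutive stimuli resemble each other — and then
combined with the noisy observation by Bayes rule. Both steps collapse into
a recursion governed by a single parameter, the precision ratio
$r = \pi_u/\pi_x$:

$$\tau_n = 1 - \frac{1}{1 + \tau_{n-1} + r}, \qquad
  \mu_n = \mu_{n-1} + \tau_n\,(u_n - \mu_{n-1}).$$

The learning rate converges to $\tau_{\mathrm{lim}} =
\tfrac{1}{2}\left(-r + \sqrt{r(r+4)}\right)$; small $r$ (a strong sameness
prior) freezes learning, large $r$ approaches veridical tracking
($\tau \to 1$). `belief_update()` implements one step,
`learning_rate_limit()` the fixed point, and the two are cross-checked
against each other and against an explicit precision-propagation oracle in
the test suite (to $10^{-10}$).

At trial level, the two stimuli are assimilated in sequence and the
probability of answering "first higher" is

$$q = \tfrac{1}{2}\bigl(1 + \mathrm{erf}(\alpha\,(\mu_1 - \mu_2) + b)\bigr),
\qquad \alpha = \sqrt{\frac{\pi_u}{2(\tau_1 + \tau_2)}},$$

with response bias $b$. The posterior contrast can equivalently be written
in closed form as the veridical difference plus two contraction terms
pulling each stimulus toward the trial-onset prior mean
(`contrast_closed_form()`); the sequential and closed forms are asserted
identical to $10^{-10}$ over randomized states. The dynamic observer (M1)
carries its belief across trials and blocks; the static control (M0) is the
$r \to \infty$ limit, deciding on $\tfrac{\sqrt{\pi_u}}{2}(u_1-u_2) + b$
with no state. Choices are Bernoulli draws from $q$; since the belief
trajectory depends only on the stimuli, the whole $q$-series can be computed
in one pass (done in C++ for speed) and reused for simulation and
likelihood alike.

### The stimulus scale

Frequencies enter the observer divided by a reference `freq_ref = 30` Hz
(the context-block standard), so the model's feature is relative frequency
and $\pi_u$ is a precision on that dimensionless scale. This choice makes
the group-typical parameter regime internally consistent: at
$\log \pi_u \approx 4.4$, a static observer then shows ~80% accuracy in the
context blocks and a 75%-correct threshold of ~3 Hz, and a dynamic observer
with TOE-block $\log r \approx -1$ shows a TOE index in the 30s — all in the
empirically observed ranges. On a raw-Hz scale the same $\log \pi_u$ would
imply an essentially noiseless observer (threshold ~0.1 Hz), which is not a
regime any of these tasks operate in. The low-level functions
(`belief_update()`, `trial_decision_*()`) are scale-agnostic; only the
session layer (`predict_q()`, `session_loglik()`, `simulate_agent()`,
`map_fit()`) applies the normalization, and `freq_ref` is an argument
throughout.

### Initial state and carry-over

Initial conditions wash out after a few trials, so we start each simulated
or fitted segment at $\mu_0$ = 30 Hz (the context standard, i.e. 1.0 on the
model scale) and $\tau_0 = \tau_{\mathrm{lim}}$ of the segment's first
precision ratio. Within a fitted segment the belief is carried continuously
across block boundaries (the multisession fit of blocks 3–5 is one
uninterrupted trajectory); when $r$ changes at a block boundary, $\tau$
re-converges through the recursion itself. The longer inter-trial gap is
not modeled: the inter-trial and within-trial transitions use the same
prior of sameness. Excluded trials (unanswered, or flagged reaction-time
outliers) still drive belief updates but contribute no likelihood term —
the stimulation was experienced even when the response is unusable.

## The synthetic designs and cohorts

`generate_experiment_design()` reproduces the two discrimination
experiments exactly: three context-setting blocks (85 trials each; F1 fixed
at 30 Hz, F2 spanning 22–38 Hz in 1 Hz steps, the 17 pairs presented as
five internally shuffled cycles, the five F1 = F2 catch trials interleaved
within cycles) followed by two TOE blocks (96 trials each; |F1 − F2| = 2 Hz
always; six F1 values centered at 30 Hz in experiment II or 26 Hz in
experiment III, 12 pairs × 8 presentations, successive trials never the
identical pair). The no-immediate-repeat order is drawn sequentially with
probabilities proportional to remaining counts and a restart on the rare
dead end — reproducible under a seed and with a practically unreachable
failure cap.

`cohort_spec()` presets draw per-subject parameters from the group-typical
Gaussian hyperparameters of the task regime: $\log \pi_u$ 4.5 ± 0.8 ("NT")
or 4.3 ± 0.7 ("ASD"); bias −0.1 vs +0.1 (± 0.2); context-block $\log r$
1.1 ± 1.9 for both groups; TOE-block $\log r$ 0.40 ± 1.8 (NT) vs
−0.96 ± 1.3 (ASD). Block-5 group means are not separately established, so
the block-4 values are reused there. Reaction times are lognormal (median
800 ms, $\sigma_{\log}$ = 0.4) and exist *only* to exercise the RT filters;
they carry no behavioral meaning. Unanswered trials occur at rate $10^{-4}$.

What the generator does **not** emulate: sequential effects beyond the
observer itself (fatigue, attention lapses, learning-to-learn), RT–difficulty
coupling, any group difference in sensory precision beyond the presets, and
the real study's counterbalancing of response buttons. Passing tests on
these cohorts therefore demonstrates that the *pipeline* is correct and
well-calibrated under the model's own assumptions — not that the model is
true of real participants.

For the detection task, `simulate_method_of_limits()` is our own generative
model of the procedure (the task description specifies the ramp, not a
response model): detection measures are the true threshold plus i.i.d.
Gaussian criterion noise, disappearance measures add an adaptation shift
$\delta$, and everything is quantized to the 0.02 mA ramp grid. Under this
model the expected four-measure intra-individual SD is
$\sqrt{\sigma^2 + \delta^2/4}$, which the calibration tests recover; the
"NT" preset ($\delta$ = 0.08 mA, $\sigma$ = 0.05 mA) thus reproduces both
the ~0.08 mA adaptation effect and the ~0.06 mA dispersion, and the "ASD"
preset ($\delta$ = 0, $\sigma$ = 0.01 mA) the near-zero analogues.

## Fitting: MAP with Laplace evidence

Subject-level inference maximizes the Bernoulli log-likelihood plus a log
Gaussian prior on the fitting scale ($\log \pi_u$, $\log r$, $b$). We use
multi-start Nelder-Mead (five starts: the prior mean plus jittered draws;
objective tolerance $10^{-8}$), a central-difference Hessian (step
$10^{-4}$) at the optimum, and the Laplace evidence
$\log p(y) \approx \log p(y,\hat\theta) + \tfrac{d}{2}\log 2\pi -
\tfrac{1}{2}\log\det H$. A non-positive-definite Hessian is ridge-regularized
and flagged in the diagnostics. The Laplace evidence is validated against an
importance-sampling estimate (within 1 nat) in the tests. MAP + Laplace was
chosen over full variational Bayes because it targets the same Gaussian
posterior functional form with no extra dependencies; everywhere it is used
it should be read as that approximation.

Default priors are weakly informative on the scales the estimates live on:
$\log \pi_u \sim N(3, 2^2)$, $\log r \sim N(0, 2^2)$, $b \sim N(0, 1^2)$.

The two-phase protocol (`fit_subject_pipeline()`): phase 1 fits M0 and M1
on blocks 1–2 — M1 with a single $\log r$, since both blocks share one
context — and forms the Bayesian-model-average of $\log \pi_u$ (weights
from the Laplace evidences). Phase 2 fits blocks 3–5 with the
$\log \pi_u$ prior recentered on that estimate; its SD is the
model-averaged (Gaussian-mixture) posterior SD from phase 1, which reduces
to the dominant model's SD when one model dominates. M1 gets one $\log r$
per block; the bias is shared across the segment and re-estimated in each
phase. Catch trials (F1 = F2) are excluded from every likelihood, as are
unanswered trials and per-segment RT outliers (mean ± 3 SD, computed
separately for blocks 1–2 and 3–5).

## Group-level model selection

`rfx_bms()` implements random-effects BMS with a uniform Dirichlet prior
($\alpha_0 = 1$): the variational updates iterate subject-wise model
posteriors against the Dirichlet concentrations to convergence
($10^{-8}$). For two models the exceedance probability is exact from the
Beta marginal, $P(\rho_1 > \tfrac12) = 1 - I_{0.5}(\alpha_1, \alpha_2)$
(Monte Carlo for $K > 2$); the Bayes omnibus risk compares the fitted
model's free energy against the equal-frequency null,
$\mathrm{BOR} = 1/(1 + e^{F_1 - F_0})$; and the protected exceedance
probability blends them, $\mathrm{PEP} = \mathrm{EP}(1-\mathrm{BOR}) +
\mathrm{BOR}/K$. One behavior worth knowing: a subject with perfectly
symmetric evidence is *assigned the group posterior* through the digamma
term, so adding such a subject does not mechanically pull frequencies
toward 0.5 — only opposing evidence does.

## Behavioral statistics

**TOE index.** For each F1, the performance bias is accuracy(F2 above)
minus accuracy(F2 below). A raw signed average of these biases would cancel
across F1 (contraction helps on one side of the range mean and hurts on the
other), so the index folds them by the side of the range mean — positive
sign above the mean — before averaging, then normalizes by overall accuracy
and scales by 100. This sign convention makes a contraction bias positive
and matches the reported magnitudes (indices in the 30s–40s for strong
effects); it is our documented reading of the verbal definition, chosen
over a raw average that would be identically near zero. Sub-indices over
the three F1 below vs above the mean expose asymmetries.
`itoe_permutation_test()` provides the significance oracle: correctness is
permuted within each F1 level, which preserves per-F1 accuracy while
breaking any direction dependence. (Permuting the F2 *direction labels*
instead would preserve the F1-dependent choice marginal — which is the TOE
signal itself — and yields a badly miscentered null; we learned this the
quantitative way.)

**Intercept of the accuracy curves.** A robust linear regression of the
per-F1 bias on F1 (Huber M-estimation, tuning constant 1.345, IRLS to
$10^{-8}$; plain least squares when the bias is exactly linear) gives the
frequency where the two accuracy curves cross — an estimate of the learned
prior's center. Crossings outside the presented F1 range, or slopes below
$10^{-6}$, are flagged invalid rather than reported.

**Psychometric threshold.** A binomial GLM with logit link of P("second
higher") on the signed difference F2 − F1; the 75% threshold is
$\log 3 / \hat\beta_1$ under the symmetric-curve assumption (the intercept
is retained in the output, and the signed-ΔF parameterization is our
documented choice). Step-like responders are reported as threshold 0 with a
warning.

**d′.** Signal is "F2 above F1"; the log-linear correction (add 0.5 to each
count, 1 to each total) keeps d′ finite at extreme rates — the correction
choice is ours, the standard one for small-sample SDT.

**Exclusions.** The chance-performance bound is the upper limit of the
two-sided normal-approximation binomial interval with continuity
correction: 56.5% for 240 scored context trials at $\alpha = 0.05$ (the
exact binomial tail agrees within 0.3 points).

## Numerical choices

Response probabilities are clipped to $[10^{-9}, 1 - 10^{-9}]$ before the
log-likelihood; `erf` is evaluated through the normal CDF; the learning
rate is floored at $10^{-6}$ when initializing from $r \approx 0$; the
Dirichlet updates and IRLS iterate to $10^{-8}$. Ties and degenerate inputs
error early with informative messages (empty tables, unknown choice codes,
missing blocks, non-finite evidence).

## Problem sizes and what the studies show

The built-in studies run at the scale a single desk CPU handles in about a
minute each, chosen as the smallest sizes at which the questions are
answerable: parameter recovery on a 30-agent cohort (15 + 15 from the two
presets, 447 trials each), model confusion on 17 agents per generating
model, the emergent-TOE demonstration on ~10,000 TOE trials with a
199-permutation null, and the detection-task calibration on 1,000 agents.

## Known limitations

- Above $\log r \approx 1.5$ the dynamic observer is behaviorally
  indistinguishable from the static one, so $\log r$ is only one-sidedly
  identified there; with the preset between-subject spreads (SD 1.3–1.8) a
  sizable fraction of simulated subjects land in that flat region, which
  caps block-wise $\log r$ recovery correlations around 0.6–0.7 at 96
  trials per block. This is an information limit of the design, not of the
  optimizer (we verified the MAP beats the generating parameters in joint
  density for every subject). Group-level contrasts and the TOE
  correlations are unaffected.
- The Laplace evidence assumes a locally Gaussian posterior; it is accurate
  here (validated by importance sampling) but would degrade for multimodal
  posteriors.
- Reaction times are filter fodder, not a process model; no claims about
  speed or confidence follow from them.
- Hierarchical (group-level generative) priors and family-level BMS are out
  of scope.
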