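---
title: "Modeling adaptive choice under a switching category boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling adaptive choice under a switching category boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(flexcat)
library(dplyr)
```

## The task and its data

`flexcat` analyzes two-alternative categorization behavior in a
block-structured task. On each trial the subject sees one of seven
log-spaced spatial frequencies (SF1–SF7) and reports "low" (left port) or
"high" (right port) relative to a category boundary it must learn from
reward alone. The boundary alternates between a *low* position (just below
the middle frequency, SF4) and a *high* position (just above it) across
blocks of trials. SF4 is therefore the *reversing stimulus*: its correct
response flips at every block switch, while the extreme frequencies never
change category. Each block presents the two block-typical stimuli (SF1 and
SF4 in low-boundary blocks, SF4 and SF7 in high-boundary blocks) on 90% of
trials, split equally, with the remaining 10% spread over the other five
frequencies. A block lasts at least 60 trials and ends once the subject is
at least 70% correct on the reversing stimulus over its last 10
presentations, which triggers an uncued boundary switch.

The canonical data structure is a tibble with one row per trial
(`fc_trials()`), carrying the stimulus in physical units and two normalized
versions of it: a signed value in [−1, 1] that is 0 at the reversing
stimulus (used by the criterion model), and a [0, 1] version (used by the
reinforcement-learning model). Both are linear in log frequency because the
stimulus set is log-spaced; the signed map is anchored at the reversing and
maximum frequencies, `(log sf − log sf4) / (log sf7 − log sf4)`, so a set
that is only approximately log-spaced can slightly overshoot −1 at the
lowest frequency. The last 15 trials before each switch are the *stable*
period and the first 15 after it the *switching* period; in hypothetical
blocks shorter than 30 trials the switching label wins on overlap, since
the switching period is the analysis focus and the task itself forbids
such blocks.

## The dynamic decision-criterion model

The core model says the subject compares the current stimulus with a latent
decision criterion. The probability of a right ("high") choice on trial $t$
is logistic in the decision variable

$$z(t) = \gamma_1 S(t) - DC(t), \qquad p(t) = \frac{1}{1 + e^{-z(t)}},$$

with $S$ the signed normalized stimulus, $\gamma_1 \ge 0$ the weight of
current evidence, and $DC$ the criterion. The criterion is updated every
trial from the history of the *previous* trial. After a reversing-stimulus
trial, the outcome matters:

* rewarded left: $DC(t) = (1-\beta)DC(t-1) + \alpha_1$
* rewarded right: $DC(t) = (1-\beta)DC(t-1) - \alpha_1$
* unrewarded left: $DC(t) = (1-\beta)DC(t-1) - \alpha_2$
* unrewarded right: $DC(t) = (1-\beta)DC(t-1) + \alpha_2$

so positive $\alpha_1$ is a win-stay strategy and positive $\alpha_2$
lose-shift. After a non-reversing trial, the previous stimulus matters:
$DC(t) = (1-\beta)DC(t-1) + \gamma_2 S(t-1)$; a positive $\gamma_2$ lets a
recently seen low frequency push the criterion down (toward right choices),
the adaptive direction, because block statistics make the frequent
non-reversing stimulus diagnostic of the current boundary. The drift
$\beta \le 1$ decays the criterion toward zero ($0<\beta<1$) or inflates it
($\beta<0$). Reduced variants `m2`–`m7` pin single parameters (e.g. `m4`
sets $\alpha_1=\alpha_2=0$, `m7` sets $\gamma_2=0$), which is how the
contribution of each history term is judged by cross-validated model
comparison.

The alternative reinforcement-learning model has no boundary: left/right
values $V_l, V_r$ are scaled by the unit-normalized stimulus into expected
values $Q_l = \gamma(1-S)V_l$, $Q_r = \gamma S V_r$, choice is the softmax
of the two, and only the chosen side's value is updated by
$\alpha(r - Q)$ with reward $r \in \{0, 1\}$ and learning rate
$\alpha \in (0,1)$.

### Likelihood, initialization and numerics

Given observed choices, the criterion recursion is a fixed linear filter of
the data, so the average negative log-likelihood (`dc_nll()`) is evaluated
segment-wise at C speed via `stats::filter()`. Two initialization policies
are supported (`init_policy()`). Under `"inherit"`, one recursion runs per
session: the criterion starts at 0 and carries across block boundaries.
Under `"period_reset"`, only stable/switching-period trials enter the
likelihood and the criterion is reset at each period segment start to the
value implied by the switch rule: at a switch the reversing-stimulus
correct rate is the criterion (70%) just before and its complement just
after, and with $S=0$ the logistic ties that rate directly to $DC$, giving
$DC_0 = \mp\ln(7/3) \approx \mp 0.847$ for stable segments in low/high
blocks and the sign-flipped values for switching segments (for an
80%-criterion task configuration the same formula yields $\mp\ln 4$).
Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before taking logs so
likelihoods stay finite for extreme parameters. RL values start at
$V_l = V_r = 1$ at each segment start — a symmetric choice that makes early
rewards informative; the task description does not pin this value, so it is
exposed as `init_policy(rl_v0 = ...)`.

## Fitting and cross-validation

`fit_mle()` minimizes the average NLL under box constraints with `L-BFGS-B`
(objective tolerance `factr = 1e7`, i.e. ~1e−9 relative), taking the best
of 5 random restarts drawn from documented boxes
($\alpha_{1,2} \in [-1,1]$, $\beta \in [-0.5, 0.9]$,
$\gamma_1 \in [0.5, 10]$, $\gamma_2 \in [-0.5, 1.5]$; RL
$\alpha \in (0.05, 0.95)$, $\gamma \in [0.5, 10]$). Fixed parameters of a
variant are excluded from the search entirely, so they can never move.

`cross_validate()` implements repeated balanced k-fold cross-validation:
folds partition *blocks* (never single trials), with low- and high-boundary
blocks dealt evenly so per-fold type counts differ by at most one. Blockwise
partitioning is the only choice that keeps the trial-by-trial recursion
well-posed. Because the criterion recursion conditions on observed history,
training and held-out likelihoods are both computed by running the
recursion over full segments in trial order and averaging the per-trial
NLL over the training (or held-out) trials only — one-step-ahead
prediction conditioned on everything observed so far. Scored trial sets
are disjoint by construction, which the tests assert. Under the
`"period_reset"` policy segments are independent, so the held-out
likelihood is additionally invariant to block permutations given the fold
assignment (also tested).

The cross-validated likelihood is reported as
$\exp(-\overline{\mathrm{NLL}}_{\text{held-out}})$: the geometric-mean
per-trial probability of held-out choices, a value in (0, 1) that is
invariant to trial count and hence comparable across subjects and
datasets. The reported parameter estimate is the element-wise median over
all (run, fold) training fits. The full protocol is 200 runs of 5-fold
cross-validation; the package default for recovery pipelines is 20 runs,
which leaves the medians essentially unchanged on simulated data at a
fraction of the cost, and the run count is a `cv_config()` knob throughout.

## The simulator as synthetic-data generator

`simulate_agent()` runs any variant generatively through the task:
stimuli are drawn from the block statistics above, choices are Bernoulli in
the model's $p(t)$, rewards follow the block's category rule, and blocks
end by the real stopping rule (≥ 60 trials and ≥ 70% correct over the last
10 reversing-stimulus trials, evaluated once 10 such trials exist). A
session holds 50 blocks of each type by default, alternating, first type
random — the reference simulation protocol for this task. The defaults *are*
the reference task conditions; they are not tuned per analysis. Design choices the
task description leaves open: the 90% frequent mass is split 0.45/0.45
between the two frequent stimuli and the 10% rare mass 0.02 per rare
stimulus (both symmetric and configurable); a safety cap of 500 trials
force-switches a block for pathological parameter sets (counted and
warned, never silent); a single RNG stream drives stimulus and choice
draws, so a seed plus configuration is bit-reproducible within this
implementation (reproducibility across implementations is distributional,
not bit-level). In `"period_reset"` mode the criterion is pinned to the
switching-period value at each block start; the stable-period value cannot
be pinned at the true stable-segment start without looking ahead (the
switch time is decided by the agent's own future performance), so the reset
lands at the earliest trial the closing stable period could begin
(`min_block_trials - period_length`), the causal approximation of the
period-fitted generative process.

What the generator deliberately does not emulate: response latencies,
within-trial dynamics, satiety or session-length effects, and any slow
drift of motivation. Passing recovery tests on these simulations therefore
demonstrates estimator correctness and identifiability under the task's
trial-generating process — not robustness to every nuisance present in
real behavior.

## Parameter recovery

`recover_point()` closes the loop: simulate at known parameters, refit with
cross-validation, compare medians. At the reference scale (50 blocks per type,
≈ 6500 trials) the package judges agreement at
$|\hat\theta - \theta| \le \max(0.1,\ 0.15|\theta|)$ per free parameter —
wide enough for sampling noise at this scale, tight enough to catch sign or
scale errors. `recover_range()` sweeps one parameter over its reference
range (e.g. $\gamma_2 \in [-0.4, 1.5]$) with the others held at the
all-animal medians and reports the original-vs-recovered rank correlation.
The recovery error demonstrably shrinks with block count (tested at 5 vs 25
blocks per type), and scaling $\gamma_2$ down before simulating — the
synthetic analog of a chemogenetic inactivation that blunts sensory-history
use — shows up as a reduced recovered $\gamma_2$.

## Behavioral metrics

* `fit_psychometric()` fits
  $\Psi(x) = \gamma + (1-\gamma-\lambda)\,/\,(1+e^{-(x-\alpha)/\beta})$ to
  per-stimulus right-choice counts by direct binomial maximum likelihood,
  with lapse rates bounded to [0, 0.5]; the axis is log frequency and
  trials within 30 trials of a switch are excluded upstream
  (`psychometric_counts()`). The fitted $\alpha$ is the subjective boundary;
  all trials (not only reversing-stimulus trials) count toward the
  exclusion window, the plain reading of the steady-state restriction.
* `reversal_curve()` / `fit_reversal()` pool all switches, fit
  $f(n) = A(1-e^{-n/\tau}) + I$ to the first 60 post-switch
  reversing-stimulus trials by least squares — weighted by the number of
  switches contributing to each ordinal, so the sparse tail of unusually
  long blocks cannot drag the fit — and report the analytic 50% crossing
  $-\tau\ln(1-(0.5-I)/A)$ (`trials_to_reverse()`), flagged when the curve
  never crosses.
* `right_choice_bias()` measures the sensory-history effect directly:
  among reversing-stimulus trials of a period, the right-choice rate after
  a low-frequency (high-frequency) previous stimulus minus the block-typed
  baseline rate, with previous-reversing trials excluded (their $S(t-1)=0$
  carries no history class). Both the conditional and its baseline are
  taken in the matching block type, since that is where those histories
  live.

A subtlety worth knowing when relating the sensory-history weight to
reversal speed: under the free-running switch rule, every reversal is
conditioned on a *just-met* 70% criterion. An agent with weak sensory
history adapts shallowly, so its pre-switch streak is mostly luck and its
post-switch correct rate starts near 50%; a strongly history-driven agent
starts near 30% but travels much faster. The two effects largely cancel in
the measured 50% crossing. The association between $\gamma_2$ and
trials-to-reverse is therefore assessed from the criterion-pinned state
(period-reset simulation, which fixes the post-switch starting point at
the complement of the switch criterion), where larger $\gamma_2$ strictly
shortens the crossing — the speed effect that the negative across-subject
correlation reflects. Reversal curves are pooled over simulations before
fitting, matching how switches are pooled over blocks and sessions.

## Neural coding on synthetic populations

`roc_preference()` is the exact rank-form (Mann–Whitney) area under the ROC
curve mapped to $2(\mathrm{auROC}-0.5) \in [-1,1]$, ties counted one half —
the standard identity, since the source analysis does not state its tie
rule. `synth_spike_table()` generates Poisson populations with log-linear
choice and previous-stimulus tuning whose per-neuron loadings can be
correlated (`coupling`), emulating coupled choice/history coding;
`apply_inclusion()` enforces the ≥ 10 trials-per-class-per-condition and
> 0.5 spikes/s criteria; `pseudopopulation_decode()` resamples 10 trials
per class per neuron without replacement, z-scores features with
training-split statistics (computed on the 75% training split and applied
to the 25% test split, preventing leakage — the source order of operations
is unstated, so the leak-free order is adopted), and classifies with a
linear support-vector machine at cost 1. `sliding_window()` tiles a 0–900
ms span with 50 ms bins stepped 25 ms (35 bins). Decoding accuracies of
real recorded populations are out of reach of synthetic data by
construction; the synthetic analyses validate chance levels, separability,
determinism and the sign conventions.

## Worked example

```{r example, eval = FALSE}
p4 <- dc_params(beta = 0.21, gamma1 = 3.61, gamma2 = 0.36)
trials <- simulate_agent(model_variant("m4"), p4,
                         sim_config(n_blocks_per_type = 50, seed = 1))
fit <- cross_validate(trials, model_variant("m4"),
                      cv_config(n_runs = 20, seed = 2))
tidy(fit)
fit_reversal(reversal_curve(trials))
```

Problem sizes used by the shipped checks: unit tests simulate 3–25 blocks
per type and cross-validate with 1–2 runs; the acceptance checks run the
full 50 + 50-block simulation with 20 runs of 5-fold cross-validation per
model, the package's standard recovery protocol.

## Known limitations

* The likelihood conditions on observed history; it does not marginalize
  over latent criterion uncertainty (the model is deterministic given
  history, as specified).
* No lapse term inside the choice model (lapses live only in the
  psychometric fit), no multi-timescale history kernels, and no
  response-latency modeling.
* `"period_reset"` simulation pins the stable-period criterion at the
  earliest possible stable trial, not the realized one (see above).
* Model comparison is by cross-validated likelihood only; information
  criteria and Bayesian posteriors are out of scope.
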