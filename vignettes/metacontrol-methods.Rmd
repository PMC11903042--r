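---
title: "Models and methods behind metacontrol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metacontrol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacontrol)
```

`metacontrol` studies the interplay of *meta-cognition* (how well confidence
tracks accuracy) and *meta-control* (how confidence modulates the balance
between model-free and model-based control) with two simulated tasks and the
analysis chain that connects them. This vignette explains the generative
models, the estimators, the defaults and the numerical choices, and what the
synthetic data can and cannot tell you about real behavior.

## The two-outcome bandit task

Four people each grow a distinct pair out of four vegetables, and each
vegetable is grown by exactly two people. Those constraints force the
person-vegetable graph to be a single alternating 8-cycle, so exactly four
person pairs share one vegetable — these are the pairs offered for choice —
and `make_structure()` draws the mapping uniformly over the 72 valid
labelled structures (verified against exhaustive enumeration in the test
suite). Choosing a person pays out each of their two vegetables
independently, 1 or 0, according to per-vegetable reward probabilities that
follow independent Gaussian random walks (`simulate_schedule()`): step sd
0.03 per trial with reflecting boundaries at 0.2 and 0.8 (a proposal `x`
above 0.8 folds back to `1.6 - x`, iterated). Sessions comprise 5 blocks of
60 trials; each block offers the four common pairs 15 times each in random
order, and probabilities are re-drawn at block starts (participants are told
the market "reset", so the agent's values reset too).

## The hybrid MF/MB agent

`simulate_bandit_agent()` implements a hybrid of two controllers sharing a
learning rate $\alpha$:

* **Model-free:** a cached value per person,
  $Q_{MF}(p) \leftarrow Q_{MF}(p) + \alpha\,[(r_C + r_U) - Q_{MF}(p)]$,
  initialized at 1.0 — the expected two-outcome sum at chance payout.
* **Model-based:** a value per vegetable,
  $V(v) \leftarrow V(v) + \alpha\,[r_v - V(v)]$ for both observed
  vegetables, initialized at 0.5, combined through the known structure:
  $Q_{MB}(p) = \sum_{v \in p} V(v)$.

After every trial all values *not* updated decay toward their
initialization by a factor $(1-f)$ (forgetting). The choice is logistic in
left-minus-right differences,

$$P(\text{left}) = \sigma\!\big(w_{MF}\,\Delta Q_{MF} + w_{MB}\,\Delta Q_{MB}
  + p_r\,\Delta \text{rep} + p_z\,\Delta \text{side}\big),$$

with indicator regressors for repeating the previous person ($p_r$) and the
previous response side ($p_z$). The weights act as inverse temperatures;
$w_{MF}=0$ or $w_{MB}=0$ give pure-MB and pure-MF agents, the key
manipulations for the signature analyses.

Confidence is reported on the task's 50–100 slider as
$50 + 50\,\sigma(g\,|\Delta Q_{\text{val}}| + \epsilon)$, with
$\Delta Q_{\text{val}}$ the weighted value difference, gain $g$
(`conf_gain`) and Gaussian noise $\epsilon$ (`conf_noise`). This is a
deliberately minimal monotone model: real confidence in value-based choice
has richer dynamics, but a monotone map of decision evidence is all the
downstream interaction analyses require. A meta-control hook closes the
loop: with `meta_gain` $= m$, the next trial's effective MB weight is
$w_{MB}\exp\{m\,(c_{t-1}-75)/25\}$, so a confident trial boosts (for
$m > 0$) the model-based contribution on the next trial. The default agent
($\alpha=0.5$, $w_{MF}=w_{MB}=3$, $f=0.1$, $p_r=0.3$, $p_z=0.1$,
`conf_gain` 1.5, `conf_noise` 1, `meta_gain` 0) produces repeat rates,
reward sensitivity and confidence spreads in the range reported for this
task family; these values were fixed once and all tests run against them.

## One-trial-back signatures and their confidence interactions

`classify_transitions()` splits consecutive within-block trial pairs by
whether trial $n{+}1$ re-offers the person chosen on trial $n$:

* **MF-type** (re-offered): the common vegetable C is the one shared with
  the alternative person; a positive effect of C's trial-$n$ payout on
  *repeating* the choice is the model-free signature, because the
  model-based system credits both offered people equally for a common
  reward.
* **MB-type** (not offered): exactly one offered person shares a vegetable
  with the previous choice (forced by the 8-cycle); a positive effect of
  that common vegetable's payout on *generalizing* to the neighbor — after
  controlling for the vegetable's generating reward probability — is the
  model-based signature, because the previous person's cached MF value
  cannot transfer.

Rewards are coded $\pm 0.5$ (symmetric with the confidence coding; signs
and tests are coding-invariant, magnitudes are not). The regressions are
hierarchical logistic models fit by Laplace-approximate maximum marginal
likelihood (`lme4::glmer`, bobyqa):

* MF: `repeat ~ C * U + (1 + C | subject)`
* MB: `generalize ~ C * prob_C + (1 + C | subject)` with `prob_C`
  standardized (and dropped with a warning if constant).
* Interactions: `y ~ C * conf + (1 + C:conf | subject)`, where `conf` is
  the within-subject median split ($\pm 0.5$, ties below) or standardized
  continuous confidence.

For the interaction model the random term follows the printed form of the
within-subject analyses (a per-subject random interaction slope); we *also*
estimate the fixed interaction, because per-subject "total" effects are
defined as fixed plus empirical-Bayes random modes, and a random-only
interaction is shrunk toward a zero population mean — it could never
express a population-level meta-control effect. Per-subject totals are read
off `coef()`, and `compare_conditions()` contrasts them across conditions
with a linear mixed model (`lmerTest`) or Wilcoxon tests.

## The perceptual task and the SDT observer

`simulate_perceptual()` emulates a dot-density discrimination with a
one-up two-down staircase on the dot difference $\Delta$ (start 20 dots,
step 1, floor 1): one error raises $\Delta$, two consecutive correct
responses lower it, which converges to the classic 70.7%-accuracy point.
The task description's nominal 65% differs from what this named rule can
deliver; we implement the rule and let accuracy settle where it must
(~0.70 in long runs). The observer samples evidence
$x \sim N(s\,k\Delta,\,1)$ ($s=\pm1$ the stimulus side), chooses
$\mathrm{sign}(x)$, and forms confidence from $y = x + N(0, \tau)$
(`meta_noise` $\tau$), reporting its posterior probability of being correct
clipped to the 50–100 slider. Two deliberate choices:

* The evidence gain default $k = \Phi^{-1}(0.707)/20 \approx 0.027$ per dot
  places the staircase equilibrium at the 20-dot starting level, so the
  step is a small relative perturbation and the session's sensitivity is
  approximately constant at $d' = 2k\Delta^* \approx 1.1$.
* The posterior uses the observer's *difficulty belief* — the trained level
  at the start of the recorded session — not the trial-exact $\Delta$ (a
  subtle dot-count difference in a brief flash is not knowable). Using the
  exact per-trial difficulty would leak extra type-2 information under a
  wobbling staircase and push meta-$d'$ above $d'$; with the belief
  version, confidence is a monotone transform of the choice evidence at
  $\tau = 0$ and the M-ratio centers on the normative 1.

`n_practice` runs (and discards) staircase-only training trials, mirroring
the task's calibration phase; `staircase = FALSE` gives the
constant-difficulty variant, the regime in which the signal-detection
model's assumptions hold exactly.

## Meta-d', M-ratio, and the hierarchical model

Continuous confidence is quantile-binned per subject into $K = 4$ ratings
(`bin_confidence()`; ties at an edge fall in the lower bin; if a point mass
— typically reports pinned at 50 — collapses quantile edges, binning falls
back to deterministic equal-count rank binning). `fit_type1()` gives
$d' = z(HR) - z(FAR)$ and $c$ with a $1/(2N)$ correction applied only at
this maximum-likelihood stage. `fit_meta_d()` maximizes the multinomial
likelihood of response-conditional rating counts under an SDT observer
whose sensitivity is meta-$d'$ and whose type-1 criterion is rescaled
proportionally ($c' = c\,\mathrm{meta}\text{-}d'/d'$), with $K-1$ ordered
type-2 criteria per response side parameterized as positive log-increments;
L-BFGS-B with three dispersed starts, and the suite checks the optimum
against an independent dense grid-search oracle.

`fit_hierarchical()` estimates metacognitive efficiency jointly across
subjects and (up to three) within-subject conditions in JAGS. Per subject
and condition, the same type-2 likelihood applies with $d'$ and $c$ fixed
at their subject-level ML estimates; the log M-ratios are draws from a
condition-wise multivariate Gaussian with priors $\mu_c \sim N(0,1)$,
$1/\sigma_c^2 \sim \mathrm{Gamma}(0.001, 0.001)$, and pairwise
$\rho \sim \mathrm{Uniform}(-1,1)$. For three conditions a uniform prior on
the three correlations admits non-positive-definite matrices; those draws
receive log-density $-\infty$, implemented with the JAGS "zeros trick" and
an explicit $3\times3$ determinant guard (the direct
`dmnorm`/`inverse` route would error rather than reject). Type-2 criterion
increments have weakly informative $\exp(N(-1,1))$ priors. Defaults are the
study's 3 chains of 12,000 draws with 2,000 warm-up; the tests and examples
use 3×2,000/500, which converges (all split-chain $\hat R < 1.1$, checked
via `coda::gelman.diag`) because the model is small. Group-level summaries
use $\exp(\mu_c)$ draws; `posterior_fraction()` reports the share of
iteration-paired draws with one condition's group M-ratio below another's,
and `subsample_wilcoxon()` implements the repeated (default 1,000×)
30-sample rank-sum comparison of two posteriors, with a paired signed-rank
variant available (off by default, matching the reported procedure even
though the design is within-subject). `qsr()` scores bandit confidence with
the quadratic scoring rule $1-(c/100-y)^2$.

## Hybrid-model fitting and simulate-then-regress

`nll_hybrid()` evaluates the exact choice log-likelihood with the same
update rules as the simulator (log-domain throughout); confidence reports
enter the likelihood only through the optional `meta_gain` pathway, not as
an observation model. `fit_subject()` runs bounded L-BFGS-B from
Latin-hypercube starts (default 10) with bounds $\alpha, f \in [0,1]$,
$w \in [0,20]$, $p_r, p_z \in [-5,5]$; pure maximum likelihood by default,
with an optional small L2 `ridge` on the weight parameters for degenerate
sessions (a non-learning chooser leaves the weights unidentified along an
$\alpha = 0$ ridge). Recovery at the study scale (30 subjects × 300
trials) yields true-vs-fitted correlations above 0.7 for $\alpha$,
$w_{MF}$ and $w_{MB}$; `forget` and $p_z$ are more weakly identified
(reported, not asserted). `simulate_and_regress()` closes the loop the way
the study's model critique does: regenerate sessions from fitted
parameters (fresh schedules and offers by default; 1,000 repetitions at
full scale), rerun the MB regression on each synthetic cohort, and average
each subject's total effect across repetitions.

## Problem sizes, determinism, limitations

All generators are seed-deterministic (identical seeds reproduce sessions
bit-for-bit). The test suite and examples use reduced problem sizes chosen
for tight iteration: hierarchical fits on 8–20 subjects × 100–200 trials
with 3×2,000 draws, signature cohorts of 12–30 subjects × 300 trials,
recovery with 5–10 optimizer starts, simulate-then-regress with a handful
of repetitions; the `"paper"` configuration profile restores the
full-scale settings (30 subjects, 3×12,000 draws, 1,000 repetitions).

What passing tests on synthetic data do show: the estimators recover the
quantities their generative models define (normative M-ratio, signature
dissociation, meta-control interactions, RL parameters), at realistic
sample sizes. What they cannot show: that real subjects obey these
generative models. The bandit confidence model is a minimal monotone map,
not a mechanistic theory; the perceptual observer has no lapses, drift, or
criterion fluctuations; sessions are stationary within blocks; and the
M-ratio itself is biased when difficulty varies, which is why no M-ratio
analysis is offered for the bandit task (its outcome qualities fluctuate by
design — the QSR serves there instead). Empirical drug-condition effects
are outside the package's reach by construction: no subject data ship with
it, and cross-condition comparisons are exercised on synthetic analogues
only.
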