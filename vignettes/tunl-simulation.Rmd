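---
title: "Simulating the TUNL touchscreen task: model, schedules, and the benefit score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the TUNL touchscreen task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunlsim)
```

## The task

In the trial-unique nonmatching-to-location (TUNL) task a rodent faces a
touchscreen covered by a mask exposing a grid of response windows. A trial
runs: nose poke in the food magazine to initiate; touch the illuminated
*sample* location; wait out a *delay*; poke the magazine again; then choose
between the re-illuminated sample location (S−) and a novel location (S+).
Choosing S+ earns a pellet; an error turns the house light off for 5 s and
is followed by a *correction trial* that repeats the same placements until
the subject is correct, protecting against location biases. Sample touches
are additionally rewarded on 1/3 of trials. A session ends at 64 completed
(non-correction) trials or one hour, whichever comes first.

Accuracy falls with the delay (a memory load) and with decreasing spatial
separation between S− and S+ (a pattern-separation load). Hippocampal
lesions make subjects acutely delay-sensitive while leaving performance
under easy conditions intact — the pattern the default agents encode.

`tunlsim` implements the task as a discrete-event simulation: mask
geometry and separation metrics, the full trial state machine,
pre-training stages, per-experiment session schedules with
counterbalancing, parametric subject agents, and the analysis layer,
including the mediating-behavior benefit score.

## Geometry and separation

Two masks are modelled: mask A (2 usable rows × 4 columns of 4.25 cm
windows) and mask B (2 × 7, 2 cm windows). Locations are 0-based
`(row, col)` with row 0 at the bottom — the source apparatus never assigns
indices, so this convention is the package's own. Two separation
currencies coexist in the literature the task comes from, and both are
implemented:

* **Intervening windows** for fixed-level sessions: same-row pairs with
  `|Δcol| − 1` windows between them. Only within-row counts yield exactly
  five usable levels above adjacency on a 7-column mask, which is why the
  five-level experiment is interpreted this way.
* **Euclidean grid distance** for mixed-separation sessions, with the
  adjacent step defined as 1 and bins `minimum` (< 3), `medium` ([3, 6))
  and `maximum` (≥ 6).

"Adjacent" for exclusion purposes means any touching neighbour —
horizontal, vertical, or diagonal (separation ≤ √2) — because control
subjects perform at chance on all of them.

```{r}
enumerate_pairs(tunl_mask("B"), "same_row", windows = 5)
```

## The agent model

Choice accuracy follows a minimal two-factor monotone model,

$$P(\text{correct}) \;=\; \tfrac12 + (p_{\max} - \tfrac12)\,
  \bigl(1 - e^{-\max(0,\, s - s_0)/\lambda}\bigr)\, e^{-d/\tau},$$

with delay $d$ (s), separation $s$ (grid units), floor $s_0$, scale
$\lambda$, asymptote $p_{\max}$ and memory time constant $\tau$. The form
is an explicit modelling choice, not an empirical claim: exponential
forgetting times a saturating discriminability is the simplest
interpretable surface that is monotone in both loads, bounded in
$[0.5, p_{\max}]$, and calibratable to the published accuracy levels.

Defaults (`default_agents()`):

| parameter | sham | lesion | meaning |
|---|---|---|---|
| `p_max` | 0.88 | 0.88 | asymptotic accuracy |
| `tau_s` | 60 s | 4 s | memory decay constant |
| `sep_floor` | 2 | 2 | separation at/below which discrimination is nil |
| `sep_scale` | 1.5 | 2.5 | separation sensitivity |

The lesion is deliberately *not* a lower asymptote: it is a short memory
constant and a shallower separation sensitivity, so that lesioned agents
match controls at a 1 s delay and large separations but collapse toward
chance at 6 s — at 6 s delay and separation 6 the model evaluates to
0.820 (sham) and 0.568 (lesion), bracketing the ~80%/~60% levels the
defaults are calibrated to.

```{r}
a <- default_agents()
round(c(sham_6s = choice_probability(a$sham, 6, 6),
        lesion_6s = choice_probability(a$lesion, 6, 6),
        sham_1s = choice_probability(a$sham, 1, 6),
        lesion_1s = choice_probability(a$lesion, 1, 6)), 3)
```

Agents also emit the 18 candidate mediating behaviors. Each non-strategy
behavior is an independent Bernoulli(0.2) mark per trial — a base rate
chosen once as typical for permissively hand-scored behavior categories,
and needed so that all 18 columns of the annotation table are exercised.
A `strategy_spec()` designates one behavior with its own emission
probability and an additive accuracy effect `benefit_beta` on emitting
trials (clipped into [0.02, 0.98]). Real mediating behaviors are richer —
temporally extended, mutually exclusive, state-dependent — but a Bernoulli
emission with an additive effect is exactly the data-generating process
the benefit-score estimator assumes nothing beyond, which makes it the
right null and the right injected-effect model for validating that
estimator. Passing tests therefore validate the estimator's arithmetic
and calibration, not any claim about real rats' behavioral repertoires.

## The engine's timing model

The source task defines no latency distributions, so each response phase
(initiation, sample touch, magazine poke, choice, reward collection)
draws a uniform 1–3 s latency; delays, timeouts and ITIs are exact. The
clock is monotone; a trial that would end past the session time cap is
discarded, as a session cut off by the hour would be. Correction trials
repeat until correct by default (`max_corrections` can cap them); the
64-trial cap counts non-correction trials only, because the dependent
variable excludes corrections and counting them would make session length
depend on error rate. Whether the sample touch is re-rewarded on
correction trials is unspecified in the source; the engine draws the 1/3
reward independently on every trial, corrections included.

## Experiment schedules

`make_plan()` builds the five standard designs: 20 all-pair acquisition
sessions on mask A (exp1); 16 sessions in the fixed order 6 s/max,
6 s/min, 1 s/max, 1 s/min (4 per condition) on mask B (exp2); 8
mixed-separation sessions with adjacent pairs excluded and delays 1 s/6 s
counterbalanced (exp3); 15 sessions covering separation levels 1–5 three
times each at a 1 s delay (exp4); and the single 48-trial
mediating-behavior probe at the largest separations with a 20 s ITI
(exp5). Where the source design says only "counter-balanced", plans use
Williams Latin-square rows assigned to subjects cyclically: each
condition appears equally often, no condition repeats within a cycle, and
the same seed and subject index always give the same plan. The exp3
session count (8) is the package's own choice — the source reports only
that delay varied between sessions — sized so each delay × separation-bin
cell collects enough trials for stable percentages. Mixed-separation
sessions draw uniformly over all non-adjacent pairs and bin post hoc; no
per-bin quotas are imposed.

## Analysis layer

The dependent variable is percent correct excluding correction trials
(`percent_correct()`), summarised by session blocks, separation bins or
levels, or delay × separation (`accuracy_by_condition()`; block means
average session-level percentages, not pooled trials). `chance_test()`
is a one-sample t-test against 50%, computed in closed form so that
constant-at-50 input returns t = 0 rather than an error.

For the mediating-behavior analysis, each subject × behavior contingency
$(a, b, c, d, e)$ — correct/total trials with and without the behavior,
and the grand total — gives the contribution $(a - \tfrac{b}{d}c)/e$: the
excess of observed correct trials with the behavior over the count
expected from that subject's accuracy without it, as a proportion of all
completed trials. The score is the mean contribution across subjects;
`test_benefits()` runs per-behavior one-sample t-tests with a Bonferroni
correction of `min(1, 18p)` — the family is always the full 18 candidate
behaviors, even if fewer are testable in a given data set. Degenerate
margins follow fixed conventions: a subject who never emits a behavior
contributes 0 and is retained; one who emits it on every trial has an
undefined contribution and is dropped for that behavior (with a message).
Under an injected strategy with emission probability $q$ and effect
$\beta$, the estimator converges to $\beta\,q$, which is what the
effect-recovery tests check.

Repeated-measures ANOVA and post hoc families are deliberately not
implemented: the tidy per-subject-per-condition tables the package emits
feed any standard ANOVA tool directly.

## Numerical and validation choices

* All simulations are bit-reproducible from integer seeds; cohort runs
  derive per-session seeds from one master seed.
* The adjacency exclusion uses a `1e-9` slack above √2 against floating
  rounding; bin boundaries are half-open exactly as stated.
* The decay constant is recoverable by maximum likelihood
  (`fit_memory_decay()`) only when session delays bracket it: the test
  suite recovers τ = 4 s from 50 standard sessions at delays 1–10 s to
  within 20%, while a 60 s constant is not identifiable from such short
  delays (the likelihood is nearly flat) — a limitation of any design
  whose delays are an order of magnitude below the constant.
* Validation problem sizes were chosen to make the statistical checks
  sharp at desk scale: 10⁴ trials for chance and reward-conservation
  properties, 20 seeds × 8 sessions × 48 trials for the accuracy
  calibration, 200 seeded cohorts of 12 subjects for the null benefit
  calibration and 50 for effect recovery.

## Limitations

The simulator validates the task's logic and its estimators, not rodent
cognition: there is no learning within or across sessions (acquisition
block effects are outside the agent model), no biophysics, no touch
kinematics, and behaviors are emitted independently across trials. Those
simplifications are what make the analysis layer's calibration checks
interpretable.
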