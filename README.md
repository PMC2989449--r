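# tunlsim

Simulation and analysis of the **trial-unique nonmatching-to-location
(TUNL)** rodent touchscreen task.

In TUNL a rat initiates a trial, touches an illuminated *sample* window on
a masked touchscreen, waits out a delay, and must then choose a *novel*
location (S+) over the re-illuminated sample location (S−). Errors trigger
correction trials with identical placements; accuracy (percent correct,
corrections excluded) falls with the sample–choice delay and with
decreasing S−/S+ separation, indexing memory load and spatial pattern
separation respectively. The task is acutely sensitive to hippocampal
damage: lesioned subjects match controls at short delays and large
separations but collapse toward chance at a 6 s delay.

`tunlsim` lets you exercise the assay's full logic without animals or
hardware: mask geometry and separation metrics, the trial state machine
(correction trials, 1/3 sample reward, 64-trial/1-hour caps),
pre-training stages, the five standard experiment schedules with
counterbalancing, parametric subject agents, and the analysis layer —
including the per-rat mediating-behavior **benefit score**

$$\bar{x} \;=\; \frac{1}{n}\sum_{i=1}^{n}\frac{1}{e_i}\Bigl(a_i - \frac{b_i}{d_i}\,c_i\Bigr)$$

where, per rat *i*, $a_i$/$c_i$ are correct/total trials with a candidate
behavior present, $b_i$/$d_i$ correct/total with it absent, and $e_i$ the
grand total — the observed correct count on behavior trials minus the
count expected from that rat's accuracy without the behavior, as a
proportion of all completed trials, averaged across rats and tested
against zero with Bonferroni-corrected one-sample t-tests (m = 18
candidate behaviors).

Agent accuracy follows a two-factor monotone model,
`P = 0.5 + (p_max − 0.5)(1 − exp(−max(0, s − s0)/λ)) exp(−d/τ)`,
with delay *d*, separation *s*, and a hippocampal lesion expressed as a
short memory constant τ and shallow separation sensitivity λ — not a
lower asymptote.

## A worked example

Simulate the mediating-behavior probe (one 48-trial session per subject
at the largest separations, 6 s delay, 20 s ITI) for 12 intact subjects,
then score the 18 candidate behaviors:

```r
library(tunlsim)

cfg <- run_config("exp5", default_agents(), rep("sham", 12), seed = 2024)
sim <- simulate_experiment(cfg)

analyze_trials(sim$trials, "accuracy")[1:3, ]
#>   subject_id session_id n_trials percent_correct
#> 1         s1          1       48        72.91667
#> 2        s10          1       48        81.25000
#> 3        s11          1       48        87.50000

bt <- analyze_trials(sim$trials, "benefit", annotations = sim$annotations)
as.data.frame(bt)[17, c("behavior", "mean_benefit", "sem",
                        "p_uncorrected", "p_bonferroni")]
#>               behavior mean_benefit         sem p_uncorrected p_bonferroni
#> 17 screen_touch_sample -0.006212472 0.007307658     0.4133733            1
```

Per-subject accuracies sit near the ~80% level the default intact agent
is calibrated to, and no behavior shows a significant benefit after
Bonferroni correction — as expected, since these agents emit behaviors at
a background rate with no injected performance effect. A
`strategy_spec()` can inject a real effect (emission probability *q*,
accuracy shift β), which the estimator recovers as β·q.

A thin CLI over the same functions lives at `inst/cli/tunl.R`
(`plan`, `simulate`, `analyze`, `benefit`, `pretrain` subcommands); an
example run configuration is in `inst/extdata/exp5_run.yaml`.

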