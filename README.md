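# vsdecision

Spike-train and behavioral analysis for sequential value-based decision
experiments: a subject sees one of six reward-predicting objects (values
1–6), and decides whether to release a button to choose it before a second
object appears. The package separates the neural signatures of *option
valuation* from *action selection* in single-unit recordings, and
quantifies how stimulation perturbs the choice. A synthetic-data generator
with the same statistical structure makes every stage testable against
ground truth.

## What it computes

**Sliding-window signal classification.** Value and choice are almost
collinear in this task (good options get chosen), so each 150-ms window of
a neuron's per-trial firing rates F is fitted with two *separate*
one-predictor models,

    value model:  F = b0 + b1 * V        choice model:  F = b0 + b1 * C

and their R² difference is referred to a Monte Carlo null built by
re-assigning the *baseline* (pre-onset) rates across trials and fitting the
same models to the shuffled baseline. A window is **value-modulated** when
the observed ΔR² beats more than 975/1000 shuffles (and the value model's
F-test is significant), **choice-modulated** in the mirror case,
**intermediate** when both models fit but neither wins. Runs of ≥ 40
consecutive windows (at the 1-ms reference step; duration-preserving at
coarser steps) become signal segments with latencies, from which per-kind
latency distributions and signal transition probabilities (e.g.
P(value→choice)) follow.

**Ridge companions.** `F = b0 + b1*V + b2*C` (and value+RT, previous-value
variants) with the penalty λ(b1²+b2²) on standardized predictors,
closed-form solution, permutation p values, and max-statistic control of
the family-wise error rate across windows for population proportion curves.

**Behavior.** Psychometric logistic fits, the indifference value −β0/β1
("risk attitude": the value chosen with 50% probability),
previous-trial-value effects, and latency-vs-value regressions with
session-level Wilcoxon inference.

**Stimulation effects.** Per-value Δchoice rate for paired
stimulation/control sessions, per-site chi-square, the |Δ| value profile
with ANOVA and value-4 contrast, a distribution-*width* shuffle test
(Gaussian ML σ vs within-site label exchange) for net effects, and
latency-effect motor controls.

## Worked example

```r
library(vsdecision)

# a 300-trial session and one neuron that codes value early, choice late
tr  <- simulate_behavior(behavior_params(beta0 = -4.8, beta1 = 1.2,
                                         n_trials = 300), seed = 7)
fit <- fit_choice_logistic(tr)
round(c(slope = fit$beta[[2]], indifference = risk_attitude(fit)), 2)
#>        slope indifference
#>         1.32         4.33

np     <- neuron_params(baseline_hz = 10, value_gain_hz = 4,
                        choice_gain_hz = 8, t_value_on_ms = 100,
                        t_switch_ms = 500)
trains <- simulate_neuron(np, tr, seed = 7)
cfg    <- analysis_config(step_ms = 10, n_shuffle = 200, seed = 7)
ser    <- classify_neuron(trains, tr, cfg)
extract_segments(ser, cfg$run_len)
#>   neuron_id   kind latency_ms end_ms n_windows
#> 1        n1  value          0    440        45
#> 2        n1 choice        470    850        39
```

The neuron's activity is read out exactly as constructed: a value-modulated
signal from onset (windows are labeled by their start time, so windows
beginning before the 100-ms epoch onset already overlap it), handing over
to a choice-modulated signal around the 500-ms switch (windows starting
at 470 ms lie mostly inside the choice epoch). Latencies are window start
times in ms; runs are counted in 10-ms steps here, so the 39-window choice
segment spans about 390 ms.

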