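---
title: "From option value to action selection: the vsdecision methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From option value to action selection: the vsdecision methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdecision)
```

## The experiment this package analyzes

A subject fixates, holds a button, and sees the first of two sequentially
presented objects. Six objects predict six graded reward amounts (values
1–6, presented uniformly at random, so the mean presented value is 3.5).
Releasing the button during the first object's 1000-ms presentation chooses
it; holding on passes to the second object. Single-unit spike times are
recorded (here, from ventral striatum) aligned at first-object onset, and in
stimulation experiments a random half of trials receive electrical or
optogenetic stimulation during the first-object period.

Within the first-object period three processes occur in close succession —
valuation of the option, selection of the action, and its execution — and
the package's purpose is to separate their neural signatures and quantify
causal perturbations of the choice.

## Data model

Trials are rows of a plain CSV (`session_id, trial_index, value1, value2,
chosen, latency_ms, stim, task`); spikes are long-format rows
(`neuron_id, session_id, trial_index, spike_ms`), in milliseconds relative
to first-object onset (negative times cover the baseline). All times are
real-valued; windows are half-open `[t, t + len)` labeled by their start
`t`, so boundary spikes are never double-counted. `latency_ms` is the
release latency and exists exactly when `chosen = 1`; an optional
`latency2_ms` carries the (reflexive) second-object release latency on
unchosen trials, which supports the second-object latency regression without
disturbing the core contract. Readers validate every invariant and report
the offending row; referential integrity between spikes and trials is
checked, never assumed.

## The sliding-window model comparison

The core question — does a neuron's activity reflect the option's *value* or
the subject's *choice*? — cannot be answered with one multiple regression,
because value and choice are strongly correlated by design (high-value
options are almost always chosen). Instead two one-predictor models are
compared on each 150-ms window of per-trial rates $F$:

$$\text{value model: } F = \beta_0 + \beta_1 V, \qquad
  \text{choice model: } F = \beta_0 + \beta_1 C,$$

with $V$ the first-object value and $C \in \{0,1\}$ the choice flag. The
observed statistic is $\Delta R^2 = R^2_{\text{value}} -
R^2_{\text{choice}}$.

Its null distribution is built from the baseline period, which carries no
task signal: the per-trial baseline rates (window $[-200, 0)$ ms) are
randomly reassigned across trials, both models are fitted to the shuffled
baseline rates, and the resulting $\Delta R^2$ is recorded; 1000 shuffles by
default. With `exceed_count` the number of shuffles the observed difference
strictly exceeds, a window is labeled

* **value** if `exceed_count > 0.975 · n_shuffle` *and* the value model's
  F-test is significant at $\alpha$;
* **choice** if `exceed_count < 0.025 · n_shuffle` *and* the choice model
  fits significantly;
* **intermediate** if neither tail is reached but *both* models fit
  significantly;
* **none** otherwise.

Ties ($\Delta R^2_{\text{obs}} = \Delta R^2_{\text{null}}$) count as
non-exceeding — the conservative direction. A window with only one
significant fit and a non-significant difference is `none`, not
intermediate. Because the `intermediate` route adds a small extra
acceptance region, the total null mislabel rate sits slightly above the
two-tailed $2 \times \alpha/2$ alone but within the calibration tolerance
the test suite enforces.

A *signal segment* is a run of at least `run_len` consecutive same-label
windows; its latency is the first window's start time. At the reference
1-ms step, `run_len = 40` corresponds to a 40-ms run. When the step is
coarsened (the package default functions accept any step; the test suite
uses 10 ms), `run_len` defaults to `round(40 / step_ms)` so the run
*duration* — the smoothing horizon of the rule — is preserved. This scaling
changes how many windows a run spans, and is therefore exposed prominently
in `analysis_config()` rather than buried.

Two further choices were genuinely open:

* **Fresh shuffles per window.** Whether the shuffle set is drawn anew for
  every window or shared across windows affects only the window-to-window
  correlation of the Monte Carlo noise, not any single window's level. We
  draw fresh, seeded substreams per (neuron, window), which keeps every
  window's decision independently reproducible.
* **The F-test gate across a run.** The significant-fit requirement is
  enforced in *every* window of a qualifying run (it is part of the
  per-window label), the stricter of the two possible readings.

**Latency semantics.** Windows are labeled by their start time, so a strong
signal whose epoch begins mid-trial can be detected up to one window length
*early*: a window starting 100 ms before the epoch still overlaps it.
Recovered latencies are therefore interpreted on the scale
$[t_{\text{on}} - \text{window\_len}, t_{\text{on}} + \text{run
horizon}]$. The latency-recovery checks in the test suite use an
onset-aligned epoch, which isolates the classifier's timing from this
partial-overlap geometry; the ordering and transition checks use a
mid-trial switch.

**Transitions.** For neurons exhibiting two signal kinds, the transition
probability P(A→B) is the fraction whose first A segment precedes the first
B segment (ties count half each way and are flagged); the transition time
is the later segment's latency.

## Ridge regression and the max-statistic procedure

As a robustness companion to the model comparison, ridge regression fits
value and choice (or value and reaction time, or previous-trial value)
jointly, with the penalty $\lambda(\beta_1^2 + \beta_2^2)$ absorbing the
collinearity. Implementation choices:

* Predictors are standardized before penalization (so the penalty is
  scale-equitable between a 1–6 value and a 0/1 flag) and the intercept is
  unpenalized; the closed form $(Z^\top Z + \lambda I)^{-1} Z^\top F_c$ is
  used and is verified against an independent numerical minimizer in the
  tests. Default $\lambda = 1$ on the standardized scale: a fixed, small
  amount of shrinkage that keeps results deterministic. Since inference is
  by permutation (below), the exact value mainly trades variance against
  bias of the point estimates; the sign-stability property the tests
  demonstrate holds across a broad $\lambda$ range.
* Coefficient significance is by permutation of the response across trials,
  $p = (1 + \#\{|\beta_{\text{perm}}| \ge |\beta_{\text{obs}}|\})/(1 +
  n_{\text{perm}})$ — the design, and hence the predictor correlation, is
  held fixed. An analytic ridge test would require an effective-degrees-of-
  freedom approximation; permutation matches the rest of the pipeline's
  logic.
* The population question — "in which windows is the proportion of
  significant neurons above chance?" — is answered with max-statistic
  family-wise control: per permutation, the proportion is computed in every
  window on shuffled data and the maximum across windows forms the null;
  a window is significant only if its observed proportion strictly exceeds
  the null's $1-\alpha$ quantile.
* Computing a permutation p value *of* shuffled data for every permutation
  would nest permutations. Instead one set of $B$ response permutations per
  neuron/window serves twice: the observed p is the rank of
  $|\beta_{\text{obs}}|$ among all $B+1$ magnitudes, and each permutation's
  p is its own rank in the same set. Under the null all $B+1$ values are
  exchangeable, so these ranks are exactly uniform, giving a calibrated
  null for the proportion statistic at no extra cost.

The `value_rt` model is restricted to chosen trials (reaction time exists
only when the button was released) and `prev_value` drops each session's
first trial; window starts for these population analyses tile the
presentation period non-overlappingly by default.

## Behavioral models

The psychometric model is a logistic in first-object value,
$P(\text{choose}) = \text{logistic}(\beta_0 + \beta_1 V)$, fitted by IRLS
with a 25-iteration cap; separation — expected in overtrained subjects whose
choices are nearly deterministic away from the indifference point — is
reported via a `converged` flag and diagnostic rather than raised. The
indifference value ("risk attitude") is $-\beta_0/\beta_1$. The
previous-trial model adds the preceding trial's second-object value, whose
coefficient is small and negative in the generator's defaults (having just
seen a rich alternative makes rejecting the current option slightly more
attractive). Latency regressions are OLS of release latency on value.
Population inference over sessions uses per-session fits and two-sided
Wilcoxon signed-rank tests of the session slopes against zero, the
session-level logic `behavior_session_summary()` mirrors.

## Stimulation-effect statistics

For a paired stimulation/control session the per-value effect is
$\Delta_v = \hat{p}_{\text{stim},v} - \hat{p}_{\text{ctrl},v}$, tested
per site with a df-1 Pearson chi-square (no continuity correction by
default; a flag enables it). Because sites can be shifted in either
direction, the *net* population effect is captured two ways: the mean
absolute effect per value (with a one-way F test and a value-4 contrast)
and the *width* of the $\Delta$ distribution across sites.

The width is the $\sigma$ of a maximum-likelihood Gaussian fit after
centering — equivalently the $1/n$-denominator SD — rather than a
histogram-based fit, avoiding binning arbitrariness; FWHM would be a fixed
multiple and change nothing. Its null is built by shuffling
stimulation/no-stimulation labels *within each site*, which preserves every
site's trial count and value composition; only the labels landing on the
focus-value trials matter, so the within-site permutation reduces to two
nested hypergeometric draws, which is how it is computed. Significance
follows the same `exceed_count > (1 - α/2) · n_shuffle` convention as the
classifier.

A motor-pathway control computes per-site release-latency differences, a
population signed-rank test, and the correlation between latency and choice
effects; an early/late-half sign-consistency table guards against slow
drifts masquerading as stimulation effects.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage has a ground-truth recovery test.

* **Behavior**: values i.i.d. uniform on 1–6; choice from the logistic
  with a weak negative previous-second-object term (omitted on each
  session's first trial; sessions never share history); release latency
  Gaussian around a decreasing linear law, truncated positive (defaults:
  600 − 25·V ms, SD 60 ms; the second-object latency is faster and
  flatter, 400 − 12·V ms, as a reflexive response should be).
* **Neurons**: inhomogeneous Poisson over [−400, 1000] ms, rate = baseline
  + value_gain·(V − 3.5) during the value epoch + choice_gain·C during the
  choice epoch, clipped at zero. Value coding is centered at 3.5 so the
  baseline equals the grand-mean rate and gain recovery decouples from
  baseline recovery. The epoch switch is *hard*: it gives an unambiguous
  ground-truth latency for classifier recovery. Real transitions are
  gradual; a smooth ramp would blur the latency target without changing
  what the calibration tests show.
* **Stimulation**: an additive per-site logit shift on the stimulated half
  of trials. The default stimulation-session psychometric is steep (logit
  $3(V-4)$): overtrained subjects choose near-deterministically away from
  the indifference value, so a logit shift visibly moves choices only at
  value 4 — the value-specific structure the width and profile statistics
  are designed to detect. Under a soft slope the same shift would move
  choice rates at several values, a closed-form fact worth knowing when
  choosing parameters. For sign-mixed site populations the expected
  |Δchoice| profile is symmetric in the shift and peaks at the indifference
  value; for a single signed shift of size δ the peak sits where the logit
  is closest to −δ/2, i.e. slightly off-center for coarse value grids.

Deliberately not modeled: non-Poisson spike-count dispersion (the analyses
never assume Poisson, but the calibration results are demonstrated under
it), aborted or error trials, inter-trial-interval structure, eye position,
slow excitability drifts, and gradual coding transitions. Passing recovery
tests therefore shows the *procedures* are correct and calibrated under
these conditions, not that real recordings satisfy them.

## Numerical conventions

* One master seed; every stochastic stage draws from a substream keyed by
  (stage name, unit id), so per-unit results are reproducible in isolation
  and independent across units.
* Monte Carlo tie-breaking is always non-exceeding (conservative); the
  FWER threshold comparison is strict.
* Window fits require at least 10 trials (F-test validity), a package
  choice exposed in `analysis_config()`.
* Degenerate inputs degrade explicitly: constant predictors give a
  coefficient of 0 with a warning (ridge) or an error (simple fit);
  constant responses give $R^2 = 0$, $p = 1$; empty margins make the
  chi-square NA; an all-flat width test never exceeds its null.
* Result tables are written with ≥ 6 significant digits and round-trip
  exactly enough to reproduce every label and statistic.

## Problem sizes used by the shipped tests

The package's own test suite and `scripts/acceptance.R` run everything at
desk scale, chosen to make each statistical property measurable with
comfortable margins: classifier calibration on 100–200 null neurons at a
10-ms step with 200 shuffles; recovery on 150-trial sessions with strong
gains (4 Hz per value unit, 8 Hz choice); family-wise calibration on 50
replicate populations of 100 neurons × 20 windows × 200 permutations;
stimulation suites on 50 sites of 600 trials. The reference configuration
(150-ms window, 1-ms step, 1000 shuffles, run of 40) is fully supported and
is simply a larger run of the same code paths.

## Known limitations

* The baseline-shuffle null assumes the baseline window is signal-free; a
  task that modulates pre-onset activity would need a different null epoch.
* The intermediate label's extra acceptance region makes the per-window
  "any label" rate slightly exceed the nominal two-tailed level; the
  calibration tests bound the total.
* Ridge $\lambda$ is fixed rather than cross-validated by default;
  permutation inference remains valid for any fixed $\lambda$, but point
  estimates shrink accordingly.
* Latencies inherit the window-start convention; comparisons across
  configurations must use a common window length and step.
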