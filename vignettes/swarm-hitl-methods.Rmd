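---
title: "Swarm consensus, deferral, and the synthetic study: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm consensus, deferral, and the synthetic study: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmdx)
```

# The problem

A machine classifier for pneumonia on chest radiographs emits a
probability per case and is binarized at a discrimination threshold
tuned on its training data (4.008% for the high-sensitivity model
considered here; humans and a conventional model use 50%). Human
readers, individually weaker, become stronger in aggregate — and a
*real-time swarm*, in which readers negotiate continuously rather than
voting once, is the strongest human aggregate. The two kinds of
decision maker fail differently: the machine is sensitive, the swarm
specific. swarmdx implements the evaluation of a human-in-the-loop
combination: the machine decides alone when confident, and defers
low-confidence cases to the swarm.

# The swarm model

## What is simulated

The commercial swarm platform's conviction-weighting algorithms are
unpublished, so the simulator implements a minimal closed-loop agent
model with the observable structure of the platform: five answer
targets (the probability ranges 0–5%, 5–25%, 25–65%, 65–85%, 85–100%)
at equally spaced angles on a unit circle; a puck starting at the
origin; per-tick unit-magnitude agent forces toward intended targets;
puck velocity equal to a speed constant times the mean agent force.
A session converges when the puck stays within the convergence radius
of one target for the dwell count, and otherwise times out at 60 s, in
which case the bin with maximal accumulated impulse wins, ties going
to the lower-probability bin (favouring the negative diagnosis, the
direction human readers lean).

Tunable constants, with defaults and rationale:

| parameter | default | units | why |
|---|---|---|---|
| `tick` | 0.1 | s | 600 ticks per 60 s session; desk-scale runtime |
| `max_duration` | 60 | s | the platform's per-question limit |
| `speed` | 0.8 | board units/s | a unanimous swarm converges in about 2 s; contested sessions run 10–20 s, inside the 15–60 s per-question range real sessions take |
| `conv_radius` | 0.45 | board units | wide capture zones that still leave adjacent zones (1.18 units apart) disjoint |
| `dwell_ticks` | 5 | ticks | debounces pass-throughs |
| `tau` | 0.08 | probability | conciliatory softmax temperature; mixes a belief mainly over its own and adjacent bins |

Two agent policies are provided. *Stubborn* agents always pull toward
the bin containing their own belief; this policy makes the
unanimous-recovery property exact and is the one used to test the
interpolation in isolation. *Conciliatory* agents (the default) sample
an intended bin each tick with probability proportional to
`exp(-|v_bin - belief| / tau)`; this is the minimal model of the
compromise behaviour that lets split panels converge. Intended bins do
not depend on the puck state, so a session's impulse profile is a pure
function of the sampled intents; split panels can still time out, which
the timeout rule handles. The platform's two-step procedure (coarse
range, then refined value) is collapsed into one converged bin plus
interpolation, a deliberate simplification: the interpolation below
already produces the refined value.

## Impulse attribution and interpolation

Each tick adds `tick x 1` (force x time) to the impulse `F(i)` of each
agent's intended bin — full attribution to the intended bin, not a
geometric projection onto all bins. This choice makes unanimous
recovery exact (a unanimous stubborn swarm puts all impulse on its bin
and interpolates to exactly that bin's midpoint) and keeps the
interpolation testable in isolation. The refined probability is

$$w_i = \frac{F(i)^2}{\sum_a F(a)^2}, \qquad
  \hat p = \sum_i w_i v_i,$$

with `v_i` the bin midpoints (0.025, 0.15, 0.45, 0.75, 0.925). The
implementation is checked against a literal element-by-element oracle
to 1e-12, and satisfies convexity (the result lies in the hull of
midpoints with positive impulse), scale invariance, and monotone
dominance (raising one bin's impulse pulls the result toward its
midpoint).

# Classification and aggregation conventions

- **Binarization is strictly above-threshold**: a probability exactly
  at the threshold is a negative call.
- **Majority vote requires a strict majority** of readers above the
  50% cutoff; even-panel ties are negative diagnoses (a tie is not
  "more readers" calling pneumonia).
- **Youden threshold selection** maximizes J = sens + spec − 1 over
  the observed probabilities, ties to the smallest threshold.
- **Confusion-matrix reconstruction from printed rates** uses half-up
  rounding (`TP = floor(sens * n_pos + 0.5)`), because published rates
  are themselves rounded and half-up inversion reproduces the printed
  integer counts.
- The machine threshold is 4.008% by default (it is also quoted as
  4.006% in some places; 4.008% is what the results computations cite);
  it is configurable everywhere.

# Metrics and inference

Percent correct, MAE, Brier score, rank (Mann–Whitney) AUC with ties
counted one half, F1, sensitivity and specificity. AUC is refused for
augmented diagnosis sets because their probabilities mix two scales
(machine values near 0.04, swarm values near 0.5) and are not
rank-comparable.

Confidence intervals are **percentile bootstrap** over whole-case
resamples with replacement — the plain reading of resampling "a full
set of cases from the observed population" — with 1000 resamples at
95% for metric tables and 90% for the sweep. Resampling is
unstratified by default (a stratified variant is available); resamples
on which a metric is undefined (single-class draws for AUC or
sensitivity/specificity) are redrawn and counted. BCa corrections are
deliberately not applied: plain resampling is the minimal faithful
procedure. Paired comparisons use a paired case-resample bootstrap
(default 10,000 resamples): the two-sided p-value is twice the
fraction of resamples whose metric difference flips sign against the
observed difference, capped at 1. This test is a package choice — the
analyses being mirrored report p-values without naming a test — so
p-values are reported but never treated as reproduction targets.

# Human-in-the-loop deferral

Routing uses a **closed** band (default [0.025, 0.055]) around the
machine threshold; "between" is read inclusively, configurable. Routed
cases take the swarm probability and are binarized at the human 50%
cutoff; others keep the machine probability and threshold. The
per-case origin travels with the augmented set.

The sensitivity sweep ranks cases by `|p - t|` (raw probability;
log-odds distance is available because machine probabilities compress
near the threshold) and defers k/2 machine-predicted-positive plus k/2
machine-predicted-negative cases at each even k. Balancing uses the
machine's *predicted* sign, not ground truth — selection must not peek
at labels; a label-balanced variant exists for comparison. When one
side is exhausted the count caps at availability and the asymmetry is
recorded. Selection is nested in k, so the curve starts exactly at the
machine-only accuracy and ends exactly at the swarm-only accuracy.
With two swarm groups, each (machine, group) pairing is augmented and
combined reports pool the diagnoses — 50 cases x 2 groups = 100
diagnoses.

The combined individual average across the unequal reader groups (7
and 6) is reported under both conventions — every reader weighted
equally ("pooled") and the mean of group means — since the published
tables do not state the weighting.

# The synthetic study

No per-case data from the original study are available, so a generator
reproduces its *conditions*: 50 cases with exactly 20 positive and 30
negative labels; reader groups of 7 and 6 near sensitivity 0.65 /
specificity 0.85 at the 50% cutoff; a machine source at sensitivity
0.90 / specificity 0.767 at threshold 0.04008.

The generative model is class-conditional logit-normal:
`logit(p) ~ N(mu_class, sigma)` with
`mu_pos = logit(t) + sigma * qnorm(sens)` and
`mu_neg = logit(t) - sigma * qnorm(spec)`, so the exceedance
probabilities at `t` equal the targets *exactly in expectation*, and
empirically within binomial error (verified at n = 10,000). Spread
choices: `sigma = 1.5` for readers (realistic single-reader overlap
between classes) and `sigma = 0.8` for the machine, deliberately
compressing its probabilities near 0.04 so that machine and swarm
outputs center about different averages (≈4% vs ≈50%), which is also
why AUC is refused for the mixed augmented set.

Readers are made realistically imperfect aggregators by a **shared
case-difficulty effect**: the logit spread is split into a shared
component `sigma * sqrt(rho)` drawn once per case (both groups read
the same images, so they share one realization) and an idiosyncratic
component `sigma * sqrt(1 - rho)`. Each reader's marginal operating
point is unchanged; any two readers' case-level logits correlate at
`rho`. With independent readers (`rho = 0`) a 7-reader aggregate is
nearly perfect (~97% accurate), which no reader panel achieves in
practice; `rho = 0.5` — half the variance attributable to the case —
yields the modest aggregation gains reader panels actually show
(individuals ≈76–77%, crowd/swarm ≈82%) and is the scenario default.
The raw panel generator keeps `rho = 0` as its default so the
independence assumption is opt-in, not hidden. Readers additionally
get a per-reader strictness shift (sd 0.3 logit units).

What the generator does *not* emulate: image content and
image-derived difficulty structure, reader fatigue or learning over a
session, and any dependence between machine and reader errors beyond
the class label (machine and readers err independently given the
label). Passing tests therefore demonstrate the pipeline's
correctness and the structural HITL effect under these conditions,
not the exact magnitudes any particular reader study would produce.

# Problem sizes and numerical choices

The shipped analyses use: 50-case scenarios; 1000 bootstrap resamples
(95% CIs for tables, 90% for the sweep); 500 replicates for the CI
coverage study; 200 replicates for the accuracy-ordering study;
n = 10,000 per class for operating-point recovery. These sizes give
stable summaries at interactive runtimes. Degenerate inputs are
errors, not silent values: all-zero impulse profiles, single-class
case sets for AUC/sensitivity/specificity, swarms of fewer than two
agents, empty diagnosis sets. F1 with zero true positives but nonzero
errors returns 0 with a warning. Sessions, generators, bootstraps and
the pipeline are pure functions of (inputs, config, seed).

# Known limitations

- The swarm dynamics are an invented stand-in for unpublished
  proprietary algorithms; only the interpolation layer and the
  bin scheme follow the published description exactly.
- Swarm sensitivity is structurally limited by the bin layout: the
  25–65% bin's midpoint (0.45) falls below the 50% cutoff, so a swarm
  that converges there yields a negative call unless higher bins
  carry impulse.
- Percentile-bootstrap CIs on 50 cases are discrete and can be
  slightly anti-conservative; the coverage study quantifies this
  (≈0.90 empirically at nominal 0.90).
- The paired bootstrap p-value is one reasonable convention among
  several; it is not calibrated against any published test.
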