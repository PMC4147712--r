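---
title: "Simulating adaptive spaced-retrieval training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating adaptive spaced-retrieval training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacedrecall)
```

## The protocol as a state machine

Spaced retrieval trains recall of discrete facts at systematically
lengthening retention intervals. The variant implemented here is a
two-phase tablet exercise for people with early-stage memory impairment,
modelled as a deterministic state machine over a simulated clock.

One *trial* is: present the information (the participant reads for as long
as they like, then taps to continue and cannot go back), wait the
scheduled delay, show the four-choice question, and collect an answer or
let it time out. The two phases differ only in how the delay evolves and
in feedback:

* **Assessment** — an adaptive staircase. The delay starts at
  `initial_delay_s` (90 s) and, after *every* trial, moves up one step on
  a correct answer and down one step (floored) otherwise. A failed item is
  re-presented; the phase ends after `assessment_max_questions` distinct
  items are resolved or at the first trial boundary at or past
  `assessment_max_time_s`. The final trial's scheduled delay is the
  participant's *recall time*, the calibration output.
* **Training** — expanding intervals seeded at the recall time: lengthen
  on success, hold on failure, repeat the failed item after a feedback
  screen, stop after `training_max_questions` distinct items.

The staircase variable is a single running value carried across items
within a phase, not a per-item state: the protocol's update rule is
trial-indexed ("the next trial"), and a per-item staircase would make the
recall time depend on which item happened to come last.

## Protocol parameters

All parameters live in `engine_config()`; defaults are the published
protocol values.

| parameter | default | meaning |
|---|---|---|
| `initial_delay_s` | 90 s | assessment starting delay |
| `delay_step_s` | 10 s | staircase step, both directions |
| `training_increment_s` | 10 s | training delay growth per success |
| `response_timeout_s` | 60 s | answer timeout; charged to the timeline |
| `feedback_duration_s` | 5 s | feedback screen length |
| `assessment_max_questions` | 10 | distinct-item cap, assessment |
| `assessment_max_time_s` | 1800 s | assessment wall-clock cap |
| `training_max_questions` | 10 | distinct-item cap, training |
| `min_delay_s` | 10 s | staircase floor |
| `show_feedback_in_assessment` | `FALSE` | feedback screens in assessment |

Three of these resolve points the protocol description leaves open, and
are deliberately configurable rather than hard-coded:

* `min_delay_s = 10` — repeated failures would otherwise drive the delay
  to zero or below; one step is the smallest floor that keeps every delay
  positive.
* `training_increment_s = 10` — the training narrative says the interval
  "is lengthened" without an amount; reusing the assessment step is the
  most parsimonious reading.
* `show_feedback_in_assessment = FALSE` — feedback screens are described
  only in the training phase; in assessment, failure is communicated by
  re-presenting the information. Feedback is shown after *answered* trials
  only: a timeout selects nothing to give feedback on, and the timeout
  itself already consumes 60 s of screen time.

Two further semantics choices: the time cap is checked at trial
boundaries (an in-flight trial completes; no new presentation starts at or
after the cap), which avoids truncating a trial mid-answer; and no ceiling
is imposed on the staircase, since none is stated.

## The simulated participant

No per-trial human data are published for this protocol, so the package
supplies the statistical structure needed to exercise it: a forgetting
curve with a guessing floor,

$$P(\text{correct} \mid d) = g + (1-g)\, e^{-d/(\tau m)},$$

with $g = 1/4$ (four choices), memory time constant $\tau$ (seconds), and
a per-modality multiplier $m$ on $\tau$ (larger = slower forgetting =
easier). This is the simplest monotone model consistent with
four-alternative forced choice: perfect recall at zero delay, chance
asymptotically. Response latencies are log-normal (strictly positive,
right-skewed, the standard response-time shape) with the log-mean shifted
by `latency_uncertainty * (1 - P(correct))`, so harder retrievals are both
less accurate and slower — the coupling that makes response time an
informative usability measure. An independent `non_response_prob` models
attention lapses as timeouts.

Default calibration, chosen once as a realistic configuration for a
mild-impairment usability cohort and not revisited:

* `tau_s = 600` — a typical member succeeds on roughly 85% of first
  attempts at protocol-scale delays (90–200 s), consistent with
  first-attempt scores around 8/10.
* `latency_log_mean = log(12)`, `latency_log_sd = 0.35` — mean response
  times near 13–15 s.
* `modality_difficulty = c(text = 1, graphic = 2)` and
  `latency_uncertainty = 1` — the two tasks are *clearly* separated, in
  the direction of the graphic task being easier; the reference study
  reports significant between-task differences on every measure, so a
  marginal modality effect would misrepresent its conditions.
* `generate_cohort()` spreads $\tau$ log-normally
  (`heterogeneity_sd = 0.5` on the log scale), giving a cohort whose
  recall times span roughly a factor of four — enough to produce the
  within-task correlation structure between performance and the
  time/workload measures.

Subjective instruments are simulated from session difficulty: every TLX
subscale rating rises with the number of failed trials and with total
session time (with subscale-specific weights — failures load mental
demand, performance, effort, and frustration; duration loads temporal
demand), and the post-task satisfaction score falls with failures, both
with additive Gaussian noise. This encodes the *assumed* direction of the
workload–performance relationship; study-level tests therefore check signs
and ordering, never magnitudes.

What the generator does **not** emulate: learning across sessions, fatigue
within a session, item-specific difficulty, age or demographic covariates,
and any interface-specific effects (fonts, audio, touch accuracy). Passing
tests show the protocol logic and analysis pipeline are correct under the
stated statistical assumptions — not that a particular human population
would produce these numbers.

## Measures

* *Average response time*: mean latency over answered trials. Timeouts are
  excluded — no answer choice was selected — but their full 60 s is
  charged to *elapsed time per question*, which sums all item-attributable
  time (reading, answering, timeouts, feedback) across an item's attempts
  and excludes only the scheduled recall delays. Feedback time is included
  there because it is screen time attributable to the item, not recall
  delay.
* *Correct answer score*: distinct items correct at first presentation,
  reported as a 0–10 count (with a percentage accessor), matching the two
  framings the measure is conventionally given.
* *Weighted NASA-TLX*: $\sum_i w_i r_i / 15$ with integer weights from the
  15 pairwise subscale comparisons; the raw (unweighted) mean is available
  as an option. Valid weights always place the score within the range of
  the ratings.

The five study measures are computed from the **training** session — the
exercise proper, feedback included — with the assessment contributing its
recall time. The protocol's one-sentence definition of elapsed time per
question does not fix whether feedback and timeout time belong inside it;
the choices above are stated conventions, not inferences.

## Study analysis

`run_synthetic_study()` mirrors the two-task usability design: each cohort
member completes assessment + training in both modalities; descriptives
(mean, min, max, sample SD with the $n-1$ denominator, standard for
$n = 10$ summaries) are tabulated per measure and task; a one-way
between-groups ANOVA compares tasks per measure; and Pearson correlations
(two-sided p from the t transform on $n-2$ df) relate the time and
workload measures to performance within each task. The between-groups
ANOVA on what is really a within-subject design reproduces the reference
analysis exactly as reported; a paired analysis is deliberately out of
scope. No multiple-testing correction is applied, matching the reference
analysis.

Numerically, the ANOVA is the classical equal-variance F (computed via
`stats::oneway.test(var.equal = TRUE)`, with the fully degenerate
all-values-identical case defined as $F = 0$), and correlations use
`stats::cor.test`; the test suite holds both to brute-force definitional
oracles (sums of squares; the $t = r\sqrt{(n-2)/(1-r^2)}$ closed form) and
to the two-group identity $F = t^2$.

## Reproducibility and numerical choices

* All session timing runs on an injectable simulated clock starting at 0;
  tests execute instantaneously.
* Every stochastic component draws from an explicit seed. Participant
  models carry private RNG streams (saved and restored around each draw),
  so simulation never perturbs the caller's `.Random.seed` and cohort
  members are independent of evaluation order.
* Session logs round-trip through JSON-lines bit-exactly; doubles are
  serialised with 17 significant digits for that reason.
* `replay_log()` re-derives delays and timestamps from the outcome
  sequence, propagating the *expected* recurrence so a single corrupted
  field produces a single violation rather than a cascade.
* Degenerate inputs are errors with structured classes (empty banks,
  all-timeout logs for response time, constant vectors for correlation,
  $n < 2$ for SD), never silent `NA`s.

## Problem sizes in the test suite

The suite exercises: staircase/expanding-delay equivalence against an
independent recurrence on 1,000 random outcome sequences (length ≤ 30);
statistics oracles on 1,000 random two-group datasets and 300 correlation
datasets; calibration validity on a 20-point $\tau$ grid
(30 s – 3,000 s, log-spaced) with 50 simulated assessments per point,
requiring Spearman $\rho > 0.9$ between $\tau$ and mean recall time; and
qualitative study replication over 20 seeded cohorts of 10, requiring at
least 70% of studies to reproduce the expected sign pattern (graphic
faster, higher-scoring, lower-workload; elapsed time and TLX negatively
correlated with performance within task). At the frozen defaults the
observed reproduction rate is 90%; the whole suite runs in about two
minutes on one CPU.

## Known limitations

* Built-in item banks are demonstration stimuli in the protocol's stated
  categories, not a published stimulus set.
* The forgetting model is memoryless across trials: re-presenting an item
  does not strengthen it within the simulation, which understates
  within-session learning.
* Simulated subjective outcomes inherit their correlation structure from
  the generator's assumptions; they validate the pipeline, not the
  psychology.
* The published summary tables of the reference study cannot be reproduced
  numerically without its raw per-participant data; the study layer
  reproduces the procedure and the direction of its findings only.
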