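---
title: "Methods: task engines, responder model, and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task engines, responder model, and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamebattery)
```

This vignette documents the modeling and numerical decisions behind the
package: how each mini-game is scored from raw events, how the synthetic
responder model is built and calibrated, and the conventions used in the
statistics chain. It is the place where every genuinely open design choice
is written down.

## Event logs and click accounting

All scoring consumes an `event_log()`: an ordered stream of `(t, kind,
target)` with `t` in seconds from task start. The click count of a task is
the number of physical click events (`click`, `select`, `start_hold`,
`stop_hold`); ending a task is not a click. Irrelevant clicks are first-class
data — they index impulsivity and hyperactivity and several of them are
among the strongest discriminating variables — so every engine counts all
clicks, not only task-relevant ones.

## Scoring rules and their edge cases

**Dressing (planning).** One point for completeness (every garment selected
at least once) and one for an executable, correct order. "Correct order" is
operationalized as a dependency partial order over garments (default: four
garments with two under-before-outer edges), and *any* dependency-respecting
order earns the point — there is no single canonical order, because a child
putting on the shirt before the underwear has made no planning error. The
order point requires completeness: an incomplete dressing has no
well-defined "correctly dressed" state. This reproduces the 0/1/2 scale and
the 4-click minimal solution.

**Sandwich (working memory).** A trial is correct only when the selection
sequence equals the presented sequence exactly, in order. The ingredient
schedule runs from 2 items up to 5; the packaged default is (2, 3, 3, 4, 5)
with one confirm click per trial, because the minimal-click solution must
total 22 clicks (17 selections + 5 confirms) and a strictly increasing
(2, 3, 4, 5) schedule cannot reach that total with any click-per-trial
convention. The schedule is fully configurable.

**Monkey (go/no-go).** The monkey's hide-and-seek schedule is not specified
beyond "appears suddenly", so the generator draws alternating hidden and
visible phase durations uniformly from configurable ranges. Scoring takes
the *realized* schedule as input (it travels with the log), keeping the
scorer deterministic. Visible intervals are closed: a swipe exactly at a
boundary counts as seen. A failed swipe is undone and does not remove a
peel, but it does not restore previously cleared peels — the undo blocks
the current action only, so completion always requires exactly 6 successful
swipes.

**Magic Land (reaction time).** Stars launch at a fixed 3-s inter-stimulus
interval (configurable; the task then lasts about 50 × 3 s, matching a
short attention-span format). Each star rises for `magicland_rise` seconds
(default 1.5 s) and is then catchable for the 2-s response window; reaction
time is measured from launch. The rise duration exists because the
published mean reaction times for collected stars exceed 2 s, which is
impossible if the clickable span were exactly the 2-s window — the
animation time before the window opens is part of the measured reaction
time. A click is credited to at most one star; an untargeted click credits
the earliest still-uncollected star whose span contains it (a deterministic
tie-break for overlapping spans). Mean RT over zero collected stars is
missing, never zero.

**Rocket (delay aversion).** The wait is the `end_task` time capped at 120
s; absence of `end_task` means the child waited out the full delay. The
binary reward choice is derived, not stored: large reward iff the full wait
was reached, so the invariant `choice = 1 ⇔ wait = 120` holds by
construction.

**Balloon (time production).** The correctness window [9, 11] s is closed
at both ends: "between 9 and 11 seconds" is read inclusively, the common
psychophysics convention, and the boundary behavior is covered by tests.
The timeout balloon granted by the story after 3 minutes is progression
only and is *not* counted as correct — counting it would award a point to a
child who never produced an interval. Timing precision is the mean absolute
deviation from the 10-s target over the first `min(3, attempts)` attempts,
exactly the printed formula.

## The responder model

The generative model realizes the triple-pathway structure as independent
latent traits per child; the goal is to reproduce the published summary
statistics, not to claim cognitive realism beyond them.

* **Executive pathway.** Planning is two Bernoulli stages (complete;
  correct order given complete). Working-memory span is linear in age,
  anchored at 3 items at age 3 and 5 items at age 7; a sandwich trial is
  reproduced when its length is within the realized span *and* every item
  is executed correctly (per-item accuracy), which is what keeps exact
  sequence reproduction rare even for adequate spans. Go/no-go failures are
  Bernoulli per swipe with a logit-linear age trend. Reaction times are
  lognormal (positive, right-skewed) with the age trend on the log mean.
* **Reward pathway.** The wait is a mixture: with the commitment
  probability the child waits the full 120 s; otherwise the quit time is a
  truncated exponential with the group's mean tolerable wait. The mixture
  mirrors the outcome's structure (a binary choice plus a continuous wait)
  and leaves the choice proportion and the mean wait separately tunable. No
  age trend: the published correlations of age with both reward outcomes
  are null.
* **Timing pathway.** Produced intervals are Gaussian around the 10-s
  target with an age-decreasing SD (floored at 0.8 s). One SD parameter
  simultaneously yields the published error magnitude and — through the
  stopping rule (3 correct or 180-s timeout) — the published number of
  correct balloons.
* **Impulsive clicks.** Irrelevant clicks are Poisson with per-task means
  and a shared lognormal child-level multiplier (overdispersion). The
  go/no-go task uses a much smaller multiplier spread because its published
  click dispersion is far tighter than the other tasks'.

**Calibration.** The packaged defaults in `default_calibration()` were set
by moment matching against the published group means and SDs, by hand, not
by formal fitting — only first and second moments are published, and
hand-set parameters keep every value inspectable. Group means are matched
for the comparison populations actually summarized in the publication:
controls aged 6–8 (the age-matched subset) and the ADHD group. The
developmental trends are calibrated on the full 4–8 control range. The
calibration suite simulates 500 children per group and requires every
simulated group mean within half a pooled SD of its published value, and
the five significant age correlations to have the published signs with
|r| > 0.1.

**What the simulator does not capture.** Within-child session-to-session
variability, comorbidity, medication effects, distraction dynamics, and any
dependence between pathways (the traits are drawn independently). Passing
calibration therefore shows that the pipeline recovers the published
statistical structure from raw event streams — not that the generator is a
faithful cognitive model of real children.

## Statistics conventions

* **Winsorization**: per group and variable, |z| > 3.29 is replaced by
  mean ± 3 SD — signed, so a low outlier moves to mean − 3 SD rather than
  above the mean. Moments are those of the input column; `recompute =
  FALSE` reuses the moments of a previous pass, making repeated application
  idempotent. Zero-variance columns are skipped with a warning, and all
  replacements are logged.
* **Correlations**: Pearson for scale variables, Spearman (average ranks)
  for the four ordinal ones (dressing total, sandwich total, reward choice,
  correct balloons); two-tailed p from the t approximation on n − 2 df for
  both. Below 4 complete pairs the result is flagged unreliable.
* **Discriminant analysis**: pooled within-group covariance, direction
  `Sw⁻¹(m₂ − m₁)` normalized to unit pooled within-group score variance;
  Wilks' Λ as `1/(1 + λ₁)`; Bartlett's χ² with df = p. Equal priors by
  default (proportional available): the published classification counts
  cannot disambiguate the priors used, and equal priors are the common
  package default. Classification is resubstitution, as published — no
  cross-validation is applied by default. Listwise deletion with the n used
  reported; a singular pooled covariance is an error naming the collinear
  columns.
* **Univariate tests**: categorical variables (dressing total, reward
  choice) get Pearson χ² without continuity correction — the uncorrected
  statistic reproduces the published reward-choice value, the Yates
  correction does not. Continuous variables get the GLM F unless the
  Brown–Forsythe check (ANOVA on |x − group median|) is significant at
  .05, in which case the Mann–Whitney U is used with the tie-corrected
  normal approximation, the min-U convention, and r = Z/√N. All p values
  are two-tailed; no multiple-testing correction is applied anywhere in the
  chain, matching the published analysis.
* **Age matching**: controls younger than 6 years are excluded from all
  group comparisons (not from the developmental correlations), because the
  clinical group spans 6–8 years.

## Numerical and reproducibility choices

One global seed drives everything: profile sampling uses it directly, and
child *i*'s behavior uses the substream seed `seed + 104729·i` (mod
2³¹ − 1), so enlarging a cohort leaves earlier children's logs bit-identical.
Scoring is free of randomness. Problem sizes in the test suite were chosen
to keep the full suite under a minute while leaving the stochastic checks
well-powered: 500 children per group for the calibration suite, 10⁴
permutations for the type-I calibration of the age correlation (expected
rejection 0.05, accepted band [0.04, 0.06]), and brute-force oracle
comparisons at n ≤ 12 where exhaustive enumeration is exact.

## Known limitations

* The published sensitivity/specificity pair (0.89/0.69) is not an exact
  function of the published confusion counts (35/40 = 0.875,
  41/57 ≈ 0.719); the package reports metrics computed from counts and
  does not force agreement with the published pair.
* The published Wilks' Λ and Bartlett χ² are mutually inconsistent at the
  stated sample size under the standard transform; the package implements
  the standard transform.
* Calibration matches first moments (and, where they bind, second moments)
  of the outcome distributions; joint distributions across tasks are a
  by-product of the independence assumptions, not calibrated targets.
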