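---
title: "Scoring and comparing discharge-satisfaction surveys: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and comparing discharge-satisfaction surveys: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dischargesat)
```

This vignette is the package's account of what it computes and why the
open design choices were made the way they were. The companion README
shows the user-facing workflow; here the emphasis is on the model, the
conventions, and their limits.

## The scoring model

The instrument asks 17 questions about a single hospital discharge,
answered once per patient within a few weeks of returning home. Fourteen
questions carry scores; three (Q1, Q6, Q8) only document the situation
and are tallied descriptively. The scored questions belong to three
items: discharge logistics organization (7 questions), preplanned
posthospital continuity-of-care organization (3), and the patient's
impressions at discharge (4).

Each item subscore is a *normalized sum*: the mean of the question
scores over the questions that apply to the patient, so every applicable
question in an item carries the same weight and the subscore lies in
[0, 1] by construction. Not-applicable responses — "Not concerned" on
the transport-wait, formality and document-wait questions, "I don't have
a primary care physician" on Q9 — remove the question from numerator and
denominator alike. This is the model's key assumption: inapplicability
is ignorable, i.e. the patient's satisfaction on the questions that do
apply is representative. The alternative (scoring "not concerned" as
neutral, say 0.5) would pull every affected subscore toward the middle
and invent information the patient never gave.

Two boundary conventions had to be fixed:

* **Undefined subscores.** If *every* question of an item is
  inapplicable the subscore is undefined (`NA`), and the total — the
  plain mean of the three subscores — is then undefined too, rather
  than a mean of the remaining two. A two-item mean would silently
  change the weighting between patients; with the packaged response
  distributions an all-inapplicable item is possible only for the
  continuity item and is vanishingly rare (the logistics and
  impressions items contain always-applicable yes/no questions, and in
  the continuity item only Q7 and Q9 can be inapplicable — both at once
  occurs for well under 1% of simulated patients).
* **Completeness.** A returned questionnaire is *complete* when no
  scored question is unanswered. Missing answers to the three
  documentation-only questions do not exclude a record, because they
  feed no score; they only shrink the denominators of the descriptive
  tallies. Incomplete questionnaires are excluded from all score
  analyses but stay in the flow accounting.

One vocabulary decision is worth flagging: the document-waiting-time
question (Q11C) carries a "Not concerned" response mapping to
not-applicable, alongside Q11D and Q11E. The descriptive denominators
(737, 720 and 719 of 755 for Q11C, Q11E and Q7) all follow from this
exclusion rule, and the package's proportion reports recompute every
percentage from its counts — half-up to one decimal, two decimals for
the overall response rate — rather than storing percentages that could
drift.

On the multi-select documents question (Q6), "None" is treated as
exclusive: a record listing "None" together with any document is
rejected at validation, since it is logically inconsistent rather than
merely unusual. Education is recorded on a 4-level ordinal scale plus an
explicit refusal category; refusals appear in descriptive tables but are
dropped from ordinal comparisons, which treat the four levels as ranks.

## The statistical battery

Three tests cover every comparison in the pipeline:

* **Fisher's exact test** for 2×2 tables (sex, responder status between
  arms): two-sided p as the sum of hypergeometric probabilities no
  larger than the observed table's, margins fixed.
* **Mann-Whitney-Wilcoxon** for two independent samples (scores, age,
  length of stay, ordinal education). The exact path enumerates all
  C(m+n, m) allocations of the pooled midranks whenever m+n ≤ 20 and
  takes the two-sided p as the probability of a rank sum at least as
  far from its null mean as observed — a definition that remains a
  valid permutation p-value under ties, where the rank-sum distribution
  need not be symmetric. Beyond the cutoff the normal approximation is
  used with tie-corrected variance
  `mn(N+1)/12 − mn·Σ(t³−t)/(12N(N−1))` and a 0.5 continuity
  correction.
* **Wilcoxon signed rank** for within-patient item contrasts. Zero
  differences are dropped (the reduced-sample convention); with n ≤ 24
  nonzero differences the null distribution of the positive-rank sum is
  computed exactly by convolution over the (doubled, hence integer)
  midranks, otherwise the tie-corrected normal approximation applies.
  An all-zero vector is flagged degenerate with p = 1.

The exact enumeration cutoffs (20 and 24) keep the worst exact case
under ~200k enumerated states; they are conventions, not tuning knobs —
any dataset near the boundary gets near-identical answers from both
paths in the tail. The approximation is *not* globally close to the
exact p at very small samples: with m = n = 8 the permutation null moves
in probability steps of roughly 0.1, so discrepancies above 0.1 occur
near p ≈ 1. What holds, and what the test suite asserts, is agreement
where decisions are made: |Δp| stays within a few hundredths for exact
p ≤ 0.2, and the two paths classify significance at α = .05
consistently in ≥ 95% of random tied datasets.

Percentile tables use linear interpolation of order statistics at
position h = (n−1)p + 1 (R's default type 7), the convention that
produces non-lattice values such as 0.43 from lattice-valued scores;
the mode is exposed as an argument for users who prefer another
convention. Reported values are rounded to two decimals, matching the
granularity of the published score tables; raw quantiles are kept in an
attribute. When the telephone arm is compared against both other arms,
the significance threshold is Bonferroni-adjusted to α/2 = 0.025; the
reports show raw p-values next to the adjusted threshold rather than
multiplying p-values, so the correction is transparent.

## What the synthetic cohort generator emulates

`sim_scenario()` packages the full generative model; `simulate_cohort()`
is a pure function of scenario + seed. The generator emulates:

* the arm structure — eligible patients randomized 1:1 to
  Internet/telephone, stratified by recruiting unit, plus a noneligible
  arm (no home Internet) at a configurable ratio of the eligible count
  (default 1:4);
* arm-specific nonresponse, optionally age-dependent through a logistic
  slope on standardized age whose intercept is solved numerically so
  the marginal response rate matches the configured one exactly;
* right-skewed age and length-of-stay distributions: log-normal matched
  to a (median, q25, q75) triple per arm, truncated to [18, 100] years
  and [2, 365] days — median/quartile matching because those are the
  summaries such studies print, log-normal because adult inpatient ages
  and stay lengths are right-skewed;
* per-arm completion-delay distributions (telephone interviews cluster
  at the scheduled day-7 call; online completion is more dispersed);
* per-question response distributions over the instrument vocabularies,
  including the not-applicable-eligible codes, sampled independently
  across questions given the arm.

Independence across questions is the minimal assumption — the study
gives no joint structure to copy. Because positively correlated answers
make rank tests on composite scores *less* powerful at fixed marginals,
an optional per-patient latent satisfaction propensity (`latent_sd`, a
shared logit shift on each question's favorable-vs-rest split) is
provided to probe robustness; it is off (0) in the packaged scenario, so
the default calibration results should be read as the
independent-questions case. Arm effects for power studies are injected
with `inject_effect()`, which shifts the favorable mass of every scored
question by a fixed amount on the probability scale and renormalizes,
erroring before any sampling if a probability would leave [0, 1].

`default_paper_scenario()` fixes the scenario to the study conditions:
arm sizes 430/437/274 (scaling proportionally when a different
`n_eligible` is requested), response rates 0.391/0.872/0.752, the
published per-arm sex, education, age and stay-length summaries, and
per-question distributions taken from the published counts (e.g. Q11C
676/61/18 over 755 responders). Three distributions are not published
and were fixed once as defaults: the Q11D transport-wait split
(0.45/0.20/0.35 with a substantial not-concerned mass — many patients
leave without waiting on arranged transport, and among those who do
wait, delays are a common complaint), the split of Q7's satisfied mass
into "Highly satisfied" vs "Satisfied" (264/260, consistent with the
published continuity-item median of 0.67), and the Q9 no-PCP rate (0,
matching the published /755 denominators, plausible in a health system
where nearly all adults have a registered primary care physician). The
responder-age slope (0.4 per SD of age) reproduces the qualitative
finding that responders are older; no effect size is published, so the
magnitude is a default, not a claim.

The generator does *not* emulate: within-unit clustering of satisfaction,
reminder-driven response dynamics beyond the delay distribution, item
nonresponse correlated with satisfaction (the `incomplete_rate` knockout
is missing-completely-at-random), or the 1-day-stay population, which
the instrument explicitly excludes (`length_of_stay ≥ 2`). Passing
calibration tests on this generator therefore shows the pipeline's
internal consistency — correct size of the tests under the null, correct
recovery of configured marginals, reproduction of the built-in item
ordering — not that real discharge surveys satisfy the independence or
distributional assumptions.

Separately from the stochastic generator, `paper_fixture_cohort()`
materializes a deterministic cohort whose *counts* equal the published
marginals exactly (down to the per-arm responder/nonresponder sex and
education splits). It exists so that flow accounting and proportion
reporting can be verified bit-exactly; its joint distributions are
synthetic (codes are interleaved with fixed strides to avoid aligning
favorable answers with arms) and carry no information. The unpublished
Q1/Q6/Q8 tallies and the Q7 satisfied-split in the fixture are likewise
synthetic placeholders consistent with the published aggregates.

## Numerical conventions and degenerate inputs

* Scores are carried in double precision; only *reported* values are
  rounded (two decimals for scores/percentiles, one for percentages,
  two for the overall response rate). Rounding is half-up, not
  banker's, to match how such tables are conventionally printed.
* Quantile convention: type 7, configurable.
* Degenerate inputs are flagged, not silently absorbed: all-zero
  difference vectors (p = 1, `degenerate = TRUE`), single-sex cohorts
  (sex test skipped as degenerate), arms with no included patients
  (omitted from the flow report with a warning), questions where every
  responder is not concerned (proportion `NA`, `undefined = TRUE`).
* Validation happens before sampling or scoring: probability vectors
  must sum to 1, response codes must belong to the vocabularies (errors
  name the row and column), Q6 "None" exclusivity is enforced, and a
  completion delay must be present exactly for responders.

## Problem sizes used by the packaged checks

The test suite and the acceptance script choose sizes at which the
checked quantities are statistically meaningful yet quick to compute:
exhaustive per-item score enumeration (432/48/16 combinations per item)
against an independent per-question oracle; enumeration-oracle sweeps
over all three tests at combined n ≤ 8 (1,000 random datasets); null
calibration with 1,000 replicates of 400 patients per randomized arm
(Monte Carlo SE ≈ 0.7 percentage points on a 5% rate); marginal
recovery at 100,000 eligible patients (binomial SE ≤ 0.2 percentage
points per marginal); and 200 replicates at the trial's own size for the
item-ordering reproduction rate.

## Known limitations

* The instrument is analyzed as given; no psychometric validation
  (reliability, dimensionality) is attempted, and none is implied by
  the scoring.
* Percentile-table agreement with the published score distributions is
  qualitative: those distributions derive from undeposited patient
  data, so the package checks attainability of the printed levels and
  distributional shape under simulation, not exact reproduction.
* The between-unit response-rate comparison is supported at the
  property level only; per-unit sizes are not published, so the
  packaged unit weights are illustrative.
* Exact tests enumerate; they are not meant for m+n in the hundreds
  (the approximation takes over well before that).
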