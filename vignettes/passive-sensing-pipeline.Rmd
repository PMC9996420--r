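---
title: "From smartphone event streams to within-person symptom models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From smartphone event streams to within-person symptom models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passivesense)
library(data.table)
```

## The problem

Passive behavioral sensing records how a person interacts with their
smartphone — screen on/off, foreground app changes, keystrokes, clicks,
scrolls — with millisecond timestamps and no active input from the person.
`passivesense` turns such event streams into five behavioral measures,
aligns them with biweekly-recalled depression items (the two 0–4 Likert
depression questions of a cross-cutting symptom inventory: loss of interest
and depressed mood), and estimates their within-person and between-person
associations with two-level linear mixed models.

Two design commitments shape everything downstream:

1. **Hour-of-day is a local-time concept.** Nighttime use is defined on the
   midnight–6 AM *local* clock, and all hourly features bin by local clock
   hour. The canonical event file therefore stores epoch milliseconds plus
   an IANA zone name, and ingest converts once to a continuous local-clock
   axis.
2. **Absence of events is not always absence of behavior.** Interaction
   sensing records only active use. Hours with no events are treated as
   *unobserved* for the intensity measures (app count, entropy, session
   duration, typing), but a silent night is a *true zero* for nighttime use:
   no events between midnight and 6 AM is exactly what "no nighttime use"
   looks like.

## From events to sessions and app segments

A *session* runs from a `screen_on` event to the next `screen_off` of the
same person. Real streams are imperfect, so `sessionize()` applies explicit
conventions, each tallied in a QC log: a duplicate `screen_on` while a
session is open is ignored (the original start is kept), a `screen_off`
without an open session is ignored, a session still open at end-of-stream is
dropped, and sessions longer than 24 h are dropped as sensor artifacts.
These rules are conservative — they never invent a session that the on/off
evidence does not support.

Within a session, consecutive `app_foreground` events tile the session into
per-app usage segments; time before the first foreground event is left
unattributed. How a proprietary collector delimits app usage across idle
gaps is unknowable from the outside, so this tiling is our documented
convention.

## The five measures

| measure | timescale | definition |
|---|---|---|
| app count | hourly | unique apps whose segments intersect the clock hour |
| app entropy | hourly | normalized Shannon entropy of app time shares |
| session duration | hourly | median duration of sessions *starting* in the hour (min) |
| typing interval | hourly | median keystroke-to-next-event gap, capped at 5 s |
| nighttime use | daily | screen time intersected with 00:00–06:00 (min) |

App entropy for within-hour shares $p_1,\dots,p_N$ is

$$ H = \frac{-\sum_{i=1}^{N} p_i \ln p_i}{\ln N} \in [0,1], $$

with $H = 0$ when $N = 1$ (the normalizer vanishes; a single app is zero
diversity) and missing when the hour has no app segments. The normalization
removes the mechanical dependence of raw entropy on the number of apps. The
log base cancels in the ratio.

```{r entropy}
app_entropy(c(0.5, 0.5))     # perfectly even split
app_entropy(c(0.75, 0.25))
app_entropy(1)               # one app: zero diversity
```

Numerical conventions worth knowing: clock-hour bins are half-open
`[h:00, h+1:00)`; a segment spanning a boundary counts in every hour it
touches; a session is attributed to its *start* hour for the duration
median; typing intervals use the next interaction event of *any* kind in
the same session (a keystroke that ends a session contributes nothing), and
intervals above 5 s are set to 5 s rather than dropped — extreme gaps
reflect distraction, not typing speed. Whether the hourly typing summary
should be a median or a mean is genuinely open; we use the median, matching
the rationale given for session durations (time variables are heavy-tailed).

## Windows, sufficiency, transforms

Each survey recalls the past two weeks, so it is paired with the half-open
window `[symptom_date - 14, symptom_date)` — the survey day itself is
excluded. Because sensing only produces data during active use, a sparse
window may be a sensing gap rather than true inactivity; a day *qualifies*
with ≥ 3 unique active hours and a window passes with ≥ 3 qualifying days
(both thresholds are arguments). Failing windows are dropped from modeling,
with reasons recorded.

Within a passing window, app count and entropy are averaged over observed
hours; session duration and typing interval are averaged the same way and
then transformed $x \mapsto \ln(1+x)$; nighttime use is averaged over all
14 days (true zeros included) before the same transform. Two open choices
are resolved here as documented conventions: the transform is $\ln(1+x)$
rather than $\ln x$ so the true zeros of nighttime use stay finite (its
transformed minimum is then exactly 0), and it is applied *after* window
averaging so each window value is transformed once. On lognormal-like time
measures this brings moment skewness $g_1 = m_3 / m_2^{3/2}$ from well
above 1 to below 1, which is the motivation for transforming at all.

## Within/between disaggregation

Psychological processes are rarely ergodic: the association between a
behavior and symptoms *across people* need not resemble the association
*within a person over time*. Each window-level predictor is therefore split
exactly as

$$ X_{it} = \bar{X}_{..} + bp_i + wp_{it}, $$

person means over each person's passing windows, grand mean unweighted over
persons. The decomposition is enforced to numerical identity: per-person
`wp` means are zero to 1e-12 and the three terms reconstruct every raw
value. Grand-mean centering of `bp` is a convention that affects only the
intercept (it then estimates a prototypical person's outcome) and is
switchable via `center_bp`.

## The two-level model

For each outcome separately (loss of interest; depressed mood):

$$ y_{it} = \beta_{0i} + \sum_{k=1}^{5}\beta_{ki}\,wp_{k,it} + e_{it},
   \qquad
   \beta_{0i} = \gamma_{00} + \sum_k \gamma_{0k}\,bp_{k,i} + u_{0i},
   \qquad
   \beta_{ki} = \gamma_{k0} + u_{ki}, $$

with $u_i \sim N(0, \mathrm{diag}(\sigma^2_{u0},\dots,\sigma^2_{u5}))$ and
$e_{it} \sim N(0,\sigma^2_e)$. The *independent* (diagonal) random-effect
structure estimates only variances: the scientific question is whether
within-person associations exist and vary across persons, not how the
random slopes covary, and the diagonal structure keeps the model estimable
at realistic cluster counts.

`fit_lmm()` maximizes the restricted likelihood with `nlminb` over
log-variances (REML by default, ML available), from three starts — 0.1×,
1×, 10× of method-of-moments values — keeping the best restricted
likelihood. The profiled deviance is computed in compiled code per person
block via Cholesky factors of $V_i = \sigma^2_e I + W_i D W_i'$. Variances
may land on the zero boundary; the optimizer's "singular convergence"
report with an active boundary is the expected shape of such an optimum and
is treated as convergence. Rows with any missing predictor or outcome are
listwise-deleted (the missing-at-random convention); an entirely missing
column or a single-person dataset is an error, not a warning.

Inference is deliberately simple and documented: Wald statistics with a
standard normal reference for fixed effects (no Satterthwaite or
Kenward-Roger degrees of freedom; at ~150 clusters the normal reference is
accurate), and seeded parametric-bootstrap percentile intervals for
variance components (`B = 500` default, refused below 50). Variance
estimates at the boundary pile bootstrap mass at 0, so near-zero components
get lower limits of exactly 0 — the expected behavior, not a defect.
Outcomes are treated as continuous despite the 0–4 item scale; the
`likert_discretize` option of the generator exists precisely to study what
that approximation costs.

## What the synthetic generators emulate

The package analyzes data that are proprietary wherever they exist in the
wild, so it ships two generators that are first-class, tested code.

**Window-level** (`generate_window_level()`): inverts the two-level model —
draws `bp`, `wp`, random effects and noise at configured values and returns
a ready-to-fit table plus the generating truth. Predictors default to a
standardized scale (unit between- and within-person SDs). This is a
deliberate choice for estimator testing: at the raw scales of real usage
data some coefficients (e.g. on entropy, which lives in [0,1]) are nearly
unestimable at desk-scale sample sizes, and recovery experiments would
measure Monte-Carlo noise rather than estimator bias. Default truth values
are the plug-in estimates quoted in `?sim_truth`. Recovery at the default
design (150 persons × 7 windows, 200 replicates in the acceptance suite)
gives absolute fixed-effect bias below 0.03 with 95% Wald coverage inside
[90%, 98%].

**Event-level** (`generate_event_streams()`): builds sessions per day
(Poisson counts, a separate rate for the night window), lognormal
durations, Dirichlet app-time shares over a random subset of the catalog,
keystroke bursts with lognormal inter-key gaps, and stable person-level
usage traits (lognormal-scale shifts of app variety, typing speed, session
length and night use) that create realistic between-person spread. Default
rates were chosen to land in the regime of published usage summaries —
several unique apps per active hour, session medians of a few minutes,
typing intervals around half a second, a few minutes of nighttime use per
day. Alongside the stream it returns the exact feature values implied by
construction, computed by an independent plain-loop accumulation *inside*
the generator, so round-trip tests compare two independent code paths; on
100 person-days the pipeline reproduces counts exactly and time quantities
to 1e-9 minutes.

**Linked scenario** (`generate_linked_scenario()`): a latent symptom state
per (person, window) drives both the survey items and behavior rates, so
the full pipeline — events → features → windows → disaggregation → fit —
can be checked for *sign recovery* of programmed effects (e.g. a negative
app-count linkage is recovered as a negative fitted within-person
coefficient in ≥ 90% of replicates).

What the generators do **not** emulate: app taxonomies and app-specific
semantics, circadian structure beyond the day/night rate split,
autocorrelated symptom trajectories, device swaps or DST transitions. A
passing suite shows the pipeline computes its definitions correctly and the
estimator recovers known truth — not that these measures are valid in any
clinical population.

## A worked example

```{r example}
cfg <- event_sim_config(n_persons = 12, lambda_day = 10,
                        link = c(app_count = -0.35, typing = 0.15,
                                 session_duration = 0, nighttime = 0),
                        seed = 42)
bundle <- generate_linked_scenario(cfg, windows_per_person = 4)
analysis <- analyze_study(bundle$events, bundle$surveys,
                          outcomes = "loss_of_interest")
analysis$fits$loss_of_interest
```

The programmed negative app-count linkage surfaces as a negative
`wp_app_count` coefficient; at this deliberately small size its standard
error is large. `report_tables()` formats two fitted models side by side in
the journal layout, and `bootstrap_varcomp_ci()` adds variance-component
intervals.

## Problem sizes and reproducibility

Simulation-based checks in the test suite use the sizes stated above
(chosen as the smallest designs at which the checked property is sharply
identified); every stochastic step takes an explicit seed, and
`scripts/acceptance.R --seed S --out f.json` recomputes the package's
headline quantities from scratch at any seed.

## Known limitations

- Inference for fixed effects is normal-reference Wald; small numbers of
  persons (a few dozen) will make p-values anticonservative.
- The sessionization conventions (duplicate-on policy, 24 h cap) are
  reasonable but untestable against the original proprietary collector.
- Timezone handling assumes each person's zone is constant per event row;
  travel across zones mid-stream is represented only if the rows say so.
- The QC rule counts *observed* hours; it cannot distinguish a sensing
  outage from true disuse, only bound its impact.
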