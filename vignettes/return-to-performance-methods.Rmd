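---
title: "Methods: surveillance-style return-to-performance analysis after severe lower-extremity injury"
author: "courtback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveillance-style return-to-performance analysis after severe lower-extremity injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(courtback)
```

## The problem

Professional basketball has no public, event-level injury registry. What is
public are two indirect traces: a dated *transaction log* of roster
deactivations and activations with free-text notes ("sprained left ankle"),
and per-player per-game *box scores*. Harmonised at the individual-game
level, these two sources identify **time-loss injuries** — tissue damage that
costs a player at least one competitive game — along with how many games were
missed, when the player returned, and how they performed afterwards.

`courtback` implements that harmonisation as a tested pipeline and the
statistical analyses that sit on top of it: prevalence of return to
preinjury performance with binomial confidence intervals, prognostic
post-on-pre regressions, a one-way ANOVA of return-to-sport time by body
region, and restricted-cubic-spline sensitivity fits. Because the real raw
data are scraped from the web and cannot ship with a package, a synthetic
league generator with known ground truth stands in for them; every pipeline
stage is validated against that ground truth.

## Constructing time-loss injury events

`link_injury_events()` scans, for each player, the team schedule for maximal
runs of consecutively missed team games. A run becomes an injury event when
a deactivation transaction is dated inside the gap. Conventions, each chosen
to make the toy examples in the test suite unambiguous:

* **Onset** is the date of the first *missed* team game. The true
  injury moment (often in practice) is unobservable at game resolution, and
  external cross-checks of data of this kind show exactly this discrepancy:
  game-level logs recount the first game missed, not the calendar injury
  date. The package adopts the first-missed-game convention throughout.
* **Recovery** is the first game *played* after the gap — being reactivated
  on a roster is not returning to sport. Players who never play again keep
  the event with `return_date = NA`, `games_missed` equal to the remaining
  team games, and a missing-recovery flag on the validation report.
* `games_missed` counts team games strictly between the last played game and
  the return game; intervals are closed on onset and open on return.
* A deactivation with no missed game (reactivated before the next game) is
  not a time-loss injury and produces no event.
* Runs before a player's first appearance are not injuries (the player was
  not yet on a roster).
* Dates are ISO 8601 everywhere; impossible dates are excluded and reported
  on an error channel, never silently dropped.

`agreement()` compares two independently constructed event sets (pairing
within player by nearest onset, default tolerance ±30 days — the matching
rule is a package choice) and reports percent agreement on exact date, games
missed, and injury site.

## Severity and body region

Severity is a deterministic function of games missed: Slight (1 game),
Minor (2–3), Moderate (4–13), Severe (14+). The bands partition the positive
integers; `classify_severity()` is property-tested over 1..1000.

Body region comes from keyword matching on the free-text note
(`map_body_region()`): case-insensitive, whole-word, earliest-match-wins.
The shipped lexicon maps knee structures (ACL, MCL, meniscus, patella) to
*knee*; groin, hip, thigh, hamstring, quadriceps and adductor terms to
*groin/hip/thigh*; and ankle terms to *ankle*. Two decisions deserve
emphasis:

* **Achilles maps to ankle.** Achilles-tendon injuries are anatomically
  between the analysed regions; *ankle* is the nearest one. The lexicon is a
  plain CSV (`read_region_lexicon()`), so this assignment is one edit away
  from being different.
* Classification is region-level only. Free-text notes rarely support
  diagnosis-level coding, and misassignment to a neighbouring structure is a
  known precision limit of this data class.

Only events whose onset falls inside a regular-season window survive
`filter_regular_season()`. Windows default to the min/max game date per
season in the schedule (data-driven, which keeps synthetic runs
self-contained); an explicit calendar can be supplied instead.

## The cohort

`build_cohort()` forms a self-controlled pre/post cohort around each
player's *primary* (first) severe lower-extremity injury:

* **Index season** = season of onset. Missed games spilling into the next
  season do not shift the index.
* **Pre-injury season** = the season immediately preceding the index; the
  player must have played it, and must not have sustained worse than a Minor
  injury (≥ 4 games missed disqualifies; Slight and Minor are tolerated)
  during it.
* **Year 1** = the season of the first post-return appearance when that
  differs from the index season, otherwise the next season played.
  **Year 2** = the next season played after Year 1.
* Eligibility further requires at least three distinct seasons with ≥ 1 game
  in the study window, age ≥ 18 at injury, and no reinjury with onset within
  14 calendar days of return (day 14 inclusive — "within 14 days" is read
  inclusively and documented here because the boundary is otherwise
  ambiguous).

Players failing only the played-a-following-season condition stay in the
severely-injured denominator; this is what makes the three nested strata
counts (severely injured ≥ played year 1 ≥ played year 2) the correct
denominators for the prevalence tables. Second-year attrition in this data
class is missing *not* at random — players disappear because they were
released — so all second-year summaries are complete-case by design;
nothing is imputed.

## Return to performance and prevalence

No standard operational definition of "returned to preinjury performance"
exists. The package default is **meet-or-exceed**: the post-injury season
value of a metric must be at least the pre-injury season value. This is the
only parameter-free reading, but it is strict — a player returning to
99% of a 2,000-minute season counts as not returned — so
`reached_preinjury()` and `prevalence_table()` accept a tolerance τ
(post ≥ (1−τ)·pre) for sensitivity analyses. This definition is the single
most consequential analytic choice in the pipeline; treat prevalence
numerators as conditional on it.

Prevalence per 100 athletes uses the Wald normal-approximation interval
p ± z·√(p(1−p)/n) with z = 1.959964, clipped to [0, 1]. The Wald form was
chosen because, after integer rounding, it is the interval that reproduces
the published worked examples the acceptance checks recompute
(58/196 → 30% (23, 36); 48/130 → 37% (29, 45)); the Wilson interval does
not (its lower bound for 58/196 rounds to 24). Reporting rounds half away
from zero to whole percent. Descriptive tables report mean (SD) with the
sample (n−1) SD convention; a single-player stratum therefore has an
undefined (NA) SD rather than a population zero.

## Prognostic models

The wording "each post-injury season included individually in the
regression, with the season prior as the comparison" is implemented as one
OLS model per metric per year: `post ~ pre`, on the raw scale. The slope is
then interpretable as the expected post-season value per unit of pre-season
value, which is consistent with coefficients in the 0.4–0.8 range on
same-unit metrics. All fits delegate to `stats::lm`; intervals and p-values
are t-based with n − p degrees of freedom; the test suite checks the slope
against the closed-form cov/var expression and the ANOVA against the F = t²
identity.

* `fit_per_minute()` ("controlled for minutes played") enters post-season
  minutes as a covariate and still reports the pre coefficient. A
  ratio-outcome variant (per-minute rates on both sides) is available behind
  a flag because "per minute played" admits both readings; the covariate
  form is the default.
* `fit_adjusted()` adds age at injury, seasons played at injury, calendar
  year of injury, body region (reference: knee), position (reference:
  guard), and the age × seasons interaction, on complete cases. Factors
  observed at a single level are dropped and recorded, not silently
  absorbed.
* The knee-only sensitivity analysis is the same battery on the knee
  stratum.
* No multiplicity correction is applied anywhere; the model battery runs
  many tests and the type-I risk that implies is the user's to weigh.

`rcs_design()` implements the truncated-power restricted cubic spline
(Harrell parameterisation): k knots give k − 1 columns including the linear
term, the function is piecewise cubic with continuous second derivatives,
and exactly linear beyond the boundary knots. Knots default to conventional
quantiles (10/50/90 for three knots — a convention, not a claim). The basis
spans the same function space as a natural cubic spline, which is exploited
in the tests: fitted values must agree with a `splines::ns` fit to 1e−8,
and a fit on straight-line data must reproduce the least-squares line.

## The synthetic league

`generate_league()` is first-class, tested code, not a fixture. Its defaults
are the study conditions the rest of the package is exercised under:

| parameter | default | anchor |
|---|---|---|
| teams × games × seasons | 30 × 82 × 3 | league structure |
| roster size | 15 | typical roster |
| baseline minutes/game | truncated normal, mean 25.8, SD 8.1, floor 0 | observed pre-injury mean (SD) |
| points, rebounds, FGA per minute | gamma across players; means 0.434, 0.140, 0.368 | 11.2 points and 3.6 rebounds per 25.8 minutes |
| rate CVs | 0.41, 0.59, 0.35 | reproduce between-player per-game SDs of 5.8 points and 2.4 rebounds |
| per-game minutes | 48 × Beta, player mean, concentration 80 | bounded support; within-player SD ≈ 2.7 min |
| injury hazard | 0.002 per played game | fixture (no generative model exists to copy) |
| severity mix | 0.35 / 0.30 / 0.22 / 0.13 | fixture; frequency decreasing with severity |
| severe region mix | 0.20 / 0.57 / 0.23 | relative frequencies 39 : 111 : 46 among severe lower-extremity injuries |
| decrement year 1 / later | 0.72 / 0.83 | observed season-minutes ratios one and two years post injury |
| dropout per subsequent season | 0.33 | observed one-in-three second-season attrition |

Model mechanics: every rostered player plays every team game unless injured
or dropped out. Injuries occur only on played games; the player then misses
a severity-dependent run of consecutive team games (Severe: 14 + a negative
binomial tail, mean ≈ 28). The deactivation transaction is dated at the
first missed game and the activation at the return game, so the injected
event is exactly what the linker should reconstruct. After a severe injury
a player's expected minutes per game are multiplied by the year-1 decrement
for the remainder of the index season and the following season, and by the
year-2 decrement afterwards; counting statistics follow minutes through
their per-minute rates. Dropout is drawn once per subsequent season and is
absorbing: the player simply has no further box-score lines, which is how
"missing not at random" attrition presents in the real sources. Ground
truth records every injected event with its *realised* games missed (an
event interrupted by dropout or the end of the data keeps its observable
span and a missing return), so end-to-end recovery is well defined without
special cases.

Design notes, made once and kept:

* **Per-player rate heterogeneity** (gamma-distributed per-minute rates) is
  a deliberate departure from a fixed-rate Poisson model: with fixed rates
  the between-player SD of points per game could not exceed ≈ 3.5, far
  below the observed 5.8. The CVs above are solved from the observed SD
  column given the spread of baseline minutes.
* **Within-player game-to-game variation is kept moderate** (concentration
  80, SD ≈ 2.7 minutes). The anchored quantities are between-player means
  and SDs, which say nothing about game-to-game noise; a moderate value
  keeps season totals dominated by stable player-level differences, i.e.
  strongly correlated year to year, which is also what makes planted
  decrements identifiable in parameter-recovery studies.
* **Even team counts only.** The scheduler plays every team once per round
  date; a bye round would break the exact games-per-team invariant.
* **The scheduler materialises only the team-date grid.** Opponents and
  travel are irrelevant to every downstream statistic; only ordering and
  counts matter.

### Two simulators, on purpose

In the mechanistic league model, the post-on-pre regression slope is *not*
exactly the planted decrement: pre-season totals measure the latent baseline
with error, so the slope is attenuated by the usual errors-in-variables
factor (here by well under 1%, given the moderate within-player noise).
Estimator-calibration studies need the planted value to *be* the estimand,
so `simulate_post_pre()` draws the post season conditionally on the realised
pre season with expectation `decrement × pre`. For counting metrics it adds
homoscedastic conditional noise (variance fixed at the Poisson variance of
the average player) rather than per-observation Poisson noise: a
mean-proportional variance would make the ordinary least-squares interval
intrinsically miscalibrated (true coverage ≈ 80–85% in this configuration),
which would test the noise family, not the estimator. The league generator
keeps per-game Poisson counts; the calibration simulator trades that realism
for a correctly specified model. With this design the planted 0.5 decrement
on season minutes is recovered with ≈ 95% interval coverage and bias below
0.001 across 500 replicates of 200 players — numbers the acceptance script
recomputes on every run.

### What the generator does not emulate

Real calendars (back-to-backs, the All-Star break), trades and multi-team
seasons (the linker flags them but the generator never creates them), rest
and load management (every absence without a deactivation is dropout, never
rest), within-season form drift, playoff and preseason play, practice
injuries, and — importantly — *heterogeneous* post-injury trajectories: the
decrement is a shared constant, so in synthetic runs almost no player whose
metric is decremented meets the meet-or-exceed bar, and synthetic
return-to-performance prevalences are not calibrated to any published rate.
Passing tests therefore demonstrate that the pipeline recovers what was
injected and that the estimators are calibrated — not that the generator
reproduces the sampling distribution of real league data.

## Problem sizes and numerics

The test suite exercises: the full-scale league (30 × 82 × 3, ≈ 110,000
box-score lines) once for end-to-end recovery; 200 randomly seeded toy
leagues (≤ 4 teams × 20 games) for linkage-oracle equivalence against an
independent brute-force scan; 500 replicates of 200 players for parameter
recovery; and 1,000 null replicates for ANOVA type-I calibration. These
sizes were chosen so Monte-Carlo error is small relative to the stated
tolerances. Degenerate inputs are errors, not guesses: zero-variance
predictors, duplicate knots, groups of one, empty event sets for agreement,
denominators of zero. Determinism is part of the contract — identical
configuration and seed give byte-identical pipeline output, which the test
suite checks at the file level.

## Known limitations

Beyond the generator's non-goals above: the meet-or-exceed definition makes
prevalences sensitive to single-game differences; region assignment
inherits the vagueness of free-text notes; days-to-return in the synthetic
league are compressed relative to a real calendar (seasons are consecutive
days), so only their ordering and group contrasts are meaningful; and the
published two-year cohort is reported inconsistently in its source (130 in
one place, 135 in another) — the package takes no side and simply exposes
its own counts.
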