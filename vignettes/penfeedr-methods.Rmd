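---
title: "Methods: from feeder visits to meal-based phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from feeder visits to meal-based phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`penfeedr` implements a complete phenotyping pipeline for group-housed
growing-finishing pigs on single-feeder pens: raw feeder-visit logs in,
per-animal feeding-behaviour, social-ranking and feed-efficiency traits out,
with robust outlier filtering and trait correlations. This vignette explains
the statistical procedures, the tunable parameters, the numerical choices at
the edges, and what the bundled synthetic generator does and does not
emulate.

## Data cleaning

A visit record is (pen, animal, start time, duration, intake, scale weight).
`clean_visits()` applies three exclusion rules in a fixed order with
first-match attribution, so the counts in the cleaning report are
unambiguous: (a) all visits of pens containing dead or culled animals —
mortality changes group size and therefore competition, confounding every
pen-level trait; (b) each pen's first and last calendar day, which are
incomplete because recording starts and stops mid-day; (c) rows with missing
fields or an animal id that does not resolve to the roster. Day indices are
then assigned per pen from the first retained date.

Two decisions deserve a note. First, *idempotence*: boundary-day trimming is
keyed on the absence of the `day_index` column that cleaning itself adds.
Re-cleaning a cleaned table must be a no-op — a literal re-application of
rule (b) would shave two further days on every pass. Second, *overlaps*:
two simultaneous visits in one pen are physically impossible on a single
feeder, so an overlapping later visit is truncated to start when the earlier
one ends. Truncation rather than deletion preserves intake totals; the
repair count is reported.

## The meal criterion (Pstart hazard)

Feeder visits under-segment behaviour: pigs pause, get displaced, and
return. The meal criterion is the gap length that separates within-meal
pauses from genuine between-meal intervals. For each animal we collect all
gaps from the *end* of one visit to the *start* of the next (occupation-free
time; start-to-start gaps would inflate the criterion by the visit duration)
and estimate the discrete hazard of returning to the feeder,

$$\mathrm{Pstart}(t) = \frac{\#\{\text{gaps in } [t, t+1)\}}{\#\{\text{gaps} \ge t\}},
\qquad t = 0, 1, \dots, 59 \text{ min},$$

with gaps beyond the 60-min search window censored into the at-risk counts
only. Two-timescale gap mixtures give this hazard a characteristic U shape:
high at the origin (within-meal returns), falling as the within-meal
component exhausts, then rising again as between-meal returns take over. A
centred 5-bin rolling mean smooths binomial noise (edge windows truncate;
undefined bins are skipped). The criterion is located by scanning successive
differences of the smoothed curve from the origin: the first boundary where
the difference turns from negative — possibly through a run of exact zeros —
to strictly positive marks the local minimum, and the criterion is the first
bin of the plateau holding that minimum. If the curve never turns up (the
hazard of a single exponential gap law is flat; no meal structure), the
argmin is returned but flagged, and degenerate curves with fewer than three
defined bins fall back to the criterion pooled over all same-breed gaps, as
do animals with fewer than `min_gaps = 50` gaps — individual curves below
that are estimated from pure noise.

Merging then applies strict inequality: consecutive visits whose gap is
*below* the criterion join one meal; a gap equal to the criterion starts a
new meal. Granularity is whole minutes because the hazard is estimated in
1-min bins; the criterion value is the left edge of the minimum bin.

Key parameters: `t_max = 60` min (real criteria reach ~25 min; a 60-min
window leaves ample room while keeping the at-risk counts interpretable),
`window = 5` min (the conventional smoothing span for this estimator),
`min_gaps = 50`.

## Meal, daily and hourly traits

Per meal: visit count NVM, occupation time OTM (s, sum of visit durations),
meal span TM (s, first start to last end), intake FIM (g), feeding rate
FR = FIM/OTM (g/s), meal-level rate FRM = FIM/TM, and IBM (s), the
start-to-start interval to the animal's previous meal (undefined for its
first). By construction OTM ≤ TM with equality exactly for single-visit
meals, and FRM ≤ FR. Zero-duration meals have no defined rate; they are
flagged invalid, counted, and excluded from trait tables. Meals may span
midnight and belong to the day of their first visit, which keeps daily
counts integral.

Daily values sum the additive traits per animal-day; ratio traits are
recomputed from summed numerators and denominators rather than averaged
across meals, because per-meal ratios are unstable for small meals. (The
per-meal FR/FRM values are still what enters the per-animal averages of the
correlation analysis, whose unit is the individual mean of meal-level
traits.) Hourly values sum per clock hour and divide by the animal's number
of observed days ND, so each is a per-day average for that hour; hours
without meals are zero-filled. ND is the number of distinct retained days on
which the animal has meals, which makes the identity
$\sum_h \mathrm{TNM}_h = \overline{\mathrm{TNM}}_{\text{daily}}$ exact.

## Social-ranking indicators

*Position.* Pen visits are segmented into feeding events: maximal runs in
which consecutive start-to-start gaps do not exceed a threshold, by default
the pen members' median meal criterion. Within an event of $n$ visits the
$k$-th visit has standardised order $k/n$; an animal's Position is the mean
of its per-event mean standardised orders. Under uniformly random queue
order the expectation is $(n+1)/2n$; systematically low Position means
priority of access. The event unit is defined at pen level because feeder
entry order is only meaningful relative to pen mates; a per-meal variant
would standardise an animal's order within its own meal and carries no
between-animal signal.

*Preferred-time ratios.* Share of an animal's visits starting inside
half-open clock windows: `window_a` = [08:00, 20:00) (daytime) and
`window_b`, the narrow preferred windows. Two presets are shipped for the
narrow window — `"methods"` = 08–10 ∪ 15–17 h (default) and `"table1"` =
07–11 ∪ 14–18 h — because both definitions circulate; results should state
which was used.

*Daily shares.* For each pen-day, an animal's share of the pen total of
visits, meals, intake and occupation time; the trait is the mean share over
the animal's observed days. Denominators include the focal animal, so
shares sum to one over pen members each day — the tested invariant. Pen-days
with a zero total for a trait are skipped for that trait.

## Growth, carcass and feed efficiency

ADGreg is the OLS slope of scale weight (g) on age (days) over all visits —
the feeder scale yields hundreds of noisy weighings, and the regression
slope is the standard estimator. Start and end weights BWs and SW are the
fitted values at the first and last observed age (raw readings are
selectable via `raw_endpoints`, but single scale readings carry ±0.5 kg
noise). Metabolic weight is $((BWs+SW)/2)^{0.75}$ in kg^0.75 — the
metabolic scaling of maintenance requirements; mid-period weight is used
because maintenance accrues over the whole test. Carcass composition uses
the printed prediction equation
$\mathrm{Lean\%} = 25.08 + 0.73\,\mathrm{Ham\%} + 0.87\,\mathrm{Loin\%} - 1.23\,\mathrm{Fat\%}$
with Ham/Fat/Loin percentages of the half carcass.

FCR is ADFI/ADGreg (the table variant TFI/BWG is also emitted; the two
coincide when both numerator and denominator are accumulated over the same
days). RFI is the residual of the within-breed OLS regression of ADFI on
ADGreg, metabolic weight and Lean% — intake unexplained by growth,
maintenance and composition; lower is more efficient. RG mirrors it
(ADGreg on ADFI, MW, Lean%), and RIG = RG − RFI. Daily intake (g/day) is
used as the response so units match ADGreg, and fits run separately per
breed, mirroring the per-breed processing of the rest of the pipeline.
Residuals of an intercept model are zero-mean within each fitting cohort by
construction — a property the tests assert exactly. Animals with missing
carcass data are excluded from the fit and reported with missing residuals.

## Robust outlier removal

Anomalous meal records (scale glitches, double transponder reads) distort
trait averages. Filtering works on the meal-level triple (TM, FIM, IBM),
whose components are strongly correlated, so a Mahalanobis criterion is
appropriate — and a robust one, because outliers corrupt classical moments.
`mcd_fit()` computes Minimum Covariance Determinant location and scatter:
the h-subset (h = ⌈0.75 n⌉) minimising the covariance determinant, found by
exhaustive enumeration when $\binom{n}{h}$ is small and otherwise by C-step
iterations from many random elemental starts (each C-step re-selects the h
points nearest in Mahalanobis distance and can only decrease the
determinant, so iteration converges; the search is reproducible given a
seed). The usual Gaussian consistency factor rescales the scatter by
default; it is toggleable and immaterial next to the generous cutoff. A
record is flagged when its *squared* robust distance
$(x-\mu)^\top S^{-1} (x-\mu)$ exceeds $5 \times \chi^2_{3,0.999} = 81.33$ —
the factor-5 cutoff is read at face value on the squared scale; it is
deliberately permissive, removing only gross anomalies. First meals have
undefined IBM; they never enter the fit and are never flagged. Filtering
runs per breed.

## Correlations

Per-animal averages of the post-filter meal traits are joined with daily
meal counts, ranking traits and performance traits, and pairwise-complete
Pearson correlations are computed per breed, with two-sided p-values from
the t transform on n − 2 degrees of freedom. Pairwise deletion (with the
per-cell n reported) is used because trait availability differs — e.g.
missing carcass data removes RFI but not behaviour. No multiple-testing
correction is applied by default, matching the plain p < 0.05 convention of
this literature; a Benjamini–Hochberg option exists.

## The synthetic pen generator

No public dataset of this kind exists, so `simulate_pens()` generates one
with the statistical structure the pipeline assumes; its defaults are the
study conditions under which the package's claims are tested.

*Structure.* Pens of 14 animals over 100 days (both configurable), breeds
assigned round-robin to pens. Each animal gets latent values: growth rate
ADG ~ N(950, 90) g/day from ~23 kg; an intake multiplier coupled to ADG
(elasticity 0.8) with residual coefficient of variation 7.5 %, which gives
the residual-feed-intake analysis realistic structure (~150 g/day of intake
unexplained by gain); a feeding-rate multiplier; and a dominance score that
shifts meal frequency (+10 %/SD), concentrates visits in the preferred
windows, slows ingestion rate (−8 %/SD; dominant pigs are "nibbler–slow
eaters") and wins contested access to the feeder queue.

*Trajectories.* Daily meal count rises from 7.0 to a peak of 8.8 around day
14 and eases to 6.3 by day 85; daily intake climbs from ~1000 to ~3000 g/day
over 100 days while ingestion rate climbs 0.35 → 0.8 g/s, plateauing near
day 88. Per-meal intake is the daily target divided by the day's meal count
with lognormal meal-to-meal noise; occupation time is intake/rate. These
values reproduce the published age patterns for this production system at
stocking densities that keep expected feeder occupation under the 95 %
feasibility bound the simulator enforces.

*Gap laws and the hazard trough.* Within-meal gaps are a two-component
mixture: an exponential bulk (mean 45 s — brief head-lifts) and a lognormal
"interruption" component (median 3 min, sdlog 0.5, probability 0.45,
truncated at 20 min) representing the longer contention pauses single-feeder
pens produce. The interruption component is essential, not cosmetic: with a
pure 45-s exponential the within-meal hazard is numerically zero beyond
~5 min, the combined hazard has an unidentifiable near-zero plateau instead
of a trough, and the sign-change scan would collapse to the plateau start —
whereas real pigs show individual criteria spread up to ~25 min with the
cohort median near 9–10 min, which requires exactly such minutes-scale
within-meal pauses. Between-meal gaps are a 5-min-shifted lognormal
(sdlog 1.0, capped at 20 h) whose scale is solved each day from the
meal-count trajectory via the closed-form capped-lognormal mean, so realised
meal counts track the target. The two sdlog values were calibrated once,
at design time, against the package's own numeric oracle so that the
theoretical combined hazard has its minimum in the 9–10 min bin across 40-,
60- and 100-day horizons, with enough curvature for the estimator to see;
they are frozen defaults, not fitting knobs.

*Circadian placement.* Meal starts follow an inhomogeneous renewal process:
the between-meal draw is made on an operational time scale and mapped
through the animal's cumulative circadian intensity (time-rescaling). The
intensity is a uniform floor (weight 0.4) plus two wrapped-normal modes
(sd 2.5 h) at 9.4 h and 17.4 h. Time-rescaling matters: modulating the gap
scale by the intensity at the gap's *start* lags the realised peaks by
roughly one mean gap (~2 h); rescaling places meals where the intensity is
high while locally preserving the gap law the oracle integrates. The modes
sit inside hour bins 9 and 17 — the bins where the published hourly profiles
peak — and slightly left of the bin centres because the occupancy queue
defers some peak-hour meals rightward; a mode at the exact bin centre leaves
the neighbouring bin competitive.

*Occupancy.* One feeder per pen. A meal due while the feeder is busy waits
until it is free; among waiting animals the most dominant is served first
(set `dom_queue = FALSE` for first-come-first-served), and an animal that
would wait more than 30 min gives up, with the skipped meal counted in the
truth object. Occupancy is resolved at meal granularity — the pig effectively
guards the trough across its short within-meal pauses — which keeps the gap
laws analytically specifiable; queue waits then perturb only the hour-scale
between-meal gaps, and the estimator-facing consequences of visit-level
contention are carried by the within-meal interruption component instead.
Visits never overlap within a pen after resolution, and all timestamps are
integer seconds.

*Oracle.* `theoretical_hazard()` numerically evaluates the per-minute
discrete hazard of the implied gap mixture — within-meal components weighted
by E[NVM] − 1 against one between-meal gap per meal, the between-meal scale
mixed over clock hours (intensity-weighted) and days (meal-count-weighted) —
and reports the trough located by the same sign-change scan the criterion
estimator uses. This is the ground truth against which criterion recovery is
tested; it is asserted on the pre-queue laws and verified empirically on the
post-queue logs.

*Reproducibility.* One root seed; per-pen substreams are derived
deterministically, so any pen is reproducible in isolation and whole runs
are byte-identical given (config, seed).

*What the generator does not emulate.* Hour-dependent meal size (real pens
show shorter meals at rush hours and the largest intakes around midday and
early evening — here meal size depends on age and animal, not clock time);
batch, room and season effects; transponder-read errors (cleaning rules are
instead exercised on hand-built fixtures); illness and culling dynamics; and
any attempt to match the real cohort's trait means — only the printed
qualitative patterns (trajectory shapes, peak hours, trough location,
correlation signs) are targeted. Passing tests therefore demonstrate that
the estimators recover known structure of this kind, not that any particular
farm's numbers will be reproduced.

## Problem sizes and numerical choices

The test suite exercises study-scale checks on a simulated cohort of 15 pens
× 14 animals over 60 days (210 animals, ~120k visits), the size at which
medians and argmax-hours stabilise, and module-level checks on a 3-pen,
30-day cohort; both are generated once per test run. Timestamps are parsed
and emitted in UTC throughout. Ties in the criterion scan resolve to the
first bin of the minimum plateau; criteria are clamped to ≥ 1 min (a 0-min
criterion would merge nothing and is only reachable on degenerate,
monotone-increasing curves). The MCD search enumerates exhaustively whenever
$\binom{n}{h} \le 50{,}000$ and otherwise uses 50 random starts; elemental
starts with singular scatter are enlarged until usable. Pearson r is clamped
to [−1, 1] before the t transform, with p = 0 at |r| = 1.

## Known limitations

The criterion estimator needs two-timescale gap structure; on data without
meal organisation (flat hazards) it falls back, flagged, to the pooled
argmin. Position assumes visits queue at a single entry point and carries no
information in pens with unconstrained feeder access. RFI/RG require ≥ 5
complete records per breed and a full-rank design, and their interpretation
is within-cohort only. The outlier filter assumes the clean bulk of
(TM, FIM, IBM) is roughly elliptical on the raw scale; heavy natural skew
(e.g. overnight IBM) consumes part of the 5× cutoff's slack, which is why
the cutoff is generous. None of the social-ranking traits are validated
against direct agonistic observation here; they are feeder-log proxies.
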