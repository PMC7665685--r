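---
title: "Methods: from landings surveys and vessel tracks to national catch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from landings surveys and vessel tracks to national catch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfmonitor)
```

## The problem

Small-scale fisheries land most of the fish eaten in many coastal nations,
yet they are chronically under-reported: catches arrive at dozens of remote
sites, in canoes and small motorboats, and no logbook system exists.
`ssfmonitor` implements the analytics used by landing-site monitoring
programmes that pair enumerator surveys (species, fork length, count, price,
trip effort) with cheap solar GPS trackers pinging every 5 seconds on a
subset of boats. The package turns those two streams into catch statistics:
per-trip catch weight, quality-controlled records, CPUE, vessel activity,
a national monthly catch estimate, and imputed gear/habitat labels for
trips that were tracked but never met an enumerator.

## Catch weight from length

Enumerators measure fork length; weight is estimated through the standard
allometric relationship $W = a L^b$ with $a, b$ per taxon in the FishBase
convention (length in cm, weight in g), scaled by the number of individuals:

$$\text{weight}_{kg} = n \cdot a \cdot L^{b} / 1000.$$

The species table carries $a$, $b$ and plausibility bounds per taxon;
`estimate_weight()` is the bare law and `add_weights()` applies it across a
dataset. We require $a > 0$ and $1 \le b \le 5$; most fishes fall near
$b \approx 3$ (isometric growth).

## Flag-and-suppress quality control

Field data arrive with digit slips, unit confusions and the occasional
genuine outlier. `apply_filters()` evaluates six independent rules
(length, count, weight and price plausibility bounds, format errors, and
gear/habitat combinations ruled out by an editable validity matrix) and
*flags* offending records; `suppress_flagged()` removes them from every
downstream aggregate while keeping them, with their offending values, in a
machine-readable report for curation. Flagging never deletes: a curator can
amend the source record and re-run the pipeline.

Two design choices deserve a note:

* **Trip-level invalidity removes the trip.** A trip reporting gleaning in
  deep water is wrong at the trip level; both its catch and its reported
  effort are untrustworthy, so the whole trip leaves the clean store. Other
  flags act record-wise, and a trip whose every landing was suppressed still
  contributes its effort — zero-catch trips are informative for CPUE.
* **Bounds are configuration, not constants.** Programmes differ; the
  shipped defaults (`qc_bounds()`: at most 1000 individuals and 500 kg per
  landing record) are deliberately permissive so they catch data-entry
  errors rather than unusual fishing days. Per-taxon length and per-kg price
  bands live in the species table. Per-fish prices are converted to per-kg
  via the record's estimated weight before the price band is applied.

## Effort, CPUE and smoothing

Effort is standardised to *fisher-hours* (trip duration × crew), the one
unit that is comparable across hand lines, nets and spearguns. CPUE per
stratum is the ratio of totals $\sum \text{catch} / \sum \text{effort}$,
which weights trips by effort and keeps units consistent with the raising
equation below; a mean-of-trip-ratios variant is available behind a flag
for sensitivity analysis. Model-based CPUE standardisation (GLMs over gear,
habitat, season) is deliberately out of scope: in a multi-gear, multi-
habitat, mixed-species fishery it demands modelling choices a monitoring
dashboard cannot defend, so the package reports raw CPUE.

For display, `smooth_cpue()` fits a cubic smoothing spline weighted by
effort (`stats::smooth.spline`), with the smoothing parameter exposed so a
user can sweep it; at maximal smoothing the fit collapses to the
effort-weighted straight line, at minimal smoothing it interpolates. At
least 4 distinct time points are required — below that the function refuses
and the raw series should be shown.

## Vessel activity and the national estimate

Landing-site sampling sees a fraction of trips; raising to the nation needs
to know how often boats fish. The *vessel activity coefficient* (VAC) is
the mean number of trips per boat per month, measured from the tracked
subfleet: segmented tracks are counted per unit and month, divided by the
number of tracked boats of that type. The default denominator is the
month's *active* roster (units with ≥ 1 ping); a fixed instrumented roster
can be supplied instead, in which case idle boats count zeros. Track
segmentation itself uses a configurable time-gap rule (default 2 h between
pings starts a new trip) since trackers stream continuously.

The national monthly catch in tonnes is

$$C = \sum_b \mathrm{CPUE}_b \times \mathrm{EPT}_b \times \mathrm{VAC}_b
      \times N_b \times 0.001,$$

summed over boat types $b$ (canoe, motor), where EPT is the *median* effort
per trip in fisher-hours (robust to the long tail of multi-day trips),
$N_b$ the census count of boats, and 0.001 converts kg to tonnes.
Shore-based fishing is excluded from the raising: it has no vessel census
and contributes a negligible share of landings. `national_catch()` fails
loudly if any component is missing for a census boat type rather than
silently dropping a term.

## Imputing gear and habitat for tracked-only trips

Most tracked trips never meet an enumerator. For those, the package copies
labels from the nearest *linked* trip (one with both a track and a survey
record): each track is summarised as 10 positions at evenly spaced times
(linear interpolation between bracketing pings), projected to kilometres by
an equirectangular projection ($x = \Delta\lambda \cos\varphi_0 \cdot
111.32$, $y = \Delta\varphi \cdot 110.57$), giving a 20-dimensional feature
vector. A query takes its donor's gear and habitat only when the full
20-dimensional Euclidean distance is below 0.20 km; otherwise it stays
unassigned. Ties break to the lowest donor id.

Choices made where the protocol is genuinely open:

* **Positions, not velocities.** Ten interpolated *positions* make the km
  cutoff dimensionally natural; a displacement-vector encoding
  (`type = "displacement"`, 18 dimensions, origin-free) is provided for
  comparison.
* **The cutoff applies to the 20-dimensional norm**, not a per-point mean;
  this matches treating the whole trajectory summary as one point in
  feature space.
* **Unassigned queries score as incorrect** in validation — the
  conservative reading.
* Distances are insensitive to the projection origin at trip scale (the
  test suite asserts < 0.1% drift for origin shifts of ~0.3°); the
  projection error itself is negligible within ~10° of the equator.

`validate_classifier()` implements the hold-out protocol: 80/20 random
splits repeated 100 times, reporting mean and SD of gear and habitat
accuracy, reproducible under a seed.

## The synthetic fishery

`make_fishery()` generates a complete, fully known month of fishing: a
fleet of canoes and motorboats, gear-specific fishing grounds, landings per
trip, 5-second GPS tracks, a census, and a truth record (total catch, true
VAC, ground locations, the exact list of injected errors). It exists so
every pipeline stage can be tested against ground truth without any field
data, and it is first-class, tested code.

What it emulates, and what it does not: trips are out-and-back (10% of the
trip travelling out, 80% loitering at the ground, 10% returning) to
Gaussian ground patches keyed to gear; lengths are lognormal within each
taxon's plausibility band; counts are sized to match a per-gear mean CPUE
with lognormal trip noise; prices sit inside the per-taxon band. It does
*not* simulate currents, search behaviour, multi-ground trips, tracker
dropout or tidal/seasonal structure — so classifier accuracies measured on
it are upper bounds for real fleets, where fishing grounds overlap and
trajectories are messier. The generator's corruption machinery
(`flag_rate`, `invalid_trip_rate`) injects errors that each violate exactly
the targeted QC rule, which is what makes exact flag-recovery checks
possible.

Two default choices matter for the estimator-recovery property:

* **Crew is fixed per boat type** (canoe 2, motor 3) and trip duration is
  lognormal with a small CV (`duration_sdlog = 0.05`, mean-preserving
  around 4 h). Per-trip effort is then lognormal, and the only discrepancy
  between the raised estimate and the generated truth is the median-versus-
  mean gap in EPT — about 0.1% in expectation, comfortably inside 2% with
  ~100 trips. With `constant_effort = TRUE` the identity is exact:
  $\mathrm{CPUE}_b \cdot \mathrm{EPT}_b \cdot \mathrm{VAC}_b \cdot N_b$
  telescopes to the summed catch. Wider effort distributions (crew sampled
  from ranges, duration CV ≫ 10%) destabilise the sample median and are
  easy to explore through the config, but they are not the reference
  conditions.
* **Ground separation (5 km) vs spread (0.02 km)** is the dial controlling
  classifier separability; at the defaults, same-gear trips differ by
  ~0.1 km in feature space (inside the 0.20 km cutoff) and different-gear
  trips by kilometres.

All randomness flows from one master seed through named substreams
(species, trips, tracks, flags), so changing the flag-injection rate leaves
the generated trips and tracks byte-identical.

## Numerical and scale choices

* Nearest-neighbour search uses the $|q|^2 + |t|^2 - 2q\cdot t$ expansion
  for the distance matrix (fast, vectorised) and then recomputes the
  winning distance directly, because the expansion loses ~1e−12 relative
  precision to cancellation; tests compare against a double-loop oracle at
  1e−12.
* Medians use R's convention (mean of the two middle values for even *n*),
  stated explicitly because EPT feeds the headline estimate.
* The test suite and examples run the generator at coarsened GPS cadence
  (60–300 s) and fleets of 5–75 boats — a few hundred trips and up to
  ~400k pings — which exercises every code path at interactive speeds; the
  5 s default cadence is retained where ping density itself is under test.
* Timestamps are interpreted in a single configured timezone (default UTC)
  and months are calendar months of the trip date.

## Known limitations

* VAC from trackers assumes the tracked subfleet's activity is
  representative of the fleet; the package cannot detect violation of that
  assumption.
* The 2 h gap segmentation merges same-day trips separated by short port
  calls and splits trips with > 2 h of anchored drifting; the threshold is
  exposed for a reason.
* CPUE is raw, not standardised; trends confound abundance with changes in
  fleet behaviour.
* The classifier transfers labels only within the spatial range of the
  linked set; a new fishing ground yields unassigned trips (by design, via
  the cutoff) rather than guesses.
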