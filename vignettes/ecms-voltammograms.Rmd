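---
title: "Mass voltammograms from EC-MS runs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass voltammograms from EC-MS runs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltagram)
```

## The measurement this package models

In online EC-MS metabolism simulation, an analyte solution is pumped through
an electrochemical thin-layer cell whose working-electrode potential follows
a staircase ramp (typically 0–3500 mV at 10 mV/s in 5 mV steps, so each
level is held 0.5 s), and the effluent flows through a transfer capillary
into an electrospray source. Every MS1 scan therefore reports the reaction
mixture at one applied potential. Arranging the centroided spectra along the
potential axis gives the *mass voltammogram*; consumed parent compounds
(educts) appear as decaying traces, oxidation products as traces that rise
at a *formation potential*.

### The staircase ramp and the transfer delay

`potential_at_time()` maps a scan time to its potential:

E(t) = E_start + s · ⌊ v · max(0, t − τ) / s ⌋, clamped to [E_start, E_end],

with scan rate `v` (mV/s), step `s` (mV) and transfer delay `τ` (s). The
staircase (rather than linear interpolation) mirrors the discrete 5 mV
levels the potentiostat actually applies. Scans before the delay-corrected
ramp start are mapped to `E_start` and scans after the end to `E_end`: the
cell holds the rail potentials there, so those scans remain usable rather
than being discarded. The delay can be given directly or derived from
plug-flow geometry, `τ = 60·V_cap/flow` (10 µL at 20 µL/min → 30 s); it
defaults to 0 because instrument-side ramp triggering often absorbs it, and
a wrongly *assumed* delay shifts every formation potential by `v·τ`.

### Voltammogram construction

Spectra sharing a level are combined by the **arithmetic mean** of their
merged centroids (not the sum), so the number of scans that happen to land
on a 0.5 s level does not bias intensity; the choice is recorded in the
object's provenance. Peaks are agglomerated into m/z channels greedily in
ascending m/z against the running intensity-weighted channel mean, with a
5 ppm default tolerance — appropriate for a QTOF whose observed deviations
are 1–3 ppm, and narrow enough to keep an M+1 satellite (≈2700 ppm away at
m/z 358) in its own channel. With `min_intensity = 0` the construction
conserves total (level-averaged) intensity exactly, which the test suite
asserts.

### Formation potentials

The onset of a product trace is the lowest level at which the 5-point
moving-averaged trace reaches 10% of its maximum (`onset_fraction = 0.10`)
and holds it for 3 consecutive levels (`sustain_steps = 3`, a guard against
isolated noise spikes at 0.5 s per level). One condition is added beyond the
obvious "first sustained crossing": the smoothed trace must *start below*
the threshold. Without it, any educt — already at its maximum at 0 mV —
would trivially "cross" at the first level; with it, educts and constant
backgrounds return no formation potential, which is what the quantity
means. At the default 701-level density, the 25 mV smoothing window shifts
a logistic 10% crossing by well under one 5 mV step (the convexity bias is
O(σ″·var(window))), so recovered onsets land within ±2 steps of the
analytic crossing; the tests assert exactly that.

## Reference subtraction and isotope handling

Subtraction operates on voltammogram channels, mirroring feature-list blank
subtraction rather than scan-by-scan subtraction: a target channel is
removed iff the reference run (same ramp grid, enforced) has a channel
within tolerance whose maximum is at least `1/fold` of the target's maximum.
The default `fold = 3` is the common blank-subtraction heuristic; fold = 1
removes on parity, larger folds remove more aggressively, and survivor sets
are nested in `fold` (a tested invariant). Removal is logged (matched
reference m/z, both maxima) on the returned object. A removed channel that
itself has a formation potential is flagged with a warning: structurally
similar co-oxidised compounds can form TPs at shared m/z, and subtracting
them silently would hide real products — the method's known limitation.

Isotope satellites are chained by the ¹³C–¹²C spacing (1.0033548378/z Th)
with the requirement that each satellite be weaker than its predecessor,
which stops chains from wandering across unrelated peaks; competing chains
resolve toward the higher-intensity predecessor by processing seeds in
descending intensity. `collapse_isotopes()` sums satellite traces into the
monoisotopic channel level-by-level, conserving total intensity exactly.

## Exact-mass annotation

All annotation is arithmetic on elemental formulas with fixed IUPAC/CODATA
monoisotopic constants embedded in the source (H 1.00782503207, C 12, N
14.0030740048, O 15.9949146196, e⁻ 0.00054857990); no external mass table
is consulted, so reported values cannot drift with a dependency. For a
cation, one electron mass is subtracted per charge — necessary to report
358.2125 for C20H28N3O3⁺ rather than the 358.2131 a neutral-mass sum would
give. Reported m/z are rounded half-up to 4 decimals and ppm deviations to
1 decimal, with the ppm computed against the already-4-decimal-rounded
calculated value; that convention matches how such tables are printed and
makes the report reproducible digit-for-digit.

The default biotransformation library covers the gains/losses EC oxidation
commonly produces (+O, +2O, +2O−2H, −2H, +O−2H, −CH2, −CH2+O, +H2O);
matching uses a 1 mDa tolerance by default (generous against sub-ppm QTOF
accuracy at m/z < 1000) and ranks by absolute error, breaking ties toward
fewer atoms changed. The library is a plain-text config
(`read_transformation_library()`), because which transformations are
plausible is a chemistry decision, not a software one.

MS/MS annotation enumerates candidate fragments as the precursor minus
every element-legal multiset of at most `max_chain = 2` neutral losses
(observed chains in this chemistry are depth ≤ 2); chains differing only in
order give the same formula and are deduplicated. Each observed peak takes
the candidate with the smallest |ppm| within 5 ppm. The water-loss presence
flag is deliberately the only "structural" statement the package makes: a
dehydrogenated dihydroxy (quinoid) product is expected to *lack* the −H₂O
fragment that a free-hydroxy product shows, but positional isomers are
beyond exact-mass evidence, so nothing more is claimed.

## The synthetic generator

`simulate_run()` generates what the pipeline needs to be testable offline:
educt channels decaying as `I_max·(1 − σ((E − E_mid)/w))` and products
rising as `I_max·σ((E − E_mid)/w)` (logistic σ), an M+1 satellite at
+1.0033548 Th with relative abundance 0.011 per carbon, and additive
Gaussian noise (sd = `noise_sd`·I_max, truncated at zero), at 2 Hz — one
scan per 5 mV level. The logistic parameterisation is chosen over
piecewise-linear because its 10% crossing has a closed form
(`E_mid + w·log(1/9)`), giving the onset-recovery tests an analytic target.

`scra_fixture()` encodes the mixed-standard study conditions: parent ion
C20H28N3O3⁺ (educt, midpoint 1700 mV, width 50 mV, 10⁶ counts), an
interferent educt at the synthetic m/z 401.1782 (a stand-in — no real
compound's mass is asserted as truth), and the two products C20H28N3O4⁺
and C20H26N3O5⁺ forming with midpoint 1700 mV, at 1% noise; the reference
run contains the interferent alone under the identical ramp. Width and
relative intensities are not measured quantities: 50 mV is a realistic
oxidation-wave width on a boron-doped diamond electrode at this step
density, and product/parent ratios of 0.15–0.2 reflect the "less intense
TP signal" regime the method operates in. The satellite model (1.1% per
carbon, single M+1) is deliberately crude — enough to exercise isotope
grouping, not a physical isotope-pattern simulation. What the generator
does **not** emulate — electrospray response factors, adducts, in-source
fragmentation, profile peak shapes, ion-mobility structure — bounds what
green tests mean: they certify the arithmetic, the bookkeeping and the
recovery logic, not instrument-grade robustness on real spectra.

## Numerical and degenerate-input choices

* Rounding is half-away-from-zero (with a 10⁻⁹ guard for float
  representation), not banker's rounding, to match reported-table
  conventions.
* `floor()` in the ramp mapping carries a 10⁻⁹ guard so level boundaries
  (t = 0.5 s at 2 Hz) land on the upper level deterministically.
* Channel agglomeration ties break toward the nearest (running-mean)
  existing channel; within-level merging happens before cross-level
  merging.
* Empty inputs: an mzML with zero spectra reads as an empty run with a
  warning; building a voltammogram from a run without MS1 scans, writing an
  empty run, mismatched subtraction grids, non-positive ramp parameters and
  element-illegal formula subtractions are all errors with distinct
  messages.
* Problem sizes used throughout the examples and tests: 701-level ramps
  (the full staircase), 2 Hz acquisition, single-digit channel counts —
  the regime the method is designed for; unit tests use 3–101-level ramps
  where the full grid adds nothing.

## Known limitations

* Subtraction is channel-wise on maxima; co-eluting (co-oxidising)
  compounds with genuinely shared TPs are removed with a warning, not
  deconvolved.
* Formula parsing covers element-count strings with a trailing charge given
  as repeated sign characters; digit-prefixed charges ("…2+") are rejected
  as ambiguous with element counts.
* xlsx table export requires the optional `writexl` package; CSV is the
  first-class format.
* No formula generation from m/z alone: annotation always starts from a
  parent formula, and positional isomery is out of scope by design.
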