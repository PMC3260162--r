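---
title: "coultertrace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coultertrace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coultertrace)
```

This vignette is the package's own account of what it computes and why:
the measurement model, the filters, the kinetics estimators, the simulator
that stands in for live-culture data, and the numerical choices made where
the procedure left room.

## The measurement model

A Coulter counter registers, for each particle transiting its aperture, a
resistive pulse. The instrument stores five integer values per pulse; only
the first — the pulse-height component — carries size information used
here. The decoded height is

> height = correction_factor + value[1], clamped at 0

(a pulse cannot have negative amplitude; clamping only matters for
pathological negative correction factors). Height converts to the
spherical-equivalent (Heywood) diameter through the calibration constants
carried in each file's header:

> d = Kd · (gain · height / (current · countspervolt))^(1/3),

with countspervolt fixed at 838 870 V⁻¹, and volume is v = (π/6)·d³. Every
constant is configurable per header; the conversion is strictly increasing
in height with d(0) = 0, so all downstream analysis can treat volumes as a
faithful monotone image of the raw heights. The vendor's exact formula
layout can be slotted in behind the `dialect = "native-adapter"` reader
without touching anything downstream, because all later stages consume
volumes only.

**Timestamps.** The instrument records, every 200 ms, the elapsed time and
the cumulative number of pulses. The m pulses arriving within one tick
(t₀, t₁] are assigned times t₀ + j·(t₁−t₀)/m for j = 1..m. Any assignment
within a tick is wrong by at most the tick width, so each event's time is
correct to 200 ms; the simulator's ground truth confirms the bound exactly.
One pulse in a tick lands at the tick's end — the rule's m = 1 case, not a
special case.

**Stitching.** The commercial software resets each file's clock to zero,
which makes multi-file rate analysis impractical; here every file keeps an
absolute start time, the timecourse epoch is the earliest file's start, and
flush gaps between files are preserved rather than compressed. Overlapping
recording intervals are an error, not a warning: they indicate a corrupted
header, and silently reordering events would poison every regression
downstream.

## Filters

Two flags, never deletions — colormaps can still show excluded data:

* **Noise floor.** Per file, exactly ⌊f·N⌋ events of smallest volume are
  flagged (f = 0.02 by default). The floor rule makes the count
  deterministic; ties in volume resolve by original record order so the
  flagging is stable and reproducible.
* **Exclusion bounds.** Events outside a bound pair (default level 10% of
  the mode) are flagged out of rate analysis. The interval is closed:
  an event exactly on a bound stays in. Bounds are derived per file, since
  the distribution drifts over a timecourse.

## Histograms and bound pairs

Default binning is 256 log-spaced bins over the included-data range with
Gaussian smoothing of bandwidth 3 bins (edge-renormalized); raw counts are
available by `smooth_bw = 0`. Log spacing suits multiplicatively spread
size distributions, with one consequence worth stating: the count-mode of a
log-normal sample under log-spaced bins estimates the mode of the
*log-volume* density (the geometric mean, e^µ), whereas linear bins
estimate the arithmetic density mode e^(µ−σ²). Both are tested; users
comparing against external mode values should match the binning.

The mode is the midpoint of the bin maximizing the smoothed counts, ties
resolved toward the lowest volume. A *bound pair* at level X is the pair of
volumes where the smoothed counts cross X·modeCount/100, one crossing on
each side, located by linear interpolation between bin midpoints. The
crossings *nearest the mode* are used — a bound pair consists of one bound
on each side of the mode, so the bracketing crossings are the defined ones,
not the outermost. If a side never falls below the target the data extremum
is returned with a clamp flag. At level 100 both bounds collapse to the
mode. Bounds are computed on smoothed counts by default (raw available by
flag); smoothing stabilizes the mode count that the target is a percentage
of.

**Subpopulations.** Local peaks of the smoothed counts with topographic
prominence at least 5% of the global mode count, at least 8 bins apart
(closer peaks merge into the taller one), are treated as subpopulation
modes. Events are assigned to regions split at the smoothed-count minima
between adjacent peaks; an event exactly on a boundary joins the
lower-volume track. Across files, peaks are associated by nearest neighbor
subject to a maximum relative jump of 15% per file; unmatched peaks start
new tracks, and a track missing a file records a gap but stays eligible
later. The prominence and separation defaults were chosen once against the
simulator's well-separated mixtures; they are not sensitive parameters for
distributions with component CVs ≲ 15% and mode ratios ≳ 2.

## Debris detection and interpolation

A partial aperture occlusion inflates the measured size distribution for a
file or two until a flush clears it. Detection compares each file's 25%
bound pair against its neighbors': file i is flagged when its bound exceeds
1.025× the corresponding bound of its neighbors. Two readings of
"neighboring files" are configurable:

* `both` (default): the bound must exceed the threshold against *both*
  neighbors. Under the `either` reading, steady growth of ~2.5% per 150 s
  file would false-flag a legitimate monotone trend; `both` targets the
  transient single-file spikes the criterion exists to remove. Note the
  flip side, exercised in the tests: a *run* of equally inflated files only
  exceeds against its outer neighbors, so detecting runs requires `either`.
* `compare_side = "upper"` (default): occlusions inflate the large-volume
  tail, so the upper bound is compared; `lower` and `either` are available.

The comparison is boundary-inclusive within a 1e-6 relative tolerance: a
bound exactly at threshold-times-neighbor counts as exceeding. The
tolerance exists because a distribution scaled by exactly r recovers a
bound ratio of r only to ~1e-8 (integer height quantization); 1e-6 is still
three orders of magnitude below the finest ratio distinction of interest.
First and last files have one neighbor and are never flagged.

Flagged files are replaced, not repaired: the replacement's pulse count is
the mean of the neighbors' included counts, its volumes are midpoint
quantile interpolations (vⱼ = mean of the neighbors' j/(m+1) empirical
quantiles), and its timestamps are spaced linearly across the replaced
file's full duration. Runs of consecutive flagged files are all replaced
from the bracketing unflagged files with time-proportional quantile
weights. Replacements are real files (provenance `interpolated`,
persisted on disk), so a cleaned timecourse round-trips through the same
IO as raw data. Cleaning is idempotent on smooth data: an interpolated
file's bound lies between its neighbors' by construction, so it cannot
out-inflate both. If more than half the files are flagged the cleaning
aborts — that pattern indicates a persistent occlusion, which interpolation
would silently paper over. Within each interpolated file the quantiles are
spread across the timestamps by a deterministic stride permutation rather
than sorted order, so volume is not artificially correlated with time
inside the file.

## Kinetics

All regressions run on single-particle (time, volume) events inside the
exclusion bounds — not on per-file summary statistics — which is what makes
confidence intervals meaningful at these event counts.

**Moving-window rates.** Per window (60 min, shifted every 3 min, by
default), the OLS slope of volume (µm³) on time (min), with the 95% CI from
the standard slope-error formula and the t quantile. Windows with fewer
than two distinct event times yield NA. Internally the windows are
evaluated from prefix sums of globally centered coordinates, making the
full scan O(n + windows); centering keeps the moment differences far from
cancellation at 10⁶-event scale, and the tests pin the implementation to
`lm()` at 1e-9 relative.

**Bilinear change points.** For each candidate split time the events are
broken in two (strictly-before versus at-or-after), an unconstrained line
is fitted to each side, and the total SSE is recorded; the candidate
minimizing it is the detected rate-change point, ties resolving to the
earliest. The default grid is every 30 s across the span excluding 5 min at
each edge, where one-sided fits are unstable. Two open choices and their
resolutions:

* *Continuity:* the two lines are not constrained to meet at the split
  (`two independent fits`); an unconstrained fit is the simpler model, and
  at the true break the constrained and unconstrained optima coincide.
* *Significance:* a change is reported as significant when the relative SSE
  reduction versus a single global line exceeds 1% (configurable). This is
  a package convention — a mock-treated control with constant volume shows
  no reduction of that size, while real responses show far more — not a
  formal test.

One structural property matters when recordings have flush gaps: every
candidate inside a gap partitions the events identically, so their SSEs tie
exactly and the earliest-tie rule reports the gap's start. A change point
falling inside a gap is therefore recovered at gap-start resolution
(≤ gap length early), which is the measurement's actual information limit,
not an estimator defect.

**Growth laws.** Linear `y = ax + b` by OLS; exponential `y = A·e^(bx)` by
Levenberg–Marquardt nonlinear least squares initialized from a log-linear
OLS fit (falling back to those log-linear parameters, flagged, on
non-convergence). R² is computed on the original scale for both models so
the comparison is like-for-like — an R² computed on log-transformed data
would structurally favor the exponential.

## The simulator

The generator emulates the acquisition structure of a continuous run, not
cell biology: files of 150 s separated by 50 s flush gaps (~75% duty
cycle), Poisson pulse counts (20 000/file by default — a desk-scale choice;
real runs are 2–5× larger), uniform arrival times within each file,
populations with log-normal biological spread (right-skewed, as size
distributions are) and `none`/`linear`/`exponential` mean-volume growth,
multiplicative Gaussian instrument noise on diameter, a configurable junk
fraction below the size range feeding the noise-floor filter, optional
single-file debris inflations, and an optional treatment that switches the
mean trajectory to a new slope after a response lag. Volumes are encoded
back to integer pulse heights through the header constants, so simulated
files exercise the identical decode path as instrument data; the ground
truth records the post-quantization volume (quantization is ~10⁻⁸ relative
at the default gains). All draws come from one stream seeded by the config,
in documented order, so a fixed seed reproduces files byte-identically.

Preset parameters the study conditions fix: beads of 4.000 µm diameter with
0.033 µm diameter SD measured for 2 h (the rate-resolution control); the
drug-response course of a 900 µm³, CV 15% mammalian-like population,
constant for 60 min, treated at 60 min, responding after a 9.7 min lag with
a linear decline of 2.25 µm³/min (15% of the mean per hour) over 2 h.
Remaining preset values are field-realistic choices made once: arrested
yeast-like means of 25–80 µm³ with size-dependent linear rates
(0.02–0.35 µm³/min), a synchronized population growing exponentially at
0.005/min from 20 µm³ over 4 h, CVs of 10–25%.

What the simulator does *not* model — and hence what passing tests do not
certify about real data: coincidence (two cells in the aperture),
orientation- and path-dependent pulse shapes, drift in calibration or
electrolyte, cell division and budding, and debris whose signature is
anything subtler than a multiplicative inflation. Results on real
instruments depend on those effects; the package's claims are about the
extraction and analysis pipeline, which the simulator covers completely.

## Problem sizes and determinism

The shipped tests run the full presets where the check is about recovery
under study conditions (2 h bead runs at 20 000 pulses/file across five
seeds; ten drug-response courses; one 4 h synchronized course) and small
configurations (500–5 000 pulses/file, 5–40 min) everywhere the property
under test is structural. The whole suite completes in well under a minute
on one core. Every stochastic test fixes its seed; there are no
environment-dependent paths.

## Known limitations

* The native vendor binary layout is not parsed; the `native-adapter`
  dialect slot is reserved for a transcription of it. The fixture dialect
  carries every field the analysis names.
* Bound-pair levels far into the tails (≲ 2%) sit where smoothing bandwidth
  choices visibly move the crossing; bounds at the conventional 10–33%
  levels are insensitive to the default bandwidth.
* The bilinear model fits exactly two segments; multi-phase responses need
  repeated application or a dedicated segmentation method, which is out of
  scope.
* Subpopulation tracking is greedy nearest-neighbor; it is adequate for
  slowly diverging modes but has no global assignment step, so crossing
  trajectories can swap labels.
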