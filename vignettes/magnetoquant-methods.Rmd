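---
title: "Quantifying magnetogenetic study readouts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying magnetogenetic study readouts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetoquant)
```

## Scope

Magnetogenetic neuromodulation experiments activate (or silence) genetically
targeted neurons with static or pulsed magnetic fields and read the effect
out across several modalities at once: open-field motor behavior scored from
keypoint tracks, behavior conditioned on a gaussmeter map of the field over
the arena, striatal calcium dynamics from dual-channel fiber photometry,
in-vitro indicator responses from ROI time-lapse traces, brain glucose
metabolism from small-animal FDG-PET, and immediate-early-gene histology
from multichannel micrographs. `magnetoquant` implements the quantification
chain for each modality, plus a synthetic-data module that generates every
input with known ground truth so the whole pipeline is testable at desk
scale.

## Trajectory behavior

Tracks hold time-stamped arena coordinates (cm) for the nose, body center,
fore- and hindpaw midpoints, and tail. The scoring convention divides each
second into five frames and scores every second frame, i.e. an effective
2.5 Hz analysis grid and 150 positions per minute per keypoint;
`resample_track()` implements exactly this decimation and preserves
timestamps.

**Freezing of gait** is a continuous period of at least 1 s with no change
of spatial position of the head, center, or extremities. "No change" needs
an explicit tolerance because real tracking jitters: a step between
consecutive analysis samples counts as static when every required keypoint
moved at most `epsilon` cm. Defaults, all exposed in `freeze_params()`:

* `min_duration = 1.0` s. On the 2.5 Hz grid this means at least three
  consecutive static steps (1.2 s), the smallest span satisfying the 1 s
  rule at this resolution.
* `epsilon = 0.5` cm per step. Chosen as roughly 10x a typical tracker
  jitter SD and well below one body length; at the default ambulation speed
  an ambulating animal covers ~3.2 cm per analysis step, so the static/
  moving margin is wide from both sides.
* Gap policy: a step with any missing required keypoint is non-static. This
  is deliberately conservative — tracker dropouts can never inflate
  freezing time.

Bouts are maximal runs of static steps, reported as half-open intervals
`[first static step, last static step + step duration)`. Freezing time is
the sum of bout durations per epoch.

**Ambulation** uses only the center keypoint: distance is summed center
displacement, a step is active when center speed exceeds a threshold
(default 2 cm/s — not a printed value anywhere, so it is exposed), activity
percentage is active time over valid (non-missing) time. Both the total
ambulating time and the per-bout table are reported, with total time as the
headline metric, since "ambulation bout duration" could be read either way.

**Rotations** derive from the center-to-nose heading. Signed heading
increments are unwrapped and accumulated; each crossing of ±90° (open-field
convention) or ±360° (rotometer convention) counts one rotation in that
direction and the threshold is subtracted, so continuous spinning yields
the closed-form count. Rotation counters reset by subtraction rather than
to zero; for threshold-crossing of a continuous rotation both conventions
agree, and subtraction keeps partial progress. With a declared lesion side,
`net_contralateral()` reports contralateral minus ipsilateral counts, and
`percent_change_rotations()` gives the percent change from a positive
pre-treatment baseline.

## Field mapping

A `field_grid` is a rectangular gaussmeter map (mT) with y pointing toward
the field source. `field_at()` interpolates bilinearly — the simplest
scheme exact at the measured nodes; since maps are coarse cage-section
measurements, anything fancier would invent structure. Out-of-hull queries
raise rather than extrapolate. `bin_behavior_by_field()` assigns each
analysis sample the field at the *center* keypoint (a body-exposure proxy;
the nose can overhang a steep gradient) and accumulates occupancy and
within-bout freezing time into half-open bins `[low, high)`; the documented
behavioral threshold of 180 mT is therefore a left-closed bin edge. Regime
labels follow the printed definitions: high DMF 0.5–1.3 T, low DMF
0.1–0.27 T.

## Fiber photometry

The calcium-dependent 465 nm channel and the isosbestic 405 nm channel
share motion and bleaching artifacts; the isosbestic channel carries no
calcium signal. Processing follows the standard subtraction recipe:

1. Optional zero-phase low-pass of both raw channels (2nd-order
   Butterworth, 15 Hz corner, mirroring the acquisition chain's corner
   frequency). Applied before fitting so the fit sees the same bandwidth
   the signal does.
2. Ordinary least squares of the 465 channel on the 405 channel over the
   *entire session* (no per-epoch refits), giving `405_fitted`.
3. `net = 465_raw - 405_fitted`; dF/F% = `100 * (net - median(net)) /
   denominator`.

The recipe divides by the median of the net trace. Because a least-squares
residual is centred, that median sits near zero whenever the fit is good,
which would blow up the percentage. `compute_dff()` therefore guards the
denominator: if `median(net)` falls below 1% of `median(465_raw)`
(configurable), the session median of the raw 465 channel is used instead
and the trace is flagged (`denominator_substituted`). This preserves the
published formula in its intended regime while defining the degenerate
case; in practice the substituted denominator is the session's baseline
fluorescence, which is what a percent change is naturally relative to.
`median(dff) = 0` holds by construction either way.

"Event values" are taken as all samples rather than peak-picked events:
epoch means average every sample in the epoch, and `align_to_events()`
cuts TTL-locked windows, re-baselines each trial to its pre-event mean, and
averages across trials. Events whose window would leave the session are
dropped with a warning.

## ROI fluorescence (calcium and chloride indicators)

Per-ROI mean intensities are background-subtracted frame-wise (one
background ROI per recording), then normalised as
`dF/F0 = (F - F0)/F0` with `F0` the mean over the pre-stimulus baseline
window. The sign is kept: calcium indicators rise, the chloride dye MQAE is
quenched by incoming chloride and goes negative. Peaks are per-ROI maxima
(largest-magnitude excursion in quench mode) with earliest-time
tie-breaking. Windowed AUC — by convention 48–180 s for the magnet-exposure
assay — is a trapezoidal integral on dF/F0 with the trace linearly
interpolated at the window endpoints, which makes areas over abutting
windows add exactly. AUC is computed on dF/F0, not raw fluorescence, and
that choice is stated here because the source convention is ambiguous; on
dF/F0 the AUC is dimensionally a time-integral of a fractional change and
comparable across cells.

## PET quantification

Starting from ROI-level activity concentrations (MBq/ml), per animal and
condition:

* final dose = initial minus residual syringe dose;
* `%ID/g = 100 * C_roi / (final_dose / weight)` with the standard
  small-animal convention 1 ml ≡ 1 g of tissue;
* left and right dorsal striatum are averaged *before* any ratio;
* the cerebellum (no D2-type receptors) is the reference region — in the
  striatum/cerebellum ratio dose and weight cancel, so it is invariant to
  global scanner calibration;
* per-animal DMF-over-baseline ratios are emitted for both the raw MBq/ml
  measure and the cerebellum-referenced measure, since both variants are
  reported in this kind of study.

No radioactive-decay correction is applied; acquisition protocols hold the
injection-to-scan interval fixed across conditions, so decay cancels from
the ratios, and no decay bookkeeping is described for the source workflow.

## Cell counting

The counting scheme mirrors a fixed-parameter ImageJ macro: Gaussian blur,
binary threshold at 30 (of 255), connected components, and removal of
objects under 20 px to discard speckle and low-signal cells. The macro
phrase pairing "threshold … 30" with "size filter … 20" leaves the blur
radius unstated; the blur SD defaults to 2 px and is exposed, and the size
filter is interpreted as a minimum area in px². A c-fos object counts only
when its centroid lies in the DAPI mask (clear nuclear colocalization), and
is double-positive when that centroid also falls inside a transduction-
marker object; centroid-in-mask is deterministic and scale-robust, where
pixel-overlap fractions would add a second free parameter. The headline
percentage is double-positives over total marker cells. 16-bit inputs are
min-max rescaled to 8-bit with a warning. `roi_sampling()` draws the
fixed-area random quantification crops reproducibly from a seed.

## The synthetic-data module

Each generator is a pure function of its parameter object, including the
seed, and returns the ground truth alongside the data.

**Locomotion** is a two-state (ambulate/freeze) semi-Markov process with
exponential dwell times. Given a target freeze fraction f and mean freeze
bout m, ambulation bouts get mean `m (1 - f) / f`, which fixes the long-run
fraction at f. During ambulation the center follows a correlated random
walk (heading increments N(0, 0.25 rad) per frame, default speed 8 cm/s)
with wall reflection inside a 26.5 cm box; keypoints are rigid body-frame
offsets rotated by the heading, plus i.i.d. jitter (default SD 0.05 cm, a
sub-millimetre tracking error). During freezing everything is static up to
jitter. Two design choices matter for testability:

* State switches are aligned to the 2.5 Hz analysis quantum (0.4 s). Dwell
  times remain exponential but are discretized, so ground-truth bouts are
  exactly representable on the detector's grid; boundary effects then probe
  the detector, not the generator's phase.
* Default mean freeze bout is 4 s. The detector cannot see bouts shorter
  than 1.2 s (three analysis steps); with exponential 4 s bouts the
  undetectable mass is ~4% of freezing time, which keeps fraction recovery
  within the ±0.05 band the tests demand.

The field-coupled variant replaces the freeze fraction with a gate: freezes
can only start where the interpolated field exceeds a threshold (default
180 mT) plus a small interior margin (`gate_margin_mT = 2`). The margin
exists because positions are read back through tracking jitter: at the
~7 mT/cm gradient of the default map, 0.05 cm of jitter moves the apparent
field by ~0.3 mT, and a freeze started exactly at threshold could be binned
just below it. Two millitesla is an order of magnitude above that
uncertainty while far below the bin width.

**Photometry** sessions are built as
`f465 = baseline * bleach + artifact + transients + noise` and
`f405 = iso_gain * (baseline * bleach + artifact) + noise`: the bleaching
exponential and a slow Ornstein–Uhlenbeck artifact are shared (scaled into
the isosbestic channel), double-exponential transients (0.5 s rise, 1.5 s
decay, a slow-indicator shape) enter the signal channel only. No artifact
or noise magnitudes are published for this kind of recording, so the
defaults (artifact SD 5, noise SD 0.3, baseline 100 a.u., bleach tau
1200 s) are stated assumptions chosen to put the shared artifact well above
the noise floor, which is the regime in which isosbestic correction is
meaningful.

**Field grids** decay exponentially with distance from the proximal edge,
constant along x; given a distal-edge target the decay length is solved so
the map spans exactly the requested range (e.g. 100–270 mT, the low-field
titration regime). The map is deterministic — monotonicity is part of its
contract.

**Cell images** place non-overlapping disks (soma radius 6 px, nucleus
4 px) by rejection sampling with a 22 px minimum separation (comfortably
above 4x the default blur SD, so blurred objects never merge), light up a
rounded fraction of them in the c-fos channel, and optionally sprinkle
1 px speckles to exercise the size filter.

What the generators do *not* emulate: no biophysics of channel gating or
ferritin magnetics, no neuron-to-behavior coupling, no video or pose
estimation, no PET physics (tables are drawn at the ROI level with known
contrast), and no anatomical structure in images. Passing tests therefore
demonstrate that the quantification chain recovers known statistical
structure at realistic noise levels — not that it is robust to every real-
world artifact (occlusions, fiber bending, segmentation of overlapping
nuclei).

## Numerical choices and degenerate inputs

* Freezing bouts tie-break as closed-open intervals; rotation accumulators
  subtract the threshold on crossing (with a 1e-9 rad tolerance so exact
  90° multiples are not lost to float accumulation).
* The dF/F denominator guard (1% of median raw 465) and its substitution
  rule are described above; a non-positive guarded denominator is an error.
* ROIs with non-positive baseline after background subtraction are excluded
  with a warning and named in the result.
* Zero-variance-in-both-groups Welch contrasts, constant-input
  correlations, zero marker-cell percentages, zero baseline rotation
  counts, and out-of-hull field queries all raise informative errors rather
  than returning NaN.
* Low-pass filtering is skipped automatically when the sampling rate cannot
  support the corner frequency (fs ≤ 2 corner).

## Problem sizes in the test-suite

The suite regenerates everything from seeds at runtime: behavior recovery
uses 600 s sessions (20 seeds per condition), oracle-equivalence checks use
100 one-minute tracks, photometry checks use 2–7 minute sessions at 100 Hz,
the field-threshold recovery uses ten 5-minute coupled sessions, and image
checks use 50 generated fields of view. These sizes were chosen so each
property is measured well inside its tolerance band while the full suite
runs in well under a minute on a laptop-class machine.

## Known limitations

* The freezing detector's resolution is one analysis step (0.4 s); bouts
  shorter than 1.2 s are invisible by definition of the 1 s rule on the
  2.5 Hz grid.
* Wall reflections can fold an ambulation step onto itself and drop its
  apparent speed below threshold for that step; ambulation time is
  accordingly exact in open arena regions and conservative within a body
  length of a wall.
* The EthoVision-style reader accepts a semicolon dialect with a metadata
  preamble; it does not reproduce every export variant of that software.
* Colocalization by centroid can miss a genuinely overlapping object whose
  centroid falls just outside the nuclear mask; with the disk geometries of
  the generator this does not occur, and on real data the blur/threshold
  parameters dominate this choice.
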