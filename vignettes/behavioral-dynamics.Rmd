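---
title: "Tracking and behavioral dynamics in two-chamber social preference tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and behavioral dynamics in two-chamber social preference tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialtrackr)
```

## The assay and the measurement problem

In a two-chamber social preference test, a subject mouse explores a
rectangular arena (37 x 22 cm by default) with two small triangular
chambers in opposite corners. Each chamber holds a stimulus — a
conspecific or an object — behind a grooved or meshed front wall, so the
subject can investigate but not reach it. Because the stimulus is only
accessible through that front wall, "investigation" has an unusually
crisp operational definition: contact between the subject and the
chamber's front wall plane. `socialtrackr` scores that contact
automatically from top-view grayscale video of a dark mouse on a light
floor, and turns the resulting per-frame labels into the behavioral
events and indices used to analyse the dynamics of social behavior:
bouts, inter-investigation intervals, transitions between stimuli,
binned investigation time, preference indices, phase summaries, and
open-field measures.

All geometry is declared once in an `arena_config`: the arena rectangle
(pixels), the pixel-to-cm calibration, two stimulus-zone segments (the
chamber front walls), two compartment polygons, the detection thresholds
and the contact tolerance. Pixel coordinates are 0-based with y pointing
down (image convention); all exported times are seconds and positions
centimetres.

## Tracking

Three per-frame tracking algorithms share one segmentation core: pixels
at or below a grayscale threshold inside the arena rectangle are
labelled, connected components are extracted, and the largest component
of at least `min_blob_area_px` becomes the subject mask (ties broken by
distance to the previous centroid, then lowest label). Contact with a
stimulus zone uses a closed inequality: the subject touches zone k when
the minimum distance from the relevant point set to the zone segment is
at most `contact_distance_px` (2 px at the default fixture scale; the
real-world tolerance is apparatus-specific, hence configurable). If both
zones qualify the nearer wins, and an exact tie is scored as no contact.

* **Body-based**: contact is measured from the whole-silhouette boundary,
  segmented at the *high* threshold so that the animal's brighter tail is
  part of the silhouette. This is deliberately permissive: rear-body and
  tail contacts count.
* **Head-directionality**: two thresholds are used. The low threshold
  captures the body but not the brighter tail; an image-moment ellipse
  fitted to that mask gives the two major-axis endpoints — head and tail,
  not yet distinguished. The pixels present only at the high threshold
  are tail evidence: the endpoint farther from that region is the head.
  With no tail evidence the endpoint nearer the previous head is used
  (temporal continuity); with neither disambiguator the head is
  undetermined for that frame and contributes no contact. Contact is then
  scored from the head point alone, which removes the false interactions
  a rump or tail can generate.
* **Wired body-based**: for animals tethered by an electrical cable or
  optical fibre, the silhouette is cleaned by a morphological opening
  with a diamond (4-neighbourhood) structuring element of radius
  `ceiling(max_cable_width_px / 2)`, keeping the largest component, then
  one geodesic dilation (same element, intersected with the original
  mask). The diamond element removes a thin cable at any orientation
  while sparing diagonal body parts one pixel wider; the geodesic step
  restores the eroded outer shell of genuine anatomy, while the cable can
  only regrow a stub of at most the element radius at its attachment
  point.

Frames with no acceptable blob are marked invalid: they carry no state
except the previous head estimate, contribute zero to every time total,
and neither break nor extend bouts on their own (short dropouts are
handled by gap correction downstream). Tracking is a pure function of
the frames, the configuration and the algorithm choice, which the suite
verifies byte for byte.

### Video format

Videos are uncompressed 8-bit grayscale image stacks: multi-page TIFF
files (or directories of PNG/TIFF frames), read and written with
`read_video()` / `write_video()`. RGB input is converted by luminance.
The tracker also accepts in-memory lists of frame matrices, so rendered
synthetic sessions can be tracked without touching disk.

## From labels to events

The per-frame contact labels form a `label_series`. Analysis rests on
three event primitives:

* **Gap correction.** Any interruption in investigation of a stimulus
  strictly shorter than 0.5 s (14 frames at 30 fps, since 15 frames is
  exactly 0.5 s and does not qualify) is merged into the surrounding
  bout, provided no frame of it belongs to the other stimulus — a visit
  to the other stimulus always breaks the bout. The 0.5-s definition
  governs at any frame rate. Correction is idempotent, never decreases a
  stimulus's total investigation time, and never increases the bout
  count as the window grows.
* **Bouts** are maximal runs of identically-labelled stimulus frames in
  the corrected series, with half-open `[start, end)` times taken from
  frame indices, so per-stimulus bout durations sum exactly to frame
  counts over the frame rate.
* **Intervals** are gaps longer than 0.5 s between consecutive bouts on
  the *same* stimulus. An interval may span bouts of the other stimulus:
  the definition is purely same-stimulus, and per-stimulus interval
  totals are analysed in their own right. A flag restricts intervals to
  investigation-free gaps for sensitivity analyses.
* **Transitions** mark the start of every bout whose stimulus differs
  from the previous bout's; the first bout of a session is not a
  transition.

## Session metrics

`session_summary()` assembles, per animal: per-stimulus totals;
investigation time per 20-s bin (durations apportioned to bins by exact
overlap, so bins always sum to totals); the preference index RDI
(relative duration of investigation),

\[
\mathrm{RDI} = \frac{d_1 - d_2}{d_1 + d_2},
\]

where \(d_k\) is the total investigation of stimulus k. The classical
definition takes the absolute value; this package returns the signed
value by default (first-listed stimulus minus second) because testing an
RDI against zero directionally, or correlating it with other signed
quantities, is only meaningful with the sign kept — `signed = FALSE`
recovers the classical index. A second variant, `rdi_by_intervals()`,
applies the same formula to per-stimulus time spent in *prolonged*
intervals (> 20 s); since the preferred stimulus accumulates less
prolonged-interval time, this index runs opposite in sign to the
duration-based RDI across subjects.

Bout durations are histogrammed into `(0, 6]`, `(6, 12.5]`,
`(12.5, 19]`, `(19, Inf)` seconds. The outer edges are the meaningful
short (<= 6 s) and long (> 19 s) classes; a four-category split needs a
middle edge, and 12.5 halves the middle range symmetrically — all edges
are configurable. The first category is right-closed at 6 and the last
left-open at 19 so that boundary readings ("at least" vs "more than")
differ only on measure-zero events. Interval durations use edges
`[10, 20]` s with both counts and total times reported.

The session is split into an *exploration phase* (first 2 min by
default: many transitions, short bouts) and an *interaction phase* (the
rest: few transitions, long bouts, mostly with the preferred stimulus).
Bouts belong to the phase containing their start and are not split,
because bout duration is itself the analysed quantity. Open-field
sessions get total distance (sum of Euclidean steps of the body centroid
between consecutive valid frames, in cm; steps across invalid frames are
skipped) and the center/periphery ratio, with the "inner quarter"
interpreted as the centred rectangle of 25% of the arena's area (sides
scaled by 1/2), the standard open-field convention. `pool_group()`
yields means with SEMs (sample SD over the square root of n) and
Pearson correlations for across-subject scatter pairs.

## The synthetic module

Every claim above is testable without animal data because the package
ships its own ground-truthed data generator, in two layers.

`simulate_behavior()` draws alternating roam/investigate segments with
exponential durations. Rates change once at the phase boundary; each
investigate segment's stimulus is re-drawn with the phase's *transition
propensity* (fresh choice: stim1 with probability `preference`, the
study's preference parameter) and otherwise repeats. A
`recognition_difficulty` knob jointly pushes the propensity toward 1 and
the preference toward 0.5, emulating a subject that cannot discriminate
the stimuli. The defaults (exploration: 2.5-s bouts, 3-s roams,
propensity 0.95; interaction: 8-s bouts, 4.5-s roams, propensity 0.6;
preference 0.75) were fixed once, by distributional calibration against
what a 5-min test of a sociable mouse plausibly looks like: roughly
170 s of total investigation, 30–40 bouts, an exploration-phase per-bin
transition rate about three times the interaction-phase rate, and a tail
of long (> 19 s) bouts late in the session. They are illustrative
defaults, not fitted parameters.

`render_video()` realises a script as video: a dark body ellipse on a
light floor, a brighter tail drawn opposite the nose at an intensity
*between* the two detection thresholds (so the dual-threshold head/tail
logic is genuinely exercised), an optional dark cable from the head to a
fixed anchor, and Gaussian pixel noise. During investigation the nose is
pinned to the target zone with the body oriented into the corner; during
roaming the centre follows a waypoint walk through the central arena.
The per-frame ground-truth log (centroid, head, contact) is computed
from the *rendered* geometry, not the commanded script, so the oracle
stays honest about quantization and pose errors; the log records both
the ellipse centre and the whole-silhouette centroid, the latter being
what a body-based tracker actually measures. Scenario builders provide
targeted probes: a tail-only-contact scenario (the false-interaction
class the head algorithm exists to remove), a parked mouse with a cable
sweeping a zone (the artifact the wired algorithm exists to remove), and
a straight walk of known physical length for distance calibration.

Everything is seeded and deterministic at every level: scripts, labels,
rendered frames and ground-truth logs are reproducible bit for bit.

### What the generator does and does not emulate

The renderer produces hard-edged, constant-illumination scenes with
mild sensor noise. It does not model fur texture, shadows, reflections,
occlusion by the chambers, grooming postures, rearing (which shortens
the apparent body), or background drift. Tests passing on synthetic
video therefore validate the geometry and logic of the pipeline — the
segmentation-to-label path, the event definitions, the metrics — not
robustness to difficult real-world imaging; on real video the detection
thresholds need per-setup tuning, which is why they are config fields.

One structural limitation is worth stating precisely. Because the
simulated preference acts through the per-bout stimulus choice, a
subject's realised transition count and realised |RDI| are functions of
the same random draws: sessions that happen to stick to one stimulus
show both a higher |RDI| and fewer transitions. Transition counts and
preference indices are therefore mechanically anticorrelated across
simulated subjects even with the difficulty knob off (empirically
r is about -0.4 at the defaults). The suite consequently asserts the
knob's *graded* effect — transitions rise and RDI falls as difficulty
increases, and the across-subject correlation under a difficulty
gradient is clearly negative — rather than a zero-correlation null that
this class of generative model cannot produce.

## Numerical and design choices

* Contact inequality closed (<=); declared once, tests depend on it.
* Subject pixels are those at or below the threshold; an `invert` flag
  handles light-on-dark setups.
* Largest-component ties break by previous-centroid distance, then
  lowest label; compartment membership is by centroid point-in-polygon
  with on-edge frames resolved to the lower-indexed compartment.
* Times are frame counts over the frame rate; no sub-frame
  interpolation anywhere, which is what makes every conservation law in
  the test suite exact rather than approximate.
* Default compartments are the two arena halves split by the
  perpendicular bisector of the zone centres, overridable by explicit
  polygons.
* The moment-based ellipse is orientation-stable for elongated masks; a
  circular mask has undefined orientation and downstream code treats the
  endpoints as an arbitrary antipodal pair, relying on the tail/continuity
  disambiguators.
* Degenerate inputs: empty label series are rejected; zero total
  investigation gives a missing RDI rather than 0; a session spent
  entirely in the arena centre gives a missing center/periphery ratio.

## Problem sizes in the test suite

The suite renders its videos at 320 x 240 px and 30 fps — 20-s sessions
for module tests and two 60-s scripted sessions plus wired and scenario
renders for the end-to-end checks — and simulates cohorts of 30–45
subjects (plus a 500-script oracle-identity sweep and 1000 random label
series for the event-extraction equivalence). These sizes keep the full
suite to a few minutes while leaving every assertion exact or
well-resolved; all of them are plain function arguments, so larger
replications are one-liners.

## Known limitations

* Single-animal tracking only; no pose beyond the head/tail axis.
* The head algorithm needs a visible tail or temporal continuity;
  a tailless, stationary first frame is undetermined by design.
* Compressed video containers are out of scope in this implementation;
  the native format is uncompressed image stacks.
* Statistical modelling beyond means, SEMs and Pearson correlations is
  deliberately excluded: the tidy per-session and group tables are the
  interface to any external stats package.
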