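---
title: "Flash-hazard analysis: models, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flash-hazard analysis: models, thresholds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashhazard)
```

## The problem

People with photosensitive epilepsy can have seizures triggered by flashing
video content. Five international guideline families constrain such content
— WCAG 2.x for the web, ISO 9241-391 for displayed imagery, ITU-R BT.1702
and the Ofcom broadcast code for television, and the NHK/JBA rules for
Japanese broadcast — and all agree on the same basic shape of the hazard:
flashing is potentially dangerous only when **three factors coincide**: the
flash magnitude (or a saturated-red color change), the flash rate, and the
flashing area all exceed their critical values. `flashhazard` implements a
harmonized version of these rules as a frame-sequence analyzer, with each
guideline available as a selectable conformance profile, so the same video
can be screened against any or all of them in one pass.

## The analysis model

### Colorimetry

All hazard arithmetic happens in *linear light*. Encoded code values are
expanded with the declared transfer function: the IEC 61966-2-1 piecewise
curve for sRGB; the BT.1886 EOTF (pure 2.4 power, black at zero) for SDR
television; the PQ and HLG curves of BT.2100 for HDR, with nominal peaks of
10,000 and 1,000 cd/m². Relative luminance Y is the weighted sum of linear
channels using the primaries' luminance coefficients (BT.709 weights for
sRGB; BT.2020 weights for wide-gamut and HDR tags), and absolute luminance
is Y times the environment's reference luminance — 200 cd/m² for typical
indoor viewing, 48 cd/m² for the dark-adapted theater preset. Chromaticity
goes through CIE XYZ to the 1976 UCS (u′, v′) plane, where the harmonized
red-flash rule measures color differences. We use the conventional
seven-digit sRGB→XYZ matrix; it reproduces all printed reference
chromaticities to four decimals.

A color is *saturated red* when its linear red channel carries at least 80%
of the linear RGB sum. Black makes that ratio 0/0: we define black as never
saturated red and as having undefined chromaticity, so a harmonized red
transition requires a non-black red state. Whether very dark reds should
additionally require a luminance floor is an open research question; the
harmonized rule has no floor and neither do we, but `red_sat_cut` and the
detection thresholds are configuration hooks. The legacy WCAG 2.0/2.1 red
metric, `max(0, R − G − B) × 320`, is retained as the
`wcag20_legacy_red` profile; it is defined at black, so legacy red
transitions against black are still caught — which is precisely why the
legacy mode flags a superset of the harmonized mode's red violations.

### Viewing geometry

In-frame window math uses the small-angle planar convention — pixels
proportional to visual angle, with the CSS reference pixel (0.0213° at a
Full HD screen viewed from 28 in) as the default scale. Whole-screen solid
angles use the exact on-axis rectangle formula. Two published convenience
constants for the 10° field derive from *different* projections: 470 px is
the exact chord `2·d·tan(5°)` at the CSS reference geometry, while the
416 px equal-area square comes from the linear conversion
(10°/0.0213° × √π/2 = 416.1). They are mutually inconsistent at the
rounding margin under any single projection, so the package exposes each
through the function that matches its derivation: `fh_window_diameter_px()`
(chord; also yields the 235 px diameter of the 0.006 sr disc) and
`fh_equal_area_square_side()` (linear). `fh_degrees_to_px()` stays linear,
which keeps it exactly proportional in the angle.

### Signal extraction

Frames are reduced to an analysis grid of square blocks whose angular size
does not exceed 0.1° (6 arcmin), the largest integer pixel size below that
bound. Block means are taken in linear light; partial edge blocks carry
their true pixel areas. This averaging *is* the fine-pattern exception: a
balanced checkerboard or balanced noise with cells finer than 0.1° has
constant block means and produces no transitions, while an unbalanced
pattern (dark cells flashing on half the area) shifts the block means by
half the cell swing and is flagged. Chroma-subsampled input should be
upsampled to full resolution before analysis — luma alone cannot give
accurate relative luminance. All temporal rules work on timestamps in
seconds, never frame counts, so variable-frame-rate input is handled
naturally and results are frame-rate invariant for waveforms the sampling
resolves.

### Transition detection

A countable luminance transition must (a) meet the critical difference —
at least 10% of the reference luminance (20 cd/m² at reference 200) when
the darker state is below 80% of reference (160 cd/m²), or a Michelson
contrast of at least 1/17 above that for the HDR-capable profiles; (b)
evolve within the qualifying duration; and (c) alternate in direction with
the previous transition. The scan keeps the running extremum since the last
counted transition and counts when the current sample differs from it by
the critical amount within the window, so non-monotonic excursions count on
their *net* change. The leading edge is the sample at which the cumulative
change first meets the threshold; it anchors the synchronicity, spacing and
fast-flash rules.

The qualifying duration ships as the 66 ms working value. A span covers
first-to-last sample, so an N-sample ramp spans N−1 frame intervals; this
reproduces the published frame budgets — up to 2 samples at 30 fps, 4 at
60 fps, and 8 at 120 fps (7 × 8.33 ms = 58.3 ms ≤ 66; one more frame makes
66.7 ms and no longer qualifies). Inequality conventions are fixed once and
used everywhere: magnitude uses ≥ (a 20 cd/m² swing counts), the red u′v′
difference uses > 0.2, and counts use > (more than 6 transitions per
second). The fast-flash rule merges runs whose same-direction leading edges
are 15 ms or less apart — about 65 Hz or faster, a regime of substantially
reduced risk — into two transitions, analyzed once placed at the start of
the run and once at the end, never both at once; the analyzer evaluates
both placements and reports the worse. 15 ms is kept as the normative
value even though 1/65 s is 15.4 ms; it is configurable.

### Area events and thresholds

Transitions of the same kind and direction whose leading edges fall within
the 20 ms synchronicity window (a conservative 50 Hz flicker-fusion bound)
merge into one event with summed area. An area contributes once per event;
if a region flashes twice inside another region's single flash, its second
transition seeds a separate event rather than vanishing into the first.

Windowed area mode slides a circular 10° field over the frame with a stride
of 1/8 window diameter plus a placement at each event's centroid, and takes
the maximum of member-area over visible window area. Window centers are
clamped so the window stays on-screen whenever it fits — a field mostly off
screen sees less flashing, not more; when the window is larger than the
frame it is centered and clipped, and the fraction uses the visible area.
An event is hazardous when some window fraction strictly exceeds 25% (the
0.006 sr disc — 235 px at CSS scale — is exactly at the limit and
compliant). Screen modes compare the summed area against 25% of the frame,
again strictly. The stride bounds the miss for compact stimuli; tests
confirm halving it changes the maximum fraction by well under 3% for
disc-shaped events.

### Counting and verdicts

A flash is a pair of opposite transitions; the shared limit is more than
3 flashes — more than 6 alternating transition counts — in any 1 s span.
Counts are piecewise constant between event edges, so windows anchored at
edges find everything a continuous slide would (verified against a 1 ms
exhaustive slide). Direction alternation is enforced on the aggregate event
sequence per kind, the strictest consistent reading of the provision.
Luminance and red transitions are counted separately, and one physical
change may legitimately count in both.

Profile specifics: `ofcom` and `itu_bt1702` exempt flashes whose leading
edges are at least 334 ms (60 Hz environments; 360 ms at 50 Hz,
configurable) from both neighbours — an isolated flash does not count.
`nhk_jba` classifies luminance events into moderate (10–20% encoded-signal
swing for SDR; 20–40 cd/m² or Michelson 1/17–1/9 for HDR), intermediate
(above those), and scene changes (intermediate magnitude on at least 80% of
the screen, a threshold taken from analysis-tool practice rather than
normative text). Scene changes are limited to 1.5 flashes/s. Moderate
flashing may reach 5 flashes/s, but an episode faster than the 3 flashes/s
base rate — successive transitions closer than 1/6 s — may last at most
2 s; the cap is evaluated as a rolling episode rule since the guideline does
not say whether it is rolling or cumulative. NHK SDR magnitudes are
measured on the gamma-encoded signal (IRE percent), which makes that
profile more tolerant of low-contrast bright flashing and less tolerant of
dark high-contrast flashing than the cd/m²-based rules — the catalog's
150→171 cd/m² fixture fails the other profiles but passes NHK for exactly
this reason. The `iso9241_391` profile does not implement ISO's 65-flash
upper safe harbor; the equivalent protection is provided by the proposed
profile's fast-flash merging, and leaving it out of the ISO profile is the
conservative choice for mixed-rate content.

The extended-failure scan is a clearly non-normative heuristic (the
guidelines mention 5 s cumulative effects but publish no thresholds): a
warning — never a violation — when over a 5 s window at least 80% of frames
participate in flashing at 0.8× the magnitude and area thresholds with at
least 2 flashes/s. All three factors are configuration parameters, and a
hard violation suppresses the warning for the same span.

## The synthetic generator

Every rule path is exercisable without external video. Patterns are
constructed in closed form — gray levels solved to hit exact absolute
luminances, masks rasterized once — and each fixture carries per-profile
expected verdicts derived *at generation time* from the rule definitions
applied to the constructed waveform and masks, never by running the
analyzer. The catalog grids each threshold axis one step below, at, and
above its boundary: rate (1.25–8 Hz), magnitude (10–60 cd/m² and the
19/20/21 boundary), the 160 cd/m² darker-state gate and the 1/17 Michelson
bracket, screen fraction (20/25/30/50%, with 25% exactly compliant),
windowed discs (0.3–0.8 of the window diameter), red pairs (the 12 Hz
red–blue alternation with a 25 cd/m² luminance gap that caused the 1997
broadcast incident; a legacy-only saturated-red pair; chromaticity
differences just below and above 0.2), ramps of 4/5/8/9 samples, 50 and
100 Hz fast flashing, paced flash bursts for the spacing exception, NHK
tier scenarios, and fine balanced/unbalanced checkerboards and balanced
noise. Seeded ±2 ms timestamp jitter variants check window robustness.

The default catalog frame is 192×108 px at 0.1°/px — a 19°×11° field, large
enough to hold the 10° window — with fine-pattern fixtures at 0.025°/px so
analysis blocks span multiple pattern cells; these sizes keep the full
round trip (43 fixtures × 7 profiles) around two minutes on one core while
exercising the same code paths as full-resolution frames. What the
generator does *not* emulate: natural video statistics, camera noise, codec
artifacts, motion (no thresholds exist for motion compensation — flagged
out of scope), or interlacing beyond field-as-frame. A clean round trip
therefore demonstrates rule correctness, not robustness to real-world
footage.

## Numerical choices

Thresholds are compared with exact IEEE comparisons after computing in
double precision, with one exception: the saturated-red cut carries a 1e-9
guard, because a color whose red fraction is exactly 0.8 in exact
arithmetic (the darkest reference red is 8/10 precisely, both channels on
the linear segment) can round one ulp below it in doubles; the generator chooses gray levels as exact doubles, so
boundary fixtures sit exactly on their thresholds. Reference-table matching
in tests uses an absolute tolerance of 5e-5 on four-decimal values; one
printed legacy-value cell appears truncated rather than rounded and gets
0.0075. The window-area denominator is exact (πr²) for interior windows
and strip-integrated for clipped ones. Series deduplication hashes
per-block time series with two independent weighted sums, which collapses
the synthetic patterns' few distinct waveforms and keeps the per-block scan
linear in practice.

## Known limitations

* No video-container decoding: inputs are lossless PNG/TIFF sequences, raw
  planar dumps, or in-memory arrays. Lossy codecs would blur the exact
  threshold boundaries the analyzer is built around.
* Spatial-pattern (grating) thresholds, motion compensation, and real-time
  mitigation are out of scope.
* The per-block grid (≤0.1°) is the analysis resolution; per-pixel analysis
  is available by setting `block_px = 1`, at a cost.
* Published screen-percentage tables for specific devices use an ambiguous
  normalization convention and are deliberately not reproduced.
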