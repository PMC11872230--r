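# flashhazard

Photosensitive-epilepsy (PSE) flash-hazard analysis of video frame
sequences in R.

Flashing video can trigger seizures in people with photosensitive epilepsy.
Five international guideline families constrain such content — WCAG 2.x,
ISO 9241-391, ITU-R BT.1702, the Ofcom broadcast code, and the NHK/JBA
rules for Japanese broadcast — and they share a common structure: flashing
is potentially hazardous only when the **magnitude** of the change (or a
saturated-red color change), the **rate** of flashing, and the **area**
involved all cross their critical values at once. `flashhazard` implements
a harmonized version of this provision as a frame-sequence analyzer, with
each guideline available as a selectable conformance profile, for content
creators, platform screeners and accessibility auditors.

## The core rules

A sequence fails when some 1-second span contains **more than 6
alternating transition counts** (more than 3 flashes) where each counted
transition:

* equals or exceeds the **critical transition difference** — 10% of the
  reference luminance (20 cd/m² at the 200 cd/m² indoor reference) when
  the darker state is below 80% of reference (160 cd/m²), or a Michelson
  contrast `(L_hi − L_lo)/(L_hi + L_lo) ≥ 1/17` above it; a **red
  transition** instead needs a saturated-red state (linear
  `R/(R+G+B) ≥ 0.8`) and a CIE 1976 UCS chromaticity difference
  `Δu′v′ > 0.2`;
* is of **qualifying duration** — evolves over at most 66 ms (up to 2
  samples at 30 fps, 4 at 60 fps, 8 at 120 fps);
* belongs to a synchronized area event — same-direction transitions with
  leading edges within **20 ms** are summed — whose area exceeds **25% of
  some 10° visual field** (0.006 sr; a 235 CSS-px disc is exactly at the
  limit) or 25% of the screen, depending on the profile;
* is not part of a **fast flash** run (same-direction edges ≤ 15 ms apart,
  ≈65 Hz or faster), which merges to two transitions.

All colorimetry is done in linear light (IEC 61966-2-1 sRGB, BT.1886,
BT.2100 PQ/HLG transfer functions), and all temporal rules operate on
timestamps, so variable frame rates are handled directly.

## Worked example

The most notorious PSE trigger on record is a 12 Hz alternation between
large red and blue fields with only a ~25 cd/m² luminance difference. The
synthetic generator reproduces it, and the analyzer flags it under every
profile:

```r
library(flashhazard)

env  <- fh_env(192, 108, px_angular_size = 0.1)   # a 19 x 11 degree field
spec <- fh_pattern("red_blue", rate = 12, duration = 1, fps = 60)
gen  <- fh_generate(spec, env)
report <- fh_analyze(gen$frames, env)
report
#> <fh_report> 60 frames 192x108 [sRGB], 0.98 s, block 1 px
#>   proposed           FAIL  (34 violations, 0 warnings)
#>   wcag2x             FAIL  (34 violations, 0 warnings)
#>   wcag20_legacy_red  FAIL  (34 violations, 0 warnings)
#>   iso9241_391        FAIL  (34 violations, 0 warnings)
#>   itu_bt1702         FAIL  (34 violations, 0 warnings)
#>   ofcom              FAIL  (34 violations, 0 warnings)
#>   nhk_jba            FAIL  (17 violations, 0 warnings)

head(report$results$proposed$violations[,
       c("kind", "t_start", "t_end", "count", "flash_equiv")], 4)
#>        kind    t_start    t_end count flash_equiv
#> 1 luminance 0.05000000 1.050000    23        11.5
#> 2 luminance 0.08333333 1.083333    22        11.0
#> 3 luminance 0.13333333 1.133333    21        10.5
#> 4 luminance 0.16666667 1.166667    20        10.0
```

Each violation row is a 1-second window: 23 alternating full-field
luminance transitions in `[0.05, 1.05)` is a flash equivalent of 11.5 —
nearly four times the limit of 3 flashes per second. The same sequence
also fails on red transitions (`kind == "red"` rows), since red↔blue is a
saturated-red color change of Δu′v′ ≈ 0.46. The generator's ground truth
(`gen$truth$expected_violation`) agrees with the analyzer for every
profile; the test suite round-trips a 43-fixture catalog that grids every
threshold boundary this way.

Colorimetric helpers are usable on their own:

```r
lin <- fh_linearize(fh_hex("#FF8800"))
fh_red_fraction(lin)                  # 0.8024386  (saturated red: >= 0.8)
fh_wcag20_critical_value(lin)         # 241.2156   (legacy WCAG 2.0 metric)
fh_chromaticity(lin)[c("u", "v")]     # u' = 0.3091, v' = 0.5401
```

Files are analyzed via `fh_read_input()` (PNG/TIFF sequences with a
`timing.json` sidecar, or raw planar dumps), and there is a thin CLI in
`inst/cli/analyze.R` (exit code 0 = pass, 2 = violations, 1 = error) plus
`inst/cli/generate-fixtures.R` to write the synthetic catalog to disk.

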