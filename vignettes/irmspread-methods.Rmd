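---
title: "Quantifying platelet adhesion dynamics in IRM time-lapse: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying platelet adhesion dynamics in IRM time-lapse: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmspread)
```

## The measurement

Interference reflection microscopy (IRM) images the interference between
light reflected at the coverslip and at the cell membrane. The practical
reading is monotone over the working range: the closer the membrane is to
the substrate, the darker the pixel. A time-lapse IRM movie of a platelet
settling on an adhesive protein therefore records, pixel by pixel, where
and when the cell touches the surface.

The spreading sequence this package quantifies has four behavioural
phases: the platelet first *hovers* above the substrate (visible as a
bright, out-of-focus blob), then probes it with thin filopodia whose tips
*tap* — attach and release with a period of roughly 5–10 s — then commits
to *lamellipodial* growth of a contact zone, and finally sits *fully
spread* with a stable footprint.

Everything below operates on a raw intensity array `H × W × T` plus a
frame interval in seconds. Intensities are never rescaled on load: the
segmentation and the event thresholds act on pooled raw intensities, and
any normalization would silently change them. Time is always
`(frame − 1) × frame_interval`.

## Focal activity

The focal activity map is the signed difference of consecutive frames,

$$\Delta \mathrm{IRM}_t = \mathrm{IRM}_t - \mathrm{IRM}_{t+1},$$

so a pixel that darkens (moves closer) between `t` and `t+1` scores
positive — local attachment — and one that brightens scores negative —
local detachment. Two deliberate choices:

* **Mean, not sum.** The integrated tapping activity of a frame is the
  *mean* absolute Δ over the bounding box. A sum would scale with the box
  the annotator happened to draw; the mean is comparable across boxes,
  although extra background pixels still dilute it, which is why traces
  from differently-padded boxes should not be compared in magnitude.
* **No division by the frame interval.** Δ is reported in intensity
  units per frame, not per second; the interval is carried alongside.
  Dividing would suggest a derivative that frame-differencing at 5 s
  does not actually resolve.

Block binning (`bin_activity()`, default 3 × 3 pixel tiles, ragged edges
averaged over the pixels they contain) is a smoothing device for
collecting local statistics and rendering; the numeric traces are
computed on the unbinned map.

The map obeys three exact identities that the test-suite checks on random
stacks: time reversal negates and reverses it; constant intensity offsets
cancel; and the per-pixel sum over time telescopes to
`frame_1 − frame_T`.

## Surface-interaction segmentation

Pixels "interacting with the surface" are segmented with a single Otsu
threshold per movie, computed from the pooled histogram of all ROI
intensities across all frames. Pooling is the crux: a per-frame threshold
would drift with the spreading state and make interaction areas
incomparable between frames. The implementation:

* integer-valued data with ≤ 256 distinct levels uses unit bins at its
  native levels; wider integer ranges and float data use 256 equal-width
  bins over the pooled min–max range, half-open edges;
* the split maximizes between-class variance; ties break toward the
  smallest threshold; the returned threshold is a bin edge;
* foreground is strictly `intensity < threshold` — pixels exactly at the
  threshold are background. The strictness is arbitrary but must be fixed
  somewhere; strict-less keeps a perfectly bimodal `{0, 255}` pool
  labelling exactly the zero class as foreground.

The pooled histogram is computed over the ROI crop, not the full field,
so a neighbouring platelet cannot shift the threshold.

From the mask follow the interaction-area curve (foreground count per
frame) and the transition map: for each pixel, the number of
interaction → no-interaction switches accumulated from the movie start.
Only losses are counted — the complementary gain count differs from it by
at most one and is derivable. On a monotonically growing contact, the map
accumulates only at the advancing edge where ramping pixels cross the
threshold; matured interior contact, many noise standard deviations below
threshold, stays at zero.

### When there is nothing to segment

Otsu always returns *some* split. On a movie with no surface contact —
pure noise, or a platelet hovering as a bright blob — the split lands
inside the background distribution and the darker *majority* class would
be reported as "interacting", which is nonsense. `analyze_platelet()`
therefore applies a plausibility guard before using the mask: the
foreground must be a minority class (≤ 50% of pooled pixel-frames) whose
mean lies at least 4 background-class standard deviations below the
background-class mean. A symmetric noise split separates the class means
by only ≈ 1.6 pooled sd (≈ 2.7 background-class sd), so it is rejected
with margin, while genuine contact — tens of intensity units dark — passes
easily. When the guard rejects, the analysis reports `contact_detected =
FALSE` and a zero interaction area. The low-level
`pooled_otsu_threshold()` / `interaction_mask()` functions stay pure and
never apply the guard.

## Attach/detach event classification

The background model pools Δ values from a manually marked empty box near
the platelet, across all frames including pre-attachment ones, and
summarizes them by mean and standard deviation (population divisor `n`;
with thousands of pooled values the `n` vs `n−1` choice is numerically
immaterial but is fixed for exactness). Active pixels are those whose Δ
strictly exceeds `mean + k·sd` (attaching) or falls below `mean − k·sd`
(detaching), with `k = 1` by default. No multiple-testing machinery is
involved — this is a plain threshold rule, and on pure Gaussian noise it
flags `2Φ(−1) ≈ 31.7%` of pixel-frames by construction; that analytic
value is one of the package's self-checks.

Per-frame attach/detach fractions are normalized by the *active* count,
so the two series are exact complements and a frame with no active pixel
is `NA`, never `0/0`. A per-box-pixel normalization is available
(`denominator = "roi"`) but non-default. A zero-variance background pool
triggers a warning, since every nonzero Δ then becomes active.

## Cohort kinetics

* **Attachment curve**: `100 × #(attachment_time ≤ t) / n` per substrate
  — a scaled empirical CDF; censored platelets carry their observation
  horizon and never count as attached. Whether "attachment" means first
  contact or immobilization is an annotation-level decision; when no
  manual call is available, a documented surrogate is used: the first
  frame from which the interaction area stays ≥ 20 px for 3 consecutive
  frames.
* **Phase durations**: differences of annotated stage frames times the
  frame interval; absent stages give `NA`, never zero.
* **Endpoint fractions**: proportions over
  `no_attach / filopodial / fully_spread`, reported with the group size.
* **Wilcoxon rank-sum**, two-sided. The statistic is the rank sum of
  group 1 with midranks under ties. For pooled `n ≤ 12` the p-value comes
  from full enumeration of all `C(n, n1)` group assignments of the
  observed ranks — enumeration handles ties exactly, which is why the
  exact branch is not restricted to tie-free data (identical samples give
  exactly p = 1). Larger samples use the normal approximation with tie
  and continuity corrections plus an Edgeworth kurtosis term: the
  rank-sum null is platykurtic
  (`γ₂ = −(6/5)(n₁² + n₂² + n₁n₂ + n₁ + n₂) / (n₁n₂(n+1))`, verified
  against enumerated fourth moments), and without the term the
  approximate tail misses the exact one by up to 0.022 at the enumeration
  boundary; with it the worst gap over all rank configurations at pooled
  n = 12, splits 3–9, is 0.003. In the far tail, where the Edgeworth
  expansion can turn negative, the plain normal tail is used as a floor.

## The synthetic movie generator

`simulate_movie()` exists so that every estimator in the package has a
recoverable target. It is a *phenomenological* generator: a two-level
proximity proxy (touching vs not), not an interference model — IRM fringe
physics is out of scope, and the analysis consumes only monotone
darker-is-closer contrast.

One movie is assembled per frame as
`background + noise + hover blob − contact darkening + membrane jitter`,
clipped to `[0, 255]`:

| parameter | default | why |
|---|---|---|
| image, interval | 64 × 64 px, 1 s | 5–10 s tapping needs ≥ 2 samples per half-period; 1 s leaves margin. A 5 s interval emulates typical acquisition and pushes tapping to the Nyquist limit (aliasing is then expected and demonstrable). |
| phase durations | hover 20 s, filopodial 60 s, lamellipodial 60 s, plateau 40 s | tens of seconds to minutes, scaled to keep a movie at 180 frames |
| background | mean 100, noise sd 5 | mid-range of an 8-bit-like scale with a realistic SNR |
| contact darkening | 60 | contact sits ≈ 6 noise-sd below any sensible pooled threshold, so segmentation errors are structural, not sensor-driven; the config validator enforces `darkening > 2 × noise sd` |
| hover blob | amplitude 1.5 noise-sd, Gaussian, σ = half max radius | visible out-of-focus brightening that can never cross to the dark foreground side |
| filopodia | 6 radial segments, 12 × 2 px, staggered onsets over the first half of the phase | staggering makes the tapping activity *rise gradually* through the filopodial stage rather than switch on |
| tapping periods | uniform in [5, 10] s per filopodium, square-wave contact | the observed oscillation band |
| lamellipodial growth | logistic ODE `dr/dt = k·r·(1 − r/r_max)` from r₀ = 4 px to r_max = 15 px, rate set so 98% of r_max is reached at phase end | the base disk appears at the onset (an organized contact zone), growth is appreciable immediately and saturates — the sigmoid-in-time parameterization was rejected because it is flat exactly at the onset the estimators must find |
| contact maturation | new lamellipodial contact darkens linearly over 10 s | young contact is shallower than matured contact; this also makes the advancing edge, and only the edge, flicker across the Otsu threshold |
| membrane jitter | extra sd 6 on touching pixels | residual membrane fluctuation; it keeps the fully-spread plateau's activity measurably above the pre-attachment baseline, as real traces show |
| arrest probability | 0 (collagen-like), 0.57 (fibrinogen-like) | the fraction of platelets that never make the filopodial-to-lamellipodial switch on a poorly activating surface |

Ground truth records the geometric contact mask per frame, phase onset
frames, per-filopodium periods and masks, and the final footprint area.
Everything is drawn inside `withr::with_seed(cfg$seed, ...)`: one seed,
one bit-identical movie.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: interference fringes and
non-monotone contrast, stage drift and focus wander, illumination
gradients, neighbouring platelets entering the box, camera-specific noise
(the defaults were chosen for comfortable SNR, since no noise statistics
were available to copy), platelet aggregation, and flow. The one known
cosmetic artefact of the jitter model: on the default presets an interior
contact pixel occasionally (p ≈ 6 × 10⁻⁵ per pixel-frame) flickers above
the threshold, so transition maps may carry a handful of isolated interior
counts; the zero-interior invariant is exact for jitter-free movies.

## Curve-based estimators

**Lamellipodial onset** (`estimate_lamellipodia_onset()`): during the
filopodial stage the interaction area oscillates — every tapping release
is a sharp drop — while the lamellipodial stage begins with an organized
contact zone and monotone growth. The estimator takes the last drop of at
least `min_drop` px (default 12, about half a filopodium footprint),
searches the following `search_window` frames (15, longer than the
longest tapping period) for the last single-frame gain of at least
`min_jump` px (35, below the smallest base-disk footprint but above
simultaneous filopodium re-attachments), and confirms the candidate by
requiring the mean area over the following 20 frames to exceed the
preceding 20 by at least `min_rise` px. Arrested or contact-free movies
fail the confirmation and return `NA`.

**Tapping period** (`estimate_tapping_period()`): the lagged
autocorrelation of a filopodial-region area trace peaks at the tapping
period. Two details matter on short traces. First, each lag uses the
direct correlation of the overlapping segments; the windowed-acf
convention divides by the full trace length and damps exactly the lags a
5–10 s period lives at, which can hand the maximum to lag 1. Second, a
period that is not a whole number of frames (5.5 s at 1 s sampling) is
exactly periodic only at *twice* its length, so the raw argmax finds the
first harmonic; when the best lag shows a clearly positive correlation
(> 0.3) at half its value, the half-lag is taken. True integer periods
are safe: their half-lag sits in antiphase and correlates negatively.

**Final area**: mean interaction area over the last 5 frames.

## Problem sizes and determinism

The recovery checks run 20 collagen-like movies of 180 × 64 × 64 and
recover the lamellipodial onset within ±1 frame (tolerance ±2), final
contact area within ~1.1% (tolerance 5%), and all 120 tapping periods
within ±0.6 frames (tolerance ±1). The analytic active-fraction check
uses a 201-frame pure-noise movie; the cohort power check runs 200
replicates at group sizes 274 vs 121. These sizes were chosen so the full
suite completes in well under a minute per module while leaving each
tolerance an order of magnitude of slack. All stochastic tests fix their
seeds; `simulate → analyze → write` is byte-deterministic, which the
suite asserts on file hashes.

## Known limitations

* The no-contact guard assumes contact occupies at most half of the
  bounding box across the pooled movie; a box drawn so tight that
  contact dominates the pool from frame 1 would be rejected as
  guard-failing rather than segmented.
* The onset estimator is built for the filopodial-then-lamellipodial
  script; movies that skip tapping entirely still work (the drop scan
  finds nothing and the jump scan starts at frame 1), but gradual
  contact growth without any organized onset returns `NA` by design.
* `wilcoxon_rank_sum()`'s Edgeworth term uses the tie-free kurtosis; under
  extreme ties (very few distinct values) the approximate branch inherits
  a small additional error, while the exact branch is unaffected.
* Non-uniform frame intervals are rejected, not interpolated; flat-field
  or drift correction is out of scope and should precede the pipeline.
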