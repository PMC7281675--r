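# irmspread

Quantification of single-platelet adhesion dynamics from interference
reflection microscopy (IRM) time-lapse movies.

## The problem

When a platelet lands on an adhesive surface (collagen IV, fibrinogen) it
does not simply stick: it hovers, probes the substrate with thin filopodia
that tap on and off with a period of roughly 5–10 s, and only then commits
to lamellipodial spreading until it is fully spread. IRM reports the
membrane–substrate distance as image intensity — **darker is closer** — so
a time-lapse IRM movie contains the whole story, but extracting it needs
pixel-level bookkeeping rather than eyeballing. `irmspread` is that
bookkeeping, for experimentalists quantifying spreading kinetics at the
single-cell and cohort level.

## The measures

For a movie `IRM_t` (frame interval Δt, default 5 s) cropped to a
platelet's bounding box:

* **Focal activity map** — `ΔIRM_t = IRM_t − IRM_{t+1}`. Positive values
  mean the next frame is darker there: local attachment. Negative values:
  local detachment.
* **Integrated tapping activity** — `mean_i |ΔIRM_t|_i` over the box
  pixels `i`: one scalar per frame integrating attachment and detachment
  flux. It rises through the filopodial stage, peaks, and decays to a
  plateau above the pre-attachment baseline.
* **Surface interaction** — one Otsu threshold computed from the pooled
  intensity histogram of the whole movie; pixels strictly below it are
  "interacting with the surface". Per-frame foreground counts give the
  interaction-area curve; per-pixel counts of interaction→no-interaction
  switches give the transition map, which highlights unstable peripheral
  contacts ("veins") while stable interior contact stays at zero.
* **Attach/detach events** — ΔIRM values in an empty background box are
  pooled over the movie; pixels whose ΔIRM exceeds `mean ± k·sd` (default
  k = 1) are the active pixels, split into attaching and detaching, and
  reported as per-frame fractions of the active set.
* **Cohort kinetics** — attachment-percentage curves over time (a scaled
  empirical CDF), filopodial/lamellipodial phase durations from annotated
  stage time points, endpoint-class fractions, and two-sided Wilcoxon
  rank-sum comparisons (exact by enumeration for pooled n ≤ 12).

A synthetic IRM movie generator (`simulate_movie()`, presets
`collagen_like`, `fibrinogen_like`, `background_only`) produces movies
with full ground truth — contact masks, phase onsets, tapping periods —
so every stage of the pipeline is verifiable by recovery without raw
microscopy data.

## Worked example

```r
library(irmspread)

sim <- simulate_movie(scenario_preset("collagen_like", seed = 4))
an  <- analyze_platelet(sim$sequence, sim$roi, sim$background)
print(an)
#> platelet_analysis
#>   Otsu threshold: 70.96057 (contact detected)
#>   final interaction area: 708.6 px
#>   attachment frame: 26, lamellipodial onset frame: 81
```

The ground truth behind this movie has its lamellipodial onset at frame 81
and a final contact footprint of 716 px, so the curve-based estimates are
exact on the onset and within ~1% on the area. The attach fraction
exceeds the detach fraction in 85% of lamellipodial-phase frames — the
sustained attachment dominance characteristic of spreading — whereas on
an arrested, cycling platelet the two fractions stay balanced near 0.5.

Cohort-level comparison of attachment speed (group sizes as in a typical
two-substrate experiment):

```r
co <- simulate_attachment_cohort(seed = 2)   # 274 collagen-like, 121 fibrinogen-like
wilcoxon_rank_sum(
  co$attachment_time[co$substrate == "collagen_iv" & co$attached],
  co$attachment_time[co$substrate == "fibrinogen"  & co$attached])
#> Wilcoxon rank-sum: W = 49226 (n1 = 274, n2 = 121), p = 1.2e-06
```

A thin command-line front-end with `simulate`, `analyze` and `cohort`
subcommands is installed under `inst/cli/irmspread.R`.

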