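---
title: "Nocturnal oximetry indices: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nocturnal oximetry indices: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Overnight pulse oximetry (NOx) is a widely used screening test for
obstructive sleep apnea syndrome (OSAS) in children: obstructive apneas and
hypopneas during sleep produce recurrent arterial oxygen desaturations that a
finger oximeter records as dips in SpO₂. This package computes, from a raw
overnight SpO₂ series, the standard screening indices — the oxygen
desaturation indices ODI3 and ODI4 and the four-level McGill oximetry score
(MOS) — together with two indices that need no event cutoffs at all: the
cumulative saturation area (CSA), a summary of the SpO₂ value distribution,
and the SpO₂ sample entropy (SSE), a regularity measure of the time series.
This vignette is the package's own account of the underlying models, the
parameters that matter, and the design choices made where published
definitions run out.

## The recording model

A recording is a uniformly sampled SpO₂ series (percent, one value per
`sample_interval_s` seconds; consumer oximeters typically store one 4 s
averaged value) with a per-sample validity mask and a half-open sleep window.
Three principles govern everything downstream:

* **values are masked, never altered** — missing, non-numeric and
  out-of-range samples stay in place with `valid = FALSE`, so the series
  keeps its uniform spacing;
* **only the sleep window is analyzed** — awake time at either end, as noted
  by a caregiver, is trimmed with `trim_to_sleep()`;
* **quality gates precede interpretation** — a recording qualifies when the
  analyzed window lasts at least 6 h and fewer than 2.5% of its samples are
  invalid (`quality_check()`; both thresholds configurable). Index
  denominators ("per hour") use *valid* analyzed time, which keeps ODI well
  defined when a small fraction of samples is rejected.

Artifact identification itself is assumed to happen upstream (oximeters
reject poor-quality beats themselves and exports carry a quality flag). The
reader additionally masks impossible values, and an optional
implausible-jump rule (`max_jump_pct`) is available but disabled by default:
at 4 s resolution a genuine severe desaturation onset can move several
percent per sample, so a jump filter is not a safe default.

## Desaturation events, ODI, clusters and the McGill score

A desaturation event is a drop of at least 3% (ODI3) or 4% (ODI4, MOS) from
*baseline* lasting at least 10 s. Published definitions leave the baseline
construction open, so it is an explicit model here: `track_baseline()`
computes a trailing rolling maximum (default window 120 s) of valid SpO₂ —
the stable saturation level the subject keeps returning to — or,
alternatively, a trailing percentile. The rolling maximum follows slow
drifts but does not follow dips shorter than its window, which is exactly
the behavior wanted from a reference level for "drop from baseline".
Cutoffs derived under one baseline convention do not automatically transfer
to another; the convention is therefore configurable and stamped into
analysis output.

`detect_desaturations()` finds maximal runs of valid samples at or below
`baseline − threshold`. Three discreteness rules matter at 4 s sampling:

* **duration**: "at least 10 s" means at least `ceiling(10/4) = 3`
  consecutive samples (12 s), since 2 samples cover only 8 s;
* **invalid gaps**: gaps of invalid samples up to `max_gap_s` (default 30 s)
  inside a run are bridged; longer ones split it. Bridged samples count
  toward the event span but never provide the nadir;
* **resaturation**: runs separated by less than `min_separation_s`
  (default 10 s) of valid above-threshold signal are one event. A 1-sample
  (4 s) bounce above the threshold inside a deep desaturation is
  quantization noise, not a recovery; without this rule such a bounce can
  split one deep event into two 4% events while the 3% run stays whole,
  yielding the nonsensical ODI4 > ODI3 on real-looking signals. With the
  rule, ODI4 ≤ ODI3 holds on all simulated cohorts we generate, though it
  remains a statistical regularity rather than a theorem: a 3-sample bounce
  inside the 1% band between the two thresholds would still split only the
  4% run.

ODI is the event count divided by valid analyzed hours. A desaturation
*cluster* is at least 5 events within a 10–30 min study period; groups are
formed greedily left to right over the ordered events, a group closing when
adding the next event would stretch its span beyond 30 min. A burst tighter
than 10 min still counts (its reported window is floored at 10 min):
excluding *denser* clusters would be clinically perverse. The McGill score
then follows the standard rule table over 4% events: score 1 with fewer than
3 clusters; scores 2/3/4 with at least 3 clusters and at least 3 event
nadirs below 90/85/80% respectively (each rung also requiring no nadir below
the next level down). Nadir counts are taken anywhere in the record — the
printed criteria do not restrict them to cluster membership — and "below
90%" is a strict inequality on the nadir.

## Cumulative saturation area

The CSA summarizes the SpO₂ *distribution*. Valid sleep-window samples are
binned at 1% width anchored on integers (a value $v$ falls in bin
$\lfloor v \rfloor$, matching the integer-percent granularity of device
output); with $F(s)$ the ascending cumulative relative frequency in percent
over bins, the CSA is the rectangle-rule area under the cumulative frequency
line from the lowest occupied bin $s_{min}$ to 100:

$$\mathrm{CSA} = \sum_{s = s_{min}}^{100} F(s).$$

The published description ("area under the cumulative frequency line")
admits several integration schemes; this construction is the one consistent
with the stated minimum — exactly 100 when every sample is 100% — and with
the index's published correlations (negative with mean SpO₂, positive with
SpO₂ SD). Every sample in a lower bin adds area: all samples at 99% give
200, all at 95% give 600. Lowering any sample's value can only increase (or,
within a bin, leave unchanged) the CSA. Bin width and anchoring are
configurable but non-default settings are unvalidated.

## SpO₂ sample entropy

SSE is the sample entropy of the valid SpO₂ series: with $B$ the number of
pairs of length-$m$ templates agreeing within Chebyshev tolerance $r$
(self-matches excluded) and $A$ the pairs still agreeing at length $m+1$,

$$\mathrm{SSE} = -\ln(A/B), \qquad r = \max(r_{\mathrm{factor}} \cdot SD,\; r_{\mathrm{floor}}).$$

Defaults are the reference-implementation conventions $m = 2$,
$r = 0.2 \cdot SD$, $r_{\mathrm{floor}} = 0$. Because device output is
integer-quantized, any tolerance in $(0, 1)$ reduces to exact symbol
matching — worth keeping in mind when comparing absolute SSE values across
devices with different resolution; a nonzero `r_floor` (e.g. 0.15%) is
exposed for near-constant signals. Degenerate cases are kept finite on
purpose: a constant series returns 0, and when no length-$(m+1)$ pair
matches ($A = 0$) the finite upper bound $-\ln(1/(B+1))$ is returned with an
`upper_bounded` attribute rather than infinity, so downstream ROC analysis
stays well defined. Invalid samples are dropped and the remaining series
concatenated; at the artifact rates the quality gate admits (< 2.5%) the
spliced transitions are negligible. The O(N²) pair count runs in compiled
code and is verified against a naive matrix-based implementation to 1e−12.

## Paired evaluation

`wilcoxon_paired()` tests pre/post change per index: zero differences are
dropped (classical convention), the exact null distribution is used up to 25
untied non-zero differences, otherwise the normal approximation with
continuity correction; an all-zero contrast returns a flagged degenerate
result with p = 1. `roc_with_youden()` treats one visit as
condition-positive and reports the trapezoidal AUC, a DeLong 95% CI
(default; a stratified bootstrap is available — DeLong is chosen as default
because it is deterministic), and the cutoff maximizing Youden's index
(sensitivity + specificity), ties broken toward higher specificity because a
positive screen is typically confirmed downstream. Reported cutoffs are
midpoints between adjacent observed values (">x" semantics). When post
recordings of the same subjects serve as controls the 2n observations are n
correlated pairs; the AUC is computed ignoring the pairing, as is
conventional for this design, and `spearman_matrix()` (average-rank ties,
`NA` for constant columns) covers the correlation analyses.

## The synthetic recording generator

No clinical recordings ship with the package; every end-to-end claim is
exercised on `generate_recording()` / `generate_paired_cohort()` output with
known ground truth. The generative model is deliberately phenomenological:

* a stable per-subject baseline (pre-operative profile ≈ 96.5%,
  post-operative ≈ 98.2%) plus a slow random-walk drift
  (0.3%/√h) and white sensor noise (SD 0.4%), rounded to integer percent
  *after* summing, mimicking device quantization;
* desaturation events as trapezoidal dips — one ramp sample down, a
  full-depth plateau of at least 12 s (guaranteeing 3 qualifying samples at
  4 s), one ramp sample up — with shifted-exponential depths (min 3%, scale
  2.5% pre / 0.7% post, so roughly two-thirds of pre-operative events exceed
  4%) and Poisson placement at the configured ground-truth rate;
* a configurable fraction of events (0.6 pre / 0.3 post) concentrated in
  periodic REM-like burst windows (10 min wide, every 90 min), which is what
  produces desaturation clusters; events keep at least 12 s apart so
  distinct events are never merged by the resaturation rule, and an event
  that cannot fit in a full burst window spills over to uniform placement;
* random invalid samples at the configured artifact rate (drawn per subject
  in 0.1–1.8%);
* per-subject event rates log-normal (pre: median 15/h, clamped to 3–55/h;
  post: median 1.3/h, clamped to 0.2–4.5/h), and a shared subject-level
  baseline offset (SD 0.5%) across both visits so paired tests are
  meaningfully paired.

These settings reproduce the cohort envelopes reported for pre/post
adenotonsillectomy populations for mean SpO₂, SpO₂ SD, ODI3/ODI4, the MOS
distribution and (approximately) CSA. Identical configuration and seed
reproduce a recording bit for bit.

**What the generator does not emulate.** Real severe-OSAS traces are
irregular almost everywhere: ventilatory instability keeps SpO₂ swinging
between scored events, which is precisely what a sample entropy picks up.
This generator confines irregularity to the carved events over a stationary
noise floor. Consequently, while synthetic SSE moves in the right direction
with severity (its medians increase strictly across event rates 0, 5, 15,
40/h under matched noise realizations), the pre/post SSE *contrast* on
synthetic cohorts is far smaller than on published clinical data (synthetic
≈ 0.72 vs 0.63; published ≈ 1.46 vs 0.58), and SSE's discriminative
performance on synthetic cohorts (AUC ≈ 0.71) understates its reported
clinical performance (AUC 1.00). We experimented with severity-coupled
sub-threshold oscillations and serially correlated noise: any fluctuation
deep enough to move pooled entropy materially also crosses the detection
threshold (the rolling-max baseline rides the noise peaks, leaving only
about 2% of headroom below a 3% criterion) and corrupts the detector's rate
calibration, which we refuse to trade away. Passing simulation tests
therefore validate the *implementations* and the direction of each index's
severity response — not the clinical effect sizes of SSE.

## Numerical and testing choices

* Problem sizes: detector-versus-oracle equivalence on 1000 random short
  recordings (≤ 200 samples); SampEn oracle equivalence on 100 series of
  length 300; severity grid {0, 5, 15, 40}/h × 50 matched seeds of 6 h
  recordings; one default paired cohort of 45 subjects (90 recordings).
  Matched seeds across severities are plain variance reduction for a
  simulation contrast.
* Detected-vs-true ODI3 regression slope is required in [0.85, 1.05]:
  detection may miss events whose depth sits at the quantization margin
  (drawn depth just above 3% can round to a 2% step below the tracked
  baseline), so slightly-below-unity slopes are expected behavior, not bugs.
* With zero injected events, detected ODI3 stays below 1/h in ≥ 95% of
  seeds: at 0.4% noise, three consecutive samples 3% below the tracked
  maximum are vanishingly rare.
* Reference screening cutoffs (ODI3 > 3.6/h, ODI4 > 2.2/h, CSA > 293,
  SSE > 0.99) ship in `nox_config()` as cohort-derived conveniences. They
  were derived on one clinical cohort with one device and — for SSE — under
  unpublished SampEn parameters; they are defaults to report against, not
  validated thresholds.

## Known limitations

* The baseline tracker is this package's convention; device software may use
  event-locked baselines or resaturation criteria that shift ODI values.
* CSA's integration scheme is pinned down here only up to the published
  constraints; other schemes (trapezoid, descending cumulation) are
  switchable but change absolute values.
* SSE on integer-quantized data is a symbolic entropy; comparisons across
  devices with different storage resolution or averaging are not meaningful
  without recalibration.
* The simulator's SSE limitation described above: synthetic cohorts are a
  correctness harness, not a clinical validation, and SSE's synthetic
  discrimination understates its published clinical discrimination.
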