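# noxi — nocturnal pulse-oximetry indices for pediatric sleep-apnea screening

Overnight pulse oximetry (NOx) is a simple, home-friendly screening test for
obstructive sleep apnea syndrome (OSAS) in children: obstructive events
during sleep cause recurrent drops in oxyhemoglobin saturation (SpO₂) that a
finger oximeter records. `noxi` takes a raw overnight SpO₂ series and
computes both the standard screening indices and two cutoff-free ones:

* **ODI3 / ODI4** — oxygen desaturation indices: events with an SpO₂ drop of
  ≥ 3% (resp. ≥ 4%) from a tracked baseline lasting ≥ 10 s, per hour of
  valid analyzed sleep;
* **MOS** — the four-level McGill oximetry score, from desaturation clusters
  (≥ 5 events in a 10–30 min period) and event nadirs below 90/85/80%;
* **CSA** — cumulative saturation area: with SpO₂ values binned at 1% and
  F(s) the ascending cumulative relative frequency (in %) of bins ≤ s,
  `CSA = Σ F(s)` from the lowest occupied bin to 100. Equals 100 when every
  sample is 100% and grows as saturation mass shifts downward;
* **SSE** — SpO₂ sample entropy `SampEn(m = 2, r = 0.2·SD)`:
  `−ln(A/B)`, where B counts template pairs of length m within Chebyshev
  tolerance r and A those still matching at length m + 1. Low for regular
  traces, high for traces with frequent fluctuation.

Around these, the package provides quality gating (≥ 6 h analyzed sleep,
< 2.5% artifacts), paired pre/post statistics (Wilcoxon signed-rank), ROC
analysis with DeLong or bootstrap CIs and Youden-optimal cutoffs, Spearman
correlation matrices, and a synthetic overnight-recording simulator with
ground-truth event annotations so that every stage is testable without
clinical data. It is aimed at sleep researchers and biosignal methodologists
working with raw oximetry exports (CSV or single-channel EDF).

## Worked example

Simulate one pre-operative-profile night (6.5 h at 4 s sampling, 17 injected
qualifying desaturations per hour) and summarize it:

```r
library(noxi)
g <- generate_recording(simulation_config(duration_h = 6.5, event_rate_per_h = 17),
                        seed = 42, subject_id = "demo", visit = "pre")
summarize_recording(g$recording)
#> <nox_summary> demo (pre)
#>   6.50 h analyzed, 0.34% artifact (pass)
#>   SpO2 95.4 +/- 2.05 %; ODI3 15.75/h; ODI4 15.28/h; MOS 3
#>   CSA 563.8; SSE 0.622
g$truth$true_rate_per_h
#> [1] 15.69
```

The detector recovers the simulated ground-truth rate (15.75/h detected vs
15.69/h injected). The quality gate passes (6.5 h, 0.34% artifacts); the MOS
of 3 reflects ≥ 3 desaturation clusters with ≥ 3 nadirs below 85%; the CSA
of 564 is far above its all-100% minimum of 100, consistent with a mean SpO₂
of 95.4% and SD of 2.1%.

A paired cohort (each subject recorded before and after adenotonsillectomy,
the post visit serving as the normal control class):

```r
co <- generate_paired_cohort(12, seed = 7)
nox_evaluate(summarize_cohort(co))
#> <nox_evaluation> 12 paired subjects
#> Wilcoxon (pre vs post):
#>  parameter statistic      p_value n_effective
#>  spo2_mean         0 0.0004882813          12
#>    spo2_sd        78 0.0004882813          12
#>       odi3        78 0.0004882813          12
#>       odi4        78 0.0004882813          12
#>        mos        21 0.0305448500           6
#>        csa        78 0.0004882813          12
#>        sse        65 0.0424804688          12
#> ROC (pre = positive class):
#>  parameter    auc ci_low ci_high   cutoff se_pct sp_pct
#>  spo2_mean 0.9167 0.8012  1.0000  96.6974     75    100
#>    spo2_sd 1.0000 1.0000  1.0000   1.0278    100    100
#>       odi3 1.0000 1.0000  1.0000   4.4499    100    100
#>       odi4 1.0000 1.0000  1.0000   4.1497    100    100
#>        mos 0.7500 0.6023  0.8977   1.5000     50    100
#>        csa 0.9167 0.8012  1.0000 430.2561     75    100
#>        sse 0.7500 0.5430  0.9570   0.7265     50    100
```

Every index improves after surgery (all exact Wilcoxon p = 2/2¹² for the
continuous indices; the MOS changes only in the 6 subjects scored above 1
pre-operatively). ODI3/ODI4 separate the visits perfectly here, with
Youden-optimal cutoffs (e.g. ODI3 > 4.4/h) reported as midpoints between
observed values. See the methods vignette
(`vignettes/nocturnal-oximetry-indices.Rmd`) for why sample entropy
separates simulated cohorts much less sharply than clinical ones.

Shell usage mirrors the R API:

```sh
inst/cli/nox simulate --out cohort/ --n 45 --seed 1
inst/cli/nox analyze  --out results/ cohort/S001_pre.csv
inst/cli/nox evaluate --out results/ cohort/manifest.csv
```

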