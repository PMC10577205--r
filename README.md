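# burnoutERP

Simulation and analysis of Go/NoGo event-related-potential (ERP)
biomarkers of occupational burnout.

Burnout and control groups can be behaviourally indistinguishable on an
executive-function task — same reaction times, same error rates — while
differing in the neural signature of each trial: the burnout group shows
a **larger centroparietal P3 amplitude** and a **longer centroparietal
N2–P3 interpeak latency (IPL)** in the Go condition, and both measures
track burnout-inventory (BBI-15) and executive-complaint (BRIEF-A
metacognition) scores. Because clinical EEG of this kind is not
shareable, this package implements the entire analysis chain against a
calibrated synthetic cohort, so every stage is reproducible and tested:

* **Task simulation** — the Executive reaction-time test: 4 practice +
  4 test blocks × 64 trials, 32 Go / 32 NoGo crossed with
  emotional/neutral distractors, rule reversal per block; response
  classification into correct / incorrect / miss / commission.
* **EEG simulation** — 500 Hz, 13-channel 10–20 montage; per-trial
  2,000 ms epochs (−200…+1798 ms) containing a frontal-maximal negative
  N2 and a centroparietal-maximal positive P3 (cos² lobes at calibrated
  group latencies/amplitudes), 1/f background noise, and blink
  artifacts; BrainVision Core read/write.
* **ERP extraction** — linked-mastoid re-reference; zero-phase 0.1–40 Hz
  Butterworth band-pass (compiled, cascade realisation); 80 µV
  peak-to-peak epoch rejection; condition averaging with a 50-epoch
  eligibility rule and −200…0 ms baseline; windowed peak detection
  (N2: minimum in 500–650 ms, P3: subsequent maximum in 600–800 ms,
  ties to the earlier sample); channel pooling and per-channel IPL.
* **Statistics** — Kruskal–Wallis group contrasts; mixed-effects
  logistic error models (subject random intercept, odds ratios with
  Wald CIs); Spearman correlations; OLS biomarker regressions
  `BBI-15 ~ P3 amplitude + IPL` and `MI ~ P3 amplitude + IPL` with
  F, R², adjusted R².

The headline biomarker is the pooled centroparietal N2–P3 interpeak
latency: with per-channel N2 latency `tN2(c)` and P3 latency `tP3(c)`
over the pool C = {CPz, CP1–CP4},

```
IPL = mean_{c in C} [ tP3(c) − tN2(c) ]  =  mean tP3 − mean tN2
```

## A worked example

```r
library(burnoutERP)

cfg <- run_config(seed = 7, n_burnout = 18, n_non_burnout = 17)
res <- run_end_to_end(cfg)

cp <- res$report$erp_contrasts
cp[cp$condition == "Go" & cp$pool == "centroparietal" &
     cp$metric %in% c("p3_amplitude_uv", "n2_p3_ipl_ms"), ]
#>  condition           pool          metric burnout_median burnout_iqr
#>         Go centroparietal p3_amplitude_uv       8.989013      3.7358
#>         Go centroparietal    n2_p3_ipl_ms     187.200000     34.9000
#>  non_burnout_median non_burnout_iqr     chisq            p
#>            6.788228        3.395738  4.187364 4.072638e-02
#>          139.600000       21.200000 19.559913 9.749354e-06
```

The burnout group's median pooled centroparietal Go P3 amplitude
(≈ 9.0 µV) exceeds the control group's (≈ 6.8 µV), and its N2–P3
interpeak latency is ≈ 48 ms longer — the two group effects the analysis
is built around; `res$report$correlations` and `res$report$regressions`
hold the corresponding questionnaire correlations and biomarker
regression summaries for this simulated cohort.

A parameter-recovery check of the measurement chain alone:

```r
erp_recovery_study("burnout", seed = 7)$median_p3_amplitude_uv
#> [1] 9.951453   # generative value: 9.89 uV
```

A thin CLI over the same functions is installed at
`system.file("cli", "burnout-erp", package = "burnoutERP")` with
subcommands `simulate-task`, `simulate-eeg`, `extract`, `analyze`,
`run-all`.

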