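# scapkin

Movement-analysis pipeline for a five-phase functional **drinking task**
(reaching, forward transport, drink, backward transport, returning) in
people with shoulder pain and scapular dyskinesis. The package covers the
complete measurement chain used in pre–post exercise studies of this task:

* **Signal conditioning** — zero-phase Butterworth filtering (EMG band-pass
  20–450 Hz order 2; hand-acceleration low-pass 4 Hz order 4), 100-sample
  sliding RMS envelopes, EMG normalization to a submaximal isometric
  contraction (%SVIC), rest-position estimation.
* **Task detection and segmentation** — onset/end where hand acceleration
  leaves/re-enters a ±0.3 m/s² band around rest; interior boundaries from
  elbow-extension maxima, shoulder-elevation initiation and
  shoulder-elevation maximum.
* **Outcomes** — per-phase range of motion of four scapular degrees of
  freedom and shoulder elevation; per-phase EMG activity of six scapular
  muscles (UT, MT, LT, SAup/mid, SAlow, LS); scapulohumeral rhythm
  SHR = shoulder-elevation ROM / scapular upward-rotation ROM; trunk
  compensation; % time-to-peak acceleration; global movement smoothness as
  log dimensionless jerk, ln(D³/v²ₚₑₐₖ ∫j²dt).
* **Statistics** — ICC(2,k) test–retest reliability with
  SEM = SD·√(1−ICC) and MDC95 = SEM·√2·1.96; Shapiro–Wilk-gated paired
  t / Wilcoxon pre–post comparisons with Cohen's d = t/√n; noncentral-t
  power analysis and sample-size estimation.
* **Synthetic-data generator** — seeded trials, SVIC recordings and paired
  pre/post cohorts with exact ground truth (minimum-jerk hand paths,
  phase-locked joint-angle profiles, phase-modulated EMG envelopes,
  injectable pre-to-post effects), so every stage of the pipeline is
  testable without access recordings.

## Worked example

Generate one synthetic trial, process it, segment the task and compute its
metrics:

```r
library(scapkin)

cfg  <- generator_config(seed = 1, n_subjects = 6,
                         effect_delta = list(emg = c(MT.forward_transport = -8)))
tr   <- generate_trial(cfg, subject_id = 1, trial_index = 1, session = "M0")
svic <- sapply(scap_muscles, function(m) svic_reference(generate_svic(cfg, m)))
rc   <- run_config(generator = cfg)
proc <- process_trial(tr, svic, rc)
(seg <- segment_phases(proc, rc$segmentation))
#> <scap_segmentation>
#>  onset     b1     b2     b3     b4    end
#>  6.014  7.217  8.210  9.678 10.685 11.892
```

The six boundaries (seconds) frame the five phases: the task starts ~14 ms
after the true movement onset at 6.0 s (1° angle noise, 0.05 m/s²
accelerometer noise), maximum elbow extension at 7.2 s starts the forward
transport, shoulder elevation initiates the drink phase at 8.2 s and peaks
at 9.7 s, and so on. Metrics for this trial:

```r
m <- trial_metrics(proc, seg)
subset(m, metric %in% c("shr", "ttp_pct", "smoothness") |
          (metric == "rom" & channel == "scap_ur" & phase == "drink"))
#>      metric channel phase value
#>         rom scap_ur drink 41.10
#>         shr    <NA> drink  1.49
#>     ttp_pct    <NA>  <NA>  3.92
#>  smoothness    <NA>  <NA> 11.70
```

Scapular upward rotation sweeps 41° while the shoulder elevates ~61°, an
SHR of 1.49 (the generator's true coupling is 1.5); the acceleration peak
falls at 3.9% of the task; ln(DJ) = 11.7 quantifies whole-task smoothness
(a single ideal minimum-jerk stroke would give 5.32; a multi-phase task
with pauses is necessarily "less smooth").

A full paired study — 6 subjects × 2 sessions × 5 trials, with an injected
−8 %SVIC drop of middle-trapezius activity during forward transport — runs
end-to-end and recovers the effect:

```r
study <- run_study(rc)
pp <- study$prepost
pp[pp$outcome == "emg_mean.MT.forward_transport",
   c("outcome", "test", "m0_center", "m1_center", "p", "difference")]
#>                        outcome     test m0_center m1_center        p difference
#>  emg_mean.MT.forward_transport paired_t     19.37     11.50 7.64e-13       7.87
```

The estimated pre–post difference (7.87 %SVIC) matches the injected 8
(the EMG plateau ramps absorb ~2% of a level step). Design-stage power
analysis reproduces the protocol's sample-size computation:

```r
d <- effect_size_from_mcid(13.2, 20.71)   # 0.63737
required_sample_size(d, alpha = 0.05, power = 0.80, tails = "one")
#> [1] 17
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/scapkin generate --seed 1 --subjects 2 --out trials/
Rscript inst/cli/scapkin run-all  --seed 1 --subjects 18 --out results/
```

See the methods vignette
(`vignettes/drinking-task-pipeline.Rmd`) for the model, the segmentation
operationalizations, the generator's design and its limitations.
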