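# vocmotor

Event-locked analysis of infant motor–vocal coupling from wearable
accelerometry.

Infant vocalisations co-occur with limb movement, and the balance between
arm and leg involvement reorganises across the first year of life.
`vocmotor` implements the full measurement chain for quantifying this
coupling from semi-naturalistic infant–caregiver recordings:

* **I/O** — session audio (WAV), utterance annotations (Praat TextGrid,
  long and short dialects), 3-axis accelerometer tables (open CSV
  dialect `time_s,acc_x,acc_y,acc_z`), YAML session manifests, TSV
  summary tables.
* **Synchronisation & QC** — audio and sensor clocks are aligned via the
  five-clap event at session start (`detect_claps()`, `estimate_lag()`,
  `apply_lag()`); sensor-throw artifacts are masked
  (`detect_artifacts()`).
* **Preprocessing** — cubic-spline packet-gap interpolation, polyphase
  resampling to 60 Hz, vector magnitude
  `Acc(t) = sqrt(x² + y² + z²)`, and a zero-phase 2nd-order 1 Hz
  highpass Butterworth filter.
* **Epoching** — vocalisation-locked epochs over [−3.5, +5] s, envelope
  baseline correction against the [+3.5, +5] s reference span, a 12-tap
  FIR analytic envelope, and per-window median summaries (baseline
  [−2.5, −0.9) s, pre [−0.9, 0) s, during [0, 0.9) s; left and right
  side medians averaged per limb).
* **Statistics** — linear mixed-effects models (`lme4`/`lmerTest`) of
  median acceleration over `Time_Window × Time_Point × Limb` with
  per-infant random intercepts and limb slopes; eight-candidate model
  comparison (AIC/BIC/logLik, LRT), Type-II ANOVA with Satterthwaite
  degrees of freedom, random-effect LRTs, `emmeans` contrasts with
  Bonferroni correction, Cohen's *f* (omnibus
  `f = sqrt(NumDF·F/DenDF)`; contrasts `f = |t|/sqrt(N)`), and Nakagawa
  marginal/conditional R².
* **Synthetic data** — a dyad-session generator with known ground truth
  (`simulate_cohort()`, `simulate_rows()`) reproducing the assumed
  coupling structure: base < pre < during window effects, a limb×age
  crossover, random intercepts and limb slopes, clap bursts, clock lag,
  packet gaps, 60→40 Hz rate drops, throw artifacts and visit attrition.

## Worked example

Simulate a small cohort, run the pipeline and fit the model suite:

```r
library(vocmotor)

cfg <- sim_config(n_infants = 2, timepoints = c(6, 9),
                  session_duration = 70, voc_rate = 10, attrition = 0,
                  sd_resid = 0.4)
coh <- simulate_cohort(cfg, seed = 42)

pc  <- pipeline_config(sessions = coh$sessions, seed = 42)
res <- process_session(coh$sessions[[1]], pc)

res$qc$lag
#> [1] 0.3500234          # injected lag was 0.35 s

head(res$rows, 3)
#>   infant_id time_point event_id limb window    median n_sides
#> 1    inf001          6        1  arm   base 0.8710946       2
#> 2    inf001          6        1  arm    pre 3.6646512       2
#> 3    inf001          6        1  arm during 3.2646512       2
```

Each row is one vocalisation × limb × window: the median of the limb's
acceleration envelope (m/s²) in that window, averaged over the left and
right sensors. On a full-size synthetic cohort (60 infants, 40
events/visit) the window contrasts recover the injected coupling:

```r
rows <- simulate_rows(sim_config(n_infants = 60, attrition = 0),
                      events_per_visit = 40, seed = 1)
fit  <- fit_model(model_spec("median", "window_by_timepoint", "slope"), rows)
emm_contrasts(fit, "window")[, c("contrast", "estimate", "t", "p_bonferroni")]
#>        contrast   estimate          t  p_bonferroni
#> 1    base - pre -0.2022905 -16.454433  3.221107e-60
#> 2 base - during -0.3031178 -24.655781 4.748619e-133
#> 3  pre - during -0.1008272  -8.201348  7.277069e-16
```

i.e. limb acceleration rises by ~0.20 m/s² just before vocalisation
onset and by ~0.30 m/s² during vocalisation, relative to the silent
baseline — the injected values were 0.21 and 0.31. `run_full_suite(rows)`
produces the complete report (model comparison, ANOVAs, random-effect
LRTs, contrasts) across all four model families.

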