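# entotrap

Automated monitoring of the olive fruit fly (*Bactrocera oleae*) with an
instrumented McPhail trap: an infrared emitter/photoreceptor pair spans the
trap entrance, and an insect flying through modulates the light at its
wingbeat frequency. The audio-like signal carries a harmonic signature —
the wingbeat fundamental f0 (170–210 Hz for *B. oleae*) and the relative
amplitudes of its harmonics — that identifies the species well enough to
count target pests without opening the trap. `entotrap` is a tested software
twin of that device for people who want to study, stress or extend its
algorithmic pipeline: entomologists and engineers prototyping optical pest
monitors, and anyone needing a reproducible wingbeat-classification
benchmark.

The pipeline, end to end:

1. **Synthesis** — labeled wingbeat events `x(t) = e(t) m(t) Σ_h w_h
   sin(h·φ(t) + φ_h)` with species presets (f0 band, harmonic weights
   `w_h`, frequency drift, two flight-duration modes, amplitude modulation,
   noise, 10-bit quantization), so every stage is testable without
   recordings.
2. **Detection** — non-overlapping 512-sample frames at 4 kHz; a frame whose
   RMS exceeds a threshold is an event; consecutive triggered frames merge.
3. **Features** — Hamming window → 512-point FFT → 256 magnitude
   coefficients (bin width 7.8125 Hz) → unit-L2 normalization
   `s_i / sqrt(Σ s_i²)` (gain invariance).
4. **Verification** — K-means codebook of K = 4 unit-norm prototype spectra;
   a signature is the target species iff its minimum L1 distance to the
   prototypes is at most `μ_d + 3σ_d`, the mean plus three standard
   deviations of the training distances. Two codebooks give closed-set
   classification.
5. **Evaluation & telemetry** — confusion matrices, per-class and
   support-weighted precision/recall/F1, repeated-random-split
   cross-validation baselines (SVM, random forest, extra trees, gradient
   boosting), and a trap runtime that emits SMS/JSON telemetry payloads.

## Worked example

Train a *B. oleae* codebook from 403 synthetic reference recordings, then run
a day's stream — 23 passes of which 3 are the target species — through the
full trap pipeline:

```r
library(entotrap)

ref  <- synthSignatures(speciesPreset("b_oleae"), 403, seed = 11)
book <- learnCodebook(ref, k = 4, seed = 1)
book
#> Codebook 'b_oleae': K=4 prototypes of 256 bins, trained on 403 spectra
#>   distance stats: mu=2.5650 sd=0.7187 threshold (mu+3sd)=4.7211

cfg  <- detectionConfig(rmsThreshold = 0.05, pretrigger = TRUE)
seqv <- rep(2L, 23); seqv[c(3, 9, 17)] <- 1L   # 3 olive flies, 20 mosquitoes
day  <- synthStream(list(speciesPreset("b_oleae"), speciesPreset("mosquito")),
                    23, seed = 2, profileSequence = seqv)
res  <- runTrap(day$samples, book, cfg, trapId = "trap-1",
                timestamp = "2016-07-01T06:00:00Z",
                temperatureC = 29, humidityPct = 69, batteryPct = 81)
res$record
#> TelemetryRecord trap-1 @ 2016-07-01T06:00:00Z: 23 events, 3 matches
#>   t=29°C h=69% lat=NA lon=NA batt=81%

head(res$log, 3)
#>   onset_sample       rms distance   decision
#> 1         2049 0.2697153 7.419017 non_target
#> 2         6657 0.3158179 6.099120 non_target
#> 3        11265 0.4233152 3.044964     target

buildReport(res$record, "sms")
#> ETv1 id=trap-1 ts=2016-07-01T06:00:00Z events=23 matches=3 t=29 h=69 lat=NA lon=NA batt=81
```

Reading the output: all 23 passes triggered the detector (`events=23`); the
mosquito passes sit 6–8 L1 units from the nearest prototype, well past the
4.72 acceptance threshold, while the olive-fly passes sit around 3 and are
counted as matches (`matches=3`). The SMS line is the payload a deployed trap
would transmit daily; `parseReport()` inverts it losslessly.

A command-line front end over the same functions lives in
`inst/scripts/entotrap.R` (subcommands `simulate`, `detect`, `featurize`,
`train-codebook`, `verify`, `evaluate`, `run`).

The methods vignette (`vignettes/wingbeat-verification.Rmd`) documents the
signal model, every tunable parameter, and the design decisions in detail.

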