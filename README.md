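# dawnchorus

Bioacoustic phenology from long-duration dawn-chorus recordings.

Autonomous recorders at remote sites capture months of audio around
songbird breeding habitat. This package turns such recordings into a
daily index of bird-community acoustic activity and dates the spring
arrival of migrant songbirds from the abrupt shift in that index. It is
aimed at ecologists running (or simulating) acoustic monitoring programs
who want a reproducible, scriptable alternative to GUI-driven audio
workflows.

## What it computes

The core quantity is the **Acoustic Complexity Index (ACI)** on
calibrated 1-second one-third-octave band sound pressure levels. For band
*f* over the 3-hour dawn window (0.5 h before to 2.5 h after local
sunrise),

    ACI_f  = sum_{t=1}^{n-1} |SPL_t - SPL_{t+1}|  /  sum_{t=1}^{n} SPL_t
    ACI_tot = sum over the N = 8 bands with nominal centres 1250-6300 Hz

Intermittent song drives the numerator; steady noise does not. The daily
`ACI_tot` series is analysed with a **Barry–Hartigan product-partition
Bayesian change-point model** (Gibbs sampler in C++, 10000 sweeps after
5000 burn-in): the first day whose posterior change probability exceeds
0.5 at a local maximum is reported as the spring transition, together
with the fold-change of ACI over the preceding days.

Around that core: WAV → band-SPL conversion with hourly A-weighted L50
summaries, offline NOAA-equation sunrise times, automated screening of
wind/rain/noise-obscured days (>25 % obscured ⇒ excluded), band-limited
energy detection of species-like calls with false-negative-rate
correction, vocalization diversity indices (richness, Shannon,
Gini–Simpson), ACI–activity association models, and a seeded synthetic
dawn-chorus generator with exhaustive ground truth that exercises the
whole pipeline.

## Worked example

A 60-day synthetic spring season (three species, song rates stepping from
2 to 40 songs/h per species at the arrival day 2012-03-30), analysed end
to end:

```r
library(dawnchorus)

cfg <- list(seed = 1,
            changepoint = list(iterations = 10000, burn_in = 5000),
            detector = list(duration_s = 60))
res <- run_pipeline(cfg, out_dir = "run1")

res$transition
#> <transition> position 30 (2012-03-30)  P(change) = 1.00  fold-change = 2.03 over 29 baseline day(s)

res$evaluation
#> <detector_evaluation> TP 62  FP 8  FN 0  recall 1.000  precision 0.886  FN-rate 0.000

res$association$calls
#> <association_result> slope 0.000485 +/- 1.133e-06, R^2 = 1.000, p = 3.4e-103, n = 60
```

Reading: the change-point model dates the transition exactly at the
configured arrival day with posterior probability 1.0, and ACI jumps to
about twice its pre-arrival mean — the magnitude of shift spring
transitions show in field recordings. The call detector recovers every
ground-truth song in the daily audio subsamples (the few false alarms
are overlapping songs split across band-specific detectors), and daily
ACI is almost perfectly linear in the true number of songs per day,
which is what licenses ACI as an activity index.

`run1/` then contains the daily ACI series, screen report, change-point
posterior, detections, diversity and association tables as CSV plus a
JSON run manifest; rerunning with the same config and seed reproduces
every file byte-identically. A commented configuration template is in
`inst/extdata/example_run.yaml`.

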