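# finsong

Detection and long-term trend analysis of fin whale (*Balaenoptera
physalus*) 20 Hz pulse songs in passive acoustic recordings.

Fin whale songs are sequences of short (~1 s), stereotyped pulses centered
near 20 Hz, produced for hours at highly regular inter-pulse intervals
(IPIs). In the Western Mediterranean the pulses fall into two types — A,
the higher-pitched "classic" 20 Hz pulse, and B, the "back-beat" — and the
interval between consecutive pulses depends on the ordered type pair
(bi-gram): AB runs about 2 s longer than AA/BA, and BB about 11 s longer.
Tracking the *modal* (stereotypical) IPI of each bi-gram over years, and
the modal pulse center frequency over the months of the song season,
reveals slow population-level song trends: an inter-annual IPI increase
near 0.1 s/year and an intra-annual center-frequency decline near
−0.1 Hz/month between August and February.

`finsong` implements the full measurement chain behind such an analysis,
for bioacousticians who want a tested, reproducible desk-scale pipeline:

- **Synthetic song generator** — Hann-enveloped chirp pulses in brown
  (1/f²) noise mixed at a controlled band SNR, first-order Markov type
  sequences, bi-gram IPI tables with truncated Gaussian jitter, and
  multi-year pulse-record datasets with implanted IPI drift and monthly
  frequency slopes. Every downstream stage is testable without any data
  download.
- **Detector** — a hand-implemented low-complexity temporal CNN
  (~36 k parameters: three depth-wise separable 1-D convolutions over
  128 mel bands, batch norm, leaky ReLU, dropout, a trainable
  log-compression exponent, Adam training with weight decay and
  brown-noise augmentation), producing per-frame pulse probabilities at
  6.25 Hz, plus a normalized spectrogram template-matching baseline and
  ROC/balance-point threshold selection.
- **Pulse measurement** — per detection: zero-phase 10–30 Hz band-pass,
  resample to 250 Hz, high-resolution power spectrogram (0.24 Hz /
  0.03 s), precise pulse time (column of the 18–22 Hz maximum),
  background-subtracted spectral envelope (1.2 s max-pool minus per-bin
  median), −6 dB (quarter-max) bandwidth and center frequency by linear
  interpolation, and SNR as peak envelope over median 15–25 Hz background
  in dB.
- **Sequencing and filters** — sequences split at 45 s gaps, bouts at 2 h;
  pulses kept with bandwidth < 6 Hz and center frequency in
  [18.5, 22.5] Hz; sequences kept with mean SNR ≥ 8 dB, ≥ 3 pulses and
  all IPIs in [11, 45] s.
- **Classification** — 2-component Gaussian mixture on center frequency
  (own EM; equal-posterior type threshold, ~19.95 Hz on mixtures matching
  the published components), bi-gram labelling, and a 3-component
  bivariate mixture on (center frequency, IPI) for per-bi-gram Pearson
  correlation analysis.
- **Trend statistics** — modal quantized values (0.1 s / 0.1 Hz grids)
  per calendar trimester or month-of-year under support gates
  (≥ 100 transitions and > 5% share; ≥ 200 pulses), with OLS slopes,
  r² and p-values, and literature-point overlays.

## Worked example

```r
library(finsong)

# a 10-minute synthetic song at 12 dB band SNR
cfg  <- synthesis_config(seed = 1)
song <- synth_song(cfg, 600)
nrow(song$ground_truth)
#> [1] 39

# refined measurement of one pulse (detection time ~ onset + 0.4 s)
wf <- preprocess(song$waveform, song$sampling_rate)
analyze_pulse(wf, 200, song$ground_truth$onset_s[3] + 0.4)
#>        t_s    cf_hz    bw_hz   snr_db  peak_hz centroid_hz valid edge_padded
#> 1 35.10482 20.52559 3.562048 21.75538 20.75195    20.17965  TRUE       FALSE

# ten synthetic years with the documented IPI drift implanted
d  <- synth_longterm_dataset(cfg, 2008, 10, 300, seed = 1)
tr <- ipi_trend(d[!is.na(d$bigram), ], "AA")
round(unlist(tr$regression), 4)
#>     slope intercept r_squared   p_value 
#>    0.1077 -201.5384    0.9350    0.0000

# type threshold from a stationary-frequency dataset
d0 <- synth_longterm_dataset(synthesis_config(seed = 1,
                                              cf_monthly_slope = 0),
                             2008, 10, 300, seed = 1)
g <- fit_gmm_1d(d0$cf_hz, seed = 1)
type_threshold(g)
#> [1] 19.89225
```

The analyzed pulse sits within 0.03 Hz of its generated center frequency
(type A, ≈ 20.55 Hz); the recovered AA IPI drift (0.108 s/year, r² 0.94)
matches the implanted 0.1 s/year; and the equal-posterior type threshold
lands at ~19.89 Hz, between the two component means (19.35 / 20.55 Hz;
fitted on mixtures matching the published component estimates it lands at
~19.95 Hz). The measured SNR (~22 dB here) is on the
peak-over-median-background scale of the pulse measurement, which sits a
constant spectral-concentration gain above the generator's band-power
mixing SNR (see the methods vignette).

## Command line

A thin Rscript front end over the package functions is installed at
`inst/cli/finsong.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/finsong.R", package="finsong"))')" \
    synth --duration 1200 --seed 1 --out songdir
```

Subcommands: `synth`, `train`, `detect`, `baseline`, `analyze`, `filter`,
`classify`, `trends`, `run`.
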