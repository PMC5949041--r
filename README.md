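# q15pipe

A desk-scale simulator for the layered real-time DSP architecture used on
open-source-hardware biomedical sensor platforms (Arduino-class 8-bit AVR
boards: 16 MHz clock, 2 KiB RAM, multiplexed 10-bit ADC). It is aimed at
embedded/biomedical engineers who want to answer, **before touching
hardware**: what will the fixed-point pipeline compute, will it ever drop
a sample, and will it fit the chip?

The simulator reproduces, bit-exactly:

- **Q15 fixed-point arithmetic** — coefficients as 16-bit integers
  representing `r/2^15`, 32-bit accumulation, and round-half-to-even
  output division (`rounded_div`), with overflow detected rather than
  wrapped;
- **the rational filter**
  `y[n] = (−Σ_{k=1..q} a_k y[n−k] + Σ_{k=0..p} b_k x[n−k]) / a_0`,
  the **polyphase decimator** `y[n] = Σ_k x[nD−k] h_k` emitting at
  `Fs/D`, the **Goertzel** single-bin power detector
  `s[n] = x[n] + 2cos(ω0) s[n−1] − s[n−2]`,
  `P = s1² + s2² − 2 s1 s2 cos(ω0)`, and **sliding windows** of length
  `L` with hop `H` plus block energy `Σ x²`;
- **the acquisition front end** — round-robin sampling of up to 8
  channels at interval `1/(Fs·Nch)` into bounded per-channel FIFO queues
  with loss counting, plus 1 ms-tick non-blocking software timers;
- **a deterministic pipeline executive** with full push/pop/overflow
  accounting (infinite-MTBF verification over simulated hours);
- **cycle/memory cost models** of every component (e.g. hardware layer
  `10/lq + 87` cycles, Goertzel 62 B of RAM) and the feasibility analyses
  they imply: maximum filter length vs sampling rate, simultaneous
  Goertzel detector count, block-FFT rate limits.

Synthetic biosignal generators (infrared blink channel with 100 Hz
powerline-harmonic interference, voice-like audio, two-axis
accelerometry) drive four end-to-end validation scenarios that compare
the fixed-point pipeline against a double-precision reference by Pearson
correlation. A System Usability Scale scorer (`sus_score`, `sus_batch`)
rounds out the toolkit.

## Worked example

Run the blink-detector scenario: a 250 Hz infrared channel carrying
100 Hz lighting interference, cleaned by the unity-gain low-pass with
double zeros at 100 Hz (`b = [2048, 6628, 9458, 6628, 2048]`,
`a0 = 26810`):

```r
library(q15pipe)
rep <- run_sc1(duration = 10, seed = 42)
rep
#> <comparison_report> SC1: pearson r = 1.0000; samples 2500/2500 per channel; overflow 0; MTBF infinite
```

Reading the report: the fixed-point output correlates with the
double-precision reference at r = 1.0000 (rounding noise only); all
2500 expected samples (10 s × 250 Hz) arrived; no queue ever overflowed,
so the mean time between failures over the run is infinite. The filter
itself, applied to raw ADC codes:

```r
q15_filter(c(512L, 700L, 512L, 300L, 512L), sc1_filter_spec())
#> [1]  39 180 393 523 506
```

Two-axis accelerometer smoothing (50-tap windowed-sinc low-pass at 5 Hz,
decimation 5, two channels at 250 Hz):

```r
run_sc4(duration = 60, seed = 42)
#> <comparison_report> SC4: pearson r = 1.0000, 1.0000; samples 3000,3000/3000 per channel; overflow 0; MTBF infinite
```

Feasibility on the default 16 MHz / 2048 B platform:

```r
max_filter_length(250, 1)    # 497 coefficients: memory-bound at 250 Hz
max_goertzel_count(9000)     # 1 detector: cycle-bound at 9 kHz
fft_feasible(10000, 256)
#> <cost_report> fft256: 232554 cycles (budget 384768), 1846 B DM (budget 2008) -> feasible
```

A thin command-line front end lives at `inst/cli/q15pipe.R`
(`run-scenario`, `feasibility`, `score-sus`).

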