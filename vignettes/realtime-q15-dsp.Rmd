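---
title: "Simulating layered real-time Q15 DSP for 8-bit biosensor platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating layered real-time Q15 DSP for 8-bit biosensor platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(q15pipe)
```

## The problem

Low-cost open-source-hardware boards (Arduino-class, 8-bit AVR, 16 MHz,
2 KiB of RAM) are attractive front ends for biomedical sensing — infrared
blink detectors, surface biopotentials, accelerometry — but real-time DSP
on them is unforgiving: there is no floating-point unit, RAM is measured
in hundreds of bytes per component, and every interrupt cycle spent
acquiring a sample is a cycle not available for filtering it. A layered
architecture addresses this: a *hardware layer* acquires samples at a
fixed rate through a multiplexed 10-bit ADC and parks them in per-channel
FIFO queues; a *DSP layer* of fixed-point components consumes the queues;
an *application layer* acts on the results; and a task manager runs the
asynchronous layers whenever their input queues hold data, while a 1 ms
timer tick drives non-blocking delays.

`q15pipe` reproduces that architecture on the desktop, bit-exactly in its
arithmetic and deterministically in its scheduling, so that three kinds of
question can be answered without hardware in the loop:

1. **Numerical** — what exactly does the Q15 fixed-point pipeline compute,
   and how far is it from the ideal double-precision result?
2. **Behavioural** — with given queue sizes, rates and window hops, is any
   sample ever lost?
3. **Budgetary** — do a component's cycle and memory costs fit the target
   at a given sampling rate?

## Fixed-point arithmetic

The DSP layer works in Q15: a 16-bit integer $r$ represents $r/2^{15} \in
[-1, 1-2^{-15}]$. Sums of coefficient products are accumulated in 32 bits
to avoid intermediate overflow, and each output is produced by a single
division with **round-half-to-even** (banker's rounding), applied to the
exact rational quotient — also for negative operands. Half-even rounding
matters for IIR structures, where a biased rounding rule feeds a
systematic drift back through the recursion. `rounded_div()` implements
the rule via exact integer arithmetic (floor division plus remainder
comparison), so ties are true ties, not floating-point accidents.

Two failure modes are made loud rather than emulated: a 32-bit
accumulator overflow raises an error (on the real device the behaviour
would be wraparound, i.e. a bug, not a feature), and a quotient outside
the 16-bit range saturates with a warning.

## The DSP components

**Rational filter.** `filter_spec(b, a)` defines
$$y[n] = \Big(-\sum_{k=1}^{q} a_k\,y[n-k] + \sum_{k=0}^{p} b_k\,x[n-k]\Big)\big/a_0,$$
evaluated per sample with a $p+q+2$-word history. The two worked
configurations ship as `sc1_filter_spec()` (low-pass with double zeros at
100 Hz, $\sum b_k = a_0$ so DC gain is exactly 1) and `sc2_filter_spec()`
(Savitzky–Golay style high-pass, $\sum b_k = 0$ so DC gain is exactly 0).

**Polyphase decimator.** `polyphase_spec(h, D)` computes
$y[n] = \sum_k x[nD-k]\,h_k$, emitting at rate $F_s/D$. Outputs are scaled
by $2^{15}$ with half-even rounding, so a unity-gain tap set stays
unity-gain. The first output is emitted on the first input (index $n = 0$
in the equation); equivalently, the output sequence equals full-rate FIR
filtering followed by keeping outputs $0, D, 2D, \dots$ — the equivalence
the tests assert against an exact oracle.

**Goertzel detector.** `goertzel_spec(cos_w0, N)` runs
$s[n] = x[n] + 2\cos\omega_0\,s[n-1] - s[n-2]$ over $N$ data samples plus
one final zero-input iteration, then emits
$P = s_1^2+s_2^2-2 s_1 s_2 \cos\omega_0$ from the final two states.
With the extra zero-input step this equals the squared magnitude of the
single-bin DFT **exactly, for arbitrary $\omega_0$** — we verified this
identity numerically before adopting it, and the test suite holds the
float-mode detector to $10^{-6}$ relative agreement with a brute-force
DFT oracle. The default mode runs the recurrence in double precision; a
`"q15"` mode quantizes $\cos\omega_0$ and runs on 32-bit integers. Because
$2\cos\omega_0$ can exceed the Q15 range, the fixed-point mode multiplies
by the quantized cosine and doubles in the accumulator; this is our
documented choice, not an attested property of any particular firmware.
The emitted $P$ is the raw recurrence value — the detector is used
comparatively (tone present/absent), so no output normalisation is
applied.

**Sliding windows.** `block_spec(L, H)` collects windows of $L$ samples
advancing by a hop of $H$; `block_energy()` returns the unscaled
$\sum x_i^2$ (an energy, not a power — callers wanting power can divide
by $L$). A stream of $n$ samples yields $\lfloor (n-L)/H \rfloor + 1$
windows.

## The pipeline executive

`run_pipeline()` advances simulated time one acquisition tick at a time.
At each tick the hardware layer pushes one ADC code onto the owning
channel's bounded queue; when a queue is full the **incoming** sample is
dropped and counted (reject-newest), which keeps queued data contiguous
and makes every loss observable. A task-manager round then runs the
stages in declared order, each draining its whole input queue (a
`"single"`-service mode exists for stress-testing queue sizing). Ties at
equal timestamps are resolved in a fixed order — acquisition, then
timers, then tasks — so identical configurations and seeds give
bit-identical runs; when a stage's queue is empty it is simply skipped
that round. The event log records push/pop/overflow/residual counts per
queue, and the invariant `pushed = popped + residual` (with overflow
counted separately at the door) is asserted in the tests.

Loss accounting follows the *expected-count* convention: a run of
duration $T$ at rate $F_s$ with decimation $D$ should deliver
$\lfloor F_s T / D \rfloor$ samples per channel; a run whose observed
counts match and whose overflow counters are zero has no failures — the
mean time between failures is infinite over the run. The acceptance
tests simulate 8 h at 250 Hz (one channel into 64-sample blocks; two
channels through a 50-tap decimate-by-5 chain) and assert exactly that.

## The ADC front end

The converter is modelled as a clamped floor quantizer,
$\mathrm{code} = \lfloor 2^{10} v / v_\mathrm{ref} \rfloor$. Only the bit
resolution of the target is documented, so the transfer curve is our
fixed convention, chosen to match common SAR models and stated bit-exactly
so tests are deterministic. Scenario correlations are insensitive to this
choice; absolute codes are not. Rates above 15 kHz warn, since the real
part drops to 8-bit resolution there. All channels share one $F_s$
(round-robin multiplexing with interval $1/(F_s N_{ch})$); per-channel
rates below $F_s$ are obtained downstream by decimation.

## Resource models and feasibility

Every component carries a measured cost model (cycles per invocation of
its hot method, bytes of data memory), shipped as data:

| component | cycles | data memory (B) |
|---|---|---|
| hardware layer | $10/l_q + 87$ (max 97) | $4 + (24+2 l_q) N_{ch}$ |
| filter | $669 + 83.5(p+q)$ | $20 + 2(p+q+2)$ (+ coefficients) |
| polyphase | $772.5 + 83.6\,p/D$ | $10 + 20D + 4\lceil (p{+}1)/D\rceil$ (+ coefficients) |
| Goertzel | $965 + 821/(N{+}1)$ (max 1786) | 62 |
| window energy | $653 + 51L$ | $12 + 2L$ |
| timer tick | $5 + (43 N_t + 37)/T_{0r}$ (max $43N_t+42$) | $7 + 6 N_t$ |

A per-sample component must finish before the next conversion:
$C_{ava} = F_{clk}/F_s - 97$; a block component consuming $N$ samples per
output gets $N$ such intervals. The platform defaults
($F_{clk} = 16$ MHz, 2048 B DM, 32768 B PM) are the ATmega328-class
target the models were measured on; they are not printed alongside the
models but are forced by the board and by the program-size percentages,
and remain configurable through `platform_model()`. A 10 B slice of data
memory is withheld from the DSP budget for stack and globals — a
calibration chosen so that the memory-bound maximum filter length at 1 Hz
is exactly 497 coefficients, the published figure; we document it as a
calibration, not a measurement.

With these models the feasibility questions come out as:

```{r feasibility}
max_filter_length(1, 1)      # memory-bound: 497 coefficients
max_filter_length(250, 1)    # still memory-bound at 250 Hz
max_goertzel_count(100)      # 62 B each: 32 fit the free RAM
max_goertzel_count(9000)     # cycle-bound: one detector
max_goertzel_count(16000)    # none above 15 kHz
round(fft_max_rate(16))      # 16-bin FFT real-time boundary (~21 kHz)
```

Two readings in the published analysis required a decision. First, the
block-budget formula is printed ambiguously; we read it as
$N(F_{clk}/F_s - C^{max}_{hl})$, the grouping that reproduces the
published 21 kHz limit for 16 bins (the other grouping gives ≈23.5 kHz).
Second, the published 182-coefficient figure for a decimate-by-64
polyphase filter at 14 kHz is not reproduced by the stated formulas
(they give a cycle-bound ≈210); the discrepancy is documented and the
figure is not asserted anywhere. Note also that the cost model admits a
trivial 2-coefficient filter up to ≈20.9 kHz; the published ≈18.5 kHz
ceiling corresponds to the smallest nontrivial filter.

## Synthetic signals and what validation shows

The generators fix the study conditions once: tones at 30% of full scale
peak-to-peak, white Gaussian noise at 2% of full scale, mid-rail
operating point at $0.5\,v_\mathrm{ref}$.

* **Blink channel** (250 Hz): baseline, raised-cosine blink bumps of
  0.3 s at Poisson rate 0.5 Hz (amplitude 20% of full scale — a plausible
  IR-reflectance excursion), a 100 Hz interference tone (twice the 50 Hz
  line frequency), noise.
* **Voice-like channel** (4 kHz): a three-harmonic carrier under a 3 Hz
  amplitude envelope (syllable rate), a slow drift of the operating
  point, noise.
* **Accelerometer axes** (250 Hz × 2): sums of sub-2 Hz sinusoids with
  random phases per axis, noise.

These emulate the *spectral placement* and *scale* of the real inputs —
interference exactly at the filter's zeros, energy bursts at syllable
rate, motion below the 5 Hz cutoff — but not their physiological
morphology, non-stationarity, or sensor artefacts. Consequently a
passing validation shows that the fixed-point pipeline tracks its
double-precision reference (Pearson $r \ge 0.97$ across 20 seeds, in
practice $r > 0.999$) and loses no samples; it does not certify
blink-detection accuracy or any clinical property on real recordings,
and the published hardware-vs-host correlations (0.982/0.971), which
depend on unavailable recordings, are deliberately not reproduced as
targets.

```{r scenario}
rep <- run_sc1(duration = 4, seed = 7)
rep
```

## Numerical choices and degenerate inputs

* Coefficients are converted to Q15 by nearest-with-saturation
  (`to_q15()`); the rounding used by the original firmware's tooling is
  not documented, so ties go to even, consistent with the rest of the
  arithmetic.
* Timer expiry is level-signalled: `timer_expired()` stays true until
  retrigger. Decrement order follows installation order (no observable
  effect; fixed for determinism). Timers at zero do not underflow.
* A window with $H = L$ degenerates to non-overlapping blocks; $D = 1$
  degenerates the polyphase to a plain FIR; both are exercised in tests.
* Empty inputs produce empty outputs and clean logs, not errors.
* `pearson()` refuses constant streams (undefined correlation) and
  unequal lengths.

## Problem sizes

The validation suite runs entirely from generated data: unit oracles use
tens-to-hundreds of samples; the correlation sweep uses 20 seeds of
10 s/5 s runs; the loss-accounting runs simulate the full 8 h
(7.2 M samples per channel) through the compiled executive, which takes
seconds of wall time. `scripts/acceptance.R` recomputes the two headline
feasibility constants (hardware-layer worst case, maximum filter length
at 1 Hz) from the installed package.

## Known limitations

* Only linear per-channel stage chains are simulated; branched pipelines
  and true preemption/interrupt latency are out of scope.
* ADC nonlinearity, jitter and the 8-bit high-speed mode are not
  modelled.
* The fixed-point Goertzel mode is a documented interpretation (see
  above), validated against the float mode only on small-amplitude
  signals.
* Cost-model constants are measurements of one firmware on one board,
  shipped as data; they do not transfer to other targets, though
  `platform_model()` lets you rescale the budgets.
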