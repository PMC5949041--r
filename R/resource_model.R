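#' Target platform model
#'
#' Constants of the AVR-class target the cost model describes: an
#' ATmega328-class board with a 16 MHz clock, 2048 B of data memory (RAM)
#' and 32768 B of program memory (flash). `reserve` is the slice of data
#' memory withheld from the DSP budget for stack and globals.
#'
#' @param fclk clock frequency in Hz.
#' @param dm_total data memory in bytes.
#' @param pm_total program memory in bytes.
#' @param reserve data-memory bytes withheld from the budget.
#' @return a `platform_model` object.
#' @export
platform_model <- function(fclk = 16e6, dm_total = 2048, pm_total = 32768,
                           reserve = 10) {
  stopifnot(fclk > 0, dm_total > 0, pm_total > 0, reserve >= 0)
  structure(list(fclk = fclk, dm_total = dm_total, pm_total = pm_total,
                 reserve = reserve),
            class = "platform_model")
}

# data memory left for DSP components after the single-channel, depth-1
# hardware layer and the reserve
free_dm <- function(platform) {
  platform$dm_total - dm_hardware(1, 1) - platform$reserve
}

#' Cycle-count models of the runtime components
#'
#' Measured execution-cost models for the target: each returns the number
#' of clock cycles one invocation of the component's hot method takes, as
#' a function of its size parameters. Where mean and worst case differ the
#' function returns both.
#'
#' * `cycles_hardware(lq)`: acquisition interrupt (ADC read + queue push);
#'   mean `10/lq + 87`, worst case 97 (depth-1 queue, pointer wrap every
#'   sample).
#' * `cycles_filter(p, q)`: rational filter output; `669 + 83.5 (p + q)`
#'   (mean and worst case agree to a few cycles).
#' * `cycles_polyphase(p, D)`: decimating FIR per input; `772.5 + 83.6 p/D`
#'   (valid while `p + 1 > D`).
#' * `cycles_goertzel(N)`: power method per sample; mean
#'   `965 + 821/(N+1)`, worst case 1786 at `N = 0`.
#' * `cycles_block(L)`: window energy; `653 + 51 L`.
#' * `cycles_timing(Nt, T0r)`: 1 ms timer interrupt; mean
#'   `5 + (43 Nt + 37)/T0r`, worst case `43 Nt + 42` (at `T0r = 1`).
#'
#' @param lq queue depth (>= 1).
#' @param p,q causal/anti-causal coefficient orders (>= 0).
#' @param D decimation factor (>= 1).
#' @param N Goertzel iteration count (>= 0; 0 gives the worst case).
#' @param L window length (>= 1).
#' @param Nt number of installed timers (>= 0).
#' @param T0r timer resolution in ms (>= 1).
#' @return a single cycle count, or a list with `mean` and `max`.
#' @examples
#' cycles_hardware(1)$max   # 97
#' cycles_goertzel(0)$max   # 1786
#' cycles_timing(0, 10)$mean # 8.7
#' @name cycle_models
NULL

#' @rdname cycle_models
#' @export
cycles_hardware <- function(lq) {
  stopifnot(lq >= 1)
  list(mean = 10 / lq + 87, max = 97)
}

#' @rdname cycle_models
#' @export
cycles_filter <- function(p, q) {
  stopifnot(p >= 0, q >= 0)
  669 + 83.5 * (p + q)
}

#' @rdname cycle_models
#' @export
cycles_polyphase <- function(p, D) {
  stopifnot(p >= 0, D >= 1)
  772.5 + 83.6 * p / D
}

#' @rdname cycle_models
#' @export
cycles_goertzel <- function(N) {
  stopifnot(N >= 0)
  list(mean = 965 + 821 / (N + 1), max = 1786)
}

#' @rdname cycle_models
#' @export
cycles_block <- function(L) {
  stopifnot(L >= 1)
  653 + 51 * L
}

#' @rdname cycle_models
#' @export
cycles_timing <- function(Nt, T0r) {
  stopifnot(Nt >= 0, T0r >= 1)
  list(mean = 5 + (43 * Nt + 37) / T0r, max = 43 * Nt + 42)
}

#' Data-memory models of the runtime components
#'
#' Bytes of RAM each component occupies.
#'
#' * `dm_hardware(Nch, lq)`: `4 + (24 + 2 lq) Nch` — interrupt variables
#'   plus one depth-`lq` queue per channel.
#' * `dm_filter(p, q, include_coeffs)`: `20 + 2 (p + q + 2)` for the class
#'   and history; the coefficient table (2 bytes each, stored outside the
#'   class) is added when `include_coeffs = TRUE`.
#' * `dm_polyphase(p, D, include_coeffs)`: `10 + 20 D + 4 ceil((p+1)/D)`,
#'   plus `2 (p + 1)` coefficient bytes if requested.
#' * `dm_goertzel()`: constant 62.
#' * `dm_block(L)`: `12 + 2 L`.
#' * `dm_timing(Nt)`: `7 + 6 Nt`.
#'
#' @inheritParams cycle_models
#' @param Nch channel count (>= 1).
#' @param include_coeffs include the externally stored coefficient table.
#' @return bytes of data memory.
#' @examples
#' dm_hardware(1, 1)                  # 30
#' dm_filter(495, 0, include_coeffs = TRUE)  # 2008
#' @name dm_models
NULL

#' @rdname dm_models
#' @export
dm_hardware <- function(Nch, lq) {
  stopifnot(Nch >= 1, lq >= 1)
  4 + (24 + 2 * lq) * Nch
}

#' @rdname dm_models
#' @export
dm_filter <- function(p, q, include_coeffs = FALSE) {
  stopifnot(p >= 0, q >= 0)
  20 + 2 * (p + q + 2) + if (include_coeffs) 2 * (p + q + 2) else 0
}

#' @rdname dm_models
#' @export
dm_polyphase <- function(p, D, include_coeffs = FALSE) {
  stopifnot(p >= 0, D >= 1)
  10 + 20 * D + 4 * ceiling((p + 1) / D) +
    if (include_coeffs) 2 * (p + 1) else 0
}

#' @rdname dm_models
#' @export
dm_goertzel <- function() 62

#' @rdname dm_models
#' @export
dm_block <- function(L) {
  stopifnot(L >= 1)
  12 + 2 * L
}

#' @rdname dm_models
#' @export
dm_timing <- function(Nt) {
  stopifnot(Nt >= 0)
  7 + 6 * Nt
}

#' Cycles available per output under the real-time deadline
#'
#' A per-sample component must produce each output before the next sample
#' arrives, so it may spend at most `fclk / fs` cycles minus the
#' worst-case cost of the acquisition interrupt (97 cycles). A block
#' component that consumes `N` samples per output has `N` such intervals:
#' `cycles_available_block(fs, N) = N * (fclk/fs - 97)`.
#'
#' @param fs sampling rate in Hz (> 0).
#' @param N samples consumed per output (>= 1).
#' @param platform a [platform_model()].
#' @return available clock cycles (negative means the deadline is already
#'   unmeetable).
#' @examples
#' cycles_available(250)  # 63903
#' @export
cycles_available <- function(fs, platform = platform_model()) {
  stopifnot(fs > 0)
  platform$fclk / fs - cycles_hardware(1)$max
}

#' @rdname cycles_available
#' @export
cycles_available_block <- function(fs, N, platform = platform_model()) {
  stopifnot(N >= 1)
  N * cycles_available(fs, platform)
}

#' Maximum feasible filter length
#'
#' Largest total coefficient count a filter can have and still run in real
#' time on the platform: the history buffer plus coefficient table must
#' fit the free data memory (total minus the single-channel hardware layer
#' minus the reserve), and one output evaluation must fit
#' [cycles_available()]. With `D = 1` the rational-filter models apply
#' (FIR case, `q = 0`, length `p + q + 2`); with `D > 1` the polyphase
#' models apply (length `p + 1`).
#'
#' @param fs sampling rate in Hz.
#' @param D decimation factor.
#' @param platform a [platform_model()].
#' @return the largest feasible coefficient count (0 if none).
#' @examples
#' max_filter_length(1, 1)    # 497: memory-bound at low rates
#' max_filter_length(250, 1)  # still 497
#' @export
max_filter_length <- function(fs, D = 1, platform = platform_model()) {
  stopifnot(fs > 0, D >= 1, D == trunc(D))
  budget_dm <- free_dm(platform)
  budget_cy <- cycles_available(fs, platform)
  if (D == 1) {
    # total length L = p + q + 2 with q = 0, so p = L - 2 >= 0
    feasible <- function(L) {
      dm_filter(L - 2, 0, include_coeffs = TRUE) <= budget_dm &&
        cycles_filter(L - 2, 0) <= budget_cy
    }
    L_lo <- 2L
  } else {
    # polyphase length L = p + 1
    feasible <- function(L) {
      dm_polyphase(L - 1, D, include_coeffs = TRUE) <= budget_dm &&
        cycles_polyphase(L - 1, D) <= budget_cy
    }
    L_lo <- 1L
  }
  # costs are monotone in L: scan down from the memory-unconstrained cap
  for (L in seq.int(2048L, L_lo)) if (feasible(L)) return(L)
  0L
}

#' Maximum simultaneous Goertzel detector count
#'
#' How many Goertzel detectors can run at once: each needs 62 B of data
#' memory, and each consumes its per-sample cycle cost out of the shared
#' real-time budget. For long blocks the per-sample cost approaches its
#' asymptote of 965 cycles, which is the figure the sampling-rate limits
#' quote; pass a finite `N` to use the exact mean cost.
#'
#' @param fs sampling rate in Hz.
#' @param N block length (default `Inf`, the asymptotic per-sample cost).
#' @param platform a [platform_model()].
#' @return number of detectors (possibly 0).
#' @examples
#' max_goertzel_count(100)    # 32: memory-bound at low rates
#' max_goertzel_count(9000)   # 1
#' max_goertzel_count(16000)  # 0
#' @export
max_goertzel_count <- function(fs, N = Inf, platform = platform_model()) {
  stopifnot(fs > 0, N >= 1)
  mem_bound <- floor(free_dm(platform) / dm_goertzel())
  per_sample <- if (is.infinite(N)) 965 else cycles_goertzel(N)$mean
  cyc <- cycles_available(fs, platform)
  cyc_bound <- if (cyc <= 0) 0 else floor(cyc / per_sample)
  max(0, min(mem_bound, cyc_bound))
}

# measured costs of the external FFT library, per block length
fft_cost_table <- data.frame(
  n_bins = c(16L, 32L, 64L, 128L, 256L),
  pm_bytes = c(3368, 3468, 3684, 4116, 5004),
  dm_bytes = c(254, 326, 470, 758, 1334),
  exec_cycles = c(10793, 22860, 49560, 107338, 232554)
)

#' Feasibility of a block FFT on the target
#'
#' Checks whether an `n_bins`-point FFT (computed by the external
#' assembler-optimised library whose measured costs are built in) can keep
#' up at sampling rate `fs`: its execution cycles must fit
#' [cycles_available_block()] and its data memory, plus the `2 * n_bins`
#' bytes of the double-buffering input queue, must fit the free data
#' memory.
#'
#' `fft_max_rate()` returns the exact sampling-rate boundary (Hz) at which
#' the cycle budget is met for `n_bins`.
#'
#' @param fs sampling rate in Hz.
#' @param n_bins FFT length: one of 16, 32, 64, 128, 256.
#' @param platform a [platform_model()].
#' @return `fft_feasible()`: a `cost_report` with fields `component`,
#'   `cycles`, `cycles_budget`, `dm_bytes`, `dm_budget`, `pm_bytes`,
#'   `feasible` and `binding` (`"cycles"`, `"memory"`, or `"none"`).
#' @examples
#' fft_feasible(10000, 256)$feasible        # TRUE
#' round(fft_max_rate(16) / 1000)           # 21 kHz
#' @export
fft_feasible <- function(fs, n_bins, platform = platform_model()) {
  row <- fft_cost_table[fft_cost_table$n_bins == n_bins, ]
  if (nrow(row) != 1)
    stop("`n_bins` must be one of 16, 32, 64, 128, 256", call. = FALSE)
  stopifnot(fs > 0)
  cyc_budget <- cycles_available_block(fs, n_bins, platform)
  dm_need <- row$dm_bytes + 2 * n_bins
  dm_budget <- free_dm(platform)
  cyc_ok <- row$exec_cycles <= cyc_budget
  dm_ok <- dm_need <= dm_budget
  structure(
    list(
      component = sprintf("fft%d", n_bins),
      cycles = row$exec_cycles, cycles_budget = cyc_budget,
      dm_bytes = dm_need, dm_budget = dm_budget,
      pm_bytes = row$pm_bytes,
      feasible = cyc_ok && dm_ok,
      binding = if (cyc_ok && dm_ok) "none"
                else if (!cyc_ok) "cycles" else "memory"
    ),
    class = "cost_report"
  )
}

#' @rdname fft_feasible
#' @export
fft_max_rate <- function(n_bins, platform = platform_model()) {
  row <- fft_cost_table[fft_cost_table$n_bins == n_bins, ]
  if (nrow(row) != 1)
    stop("`n_bins` must be one of 16, 32, 64, 128, 256", call. = FALSE)
  # solve n_bins * (fclk/fs - 97) >= exec_cycles for fs
  platform$fclk / (row$exec_cycles / n_bins + cycles_hardware(1)$max)
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf(
    "<cost_report> %s: %g cycles (budget %g), %g B DM (budget %g) -> %s%s\n",
    x$component, x$cycles, x$cycles_budget, x$dm_bytes, x$dm_budget,
    if (x$feasible) "feasible" else "infeasible",
    if (x$binding == "none") "" else paste0(" (", x$binding, "-bound)")
  ))
  invisible(x)
}
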