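#' Rational Q15 filter specification
#'
#' Defines the difference equation evaluated by the fixed-point filter:
#'
#' \deqn{y[n] = \left(-\sum_{k=1}^{q} a[k]\, y[n-k]
#'              + \sum_{k=0}^{p} b[k]\, x[n-k]\right) / a[0]}
#'
#' with all coefficients stored as raw Q15 integers. Sums of products are
#' accumulated in 32 bits; the division by `a[0]` uses round-half-to-even
#' ([rounded_div()]). The filter keeps `p + q + 2` words of history
#' (current and past inputs, current and past outputs), addressed modulo
#' the buffer length on the target; [filter_view()] exposes that buffer
#' with inputs first (newest to oldest) then outputs.
#'
#' `b` and `a` may each hold at most 255 coefficients (`p, q <= 254`), the
#' limit imposed by byte-sized indexing on the 8-bit target.
#'
#' @param b causal coefficients `b[0..p]`, raw Q15 integers.
#' @param a anti-causal coefficients `a[0..q]`, raw Q15 integers;
#'   `a[1]` (i.e. `a[0]` in 0-based notation) must be nonzero.
#' @return a `filter_spec` object.
#' @examples
#' # unity-gain low-pass with double zeros at 100 Hz (Fs = 250 Hz)
#' spec <- filter_spec(b = c(2048, 6628, 9458, 6628, 2048), a = 26810)
#' @export
filter_spec <- function(b, a) {
  b <- check_q15_raw(b, "b")
  a <- check_q15_raw(a, "a")
  if (length(b) < 1 || length(a) < 1)
    stop("`b` and `a` must be non-empty", call. = FALSE)
  if (a[1] == 0L) stop("a[0] must be nonzero", call. = FALSE)
  if (length(b) > 255 || length(a) > 255)
    stop("at most 255 coefficients per part (p, q <= 254)", call. = FALSE)
  structure(
    list(b = b, a = a, p = length(b) - 1L, q = length(a) - 1L),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> p = %d, q = %d, a[0] = %d, history = %d words\n",
              x$p, x$q, x$a[1], x$p + x$q + 2L))
  invisible(x)
}

#' Filter state: history buffer
#'
#' Allocates and manages the `p + q + 2`-word history of a [filter_spec()].
#' `filter_reset()` zeroes the buffer; `filter_view()` reads one word
#' without mutation. The view layout is fixed: indices `0..p` hold inputs
#' `x[n], x[n-1], ..., x[n-p]` and indices `p+1 .. p+q+1` hold outputs
#' `y[n], y[n-1], ..., y[n-q]`.
#'
#' @param spec a [filter_spec()].
#' @return a mutable `filter_state` object.
#' @export
filter_state <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$xs <- integer(spec$p + 1L)  # x[n], x[n-1], ...
  e$ys <- integer(spec$q + 1L)  # y[n], y[n-1], ...
  class(e) <- "filter_state"
  e
}

#' @rdname filter_state
#' @param state a `filter_state`.
#' @export
filter_reset <- function(state) {
  state$xs[] <- 0L
  state$ys[] <- 0L
  invisible(state)
}

#' @rdname filter_state
#' @param index 0-based buffer index in `[0, p+q+1]`.
#' @export
filter_view <- function(state, index) {
  spec <- state$spec
  if (index < 0 || index > spec$p + spec$q + 1L || index != trunc(index))
    stop("view index out of bounds", call. = FALSE)
  if (index <= spec$p) state$xs[index + 1L] else state$ys[index - spec$p]
}

#' Evaluate one filter output sample
#'
#' Pushes one 16-bit input into the history and evaluates the difference
#' equation of the [filter_spec()] in exact Q15 fixed point: 32-bit
#' accumulation of coefficient products, then division by `a[0]` with
#' round-half-to-even. An accumulator that leaves the 32-bit signed range
#' raises an error rather than wrapping.
#'
#' For whole streams use [q15_filter()], which runs the identical
#' arithmetic in compiled code.
#'
#' @param state a [filter_state()].
#' @param x input sample, 16-bit signed integer.
#' @return the 16-bit output sample.
#' @examples
#' spec <- filter_spec(b = 26810, a = 26810)  # identity
#' st <- filter_state(spec)
#' filter_assess(st, 123)  # 123
#' @export
filter_assess <- function(state, x) {
  if (!is.finite(x) || x != trunc(x) || x < -32768 || x > 32767)
    stop("input sample must be a 16-bit signed integer", call. = FALSE)
  spec <- state$spec
  state$xs <- c(as.integer(x), state$xs[-length(state$xs)])
  acc <- sum(as.numeric(spec$b) * as.numeric(state$xs))
  if (spec$q > 0)
    acc <- acc - sum(as.numeric(spec$a[-1]) * as.numeric(state$ys[-length(state$ys)]))
  check_accum32(acc, "filter accumulator")
  y <- rounded_div(acc, spec$a[1])
  state$ys <- c(y, state$ys[-length(state$ys)])
  y
}

#' Filter a whole sample stream in Q15 fixed point
#'
#' Stream version of [filter_assess()]: applies the filter to an entire
#' integer sample vector with zero initial history. Bit-identical to
#' calling [filter_assess()] sample by sample, but runs in compiled code
#' so that hours of signal at biosignal rates process in well under a
#' second.
#'
#' @param x integer vector of 16-bit input samples.
#' @param spec a [filter_spec()].
#' @return integer vector of output samples, same length as `x`.
#' @export
q15_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  x <- check_sample_vec(x)
  cpp_q15_filter(x, spec$b, spec$a)
}

#' Double-precision reference filter
#'
#' Evaluates the same difference equation as [q15_filter()] but in double
#' precision with exact division (no rounding to integers). This is the
#' reference the fixed-point pipeline is validated against, mirroring the
#' role of an offline numerical environment in a hardware-vs-host
#' comparison. Delegates to [signal::filter()].
#'
#' @inheritParams q15_filter
#' @return numeric vector of reference outputs.
#' @export
ref_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  as.numeric(signal::filter(as.numeric(spec$b), as.numeric(spec$a),
                            as.numeric(x)))
}

check_sample_vec <- function(x) {
  if (!is.numeric(x)) stop("samples must be numeric", call. = FALSE)
  if (any(!is.finite(x)) || any(x != trunc(x)) || any(x < -32768 | x > 32767))
    stop("samples must be 16-bit signed integers", call. = FALSE)
  as.integer(x)
}

# ---------------------------------------------------------------------------
# polyphase decimating FIR

#' Polyphase decimating FIR specification
#'
#' A `p+1`-tap FIR filter combined with keep-every-`D` downsampling:
#' \deqn{y[n] = \sum_{k=0}^{p} x[nD - k]\, h[k]}
#' Internally the taps are split across `D` sub-filters of
#' `ceiling((p+1)/D)` taps each, so every input sample touches a single
#' sub-filter and outputs appear at rate `Fs / D`. Taps are raw Q15
#' integers; each emitted output is the 32-bit accumulator divided by
#' `2^15` with round-half-to-even, so a unity-gain tap set keeps unity
#' gain.
#'
#' @param h FIR taps `h[0..p]`, raw Q15 integers (at most 255).
#' @param D decimation factor (>= 1).
#' @return a `polyphase_spec` object.
#' @export
polyphase_spec <- function(h, D) {
  h <- check_q15_raw(h, "h")
  if (length(h) < 1 || length(h) > 255)
    stop("`h` must hold 1..255 taps", call. = FALSE)
  if (D < 1 || D != trunc(D)) stop("`D` must be a positive integer", call. = FALSE)
  structure(list(h = h, D = as.integer(D), p = length(h) - 1L),
            class = "polyphase_spec")
}

#' @rdname polyphase_spec
#' @param spec a `polyphase_spec`.
#' @export
polyphase_state <- function(spec) {
  stopifnot(inherits(spec, "polyphase_spec"))
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$xs <- integer(spec$p + 1L)
  e$n_in <- 0L
  class(e) <- "polyphase_state"
  e
}

#' Consume one sample through the polyphase decimator
#'
#' Consumes one input sample and returns an output only on inputs
#' `1, D+1, 2D+1, ...` (i.e. the output sequence equals full-rate FIR
#' filtering followed by keeping every `D`-th output, starting at the
#' first). Returns `NULL` on the `D - 1` intermediate inputs.
#'
#' For whole streams use [q15_polyphase()].
#'
#' @param state a [polyphase_state()].
#' @param x input sample, 16-bit signed integer.
#' @return output sample or `NULL`.
#' @export
polyphase_assess <- function(state, x) {
  if (!is.finite(x) || x != trunc(x) || x < -32768 || x > 32767)
    stop("input sample must be a 16-bit signed integer", call. = FALSE)
  spec <- state$spec
  state$xs <- c(as.integer(x), state$xs[-length(state$xs)])
  state$n_in <- state$n_in + 1L
  if ((state$n_in - 1L) %% spec$D != 0L) return(NULL)
  acc <- sum(as.numeric(spec$h) * as.numeric(state$xs))
  check_accum32(acc, "polyphase accumulator")
  rounded_div(acc, 32768)
}

#' Decimate a whole stream through the polyphase FIR
#'
#' Stream version of [polyphase_assess()], in compiled code. With `n`
#' inputs it emits `ceiling(n / D)` outputs.
#'
#' @param x integer vector of 16-bit input samples.
#' @param spec a [polyphase_spec()].
#' @return integer vector of decimated output samples.
#' @export
q15_polyphase <- function(x, spec) {
  stopifnot(inherits(spec, "polyphase_spec"))
  x <- check_sample_vec(x)
  cpp_q15_polyphase(x, spec$h, spec$D)
}

# ---------------------------------------------------------------------------
# Goertzel single-bin power

#' Goertzel single-bin power detector
#'
#' Measures the spectral power of one frequency without a full FFT, via
#' the second-order recurrence
#' \deqn{s[n] = x[n] + 2\cos(\omega_0)\, s[n-1] - s[n-2]}
#' iterated over `N` data samples plus one final iteration with the input
#' forced to zero, after which the power is
#' \deqn{P = s_1^2 + s_2^2 - 2 s_1 s_2 \cos(\omega_0)}
#' from the final two state values. With the extra zero-input iteration
#' this equals the squared magnitude of the length-`N` single-bin DFT at
#' `w0` exactly (for any `w0`, not only bin centres). The state resets
#' after each emission, so a long stream yields one power value per `N`
#' inputs.
#'
#' In `"float"` mode (default) the recurrence runs in double precision.
#' In `"q15"` mode the tuning constant is quantized to Q15 and the
#' recurrence runs on 32-bit integers: the state update multiplies by the
#' quantized cosine, doubles in the accumulator, and rescales by `2^15`
#' with round-half-to-even; overflow raises an error.
#'
#' @param cos_w0 tuning value, `cos(w0)` with `w0 = 2 * pi * f / fs`.
#' @param N iteration (block) length, >= 1.
#' @param mode `"float"` or `"q15"`.
#' @return `goertzel_spec()`: specification; `goertzel_state()`: mutable
#'   state.
#' @examples
#' sp <- goertzel_spec(cos(2 * pi * 8 / 64), N = 64)
#' st <- goertzel_state(sp)
#' x <- round(1000 * cos(2 * pi * 8 * (0:63) / 64))
#' p <- NULL
#' for (xi in x) p <- goertzel_power(st, xi)
#' p  # squared magnitude of the 8th DFT bin
#' @export
goertzel_spec <- function(cos_w0, N, mode = c("float", "q15")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(cos_w0), length(cos_w0) == 1, abs(cos_w0) <= 1)
  if (N < 1 || N != trunc(N)) stop("`N` must be a positive integer", call. = FALSE)
  structure(
    list(cos_w0 = cos_w0, cos_q15 = to_q15(cos_w0), N = as.integer(N),
         mode = mode),
    class = "goertzel_spec"
  )
}

#' @rdname goertzel_spec
#' @param spec a `goertzel_spec`.
#' @export
goertzel_state <- function(spec) {
  stopifnot(inherits(spec, "goertzel_spec"))
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$s1 <- 0
  e$s2 <- 0
  e$iter <- 0L
  class(e) <- "goertzel_state"
  e
}

goertzel_step <- function(state, xi) {
  spec <- state$spec
  if (spec$mode == "float") {
    s <- xi + 2 * spec$cos_w0 * state$s1 - state$s2
  } else {
    prod2 <- 2 * as.numeric(spec$cos_q15) * state$s1
    s <- xi + rounded_div_wide(prod2, 32768) - state$s2
    check_accum32(s, "Goertzel state")
  }
  state$s2 <- state$s1
  state$s1 <- s
  invisible(state)
}

# rounded_div without the 16-bit saturation: used where the quotient is a
# 32-bit state value, not a sample
rounded_div_wide <- function(n, d) {
  s <- sign(d)
  n <- n * s
  d <- abs(d)
  q <- n %/% d
  r <- n - q * d
  if (r < 0) { q <- q - 1; r <- r + d }
  if (2 * r > d || (2 * r == d && q %% 2 != 0)) q <- q + 1
  q
}

#' @rdname goertzel_spec
#' @param state a `goertzel_state`.
#' @param x input sample.
#' @return `goertzel_power()`: the power `P` after every `N`-th input,
#'   otherwise `NULL`.
#' @export
goertzel_power <- function(state, x) {
  if (!is.finite(x)) stop("input sample must be finite", call. = FALSE)
  spec <- state$spec
  goertzel_step(state, x)
  state$iter <- state$iter + 1L
  if (state$iter < spec$N) return(NULL)
  # final iteration with x[N] = 0, then evaluate the power
  goertzel_step(state, 0)
  s1 <- state$s1
  s2 <- state$s2
  if (spec$mode == "float") {
    P <- s1^2 + s2^2 - 2 * s1 * s2 * spec$cos_w0
  } else {
    cross <- rounded_div_wide(2 * s1 * s2 * as.numeric(spec$cos_q15), 32768)
    P <- s1^2 + s2^2 - cross
    if (abs(P) > 2^31 - 1)
      stop("Goertzel power overflowed the 32-bit range", call. = FALSE)
  }
  state$s1 <- 0
  state$s2 <- 0
  state$iter <- 0L
  P
}

#' Goertzel power of whole blocks
#'
#' Convenience wrapper: splits `x` into consecutive blocks of `N` samples
#' (discarding a trailing partial block) and returns one power value per
#' block via [goertzel_power()].
#'
#' @param x numeric sample vector.
#' @param spec a [goertzel_spec()].
#' @return numeric vector of power values, one per complete block.
#' @export
goertzel_stream <- function(x, spec) {
  st <- goertzel_state(spec)
  n_blocks <- length(x) %/% spec$N
  out <- numeric(n_blocks)
  j <- 0L
  for (xi in x[seq_len(n_blocks * spec$N)]) {
    p <- goertzel_power(st, xi)
    if (!is.null(p)) {
      j <- j + 1L
      out[j] <- p
    }
  }
  out
}

# ---------------------------------------------------------------------------
# sliding-window segmentation

#' Sliding-window block segmentation
#'
#' Collects incoming samples into analysis windows of length `L` that
#' advance by a hop of `H` samples: each new window shares its oldest
#' `L - H` samples with its predecessor. `block_add()` appends one sample
#' (an error once the window is full), `block_ready()` tests whether `L`
#' samples are buffered, `block_access()` reads sample `i` (0-based, oldest
#' first), and `block_advance()` discards the oldest `H` samples so `H` new
#' ones complete the next window. `block_energy()` returns the sum of
#' squares of the current window, accumulated in 32 bits.
#'
#' @param L window length in samples.
#' @param H hop size in samples, `1 <= H <= L`.
#' @return `block_spec()`: specification; `block_state()`: mutable window
#'   state.
#' @examples
#' st <- block_state(block_spec(L = 10, H = 4))
#' for (i in 1:10) block_add(st, 1)
#' block_ready(st)    # TRUE
#' block_energy(st)   # 10
#' block_advance(st)  # keep newest 6, need 4 more
#' @export
block_spec <- function(L, H) {
  stopifnot(L >= 1, L == trunc(L), H >= 1, H == trunc(H), H <= L)
  structure(list(L = as.integer(L), H = as.integer(H)), class = "block_spec")
}

#' @rdname block_spec
#' @param spec a `block_spec`.
#' @export
block_state <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$buf <- numeric(0)
  class(e) <- "block_state"
  e
}

#' @rdname block_spec
#' @param state a `block_state`.
#' @param x sample to append.
#' @export
block_add <- function(state, x) {
  if (length(state$buf) >= state$spec$L)
    stop("window overflow: window is full, advance before adding", call. = FALSE)
  state$buf <- c(state$buf, x)
  invisible(state)
}

#' @rdname block_spec
#' @export
block_ready <- function(state) length(state$buf) == state$spec$L

#' @rdname block_spec
#' @param i 0-based sample index in `[0, L-1]`, oldest first.
#' @export
block_access <- function(state, i) {
  if (!block_ready(state))
    stop("window not ready", call. = FALSE)
  if (i < 0 || i >= state$spec$L || i != trunc(i))
    stop("block index out of bounds", call. = FALSE)
  state$buf[i + 1]
}

#' @rdname block_spec
#' @export
block_advance <- function(state) {
  H <- state$spec$H
  if (length(state$buf) < H)
    stop("fewer than H samples buffered", call. = FALSE)
  state$buf <- state$buf[-seq_len(H)]
  invisible(state)
}

#' @rdname block_spec
#' @export
block_energy <- function(state) {
  if (!block_ready(state)) stop("window not ready", call. = FALSE)
  e <- sum(as.numeric(state$buf)^2)
  check_accum32(e, "block energy")
  e
}

#' Sliding-window energies of a whole stream
#'
#' Stream version of the window/energy pair: returns the energy of every
#' complete window of length `L` advancing by `H` over `x`; with `n`
#' samples that is `floor((n - L) / H) + 1` values (0 if `n < L`).
#' Runs in compiled code.
#'
#' @param x integer sample vector.
#' @param spec a [block_spec()].
#' @return numeric vector of window energies.
#' @export
block_energies <- function(x, spec) {
  stopifnot(inherits(spec, "block_spec"))
  x <- check_sample_vec(x)
  cpp_block_energy(x, spec$L, spec$H)
}
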