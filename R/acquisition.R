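#' Acquisition (virtual hardware layer) configuration
#'
#' Describes the front end of the simulated platform: a single successive
#' approximation ADC multiplexed over `n_channels` analog inputs, triggered
#' at a fixed interval `t_int = 1 / (fs * n_channels)` so that every channel
#' is sampled at `fs` Hz with uniform spacing. Each channel feeds its own
#' bounded FIFO queue of depth `queue_depth`, from which the DSP layer
#' consumes.
#'
#' The reference platform converts at full 10-bit resolution up to 15 kHz;
#' a configuration above that rate keeps the stated resolution but raises a
#' warning, since the real hardware would have to drop to 8 bits.
#'
#' @param fs per-channel sampling rate in Hz (> 0).
#' @param n_channels number of analog channels, 1..8.
#' @param queue_depth per-channel FIFO capacity in samples (>= 1).
#' @param adc_bits ADC resolution in bits (default 10).
#' @param vref full-scale voltage of the converter (arbitrary units).
#' @return an object of class `acquisition_config` with derived field
#'   `t_int`, the inter-conversion interval in seconds.
#' @examples
#' cfg <- acquisition_config(fs = 250, n_channels = 2, queue_depth = 32)
#' cfg$t_int  # 2 ms
#' @export
acquisition_config <- function(fs, n_channels = 1, queue_depth = 64,
                               adc_bits = 10, vref = 1.0) {
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  if (n_channels < 1 || n_channels > 8 || n_channels != trunc(n_channels))
    stop("`n_channels` must be an integer in 1..8", call. = FALSE)
  if (queue_depth < 1 || queue_depth != trunc(queue_depth))
    stop("`queue_depth` must be a positive integer", call. = FALSE)
  stopifnot(adc_bits >= 1, vref > 0)
  if (adc_bits == 10 && fs > 15000)
    warning("fs above 15 kHz exceeds the platform's full-resolution rate",
            call. = FALSE)
  structure(
    list(
      fs = fs, n_channels = as.integer(n_channels),
      queue_depth = as.integer(queue_depth),
      adc_bits = as.integer(adc_bits), vref = vref,
      t_int = 1 / (fs * n_channels)
    ),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> fs = %g Hz x %d channel(s), Tint = %g ms, %d-bit ADC, queue depth %d\n",
    x$fs, x$n_channels, 1000 * x$t_int, x$adc_bits, x$queue_depth
  ))
  invisible(x)
}

#' Quantize a voltage to an ADC code
#'
#' Models the converter transfer curve as a clamped floor quantizer:
#' `code = floor(2^bits * v / vref)`, limited to `[0, 2^bits - 1]`.
#' Voltages outside `[0, vref)` clip at the rails rather than erroring, as
#' the physical converter would.
#'
#' @param v numeric vector of voltages.
#' @param cfg an [acquisition_config()].
#' @return integer vector of ADC codes.
#' @examples
#' cfg <- acquisition_config(fs = 250)
#' quantize(c(0, 0.5, 1), cfg)  # 0 512 1023
#' @export
quantize <- function(v, cfg) {
  stopifnot(inherits(cfg, "acquisition_config"))
  full <- 2^cfg$adc_bits
  code <- floor(full * v / cfg$vref)
  as.integer(pmin(full - 1, pmax(0, code)))
}

#' Bounded FIFO channel queue
#'
#' The per-channel queue between the hardware layer and the DSP layer.
#' When a push arrives while the queue is full, the incoming sample is
#' dropped (reject-newest) and the overflow counter is incremented, so
#' queued data stays contiguous and every loss is observable.
#'
#' @param capacity queue depth in samples.
#' @return a `channel_queue` object (mutable, environment-backed).
#' @examples
#' q <- channel_queue(2)
#' queue_push(q, 1); queue_push(q, 2); queue_push(q, 3)
#' queue_overflows(q)  # 1: the third push was rejected
#' queue_pop(q)        # 1
#' @export
channel_queue <- function(capacity) {
  stopifnot(capacity >= 1, capacity == trunc(capacity))
  e <- new.env(parent = emptyenv())
  e$buf <- numeric(0)
  e$capacity <- as.integer(capacity)
  e$overflow_count <- 0L
  e$pushed <- 0L
  e$popped <- 0L
  class(e) <- "channel_queue"
  e
}

#' @rdname channel_queue
#' @param q a `channel_queue`.
#' @param x sample value to push.
#' @export
queue_push <- function(q, x) {
  if (length(q$buf) >= q$capacity) {
    q$overflow_count <- q$overflow_count + 1L
    return(invisible(FALSE))
  }
  q$buf <- c(q$buf, x)
  q$pushed <- q$pushed + 1L
  invisible(TRUE)
}

#' @rdname channel_queue
#' @export
queue_pop <- function(q) {
  if (length(q$buf) == 0) stop("pop from empty queue", call. = FALSE)
  x <- q$buf[1]
  q$buf <- q$buf[-1]
  q$popped <- q$popped + 1L
  x
}

#' @rdname channel_queue
#' @export
queue_length <- function(q) length(q$buf)

#' @rdname channel_queue
#' @export
queue_overflows <- function(q) q$overflow_count

#' Multichannel signal source
#'
#' Wraps per-channel voltage functions of time, the simulator's stand-in
#' for the analog world. Each element of `channels` is a function
#' `f(t)` returning the channel voltage at time `t` seconds (vectorised
#' over `t`), defined on `[0, duration]`.
#'
#' @param channels a function or list of functions `time -> voltage`.
#' @param duration signal duration in seconds.
#' @return a `signal_source` object.
#' @examples
#' src <- signal_source(function(t) 0.5 + 0.2 * sin(2 * pi * 10 * t), 1)
#' @export
signal_source <- function(channels, duration) {
  if (is.function(channels)) channels <- list(channels)
  stopifnot(all(vapply(channels, is.function, logical(1))), duration >= 0)
  structure(list(channels = channels, duration = duration),
            class = "signal_source")
}

#' Run the round-robin acquisition process
#'
#' Steps the virtual hardware layer over `duration` seconds: at every
#' multiple of `t_int` the multiplexer selects the next channel in
#' round-robin order, the ADC quantizes the source voltage, and the code is
#' pushed onto that channel's queue. Channel `k` (0-based) is therefore
#' sampled at `t = (k + m * n_channels) * t_int`, i.e. exactly at rate `fs`
#' per channel. If `drain` is `TRUE` (the default) each pushed sample is
#' popped immediately, modelling a consumer that keeps up; with
#' `drain = FALSE` samples accumulate in the bounded queues and overflow is
#' counted.
#'
#' @param source a [signal_source()] with as many channels as `cfg`.
#' @param cfg an [acquisition_config()].
#' @param duration seconds to simulate (defaults to the source duration).
#' @param drain whether a consumer drains every sample as it arrives.
#' @return list with per-channel integer code vectors `codes`, the queue
#'   objects `queues`, and per-channel `overflows`.
#' @export
acquisition_run <- function(source, cfg, duration = source$duration,
                            drain = TRUE) {
  stopifnot(inherits(source, "signal_source"),
            inherits(cfg, "acquisition_config"))
  if (length(source$channels) != cfg$n_channels)
    stop("source channel count does not match configuration", call. = FALSE)
  n_ticks <- floor(duration / cfg$t_int + 1e-9)
  queues <- replicate(cfg$n_channels, channel_queue(cfg$queue_depth),
                      simplify = FALSE)
  codes <- vector("list", cfg$n_channels)
  for (ch in seq_len(cfg$n_channels)) {
    # ticks k = 0 .. n_ticks-1 with k %% Nch == ch-1
    k <- seq.int(ch - 1, n_ticks - 1, by = cfg$n_channels)
    if (length(k) == 0 || k[1] > n_ticks - 1) {
      codes[[ch]] <- integer(0)
      next
    }
    t <- k * cfg$t_int
    v <- source$channels[[ch]](t)
    cd <- quantize(v, cfg)
    if (drain) {
      for (x in cd) {
        queue_push(queues[[ch]], x)
        queue_pop(queues[[ch]])
      }
    } else {
      for (x in cd) queue_push(queues[[ch]], x)
    }
    codes[[ch]] <- cd
  }
  list(
    codes = codes,
    queues = queues,
    overflows = vapply(queues, queue_overflows, integer(1))
  )
}

#' Sample a signal source on each channel's uniform grid
#'
#' Convenience used by the pipeline and scenario runners: returns, per
#' channel, the ADC codes the round-robin acquisition process would push
#' over `duration` seconds (channel k sampled at offsets `(k-1) * t_int`).
#'
#' @inheritParams acquisition_run
#' @return list of integer code vectors, one per channel.
#' @export
sample_codes <- function(source, cfg, duration = source$duration) {
  acquisition_run(source, cfg, duration, drain = TRUE)$codes
}

#' Read a multichannel signal from CSV
#'
#' Expects a header `time,ch0[,ch1,...]` with time in seconds on a strictly
#' increasing regular grid. Values are either raw ADC codes
#' (`input_kind = "codes"`, integers in `[0, 2^bits - 1]`) or voltages
#' (`input_kind = "volts"`, quantized on load through [quantize()]).
#'
#' @param path CSV file path.
#' @param cfg an [acquisition_config()]; its channel count must match.
#' @param input_kind `"codes"` or `"volts"`.
#' @return list with `time` and per-channel integer `codes`.
#' @export
read_signal_csv <- function(path, cfg, input_kind = c("codes", "volts")) {
  input_kind <- match.arg(input_kind)
  d <- read.csv(path, check.names = FALSE)
  if (names(d)[1] != "time")
    stop("first CSV column must be `time`", call. = FALSE)
  tm <- d[[1]]
  if (length(tm) >= 2) {
    dt <- diff(tm)
    if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-6 * mean(dt))
      stop("time must lie on a regular grid", call. = FALSE)
  }
  if (ncol(d) - 1 != cfg$n_channels)
    stop("CSV channel count does not match configuration", call. = FALSE)
  codes <- lapply(d[-1], function(col) {
    if (input_kind == "volts") return(quantize(col, cfg))
    if (any(col != trunc(col) | col < 0 | col > 2^cfg$adc_bits - 1))
      stop("code column outside ADC range", call. = FALSE)
    as.integer(col)
  })
  names(codes) <- names(d)[-1]
  list(time = tm, codes = codes)
}
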