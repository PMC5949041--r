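#' Pipeline stage descriptors
#'
#' A pipeline is a linear chain of DSP stages applied per channel between
#' the hardware-layer queue and the output stream. Each constructor
#' returns a stage descriptor for [pipeline_config()]; `capacity` bounds
#' the stage's output queue (the last stage's output stream is unbounded).
#'
#' * `stage_filter()`: rational Q15 filter (see [filter_spec()]).
#' * `stage_polyphase()`: decimating FIR (see [polyphase_spec()]).
#' * `stage_block_energy()`: sliding-window energy (see [block_spec()]).
#' * `stage_block_emit()`: sliding windows emitted whole (for host-side
#'   transforms such as an FFT applied per block).
#' * `stage_goertzel()`: Goertzel power, one value per `N` samples
#'   (float-mode recurrence; see [goertzel_spec()]).
#'
#' @param spec the corresponding DSP specification object.
#' @param capacity output-queue capacity in samples (default unbounded).
#' @return a `pipeline_stage` descriptor.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_filter <- function(spec, capacity = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  new_stage("filter", list(b = spec$b, a = spec$a), capacity)
}

#' @rdname pipeline_stages
#' @export
stage_polyphase <- function(spec, capacity = NULL) {
  stopifnot(inherits(spec, "polyphase_spec"))
  new_stage("polyphase", list(h = spec$h, D = spec$D), capacity)
}

#' @rdname pipeline_stages
#' @export
stage_block_energy <- function(spec, capacity = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  new_stage("block_energy", list(L = spec$L, H = spec$H), capacity)
}

#' @rdname pipeline_stages
#' @export
stage_block_emit <- function(spec, capacity = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  new_stage("block_emit", list(L = spec$L, H = spec$H), capacity)
}

#' @rdname pipeline_stages
#' @export
stage_goertzel <- function(spec, capacity = NULL) {
  stopifnot(inherits(spec, "goertzel_spec"))
  new_stage("goertzel", list(cos_w0 = spec$cos_w0, N = spec$N), capacity)
}

new_stage <- function(type, params, capacity) {
  if (!is.null(capacity)) {
    stopifnot(capacity >= 1, capacity == trunc(capacity))
    params$capacity <- as.integer(capacity)
  }
  structure(c(list(type = type), params), class = "pipeline_stage")
}

#' Pipeline configuration
#'
#' Combines an acquisition front end with an ordered chain of DSP stages.
#' The same chain is applied independently to every channel (fan-out of
#' the linear chain across channels).
#'
#' @param acquisition an [acquisition_config()].
#' @param stages list of [pipeline_stages] descriptors (may be empty, in
#'   which case the raw codes are the output).
#' @param drain_policy `"whole"`: each stage drains its entire input queue
#'   per task-manager round (the default executive behaviour); `"single"`:
#'   each stage serves one sample per round, for stress-testing queue
#'   sizing.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(acquisition, stages = list(),
                            drain_policy = c("whole", "single")) {
  stopifnot(inherits(acquisition, "acquisition_config"))
  if (inherits(stages, "pipeline_stage")) stages <- list(stages)
  stopifnot(all(vapply(stages, inherits, logical(1), "pipeline_stage")))
  drain_policy <- match.arg(drain_policy)
  structure(
    list(acquisition = acquisition, stages = stages,
         drain_policy = drain_policy),
    class = "pipeline_config"
  )
}

#' Run the acquisition + DSP pipeline
#'
#' Deterministic discrete-event executive: simulated time advances one
#' acquisition tick at a time; at each tick the hardware layer pushes one
#' ADC code onto the owning channel's bounded queue (dropping and counting
#' the sample if the queue is full), then a task-manager round lets every
#' stage consume from its input queue in declared order. Identical
#' configuration and input always yield bit-identical outputs.
#'
#' Inputs may be a [signal_source()] (sampled through the virtual ADC) or
#' a list of per-channel integer code vectors.
#'
#' @param config a [pipeline_config()].
#' @param source a [signal_source()] or list of integer code vectors (one
#'   per channel).
#' @param duration seconds to simulate (required for a `signal_source`;
#'   ignored for code vectors).
#' @return list with `streams` (per-channel output vectors) and `log`, an
#'   `event_log` with per-queue push/pop/overflow/residual counts and
#'   per-stage invocation counts.
#' @examples
#' cfg <- pipeline_config(
#'   acquisition_config(fs = 250, queue_depth = 16),
#'   stage_filter(filter_spec(b = c(2048, 6628, 9458, 6628, 2048), a = 26810))
#' )
#' src <- signal_source(function(t) 0.5 + 0.1 * sin(2 * pi * 5 * t), 2)
#' res <- run_pipeline(cfg, src)
#' length(res$streams[[1]])  # 500 samples: 2 s at 250 Hz
#' @export
run_pipeline <- function(config, source, duration = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  acq <- config$acquisition
  if (inherits(source, "signal_source")) {
    if (is.null(duration)) duration <- source$duration
    codes <- sample_codes(source, acq, duration)
  } else if (is.list(source)) {
    codes <- lapply(source, check_code_vec, acq)
    if (length(codes) != acq$n_channels)
      stop("code list length must equal the channel count", call. = FALSE)
  } else {
    stop("`source` must be a signal_source or a list of code vectors",
         call. = FALSE)
  }
  stages <- lapply(config$stages, unclass)
  drain_whole <- config$drain_policy == "whole"
  per_ch <- lapply(codes, function(cd)
    cpp_sim_chain(cd, acq$queue_depth, stages, drain_whole))
  streams <- lapply(per_ch, `[[`, "out")
  log <- structure(
    list(
      pushed = vapply(per_ch, `[[`, numeric(length(stages) + 1), "pushed"),
      popped = vapply(per_ch, `[[`, numeric(length(stages) + 1), "popped"),
      overflow = vapply(per_ch, `[[`, numeric(length(stages) + 1), "overflow"),
      residual = vapply(per_ch, `[[`, numeric(length(stages) + 1), "residual"),
      invocations = if (length(stages))
        vapply(per_ch, `[[`, numeric(length(stages)), "invocations")
      else NULL,
      saturations = sum(vapply(per_ch, `[[`, numeric(1), "saturations"))
    ),
    class = "event_log"
  )
  list(streams = streams, log = log)
}

check_code_vec <- function(x, acq) {
  x <- check_sample_vec(x)
  if (any(x < 0 | x > 2^acq$adc_bits - 1))
    stop("codes outside ADC range", call. = FALSE)
  x
}

#' @export
print.event_log <- function(x, ...) {
  ov <- sum(x$overflow)
  cat(sprintf("<event_log> %d queue level(s) x %d channel(s); total overflow %g\n",
              nrow(as.matrix(x$pushed)), ncol(as.matrix(x$pushed)), ov))
  invisible(x)
}

#' Total queue overflow recorded in an event log
#'
#' @param log an `event_log` from [run_pipeline()].
#' @return total number of samples dropped at full queues.
#' @export
total_overflow <- function(log) {
  stopifnot(inherits(log, "event_log"))
  sum(log$overflow)
}

#' Expected per-channel sample count
#'
#' The bookkeeping reference used for loss accounting: the number of
#' samples each channel should deliver after decimation, given the
#' sampling rate, run length and decimation factor. A run whose observed
#' counts all equal this value (and whose queues never overflowed) has no
#' failures, i.e. infinite mean time between failures over the run.
#'
#' @param cfg an [acquisition_config()].
#' @param duration run length in seconds.
#' @param decimation decimation factor `D` (default 1).
#' @return expected samples per channel, `floor(fs * duration / D)`.
#' @examples
#' cfg <- acquisition_config(fs = 250, n_channels = 2)
#' expected_sample_count(cfg, 60, decimation = 5)  # 3000 per channel
#' @export
expected_sample_count <- function(cfg, duration, decimation = 1) {
  stopifnot(inherits(cfg, "acquisition_config"), duration >= 0,
            decimation >= 1, decimation == trunc(decimation))
  floor(cfg$fs * duration / decimation + 1e-9)
}
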