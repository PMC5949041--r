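#' Windowed-sinc low-pass FIR design helper
#'
#' Designs a linear-phase low-pass FIR by the Hamming-windowed-sinc
#' method, normalised to unity DC gain, and quantizes the taps to Q15.
#' Used where a scenario needs a low-pass whose taps are not otherwise
#' given (the accelerometer smoothing chain), so that every run uses the
#' identical tap set.
#'
#' @param n_taps number of taps.
#' @param fc cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return list with `h` (raw Q15 integer taps) and `h_float` (the
#'   normalised double-precision taps).
#' @examples
#' d <- design_lowpass_fir(50, fc = 5, fs = 250)
#' sum(d$h_float)  # 1
#' @export
design_lowpass_fir <- function(n_taps, fc, fs) {
  stopifnot(n_taps >= 1, fc > 0, fs > 0, fc < fs / 2)
  m <- (n_taps - 1) / 2
  k <- seq_len(n_taps) - 1
  x <- 2 * fc / fs * (k - m)
  h <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))       # sinc
  h <- h * (0.54 - 0.46 * cos(2 * pi * k / (n_taps - 1)))  # Hamming
  h <- h / sum(h)                                      # unity DC gain
  list(h = to_q15(h), h_float = h)
}

#' Printed scenario filters
#'
#' The two fixed filter configurations of the validation scenarios:
#' `sc1_filter_spec()` is the unity-DC-gain low-pass with double zeros at
#' 100 Hz (Fs = 250 Hz) that removes first-harmonic lighting interference
#' from the infrared blink channel; `sc2_filter_spec()` is the
#' Savitzky-Golay derivative-style high-pass (DC gain exactly zero) that
#' removes the bias of the 4 kHz voice channel.
#'
#' @return a [filter_spec()].
#' @export
sc1_filter_spec <- function() {
  filter_spec(b = c(2048, 6628, 9458, 6628, 2048), a = 26810)
}

#' @rdname sc1_filter_spec
#' @export
sc2_filter_spec <- function() {
  filter_spec(b = c(2731, -21845, 0, 21845, -2731), a = 32767)
}

# evaluate code under a given RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# shared synthetic-signal conditions, as fractions of the ADC full scale
.sc_defaults <- list(
  baseline = 0.5,    # mid-rail operating point
  tone_amp = 0.15,   # 30% of full scale peak-to-peak
  noise_sd = 0.02,   # 2% of full scale
  blink_rate = 0.5,  # blinks per second (Poisson)
  blink_amp = 0.20,
  blink_width = 0.3  # seconds
)

#' Synthetic scenario signals
#'
#' Deterministic (per seed) generators emulating the analog inputs of the
#' validation scenarios, returned already sampled on each channel's
#' uniform grid:
#'
#' * `generate_sc1()`: infrared blink channel at 250 Hz — baseline, smooth
#'   raised-cosine blink bumps (~0.3 s, Poisson arrivals at 0.5 Hz), a
#'   100 Hz powerline-harmonic interference tone, and white Gaussian
#'   noise.
#' * `generate_sc2()`: voice-like channel at 4 kHz — an amplitude-
#'   modulated harmonic tone mixture, a slow drift of the DC operating
#'   point, and noise.
#' * `generate_sc4()`: two accelerometer axes at 250 Hz each —
#'   low-frequency motion (sub-2 Hz sinusoid mixture, random phases) plus
#'   noise.
#'
#' Amplitudes default to 30% of full scale peak-to-peak with noise at 2%
#' of full scale.
#'
#' @param duration signal length in seconds.
#' @param seed RNG seed fixing the signal bit-exactly.
#' @param fs sampling rate in Hz.
#' @param tone_amp interference/tone amplitude (fraction of full scale).
#' @param noise_sd noise standard deviation (fraction of full scale).
#' @param blink_rate blink arrival rate in Hz (SC1).
#' @return list with `time`, per-channel voltage vectors `volts` and, for
#'   convenience, the matching `fs`.
#' @export
generate_sc1 <- function(duration, seed = 1, fs = 250,
                         tone_amp = .sc_defaults$tone_amp,
                         noise_sd = .sc_defaults$noise_sd,
                         blink_rate = .sc_defaults$blink_rate) {
  stopifnot(duration > 0)
  with_seed(seed, {
    t <- seq.int(0, floor(duration * fs + 1e-9) - 1) / fs
    v <- .sc_defaults$baseline + tone_amp * sin(2 * pi * 100 * t)
    n_blinks <- rpois(1, blink_rate * duration)
    if (n_blinks > 0) {
      w <- .sc_defaults$blink_width
      starts <- runif(n_blinks, 0, max(duration - w, 0))
      for (t0 in starts) {
        idx <- seq.int(ceiling(t0 * fs), min(floor((t0 + w) * fs), length(t) - 1)) + 1
        v[idx] <- v[idx] +
          .sc_defaults$blink_amp * 0.5 * (1 - cos(2 * pi * (t[idx] - t0) / w))
      }
    }
    if (noise_sd > 0) v <- v + rnorm(length(t), 0, noise_sd)
    list(time = t, volts = list(v), fs = fs)
  })
}

#' @rdname generate_sc1
#' @export
generate_sc2 <- function(duration, seed = 1, fs = 4000,
                         tone_amp = .sc_defaults$tone_amp,
                         noise_sd = .sc_defaults$noise_sd) {
  stopifnot(duration > 0)
  with_seed(seed, {
    t <- seq.int(0, floor(duration * fs + 1e-9) - 1) / fs
    carrier <- (sin(2 * pi * 220 * t) + 0.5 * sin(2 * pi * 440 * t) +
                  0.25 * sin(2 * pi * 880 * t)) / 1.75
    envelope <- 0.5 * (1 + sin(2 * pi * 3 * t))  # syllable-rate AM
    drift <- 0.05 * sin(2 * pi * 0.2 * t)        # slow bias wander
    v <- .sc_defaults$baseline + drift + tone_amp * envelope * carrier
    if (noise_sd > 0) v <- v + rnorm(length(t), 0, noise_sd)
    list(time = t, volts = list(v), fs = fs)
  })
}

#' @rdname generate_sc1
#' @export
generate_sc4 <- function(duration, seed = 1, fs = 250,
                         tone_amp = .sc_defaults$tone_amp,
                         noise_sd = .sc_defaults$noise_sd) {
  stopifnot(duration > 0)
  with_seed(seed, {
    t <- seq.int(0, floor(duration * fs + 1e-9) - 1) / fs
    mk_axis <- function() {
      freqs <- c(0.3, 0.7, 1.3)
      amps <- tone_amp * c(0.5, 0.3, 0.2)
      phases <- runif(3, 0, 2 * pi)
      v <- .sc_defaults$baseline
      for (i in 1:3) v <- v + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
      if (noise_sd > 0) v <- v + rnorm(length(t), 0, noise_sd)
      v
    }
    list(time = t, volts = list(mk_axis(), mk_axis()), fs = fs)
  })
}

#' Pearson product-moment correlation of two streams
#'
#' The comparison statistic of the validation methodology: fixed-point
#' pipeline output against the double-precision reference.
#'
#' @param x,y numeric vectors of equal length (>= 2), not constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("streams differ in length", call. = FALSE)
  if (length(x) < 2) stop("need at least two samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant stream", call. = FALSE)
  cor(x, y)
}

new_comparison_report <- function(id, pearson_r, expected_n, observed_n,
                                  overflow, streams, extra = list()) {
  structure(
    c(list(
      id = id, pearson_r = pearson_r,
      expected_n = expected_n, observed_n = observed_n,
      overflow = overflow,
      mtbf_infinite = all(observed_n == expected_n) && overflow == 0,
      streams = streams
    ), extra),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  r <- if (all(is.na(x$pearson_r))) "n/a"
       else paste(sprintf("%.4f", x$pearson_r), collapse = ", ")
  cat(sprintf(
    "<comparison_report> %s: pearson r = %s; samples %s/%s per channel; overflow %g; MTBF %s\n",
    x$id, r,
    paste(x$observed_n, collapse = ","), paste(x$expected_n, collapse = ","),
    x$overflow, if (x$mtbf_infinite) "infinite" else "FINITE (losses!)"
  ))
  invisible(x)
}

#' Run validation scenario SC1: blink channel interference filter
#'
#' Samples the synthetic infrared blink channel at 250 Hz through the
#' virtual ADC, runs the printed unity-gain low-pass (double zeros at
#' 100 Hz) through the fixed-point pipeline, applies the identical
#' recurrence in double precision as reference, and reports the Pearson
#' correlation between the two outputs together with the sample-count
#' bookkeeping.
#'
#' @param duration run length in seconds.
#' @param seed RNG seed for the synthetic input.
#' @param queue_depth hardware-layer queue depth.
#' @return a `comparison_report`.
#' @examples
#' rep <- run_sc1(duration = 4, seed = 7)
#' rep$pearson_r  # ~1: fixed point tracks the reference
#' @export
run_sc1 <- function(duration = 10, seed = 1, queue_depth = 32) {
  sig <- generate_sc1(duration, seed)
  acq <- acquisition_config(fs = sig$fs, n_channels = 1,
                            queue_depth = queue_depth)
  codes <- quantize(sig$volts[[1]], acq)
  spec <- sc1_filter_spec()
  cfg <- pipeline_config(acq, stage_filter(spec))
  res <- run_pipeline(cfg, list(codes))
  fixed <- res$streams[[1]]
  ref <- ref_filter(codes, spec)
  new_comparison_report(
    "SC1", pearson(fixed, ref),
    expected_n = expected_sample_count(acq, duration),
    observed_n = length(fixed),
    overflow = total_overflow(res$log),
    streams = list(codes = codes, fixed = fixed, ref = ref)
  )
}

#' Run validation scenario SC2: voice-band power estimation
#'
#' Synthetic voice-like signal at 4 kHz through the printed
#' Savitzky-Golay high-pass (zero DC gain), segmented into 50-sample
#' windows advancing by 25, with the energy of each window emitted. The
#' reference chain runs the same filter and windowing in double
#' precision; the report correlates the two energy streams.
#'
#' @inheritParams run_sc1
#' @export
run_sc2 <- function(duration = 5, seed = 1, queue_depth = 64) {
  sig <- generate_sc2(duration, seed)
  acq <- acquisition_config(fs = sig$fs, n_channels = 1,
                            queue_depth = queue_depth)
  codes <- quantize(sig$volts[[1]], acq)
  spec <- sc2_filter_spec()
  win <- block_spec(L = 50, H = 25)
  cfg <- pipeline_config(acq, list(stage_filter(spec),
                                   stage_block_energy(win)))
  res <- run_pipeline(cfg, list(codes))
  fixed <- res$streams[[1]]
  yref <- ref_filter(codes, spec)
  cs <- cumsum(yref^2)
  starts <- seq.int(0, length(yref) - win$L, by = win$H)
  ref <- cs[starts + win$L] - c(0, cs)[starts + 1]
  n_windows <- floor((expected_sample_count(acq, duration) - win$L) / win$H) + 1
  new_comparison_report(
    "SC2", pearson(fixed, ref),
    expected_n = n_windows,
    observed_n = length(fixed),
    overflow = total_overflow(res$log),
    streams = list(codes = codes, fixed = fixed, ref = ref)
  )
}

#' Run validation scenario SC3: block FFT integration
#'
#' One channel at 250 Hz segmented into non-overlapping 64-sample blocks
#' (hop equal to the window length); each complete block is handed to the
#' host Fourier transform, standing in for the external FFT library of
#' the embedded target. The run verifies sample-count integrity: every
#' acquired sample must reach the block stage and every complete block
#' must be transformed, with zero queue overflow (infinite MTBF over the
#' run).
#'
#' @inheritParams run_sc1
#' @param keep_spectra retain per-block magnitude spectra (memory-heavy
#'   for long runs; the averaged spectrum is always returned).
#' @return a `comparison_report` with extra fields `n_blocks`,
#'   `mean_spectrum` (mean magnitude per bin) and `dominant_bin` (0-based
#'   index of the strongest non-DC bin in the lower half of the 64).
#' @export
run_sc3 <- function(duration = 60, seed = 1, queue_depth = 128,
                    keep_spectra = FALSE) {
  sig <- generate_sc1(duration, seed)  # same front-end family: 250 Hz biosignal
  acq <- acquisition_config(fs = sig$fs, n_channels = 1,
                            queue_depth = queue_depth)
  codes <- quantize(sig$volts[[1]], acq)
  win <- block_spec(L = 64, H = 64)
  cfg <- pipeline_config(acq, stage_block_emit(win))
  res <- run_pipeline(cfg, list(codes))
  flat <- res$streams[[1]]
  n_blocks <- length(flat) %/% 64
  # host transform per block, chunked to bound memory on long runs
  mean_mag <- numeric(64)
  spectra <- if (keep_spectra) vector("list", ceiling(n_blocks / 20000)) else NULL
  done <- 0L
  ci <- 0L
  while (done < n_blocks) {
    nb <- min(20000L, n_blocks - done)
    m <- matrix(flat[(done * 64 + 1):((done + nb) * 64)], nrow = 64)
    mg <- Mod(mvfft(m))
    mean_mag <- mean_mag + rowSums(mg)
    if (keep_spectra) {
      ci <- ci + 1L
      spectra[[ci]] <- mg
    }
    done <- done + nb
  }
  if (n_blocks > 0) mean_mag <- mean_mag / n_blocks
  expected <- expected_sample_count(acq, duration)
  rep <- new_comparison_report(
    "SC3", NA_real_,
    expected_n = expected %/% 64 * 64,   # samples consumed by complete blocks
    observed_n = n_blocks * 64,
    overflow = total_overflow(res$log),
    streams = list(codes = codes),
    extra = list(
      n_blocks = n_blocks,
      mean_spectrum = mean_mag,
      dominant_bin = if (n_blocks > 0) which.max(mean_mag[2:32]) else NA_integer_,
      spectra = if (keep_spectra) do.call(cbind, spectra[seq_len(ci)]) else NULL
    )
  )
  rep
}

#' Run validation scenario SC4: two-axis accelerometer smoothing
#'
#' Two channels sampled round-robin at 250 Hz each, smoothed per channel
#' by a 50-tap windowed-sinc low-pass (5 Hz cutoff) with decimation
#' factor 5, so each axis emits 50 samples/s. The double-precision
#' reference applies the same taps at full rate and keeps every fifth
#' output. The report carries per-channel Pearson correlations and the
#' loss bookkeeping of the full run.
#'
#' @inheritParams run_sc1
#' @export
run_sc4 <- function(duration = 60, seed = 1, queue_depth = 64) {
  sig <- generate_sc4(duration, seed)
  acq <- acquisition_config(fs = sig$fs, n_channels = 2,
                            queue_depth = queue_depth)
  design <- design_lowpass_fir(50, fc = 5, fs = sig$fs)
  spec <- polyphase_spec(design$h, D = 5)
  cfg <- pipeline_config(acq, stage_polyphase(spec))
  codes <- lapply(sig$volts, quantize, cfg = acq)
  res <- run_pipeline(cfg, list(codes[[1]], codes[[2]]))
  ref_full <- lapply(codes, function(cd)
    as.numeric(signal::filter(design$h / 32768, 1, as.numeric(cd))))
  keep <- function(y) y[seq.int(1, length(y), by = spec$D)]
  refs <- lapply(ref_full, keep)
  r <- mapply(pearson, res$streams, refs)
  new_comparison_report(
    "SC4", r,
    expected_n = expected_sample_count(acq, duration, decimation = 5),
    observed_n = vapply(res$streams, length, integer(1)),
    overflow = total_overflow(res$log),
    streams = list(codes = codes, fixed = res$streams, ref = refs),
    extra = list(taps = design$h, group_delay = (length(design$h) - 1) / 2)
  )
}
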