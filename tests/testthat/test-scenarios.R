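test_that("synthetic generators are deterministic per seed", {
  a <- generate_sc1(2, seed = 4)
  b <- generate_sc1(2, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$volts, generate_sc1(2, seed = 5)$volts))
  c1 <- generate_sc4(2, seed = 4)
  expect_identical(c1, generate_sc4(2, seed = 4))
  expect_false(identical(c1$volts[[1]], c1$volts[[2]]))  # independent axes
})

test_that("blink-channel signal carries the 100 Hz interference line", {
  sig <- generate_sc1(8, seed = 2)
  v <- sig$volts[[1]] - mean(sig$volts[[1]])
  spec <- Mod(fft(v))[1:(length(v) / 2)]
  freqs <- (seq_along(spec) - 1) * sig$fs / length(v)
  expect_equal(freqs[which.max(spec)], 100, tolerance = 0.01)
  # degenerate parameters: pure tone + baseline only
  pure <- generate_sc1(1, seed = 2, noise_sd = 0, blink_rate = 0)
  t <- pure$time
  expect_equal(pure$volts[[1]], 0.5 + 0.15 * sin(2 * pi * 100 * t))
})

test_that("interference filter rejects 100 Hz by three orders at unity DC gain", {
  s <- sc1_filter_spec()
  dc <- oracle_freq_response(s$b, s$a, 0)
  expect_identical(Re(dc), 1)  # coefficient sums are exactly equal
  h100 <- oracle_freq_response(s$b, s$a, 2 * pi * 100 / 250)
  expect_lt(Mod(h100) / Mod(dc), 1e-3)
})

test_that("voice-band high-pass has exactly zero DC gain", {
  s <- sc2_filter_spec()
  expect_identical(Mod(oracle_freq_response(s$b, s$a, 0)), 0)
  # a constant input produces all-zero window energies after the transient
  codes <- rep(700L, 1000)
  y <- q15_filter(codes, s)
  en <- block_energies(y, block_spec(50, 25))
  expect_true(all(en[-1] == 0))
})

test_that("fixed-point pipeline tracks the double-precision reference closely", {
  for (seed in 1:3) {
    r1 <- run_sc1(duration = 4, seed = seed)
    expect_gte(r1$pearson_r, 0.97)
    expect_true(r1$mtbf_infinite)
    r2 <- run_sc2(duration = 2, seed = seed)
    expect_gte(r2$pearson_r, 0.97)
    expect_true(r2$mtbf_infinite)
  }
})

test_that("64-bin analysis puts a 62.5 Hz tone in bin 16", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  codes <- quantize(0.5 + 0.3 * sin(2 * pi * 62.5 * t),
                    acquisition_config(fs = fs))
  cfg <- pipeline_config(acquisition_config(fs = fs, queue_depth = 128),
                         stage_block_emit(block_spec(64, 64)))
  res <- run_pipeline(cfg, list(codes))
  blocks <- matrix(res$streams[[1]], nrow = 64)
  mag <- rowMeans(Mod(mvfft(blocks)))
  expect_identical(which.max(mag[2:33]), 16L)  # 0-based bin 16 of 64
  # zero signal gives a flat zero spectrum
  res0 <- run_pipeline(cfg, list(rep(0L, 640)))
  expect_true(all(Mod(mvfft(matrix(res0$streams[[1]], 64))) == 0))
})

test_that("SC3 block runner accounts for every sample", {
  r <- run_sc3(duration = 30, seed = 8)
  expect_true(r$mtbf_infinite)
  expect_equal(r$n_blocks, floor(30 * 250 / 64))
  expect_equal(r$observed_n, r$n_blocks * 64)
  expect_identical(r$overflow, 0)
})

test_that("SC4 decimates two axes to 50 Hz with the designed group delay", {
  r <- run_sc4(duration = 20, seed = 8)
  expect_identical(r$observed_n, c(20L * 50L, 20L * 50L))  # 250/5 per axis
  expect_true(r$mtbf_infinite)
  expect_true(all(r$pearson_r >= 0.97))
  expect_equal(r$group_delay, 24.5)
  # the linear-phase lag is visible in the impulse response: a symmetric
  # 50-tap kernel peaks at samples 24 and 25 (0-based), centre 24.5
  imp <- q15_filter(c(10000L, rep(0L, 59)), filter_spec(r$taps, a = 32767))
  peaks <- order(imp, decreasing = TRUE)[1:2] - 1
  expect_setequal(peaks, c(24, 25))
})

test_that("windowed-sinc design is unity-gain, symmetric and reproducible", {
  d <- design_lowpass_fir(50, fc = 5, fs = 250)
  expect_equal(sum(d$h_float), 1)
  expect_equal(d$h_float, rev(d$h_float))
  expect_identical(d$h, design_lowpass_fir(50, 5, 250)$h)
  # stopband: response at 25 Hz well below passband
  h25 <- Mod(sum(d$h_float * exp(-1i * 2 * pi * 25 / 250 * (0:49))))
  expect_lt(h25, 0.01)
})

test_that("pearson matches the direct product-moment formula", {
  expect_equal(pearson(1:10, 1:10), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  set.seed(2)
  x <- rnorm(100); y <- rnorm(100)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), direct)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:4, 1:5), "length")
})
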