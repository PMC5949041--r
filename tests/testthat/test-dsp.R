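test_that("unity filter passes the input through exactly", {
  spec <- filter_spec(b = 26810, a = 26810)
  st <- filter_state(spec)
  x <- c(0L, 7L, -3L, 1000L, -32768L, 32767L)
  got <- vapply(x, function(xi) filter_assess(st, xi), integer(1))
  expect_identical(got, x)
})

test_that("printed scenario filters hit their exact steady states", {
  # unity-DC-gain low-pass: coefficient sum equals a[0]
  s1 <- sc1_filter_spec()
  expect_identical(sum(s1$b), s1$a[1])
  y1 <- q15_filter(rep(1000L, 100), s1)
  expect_identical(tail(y1, 50), rep(1000L, 50))
  # zero-DC-gain high-pass: coefficient sum is zero
  s2 <- sc2_filter_spec()
  expect_identical(sum(s2$b), 0L)
  y2 <- q15_filter(rep(1000L, 100), s2)
  expect_identical(tail(y2, 50), rep(0L, 50))
})

test_that("stream filter is bit-identical to per-sample assessment and the oracle", {
  set.seed(3)
  for (trial in 1:5) {
    b <- sample(-2000:2000, sample(1:6, 1))
    a <- c(sample(c(20000:32767), 1), sample(-500:500, sample(0:2, 1)))
    x <- sample(-1024:1023, 60, replace = TRUE)
    spec <- filter_spec(b, a)
    stream <- q15_filter(x, spec)
    st <- filter_state(spec)
    single <- vapply(x, function(xi) filter_assess(st, xi), integer(1))
    expect_identical(stream, single)
    expect_identical(as.numeric(stream), oracle_q15_filter(x, b, a))
  }
})

test_that("FIR fixed-point output stays within 1 LSB of the exact-rational filter", {
  set.seed(9)
  for (trial in 1:5) {
    b <- sample(-8000:8000, 7)
    x <- sample(-1024:1023, 80, replace = TRUE)
    y_fix <- q15_filter(x, filter_spec(b, a = 32767))
    # exact rational recurrence, division without rounding
    y_exact <- as.numeric(signal::filter(b, 32767, x))
    expect_true(all(abs(y_fix - y_exact) <= 0.5 + 1e-9))
  }
})

test_that("filter history: reset, view layout and bounds", {
  spec <- filter_spec(b = c(100, 200, 300), a = 26810)
  st <- filter_state(spec)
  filter_assess(st, 7L)
  expect_identical(filter_view(st, 0), 7L)  # newest input slot
  filter_assess(st, 9L)
  expect_identical(filter_view(st, 0), 9L)
  expect_identical(filter_view(st, 1), 7L)
  filter_reset(st)
  for (k in 0:(spec$p + spec$q + 1))
    expect_identical(filter_view(st, k), 0L)
  expect_error(filter_view(st, spec$p + spec$q + 2), "bounds")
})

test_that("filter accumulator overflow is detected, not wrapped", {
  spec <- filter_spec(b = rep(32767L, 10), a = 32767)
  expect_error(q15_filter(rep(32767L, 20), spec), "32-bit")
})

test_that("polyphase decimation equals full-rate filtering plus keep-every-D", {
  # full-rate reference: same taps, accumulate and divide by 2^15 at every
  # sample (exact oracle), then keep outputs 0, D, 2D, ...
  set.seed(5)
  for (trial in 1:8) {
    D <- sample(1:6, 1)
    h <- sample(-5000:5000, sample(D:12, 1))
    x <- sample(-1024:1023, 100, replace = TRUE)
    dec <- q15_polyphase(x, polyphase_spec(h, D))
    full <- vapply(seq_along(x), function(n) {
      xs <- x[n:max(1, n - length(h) + 1)]
      oracle_half_even_div(sum(h[seq_along(xs)] * xs), 2^15)
    }, numeric(1))
    expect_equal(as.numeric(dec), full[seq.int(1, length(x), by = D)])
  }
})

test_that("polyphase emission rate and degenerate D = 1", {
  x <- sample(-1024:1023, 100, replace = TRUE)
  expect_length(q15_polyphase(x, polyphase_spec(c(1000, 2000), D = 5)), 20)
  # pass-through tap at D = 2: outputs on inputs 1, 3, 5, ...
  dec <- q15_polyphase(c(1000L, 2000L, 3000L, 4000L),
                       polyphase_spec(32767, D = 2))
  expect_identical(dec, c(
    rounded_div(32767 * 1000, 32768),
    rounded_div(32767 * 3000, 32768)
  ))
  expect_identical(dec[1], 1000L)
  # D = 1 emits every input
  d1 <- q15_polyphase(x, polyphase_spec(c(1000, 2000), D = 1))
  expect_length(d1, length(x))
})

test_that("Goertzel float mode equals the direct single-bin DFT power", {
  set.seed(21)
  for (N in c(4, 17, 33, 64)) {
    x <- sample(-1024:1023, N)
    for (w0 in c(2 * pi * 3 / N, 2 * pi * 0.137)) {
      sp <- goertzel_spec(cos(w0), N)
      got <- goertzel_stream(x, sp)
      want <- oracle_dft_power(x, w0)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("Goertzel discriminates a matched tone from a mismatched one", {
  N <- 64
  w0 <- 2 * pi * 8 / N
  n <- 0:(N - 1)
  matched <- round(1000 * cos(w0 * n))
  mismatched <- round(1000 * cos(2 * w0 * n))
  sp <- goertzel_spec(cos(w0), N)
  expect_gt(goertzel_stream(matched, sp), goertzel_stream(mismatched, sp))
  # silence gives zero power and the state resets between blocks
  expect_identical(goertzel_stream(rep(0, 3 * N), sp), rep(0, 3))
})

test_that("Goertzel q15 mode approximates the float power on small signals", {
  N <- 32
  w0 <- 2 * pi * 4 / N
  x <- round(200 * cos(w0 * (0:(N - 1))))
  pf <- goertzel_stream(x, goertzel_spec(cos(w0), N, mode = "float"))
  pq <- goertzel_stream(x, goertzel_spec(cos(w0), N, mode = "q15"))
  expect_equal(pq, pf, tolerance = 0.01)
})

test_that("sliding window fills, advances by the hop, and re-fills", {
  st <- block_state(block_spec(L = 10, H = 4))
  for (i in 1:9) block_add(st, i)
  expect_false(block_ready(st))
  block_add(st, 10)
  expect_true(block_ready(st))
  expect_error(block_add(st, 11), "overflow")
  expect_identical(block_access(st, 0), 1)
  expect_identical(block_access(st, 9), 10)
  expect_error(block_access(st, 10), "bounds")
  block_advance(st)
  expect_false(block_ready(st))
  for (i in 11:14) block_add(st, i)
  expect_true(block_ready(st))          # 4 new samples complete the window
  expect_identical(block_access(st, 0), 5)  # oldest surviving sample
})

test_that("block energy equals direct summation, including edge cases", {
  st <- block_state(block_spec(L = 10, H = 10))
  expect_error(block_energy(st), "not ready")
  for (i in 1:10) block_add(st, 1)
  expect_identical(block_energy(st), 10)
  set.seed(13)
  x <- sample(-1024:1023, 500, replace = TRUE)
  for (hop in c(10, 25, 50)) {
    sp <- block_spec(L = 50, H = hop)
    expect_identical(block_energies(x, sp), oracle_energies(x, 50, hop))
  }
})

test_that("non-overlapping 64-sample blocks match the frequency-analysis setup", {
  sp <- block_spec(L = 64, H = 64)
  x <- sample(-1024:1023, 640, replace = TRUE)
  expect_length(block_energies(x, sp), 10)
  expect_error(block_spec(L = 10, H = 11), "H")
})
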