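test_that("cycle models reproduce their printed special cases", {
  expect_identical(cycles_hardware(1)$max, 97)
  expect_equal(cycles_hardware(10)$mean, 88)
  expect_equal(cycles_hardware(1e9)$mean, 87, tolerance = 1e-6)
  expect_identical(cycles_goertzel(0)$max, 1786)
  expect_equal(cycles_goertzel(0)$mean, 1786)  # mean meets max at N = 0
  expect_equal(cycles_timing(0, 10)$mean, 8.7)
  expect_equal(cycles_timing(5, 10)$mean, 4.3 * 5 + 8.7)
  expect_identical(cycles_timing(0, 1)$max, 42)
  expect_equal(cycles_filter(0, 0), 669)
  expect_equal(cycles_block(10), 653 + 510)
})

test_that("polyphase cost sits a structural offset above the plain filter", {
  for (p in c(0, 10, 49, 254)) {
    offset <- cycles_polyphase(p, 1) - cycles_filter(p, 0)
    expect_equal(offset, 103.5 + 0.1 * p)
  }
})

test_that("memory models reproduce their printed values", {
  expect_equal(dm_hardware(1, 1), 30)
  expect_equal(dm_hardware(2, 8), 4 + 40 * 2)
  expect_equal(dm_filter(495, 0, include_coeffs = TRUE), 2008)
  expect_equal(dm_filter(2, 2), 20 + 2 * 6)
  expect_equal(dm_goertzel(), 62)
  expect_equal(dm_block(50), 112)
  expect_equal(dm_timing(3), 25)
  expect_equal(dm_polyphase(49, 5, include_coeffs = TRUE),
               10 + 100 + 4 * 10 + 100)
})

test_that("available-cycle budget shrinks with rate and scales with block size", {
  expect_equal(cycles_available(250), 63903)
  expect_equal(cycles_available_block(10000, 256), 256 * (1600 - 97))
  expect_lt(cycles_available(16e6), 0)
  fs <- c(10, 100, 1000, 10000)
  expect_true(all(diff(vapply(fs, cycles_available, numeric(1))) < 0))
})

test_that("maximum filter length is memory-bound at biosignal rates", {
  expect_identical(max_filter_length(1, 1), 497L)
  # at 250 Hz the budget is still memory-bound: same length as at 1 Hz
  expect_identical(max_filter_length(250, 1), max_filter_length(1, 1))
  # once the budget is below even a 2-coefficient filter, nothing fits
  expect_identical(max_filter_length(22000, 1), 0L)
  # just under the rate limit only trivial lengths survive
  expect_lte(max_filter_length(18000, 1), 4L)
  # non-increasing in sampling rate
  lens <- vapply(c(1, 100, 1000, 5000, 15000, 18000),
                 max_filter_length, integer(1), D = 1)
  expect_true(all(diff(lens) <= 0))
})

test_that("simultaneous Goertzel detectors: memory cap 32, rate caps 1 then 0", {
  expect_identical(max_goertzel_count(100), 32)
  expect_identical(floor((2048 - 30 - 10) / 62), 32)  # the memory bound itself
  expect_identical(max_goertzel_count(9000), 1)
  expect_identical(max_goertzel_count(15000), 1)
  expect_identical(max_goertzel_count(16000), 0)
  # largest whole-kHz rate admitting one detector is 15 kHz
  khz <- 1:20 * 1000
  admitting <- khz[vapply(khz, max_goertzel_count, numeric(1)) >= 1]
  expect_identical(max(admitting), 15000)
  # non-increasing in fs, non-decreasing in N
  counts_fs <- vapply(c(100, 1000, 4000, 8000, 12000, 16000),
                      max_goertzel_count, numeric(1))
  expect_true(all(diff(counts_fs) <= 0))
  counts_N <- vapply(c(1, 4, 16, 64, 1000), function(N)
    max_goertzel_count(5000, N), numeric(1))
  expect_true(all(diff(counts_N) >= 0))
})

test_that("FFT feasibility: any block length to 10 kHz, 16 bins to ~21 kHz", {
  for (n in c(16, 32, 64, 128, 256))
    expect_true(fft_feasible(10000, n)$feasible)
  expect_identical(round(fft_max_rate(16) / 1000), 21)
  expect_false(fft_feasible(22000, 16)$feasible)
  expect_true(fft_feasible(fft_max_rate(16) - 1, 16)$feasible)
  # 256-bin memory check: 1334 + 512 = 1846 fits the 2008 B budget
  rep256 <- fft_feasible(10000, 256)
  expect_equal(rep256$dm_bytes, 1846)
  expect_equal(rep256$dm_budget, 2008)
  expect_error(fft_feasible(1000, 48), "one of")
})

test_that("feasibility curves cross from memory-bound to cycle-bound once", {
  fs <- c(1, 10, 100, 500, 1000, 2000, 5000, 10000, 15000, 18000)
  lens <- vapply(fs, max_filter_length, integer(1), D = 1)
  mem_cap <- max_filter_length(1, 1)
  at_cap <- lens == mem_cap
  # a prefix sits at the memory cap, the suffix decays under the cycle bound
  expect_true(at_cap[1])
  expect_identical(at_cap, rev(sort(at_cap)))
  expect_true(all(diff(lens[!at_cap]) <= 0))
})
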