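test_that("quantize implements the clamped floor transfer curve", {
  cfg <- acquisition_config(fs = 250)
  expect_identical(quantize(0, cfg), 0L)
  expect_identical(quantize(1, cfg), 1023L)    # clamped upper rail
  expect_identical(quantize(0.5, cfg), 512L)   # floor convention midpoint
  expect_identical(quantize(-3, cfg), 0L)
  # quantization error below one code width for in-range voltages
  v <- runif(200)
  err <- abs(v * 1024 - quantize(v, cfg))
  expect_true(all(err < 1))
})

test_that("configuration validates and derives the conversion interval", {
  cfg <- acquisition_config(fs = 250, n_channels = 2, queue_depth = 8)
  expect_equal(cfg$t_int, 0.002)
  expect_error(acquisition_config(fs = 0), "fs")
  expect_error(acquisition_config(fs = 250, n_channels = 9), "1..8")
  expect_error(acquisition_config(fs = 250, queue_depth = 0), "positive")
  expect_warning(acquisition_config(fs = 20000), "15 kHz")
})

test_that("round-robin sampling puts each channel on a uniform fs grid", {
  cfg <- acquisition_config(fs = 250, n_channels = 2, queue_depth = 4)
  # channel identity encoded in the voltage so codes reveal the schedule
  src <- signal_source(list(function(t) rep(0.25, length(t)),
                            function(t) rep(0.75, length(t))), 1)
  res <- acquisition_run(src, cfg)
  expect_length(res$codes[[1]], 250)
  expect_length(res$codes[[2]], 250)
  expect_true(all(res$codes[[1]] == 256))
  expect_true(all(res$codes[[2]] == 768))
  # single channel: exactly fs samples per second
  cfg1 <- acquisition_config(fs = 250, queue_depth = 4)
  res1 <- acquisition_run(signal_source(function(t) rep(0.5, length(t)), 1), cfg1)
  expect_length(res1$codes[[1]], 250)
  expect_identical(sum(res1$overflows), 0L)
})

test_that("full queues reject the newest sample and count the loss", {
  q <- channel_queue(2)
  queue_push(q, 1); queue_push(q, 2); queue_push(q, 3)
  expect_identical(queue_overflows(q), 1L)
  expect_identical(queue_length(q), 2L)
  expect_identical(queue_pop(q), 1)  # FIFO order, oldest survives
  expect_identical(queue_pop(q), 2)
  expect_error(queue_pop(q), "empty")
})

test_that("sample counts are conserved: pushed = popped + queued + overflowed", {
  set.seed(11)
  q <- channel_queue(3)
  attempted <- 0L
  for (i in 1:200) {
    if (runif(1) < 0.6) {
      queue_push(q, i)
      attempted <- attempted + 1L
    } else if (queue_length(q) > 0) {
      queue_pop(q)
    }
    expect_identical(q$pushed + q$overflow_count, attempted)
    expect_identical(q$pushed, q$popped + queue_length(q))
  }
})

test_that("undrained slow consumer loses samples, drained consumer none", {
  cfg <- acquisition_config(fs = 100, queue_depth = 5)
  src <- signal_source(function(t) rep(0.5, length(t)), 2)
  expect_identical(sum(acquisition_run(src, cfg, drain = TRUE)$overflows), 0L)
  res <- acquisition_run(src, cfg, drain = FALSE)
  expect_identical(sum(res$overflows), 200L - 5L)
})

test_that("CSV signals load as codes or quantized voltages", {
  cfg <- acquisition_config(fs = 100, n_channels = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(time = (0:9) / 100, ch0 = 0:9, ch1 = 100:109)
  write.csv(d, path, row.names = FALSE)
  sig <- read_signal_csv(path, cfg, "codes")
  expect_identical(sig$codes$ch0, 0:9)
  # voltage mode quantizes on load
  d2 <- data.frame(time = (0:9) / 100, ch0 = seq(0, 0.9, by = 0.1),
                   ch1 = rep(0.5, 10))
  write.csv(d2, path, row.names = FALSE)
  sig2 <- read_signal_csv(path, cfg, "volts")
  expect_identical(sig2$codes$ch1, rep(512L, 10))
  # irregular grid rejected
  d$time[5] <- d$time[5] + 0.003
  write.csv(d, path, row.names = FALSE)
  expect_error(read_signal_csv(path, cfg, "codes"), "regular")
})
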