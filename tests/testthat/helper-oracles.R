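# Independent reference implementations used to validate the package.
# All are written as directly as possible (brute force over cleverness) and
# never share code with the implementation under test.

# round-half-to-even of the exact rational n/d, via floor division and
# remainder comparison (exact for |n| < 2^53)
oracle_half_even_div <- function(n, d) {
  stopifnot(d != 0)
  if (d < 0) { n <- -n; d <- -d }
  q <- floor(n / d)
  r <- n - q * d
  # repair any floating error in floor()
  while (r < 0) { q <- q - 1; r <- r + d }
  while (r >= d) { q <- q + 1; r <- r - d }
  if (2 * r > d) q + 1
  else if (2 * r < d) q
  else if (q %% 2 == 0) q else q + 1
}

# direct evaluation of the rational filter recurrence in exact integer
# arithmetic with half-even division at each output (sample-by-sample loop)
oracle_q15_filter <- function(x, b, a) {
  p <- length(b) - 1
  q <- length(a) - 1
  xs <- numeric(0)
  ys <- numeric(0)
  out <- numeric(length(x))
  for (n in seq_along(x)) {
    xs <- c(x[n], xs)
    acc <- 0
    for (k in 0:p) if (k + 1 <= length(xs)) acc <- acc + b[k + 1] * xs[k + 1]
    if (q > 0)
      for (k in 1:q) if (k <= length(ys)) acc <- acc - a[k + 1] * ys[k]
    y <- oracle_half_even_div(acc, a[1])
    ys <- c(y, ys)
    out[n] <- y
  }
  out
}

# squared magnitude of the single-bin DFT at angular frequency w0
oracle_dft_power <- function(x, w0) {
  n <- seq_along(x) - 1
  Mod(sum(x * exp(-1i * w0 * n)))^2
}

# sliding-window energies by direct summation
oracle_energies <- function(x, L, H) {
  if (length(x) < L) return(numeric(0))
  starts <- seq.int(1, length(x) - L + 1, by = H)
  vapply(starts, function(s) sum(x[s:(s + L - 1)]^2), numeric(1))
}

# frequency response of the rational filter at angular frequency w
oracle_freq_response <- function(b, a, w) {
  num <- sum(b * exp(-1i * w * (seq_along(b) - 1)))
  den <- a[1] + if (length(a) > 1)
    sum(a[-1] * exp(-1i * w * seq_along(a[-1]))) else 0
  num / den
}
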