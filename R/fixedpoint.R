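#' Q15 fixed-point conversion
#'
#' Q15 is the signed fixed-point format used throughout the DSP layer: a
#' 16-bit integer `raw` represents the rational value `raw / 2^15`, so the
#' representable range is `[-1, 1 - 2^-15]`. Filter coefficients, polyphase
#' taps and the Goertzel tuning constant are all stored in this format.
#'
#' `to_q15()` converts a real value to its nearest Q15 integer, saturating
#' at the format bounds (so `1.0` maps to 32767, not 32768). `from_q15()`
#' is the exact inverse scaling. Conversion is vectorised.
#'
#' @param x numeric vector of real values, nominally in `[-1, 1)`.
#' @param raw integer vector of raw Q15 values in `[-32768, 32767]`.
#' @return `to_q15()`: integer vector of raw Q15 values. `from_q15()`:
#'   numeric vector `raw / 2^15`.
#' @examples
#' to_q15(c(0, 0.5, 1, -1))   # 0 16384 32767 -32768
#' from_q15(to_q15(0.25))     # exactly 0.25
#' @export
to_q15 <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  raw <- round(x * 32768)
  as.integer(pmin(32767, pmax(-32768, raw)))
}

#' @rdname to_q15
#' @export
from_q15 <- function(raw) {
  raw <- check_q15_raw(raw, "raw")
  raw / 32768
}

# validate a vector of raw Q15 integers; returns them as integer
check_q15_raw <- function(raw, name) {
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("`", name, "` must be finite numeric", call. = FALSE)
  if (any(raw != trunc(raw)))
    stop("`", name, "` must hold integer raw Q15 values", call. = FALSE)
  if (any(raw < -32768 | raw > 32767))
    stop("`", name, "` outside 16-bit signed range", call. = FALSE)
  as.integer(raw)
}

#' Integer division with round-half-to-even
#'
#' Divides a 32-bit signed accumulator by a nonzero divisor and rounds the
#' exact rational quotient to the nearest integer, resolving ties to the
#' even neighbour (banker's rounding). This is the quotient rule applied at
#' every filter output: the sum of coefficient products is accumulated in
#' 32 bits and divided by `a[0]` (IIR/FIR filter) or `2^15` (polyphase,
#' Goertzel fixed-point mode). Half-even rounding avoids the systematic
#' bias that round-half-up would feed back through IIR recursions.
#'
#' Rounding is applied to the exact rational value `numerator/denominator`,
#' including for negative operands; there is no truncate-then-adjust step.
#' If the rounded quotient falls outside the 16-bit signed range it is
#' saturated to `[-32768, 32767]` and a warning is raised.
#'
#' @param numerator integer-valued numeric vector (32-bit signed range).
#' @param denominator nonzero integer-valued scalar or vector.
#' @return integer vector of rounded quotients, saturated to 16-bit range.
#' @examples
#' rounded_div(5, 2)   # 2.5 -> 2 (even)
#' rounded_div(7, 2)   # 3.5 -> 4 (even)
#' rounded_div(-5, 2)  # -2.5 -> -2
#' @export
rounded_div <- function(numerator, denominator) {
  if (any(denominator == 0)) stop("division by zero", call. = FALSE)
  if (any(!is.finite(numerator)) || any(!is.finite(denominator)))
    stop("non-finite operand", call. = FALSE)
  if (any(numerator != trunc(numerator)) || any(denominator != trunc(denominator)))
    stop("operands must be integer-valued", call. = FALSE)
  len <- max(length(numerator), length(denominator))
  d <- rep_len(denominator, len)
  # normalise to positive divisor; all quantities stay exactly representable
  n <- rep_len(numerator, len) * sign(d)
  d <- abs(d)
  q <- n %/% d
  r <- n - q * d
  # guard against any floating rounding in %/% for large operands
  fix <- r < 0
  q[fix] <- q[fix] - 1
  r[fix] <- r[fix] + d[fix]
  fix <- r >= d
  q[fix] <- q[fix] + 1
  r[fix] <- r[fix] - d[fix]
  up <- 2 * r > d | (2 * r == d & q %% 2 != 0)
  q[up] <- q[up] + 1
  out <- q
  if (any(out > 32767 | out < -32768)) {
    warning("rounded_div: quotient saturated to 16-bit range", call. = FALSE)
    out <- pmin(32767, pmax(-32768, out))
  }
  as.integer(out)
}

# 32-bit accumulator guard: stop (never wrap) if a sum of products has left
# the representable range. Values are tracked in doubles, exact below 2^53.
check_accum32 <- function(value, context = "accumulator") {
  if (any(abs(value) > 2147483647))
    stop(
      sprintf("%s overflowed the 32-bit signed range", context),
      call. = FALSE
    )
  value
}
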