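#' Non-blocking software timers
#'
#' The platform drives all delays from a single hardware interrupt that
#' fires every millisecond. Every `t0r` milliseconds (the timer resolution,
#' 10 ms by default) the tick routine walks the list of installed timers
#' and decrements each one that has not yet reached zero. Code polls
#' [timer_expired()] instead of blocking, so the pipeline never stalls.
#'
#' A timer counts in units of `t0r` milliseconds: a timer loaded with 100
#' at the default 10 ms resolution expires exactly 1 s after (re)trigger.
#'
#' @param initial reload value in units of `t0r` ms (>= 0).
#' @return `soft_timer()`: a mutable timer object. `timer_system()`: a
#'   mutable system holding the installed-timer list.
#' @examples
#' sys <- timer_system(t0r = 10)
#' tm <- soft_timer(100)
#' timer_install(sys, tm)
#' timer_tick(sys, 1000)   # 1000 ms of simulated time
#' timer_expired(tm)       # TRUE
#' @export
soft_timer <- function(initial) {
  stopifnot(initial >= 0, initial == trunc(initial))
  e <- new.env(parent = emptyenv())
  e$timeout <- as.integer(initial)
  e$timeout_initial <- as.integer(initial)
  class(e) <- "soft_timer"
  e
}

#' @rdname soft_timer
#' @param t0r timer resolution in milliseconds (>= 1).
#' @export
timer_system <- function(t0r = 10) {
  stopifnot(t0r >= 1, t0r == trunc(t0r))
  e <- new.env(parent = emptyenv())
  e$installed <- list()
  e$t0r <- as.integer(t0r)
  e$tick_count <- 0L
  class(e) <- "timer_system"
  e
}

#' @rdname soft_timer
#' @param system a `timer_system`.
#' @param timer a `soft_timer`.
#' @export
timer_install <- function(system, timer) {
  for (t in system$installed)
    if (identical(t, timer))
      stop("timer already installed", call. = FALSE)
  system$installed <- c(system$installed, list(timer))
  invisible(system)
}

#' @rdname soft_timer
#' @export
timer_uninstall <- function(system, timer) {
  keep <- !vapply(system$installed, identical, logical(1), y = timer)
  if (all(keep)) stop("timer not installed", call. = FALSE)
  system$installed <- system$installed[keep]
  invisible(system)
}

#' @rdname soft_timer
#' @export
timer_count <- function(system) length(system$installed)

#' Advance the 1 ms timer tick
#'
#' Each call advances simulated time by `n` milliseconds. On every
#' millisecond whose cumulative count is a multiple of `t0r`, all installed
#' timers with a positive count are decremented by one; timers at zero stay
#' at zero (no underflow). Decrement order follows installation order.
#'
#' @param system a [timer_system()].
#' @param n milliseconds to advance (default 1).
#' @export
timer_tick <- function(system, n = 1) {
  stopifnot(n >= 0, n == trunc(n))
  if (n == 0) return(invisible(system))
  # number of t0r boundaries crossed in (tick_count, tick_count + n]
  t0r <- system$t0r
  crossings <- (system$tick_count + n) %/% t0r - system$tick_count %/% t0r
  system$tick_count <- system$tick_count + as.integer(n)
  if (crossings > 0) {
    for (tm in system$installed)
      tm$timeout <- max(0L, tm$timeout - as.integer(crossings))
  }
  invisible(system)
}

#' @rdname soft_timer
#' @export
timer_expired <- function(timer) timer$timeout == 0L

#' @rdname soft_timer
#' @export
timer_retrigger <- function(timer) {
  timer$timeout <- timer$timeout_initial
  invisible(timer)
}

#' @rdname soft_timer
#' @export
timer_value <- function(timer) timer$timeout
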