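#' Coerce a value to a time schedule
#'
#' Schedules are functions of time (hours) returning a parameter value.  A
#' single number becomes a constant schedule; a data frame (or list) with
#' columns/fields `t` and `value` becomes a piecewise-linear interpolation
#' (flat extrapolation beyond the breakpoints); a function is used as-is and
#' must be vectorised over time.
#'
#' @param x numeric scalar, data.frame/list with `t` and `value`, or function.
#' @return A vectorised function of time.
#' @export
as_schedule <- function(x) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    force(x)
    return(function(t) rep_len(x, length(t)))
  }
  if ((is.data.frame(x) || is.list(x)) && !is.null(x$t) && !is.null(x$value)) {
    if (length(x$t) != length(x$value) || length(x$t) < 1L)
      stop_cyclekin("breakpoint schedule needs equal-length t and value",
                    class = "invalid_config")
    if (length(x$t) == 1L) return(as_schedule(x$value))
    return(stats::approxfun(x$t, x$value, rule = 2))
  }
  stop_cyclekin("cannot interpret schedule of class %s", class(x)[1L],
                class = "invalid_config")
}

#' Time-dependent simulation parameters
#'
#' Bundles the four population-level schedules: mean cell-cycle length
#' `T_mean(t)` (hours), net mode of division `ppdd(t)` = pp - dd in [-1, 1],
#' growth fraction `gamma(t)` in [0, 1] (fraction of progenitors actively
#' cycling), and the per-cell apoptosis hazard `apoptosis_rate(t)` (per hour),
#' plus the coefficient of variation `cv` of per-cell cycle lengths.
#'
#' @param T_mean mean cycle length schedule (hours); constant, breakpoints or
#'   function.
#' @param ppdd mode-of-division schedule, values in [-1, 1].
#' @param gamma growth-fraction schedule, values in [0, 1].
#' @param apoptosis_rate apoptosis hazard schedule (per cell per hour, >= 0).
#' @param cv coefficient of variation of per-cell cycle length (default 0.30).
#' @return An object of class `schedule_set`.
#' @export
schedule_set <- function(T_mean = 20, ppdd = 0, gamma = 1,
                         apoptosis_rate = 0, cv = 0.3) {
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0 || cv >= 1)
    stop_cyclekin("cv must be a single value in [0, 1)", class = "invalid_config")
  out <- list(
    T_mean = as_schedule(T_mean),
    ppdd = as_schedule(ppdd),
    gamma = as_schedule(gamma),
    apoptosis_rate = as_schedule(apoptosis_rate),
    cv = cv
  )
  class(out) <- "schedule_set"
  out
}

#' Validate a schedule set on a time grid
#'
#' Evaluates all four schedules at the given times and checks the range
#' invariants: T_mean > 0, ppdd in [-1, 1], gamma in [0, 1],
#' apoptosis_rate >= 0.
#'
#' @param schedules a `schedule_set`.
#' @param times evaluation times (hours).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_schedules <- function(schedules, times) {
  stopifnot(inherits(schedules, "schedule_set"))
  Tv <- schedules$T_mean(times)
  if (any(!is.finite(Tv)) || any(Tv <= 0))
    stop_cyclekin("T_mean(t) must be finite and > 0", class = "invalid_config")
  pv <- schedules$ppdd(times)
  if (any(pv < -1 - 1e-12) || any(pv > 1 + 1e-12))
    stop_cyclekin("ppdd(t) must lie in [-1, 1]", class = "invalid_parameter")
  gv <- schedules$gamma(times)
  if (any(gv < -1e-12) || any(gv > 1 + 1e-12))
    stop_cyclekin("gamma(t) must lie in [0, 1]", class = "invalid_config")
  av <- schedules$apoptosis_rate(times)
  if (any(av < 0))
    stop_cyclekin("apoptosis_rate(t) must be >= 0", class = "invalid_config")
  invisible(TRUE)
}

# Average of a schedule over [t0, t1] by the trapezoid rule on a fine grid.
schedule_mean <- function(f, t0, t1, n = 200L) {
  if (t1 <= t0) return(f(t0))
  tt <- seq(t0, t1, length.out = n + 1L)
  trapz(tt, f(tt)) / (t1 - t0)
}
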