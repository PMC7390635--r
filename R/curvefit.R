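# Shared regression utilities: three-parameter sigmoid (logistic) fits of
# count time-series and linear fits with the +/-SE slope-error scheme.

#' Fit a three-parameter sigmoid to a count time-series
#'
#' Fits f(t) = A / (1 + exp(-(t - t0)/tau)) by Levenberg-Marquardt least
#' squares, optionally weighted by 1/se^2.  Initialisation uses
#' A0 = max(counts), t0 at the half-maximum crossing and tau0 = span/10,
#' with a deterministic set of jittered restarts (logistic fits are
#' initialisation sensitive).  Decreasing series are fitted with negative
#' tau, so shrinking progenitor pools are representable.  Exactly constant
#' data are returned as a degenerate flat fit; if no sigmoid start
#' converges, a straight-line fallback is used (recorded in `method`).
#'
#' @param times,counts data points (>= 4).
#' @param ses optional standard errors (weights 1/se^2).
#' @return An object of class `sigmoid_fit` with elements `method`
#'   ("sigmoid", "linear" or "constant"), `coef`, `rss`, `sigma`; use
#'   [predict.sigmoid_fit()] and [sigmoid_deriv()] to evaluate.
#' @export
sigmoid_fit <- function(times, counts, ses = NULL) {
  if (length(times) < 4L)
    stop_cyclekin("sigmoid fit needs >= 4 points", class = "insufficient_data")
  if (length(times) != length(counts))
    stop_cyclekin("times and counts differ in length", class = "invalid_parameter")
  o <- order(times)
  times <- times[o]; counts <- counts[o]
  w <- NULL
  if (!is.null(ses)) {
    ses <- ses[o]
    if (all(is.finite(ses)) && all(ses > 0)) w <- 1 / ses^2
  }

  if (diff(range(counts)) == 0) {
    out <- list(method = "constant",
                coef = c(A = counts[1L], t0 = mean(times), tau = Inf),
                rss = 0, sigma = 0, n = length(times))
    class(out) <- "sigmoid_fit"
    return(out)
  }

  span <- diff(range(times))
  increasing <- stats::cor(times, counts) >= 0
  A0 <- max(counts)
  half <- (max(counts) + min(counts)) / 2
  t00 <- times[which.min(abs(counts - half))]
  tau0 <- (if (increasing) 1 else -1) * span / 10

  starts <- list(
    c(A0, t00, tau0),
    c(A0 * 1.5, t00, tau0 * 2),
    c(A0 * 1.1, t00 - span / 5, tau0 / 2),
    c(A0 * 2.5, t00 + span / 5, tau0 * 4),
    c(A0 * 1.2, mean(times), tau0),
    c(A0 * 4, t00 + span / 2, tau0 * 8)  # near-linear regime
  )

  df <- data.frame(t = times, y = counts)
  if (!is.null(w)) df$w <- w
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      if (is.null(w))
        minpack.lm::nlsLM(y ~ A / (1 + exp(-(t - t0) / tau)), data = df,
                          start = list(A = st[1L], t0 = st[2L], tau = st[3L]),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ A / (1 + exp(-(t - t0) / tau)), data = df,
                          start = list(A = st[1L], t0 = st[2L], tau = st[3L]),
                          weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }

  n <- length(times)
  if (!is.null(best)) {
    cf <- stats::coef(best$fit)
    out <- list(method = "sigmoid",
                coef = c(A = unname(cf["A"]), t0 = unname(cf["t0"]),
                         tau = unname(cf["tau"])),
                rss = best$rss, sigma = sqrt(best$rss / max(1L, n - 3L)),
                n = n)
  } else {
    lf <- if (is.null(w)) stats::lm(y ~ t, data = df)
          else stats::lm(y ~ t, data = df, weights = w)
    rss <- sum(stats::residuals(lf)^2)
    warning("sigmoid fit did not converge from any start; ",
            "using a straight-line fallback", call. = FALSE)
    out <- list(method = "linear",
                coef = c(intercept = unname(stats::coef(lf)[1L]),
                         slope = unname(stats::coef(lf)[2L])),
                rss = rss, sigma = sqrt(rss / max(1L, n - 2L)), n = n)
  }
  class(out) <- "sigmoid_fit"
  out
}

#' Evaluate a sigmoid fit
#'
#' @param object a `sigmoid_fit`.
#' @param t times at which to evaluate.
#' @param ... unused.
#' @return Fitted values at `t`.
#' @export
predict.sigmoid_fit <- function(object, t, ...) {
  cf <- object$coef
  switch(object$method,
    constant = rep_len(cf[["A"]], length(t)),
    linear = cf[["intercept"]] + cf[["slope"]] * t,
    sigmoid = cf[["A"]] / (1 + exp(-(t - cf[["t0"]]) / cf[["tau"]]))
  )
}

#' Derivative of a sigmoid fit
#'
#' @param object a `sigmoid_fit`.
#' @param t times at which to evaluate the derivative.
#' @return d f / d t at `t`.
#' @export
sigmoid_deriv <- function(object, t) {
  cf <- object$coef
  switch(object$method,
    constant = rep_len(0, length(t)),
    linear = rep_len(cf[["slope"]], length(t)),
    sigmoid = {
      e <- exp(-(t - cf[["t0"]]) / cf[["tau"]])
      cf[["A"]] * e / (cf[["tau"]] * (1 + e)^2)
    }
  )
}

#' Ordinary least squares with the plus/minus-SE slope error
#'
#' Fits y ~ x by OLS and reports the slope uncertainty as half the
#' difference between the slopes of two refits with every point shifted up,
#' respectively down, by its standard error (not the OLS standard error).
#'
#' @param x,y data points (>= 2).
#' @param y_se optional per-point standard errors; when absent slope_se is 0.
#' @return A list: slope, intercept, slope_se.
#' @export
linear_fit_with_band <- function(x, y, y_se = NULL) {
  if (length(x) < 2L)
    stop_cyclekin("linear fit needs >= 2 points", class = "insufficient_data")
  if (stats::var(x) == 0)
    stop_cyclekin("identical x values; singular fit", class = "singular_fit")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  slope_se <- 0
  if (!is.null(y_se)) {
    up <- unname(stats::coef(stats::lm((y + y_se) ~ x))[2L])
    dn <- unname(stats::coef(stats::lm((y - y_se) ~ x))[2L])
    slope_se <- abs(up - dn) / 2
  }
  list(slope = slope, intercept = intercept, slope_se = slope_se)
}
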