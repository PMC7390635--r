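# The four cell-cycle / mode-of-division estimators.
#
# C1: single cumulative labeling curve -> T and growth fraction gamma.
# C2: dual cumulative curve -> T and T_S.
# PC: pulse-chase double-positive curve -> T (peak position) and T_S.
# BP: branching-process inversion of the population balance over time
#     windows: with dP = P(t1) - P(t0), dD = D(t1) - D(t0),
#     I = integral of P dt and Phi = integral of apoptosis_rate * P dt,
#       pp - dd = (dP + Phi) / (dP + dD + Phi)
#       T       = gamma_bar * I / (dP + dD + Phi).

#' Single cumulative-curve estimate (C1)
#'
#' Slope from OLS on the first `n_early` points (pre-plateau regime), growth
#' fraction from the mean of the last `n_late` fractions (the plateau), and
#' T = gamma / slope.  The slope error uses the plus/minus-SE refit scheme
#' ([linear_fit_with_band()]); the gamma error is the standard error of the
#' plateau points; the T error combines both in quadrature.
#'
#' @param curve a `cumulative_curve` (exposure_h, fraction, se, n).
#' @param n_early points used for the initial slope: a count (default 4,
#'   the classic four-first-points rule) or "auto" to keep every point
#'   below 90% of the plateau estimate.
#' @param n_late points averaged for the plateau (default 4).
#' @return A list of class `c1_result`: T_hat, gamma_hat, slope, slope_se,
#'   gamma_se, T_se.
#' @export
c1_fit <- function(curve, n_early = 4L, n_late = 4L) {
  curve <- curve[order(curve$exposure_h), ]
  n_early <- resolve_n_early(curve, n_early, min_pts = 2L)
  if (nrow(curve) < n_early + 1L)
    stop_cyclekin("cumulative curve needs at least n_early + 1 points",
                  class = "insufficient_data")
  early <- curve[seq_len(n_early), ]
  lf <- linear_fit_with_band(early$exposure_h, early$fraction, early$se)
  if (lf$slope <= 1e-10)
    stop_cyclekin("non-positive early slope; curve already at plateau",
                  class = "estimation_failure")
  late <- curve[seq(nrow(curve) - min(n_late, nrow(curve)) + 1L, nrow(curve)), ]
  gamma_hat <- mean(late$fraction)
  gamma_se <- if (nrow(late) > 1L) stats::sd(late$fraction) / sqrt(nrow(late))
              else late$se
  if (gamma_hat > 1 || gamma_hat < 0) {
    warning("plateau estimate outside [0, 1]; clipped", call. = FALSE)
    gamma_hat <- min(max(gamma_hat, 0), 1)
  }
  T_hat <- gamma_hat / lf$slope
  T_se <- T_hat * sqrt((gamma_se / gamma_hat)^2 + (lf$slope_se / lf$slope)^2)
  structure(list(T_hat = T_hat, gamma_hat = gamma_hat, slope = lf$slope,
                 slope_se = lf$slope_se, gamma_se = gamma_se, T_se = T_se),
            class = "c1_result")
}

#' Dual cumulative-curve estimate (C2)
#'
#' Least-squares line on the pre-plateau points of the double-positive
#' fraction versus second-label exposure: slope = gamma/T and intercept =
#' gamma * T_S / T, so T = gamma / slope and T_S = intercept * T / gamma.
#' The growth fraction is taken from the plateau when the curve reaches one,
#' otherwise it must be supplied (the dual design does not measure it).
#'
#' @param curve a `cumulative_curve` over second-label exposure duration.
#' @param gamma known growth fraction; if NULL, estimated from the plateau
#'   when the curve has flattened.
#' @param n_early points for the regression (>= 3 required), or "auto" for
#'   the below-90%-of-plateau rule (the pre-plateau regime this design
#'   regresses on).
#' @param n_late points averaged when reading a plateau.
#' @return A list of class `c2_result`: T_hat, T_S_hat, slope, intercept,
#'   gamma_hat, slope_se, T_se.
#' @export
c2_fit <- function(curve, gamma = NULL, n_early = 4L, n_late = 4L) {
  curve <- curve[order(curve$exposure_h), ]
  n_use <- min(resolve_n_early(curve, n_early, min_pts = 3L,
                               plateau = gamma), nrow(curve))
  if (n_use < 3L)
    stop_cyclekin("dual cumulative fit needs >= 3 pre-plateau points",
                  class = "insufficient_data")
  early <- curve[seq_len(n_use), ]
  lf <- linear_fit_with_band(early$exposure_h, early$fraction, early$se)
  if (lf$slope <= 1e-10)
    stop_cyclekin("non-positive early slope in dual cumulative curve",
                  class = "estimation_failure")
  if (is.null(gamma)) {
    late <- curve[seq(nrow(curve) - min(n_late, nrow(curve)) + 1L, nrow(curve)), ]
    flat <- stats::sd(late$fraction) < 0.02 * max(mean(late$fraction), 1e-9)
    if (!flat)
      stop_cyclekin(
        "curve does not reach a plateau; supply gamma (the dual design does not measure the growth fraction)",
        class = "estimation_failure")
    gamma <- min(max(mean(late$fraction), 0), 1)
  }
  T_hat <- gamma / lf$slope
  T_S_hat <- lf$intercept * T_hat / gamma
  if (T_S_hat < 0) {
    warning("negative T_S estimate; clipped to 0", call. = FALSE)
    T_S_hat <- 0
  }
  T_se <- T_hat * lf$slope_se / lf$slope
  structure(list(T_hat = T_hat, T_S_hat = T_S_hat, slope = lf$slope,
                 intercept = lf$intercept, gamma_hat = gamma,
                 slope_se = lf$slope_se, T_se = T_se),
            class = "c2_result")
}

#' Pulse-chase estimate (PC)
#'
#' T is the chase time of the double-positive maximum (labeled cells
#' re-enter S one full cycle after the pulse), refined by a quadratic
#' through the maximum and its two neighbours for sub-grid resolution.
#' T_S is estimated from the rising flank: peak height divided by the slope
#' of the rise (the rise spans roughly one S phase).
#'
#' @param curve a `pulse_chase_curve` (chase_h, fraction, se, n).
#' @return A list of class `pc_result`: T_hat, T_S_hat, peak_fraction.
#' @export
pc_fit <- function(curve) {
  curve <- curve[order(curve$chase_h), ]
  f <- curve$fraction
  if (all(!is.finite(f)) || max(f, na.rm = TRUE) <= 0)
    stop_cyclekin("flat zero double-positive curve; no S-phase re-entry",
                  class = "estimation_failure")
  n <- nrow(curve)
  # Short chases still show the first S phase (pulse-labeled cells that have
  # not yet divided): locate the trough of that initial decay, then the
  # re-entry peak beyond it.
  i_trough <- which.min(f)
  if (i_trough == n)
    stop_cyclekin("double-positive fraction decays without re-entry",
                  class = "estimation_failure")
  i <- i_trough - 1L + which.max(f[i_trough:n])
  if (i == n)
    stop_cyclekin("maximum at the last chase point; peak not bracketed",
                  class = "peak_not_bracketed")
  if (i == i_trough || f[i] <= f[i_trough])
    stop_cyclekin("no re-entry peak beyond the trough",
                  class = "estimation_failure")
  x <- curve$chase_h[(i - 1L):(i + 1L)]
  y <- f[(i - 1L):(i + 1L)]
  qf <- stats::lm(y ~ x + I(x^2))
  b <- stats::coef(qf)
  T_hat <- if (is.finite(b[3L]) && b[3L] < 0) unname(-b[2L] / (2 * b[3L]))
           else curve$chase_h[i]
  # rising flank: points between 10% and 90% of peak height above the trough
  base <- f[i_trough]
  flank <- i_trough:i
  rise <- flank[f[flank] - base >= 0.1 * (f[i] - base) &
                f[flank] - base <= 0.9 * (f[i] - base)]
  T_S_hat <- NA_real_
  if (length(rise) >= 2L) {
    lf <- linear_fit_with_band(curve$chase_h[rise], f[rise])
    if (lf$slope > 0) T_S_hat <- (f[i] - base) / lf$slope
  }
  structure(list(T_hat = T_hat, T_S_hat = T_S_hat, peak_fraction = f[i]),
            class = "pc_result")
}

# Pre-plateau point selection: n_early = "auto" keeps the points below 90%
# of the plateau estimate (the linear-rise regime); an integer keeps that
# many leading points.  `plateau` overrides the plateau estimate (e.g. a
# known growth fraction).
resolve_n_early <- function(curve, n_early, min_pts, plateau = NULL) {
  if (!identical(n_early, "auto")) return(as.integer(n_early))
  if (is.null(plateau)) {
    k <- min(4L, nrow(curve))
    plateau <- mean(curve$fraction[seq(nrow(curve) - k + 1L, nrow(curve))])
  }
  n <- sum(curve$fraction < 0.9 * plateau)
  max(n, min_pts)
}

# Resolve P/D inputs for the branching-process estimator into functions.
resolve_count_fun <- function(counts, col, fit, se_col) {
  y <- counts[[col]]
  tt <- counts$time_h
  if (fit == "sigmoid") {
    ses <- if (!is.null(se_col) && se_col %in% names(counts)) counts[[se_col]]
    sf <- sigmoid_fit(tt, y, ses)
    function(t) predict(sf, t)
  } else {
    stats::approxfun(tt, y, rule = 2)
  }
}

#' Branching-process inversion (BP)
#'
#' Inverts the population balance over consecutive windows of a time grid.
#' For a window [t0, t1] with progenitor change dP, differentiated-cell
#' change dD, progenitor exposure I = integral of P dt, apoptotic mass
#' Phi = integral of apoptosis_rate(t) P(t) dt and window-average growth
#' fraction gamma_bar:
#' \deqn{pp - dd = (\Delta P + \Phi) / (\Delta P + \Delta D + \Phi)}
#' \deqn{T = \bar\gamma I / (\Delta P + \Delta D + \Phi)}
#' Windows where dP + dD + Phi <= 0 (no net divisions) are masked, not
#' extrapolated; pp - dd values outside [-1, 1] are clipped with a warning.
#'
#' @param counts a `counts_ts` (or any data.frame with time_h, P, D); used
#'   unless `P_fun`/`D_fun` are given.
#' @param gamma growth fraction: constant, breakpoints or function of time.
#' @param apoptosis_rate progenitor apoptosis hazard (same forms).
#' @param grid estimation grid (hours); default hourly over the data span.
#' @param fit "sigmoid" fits three-parameter sigmoids to P and D first (the
#'   smooth-inversion workflow); "direct" interpolates the raw points.
#' @param P_fun,D_fun optional functions of time overriding `counts`
#'   (e.g. noise-free model curves).
#' @param subdivisions sub-intervals per window for the integrals.
#' @return A data.frame of class `branching_estimate`: t0, t1, t_mid, ppdd,
#'   T, masked.  `summary()` gives exposure-weighted averages.
#' @export
bp_estimate <- function(counts = NULL, gamma = 1, apoptosis_rate = 0,
                        grid = NULL, fit = c("sigmoid", "direct"),
                        P_fun = NULL, D_fun = NULL, subdivisions = 25L) {
  fit <- match.arg(fit)
  gamma_f <- as_schedule(gamma)
  apop_f <- as_schedule(apoptosis_rate)
  if (is.null(P_fun) || is.null(D_fun)) {
    if (is.null(counts))
      stop_cyclekin("supply counts or P_fun and D_fun", class = "invalid_parameter")
    if (is.null(grid))
      grid <- seq(min(counts$time_h), max(counts$time_h), by = 1)
    if (is.null(P_fun))
      P_fun <- resolve_count_fun(counts, "P", fit, "P_se")
    if (is.null(D_fun))
      D_fun <- resolve_count_fun(counts, "D", fit, "D_se")
  }
  if (is.null(grid))
    stop_cyclekin("a grid is required when using P_fun/D_fun",
                  class = "invalid_parameter")
  grid <- sort(unique(grid))
  if (length(grid) < 2L)
    stop_cyclekin("grid needs at least two points", class = "insufficient_data")

  nw <- length(grid) - 1L
  ppdd <- T_hat <- numeric(nw)
  masked <- logical(nw)
  for (j in seq_len(nw)) {
    t0 <- grid[j]; t1 <- grid[j + 1L]
    tt <- seq(t0, t1, length.out = subdivisions + 1L)
    Pv <- P_fun(tt)
    if (any(!is.finite(Pv)) || any(Pv <= 0)) { masked[j] <- TRUE; next }
    dP <- Pv[length(Pv)] - Pv[1L]
    dD <- D_fun(t1) - D_fun(t0)
    I <- trapz(tt, Pv)
    Phi <- trapz(tt, apop_f(tt) * Pv)
    gbar <- trapz(tt, gamma_f(tt)) / (t1 - t0)
    denom <- dP + dD + Phi
    if (!is.finite(denom) || denom <= 0) { masked[j] <- TRUE; next }
    ppdd[j] <- (dP + Phi) / denom
    T_hat[j] <- gbar * I / denom
  }
  ppdd[!masked] <- clip_range(ppdd[!masked], -1, 1, what = "pp - dd estimate")
  ppdd[masked] <- NA_real_
  T_hat[masked] <- NA_real_
  out <- data.frame(t0 = grid[-length(grid)], t1 = grid[-1L],
                    t_mid = (grid[-length(grid)] + grid[-1L]) / 2,
                    ppdd = ppdd, T = T_hat, masked = masked)
  class(out) <- c("branching_estimate", "data.frame")
  out
}

#' Summarise a branching-process estimate
#'
#' @param object a `branching_estimate`.
#' @param ... unused.
#' @return A list with window-length-weighted means `T_mean` and
#'   `ppdd_mean` over unmasked windows, and the number of masked windows.
#' @export
summary.branching_estimate <- function(object, ...) {
  ok <- !object$masked
  w <- (object$t1 - object$t0)[ok]
  list(T_mean = sum(object$T[ok] * w) / sum(w),
       ppdd_mean = sum(object$ppdd[ok] * w) / sum(w),
       n_masked = sum(!ok))
}

#' 50% confidence bands for the branching-process estimate
#'
#' Shifts the P and D series by plus/minus half of the maximum of their
#' standard errors, refits the sigmoids, re-runs [bp_estimate()] for every
#' shift combination and takes the envelope of the shifted estimates as the
#' 50% confidence band.
#'
#' @param counts data.frame with time_h, P, D, P_se, D_se.
#' @inheritParams bp_estimate
#' @return A `branching_estimate` with extra columns ppdd_lo, ppdd_hi,
#'   T_lo, T_hi.
#' @export
propagate_ci50 <- function(counts, gamma = 1, apoptosis_rate = 0,
                           grid = NULL, fit = "sigmoid", subdivisions = 25L) {
  if (!all(c("P_se", "D_se") %in% names(counts)))
    stop_cyclekin("counts must carry P_se and D_se columns",
                  class = "invalid_parameter")
  centre <- bp_estimate(counts, gamma, apoptosis_rate, grid, fit,
                        subdivisions = subdivisions)
  dP <- max(counts$P_se) / 2
  dD <- max(counts$D_se) / 2
  lo_p <- lo_T <- rep(Inf, nrow(centre))
  hi_p <- hi_T <- rep(-Inf, nrow(centre))
  for (sp in c(-1, 1)) for (sd_ in c(-1, 1)) {
    shifted <- counts
    shifted$P <- counts$P + sp * dP
    shifted$D <- counts$D + sd_ * dD
    est <- suppressWarnings(
      bp_estimate(shifted, gamma, apoptosis_rate, grid, fit,
                  subdivisions = subdivisions))
    lo_p <- pmin(lo_p, est$ppdd, na.rm = FALSE)
    hi_p <- pmax(hi_p, est$ppdd)
    lo_T <- pmin(lo_T, est$T)
    hi_T <- pmax(hi_T, est$T)
  }
  centre$ppdd_lo <- pmin(lo_p, centre$ppdd)
  centre$ppdd_hi <- pmax(hi_p, centre$ppdd)
  centre$T_lo <- pmin(lo_T, centre$T)
  centre$T_hi <- pmax(hi_T, centre$T)
  # a window any shifted refit could not estimate has no defined band
  und <- !is.finite(centre$ppdd_lo) | !is.finite(centre$ppdd_hi) |
         !is.finite(centre$T_lo) | !is.finite(centre$T_hi)
  if (any(und)) {
    centre$masked[und] <- TRUE
    for (cl in c("ppdd", "T", "ppdd_lo", "ppdd_hi", "T_lo", "T_hi"))
      centre[[cl]][und] <- NA_real_
  }
  centre
}

#' Decompose the net mode of division into pp/pd/dd rates
#'
#' Under independent daughter fates with P(progenitor) = p = (1 + ppdd)/2:
#' pp = p^2, pd = 2 p (1 - p), dd = (1 - p)^2, which sum to one and satisfy
#' pp - dd = ppdd exactly.
#'
#' @param ppdd net mode(s) of division in [-1, 1]; vectorised.
#' @return A data.frame of class `mode_rates` with columns ppdd, pp, pd, dd.
#' @export
decompose_modes <- function(ppdd) {
  if (any(!is.finite(ppdd)) || any(ppdd < -1) || any(ppdd > 1))
    stop_cyclekin("ppdd must lie in [-1, 1]", class = "invalid_parameter")
  p <- (1 + ppdd) / 2
  out <- data.frame(ppdd = ppdd, pp = p^2, pd = 2 * p * (1 - p),
                    dd = (1 - p)^2)
  class(out) <- c("mode_rates", "data.frame")
  out
}
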