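# Scenario library and harness comparing the four estimation methods under
# constant and time-varying dynamics, plus the forward-consistency check and
# the factor-decomposition counterfactual.

#' Build a named benchmark scenario
#'
#' Scenarios bundle the schedules and the sampling design used by the
#' methods comparison:
#' \itemize{
#'   \item `constant`: homeostasis, T = 20 h, pp - dd = 0, gamma = 1, no
#'     apoptosis (the regime in which cumulative labeling was derived).
#'   \item `growing`: as constant but pp - dd = 0.3.
#'   \item `variable_T`: T(t) = 20 + 6 cos(2 pi t / t_end) - a smooth
#'     profile ranging 14-26 h whose time average over the run is exactly
#'     20 h; pp - dd = 0.
#'   \item `variable_mode`: pp - dd ramps linearly from +0.5 to -0.5.
#'   \item `variable_both`: both of the above.
#'   \item `custom`: supply `schedules` yourself.
#' }
#' Sampling defaults mirror a 2-h experimental cadence: cumulative
#' fixations at 2-30 h of exposure, dual-label second starts giving 2-16 h
#' of second exposure before a common 30-h fixation, pulse-chase grid
#' 2-30 h.
#'
#' @param name scenario name (above).
#' @param ... overrides of any field (m, t_end, n_runs, seed, cv, dt,
#'   schedules, T, ppdd, gamma, apoptosis_rate, protocol fields ...).
#' @return A list of class `scenario_spec`; `true_T` holds the
#'   time-averaged input cycle length over the run.
#' @export
make_scenario <- function(name = c("constant", "growing", "variable_T",
                                   "variable_mode", "variable_both",
                                   "custom"), ...) {
  name <- match.arg(name)
  ov <- list(...)
  sc <- list(
    name = name, m = 500L, t_end = 48, n_runs = 10L, seed = 1L,
    cv = 0.3, dt = 0.1, record_interval = 2,
    T = 20, ppdd = 0, gamma = 1, apoptosis_rate = 0,
    cum_label_start = 0, cum_fixations = seq(2, 30, by = 2),
    c2_first_start = 0, c2_fixation = 30,
    c2_second_exposures = seq(2, 16, by = 2),
    pc_pulse_at = 2, pc_pulse_width = 0.5, pc_chase = seq(2, 30, by = 2),
    bp_grid = NULL  # NULL: single full-run window (the method's average-T
                    # form); or a numeric grid for a time-resolved estimate
  )
  for (nm in names(ov)) sc[[nm]] <- ov[[nm]]

  t_end <- sc$t_end
  T_sched <- switch(name,
    variable_T = , variable_both =
      function(t) sc$T + 0.3 * sc$T * cos(2 * pi * t / t_end),
    sc$T)
  ppdd_sched <- switch(name,
    growing = if ("ppdd" %in% names(ov)) sc$ppdd else 0.3,
    variable_mode = , variable_both =
      function(t) 0.5 - (t / t_end) * 1.0,
    sc$ppdd)
  if (name == "custom") {
    if (is.null(ov$schedules))
      stop_cyclekin("custom scenario requires `schedules`",
                    class = "invalid_config")
    sc$schedules <- ov$schedules
  } else if (is.null(ov$schedules)) {
    sc$schedules <- schedule_set(T_mean = T_sched, ppdd = ppdd_sched,
                                 gamma = sc$gamma,
                                 apoptosis_rate = sc$apoptosis_rate,
                                 cv = sc$cv)
  }
  sc$true_T <- schedule_mean(sc$schedules$T_mean, 0, sc$t_end)
  sc$true_gamma <- schedule_mean(sc$schedules$gamma, 0, sc$t_end)
  class(sc) <- "scenario_spec"
  sc
}

scenario_config <- function(sc, seed, t_end = sc$t_end) {
  sim_config(sc$m, t_end, sc$schedules, seed = seed, dt = sc$dt,
             record_interval = sc$record_interval)
}

#' Run the four-method comparison on a scenario
#'
#' For each of `n_runs` master seeds, simulates the protocol arms the four
#' methods need (single cumulative, dual cumulative, pulse-chase and an
#' unlabeled counts run), applies C1, C2, PC and BP, and tabulates per-run
#' estimates against the scenario's true time-averaged T.  Estimator
#' failures are recorded per run, not fatal.
#'
#' @param scenario a [make_scenario()] spec.
#' @param methods subset of c("C1", "C2", "PC", "BP").
#' @param verbose print per-run progress.
#' @return A list of class `benchmark_result` with `runs` (method, run,
#'   estimate_h, rel_err, failed) and `summary` (per method: mean estimate,
#'   sd across runs, rel_err_of_mean, mean_abs_rel_err, n_failed).
#' @export
run_comparison <- function(scenario, methods = c("C1", "C2", "PC", "BP"),
                           verbose = FALSE) {
  stopifnot(inherits(scenario, "scenario_spec"))
  sc <- scenario
  rows <- list()
  for (k in seq_len(sc$n_runs)) {
    sk <- derive_seed(sc$seed, k)
    for (mth in methods) {
      est <- tryCatch(switch(mth,
        C1 = {
          cfg <- scenario_config(sc, derive_seed(sk, 1L))
          curve <- cumulative_experiment(cfg, sc$cum_label_start,
                                         sc$cum_label_start + sc$cum_fixations)
          c1_fit(curve)$T_hat
        },
        C2 = {
          cfg <- scenario_config(sc, derive_seed(sk, 2L))
          curve <- dual_cumulative_experiment(
            cfg, sc$c2_first_start,
            sc$c2_fixation - sc$c2_second_exposures, sc$c2_fixation)
          c2_fit(curve, gamma = sc$true_gamma, n_early = "auto")$T_hat
        },
        PC = {
          cfg <- scenario_config(sc, derive_seed(sk, 3L))
          curve <- suppressWarnings(pulse_chase_experiment(
            cfg, sc$pc_pulse_at, sc$pc_pulse_width, sc$pc_chase))
          pc_fit(curve)$T_hat
        },
        BP = {
          cfg <- scenario_config(sc, derive_seed(sk, 4L))
          counts <- run_simulation(cfg)
          # simulated counts feed the equations directly (no measurement
          # noise model to smooth); one full-run window gives the average T
          bpe <- suppressWarnings(bp_estimate(
            counts, gamma = sc$schedules$gamma,
            apoptosis_rate = sc$schedules$apoptosis_rate,
            grid = sc$bp_grid %||% c(0, sc$t_end), fit = "direct"))
          summary(bpe)$T_mean
        }), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        method = mth, run = k, estimate_h = est,
        rel_err = abs(est - sc$true_T) / sc$true_T,
        failed = is.na(est))
    }
    if (verbose) message(sprintf("run %d/%d done", k, sc$n_runs))
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$method), function(d) {
    ok <- !d$failed
    data.frame(
      method = d$method[1L],
      mean_estimate = mean(d$estimate_h[ok]),
      sd_estimate = stats::sd(d$estimate_h[ok]),
      rel_err_of_mean = abs(mean(d$estimate_h[ok]) - sc$true_T) / sc$true_T,
      mean_abs_rel_err = mean(d$rel_err[ok]),
      n_failed = sum(!ok))
  }))
  rownames(summ) <- NULL
  structure(list(scenario = sc$name, true_T = sc$true_T, runs = runs,
                 summary = summ),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark scenario '%s' (true mean T = %.2f h, %d runs)\n",
              x$scenario, x$true_T, max(x$runs$run)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Forward-consistency check of a branching-process estimate
#'
#' Re-simulates the population forward with the estimated schedules from the
#' initial observed state and reports the fraction of observed count points
#' falling inside the 5-95% envelope of the simulations, for P and D
#' separately.  Counts generated by the same dynamics should be covered;
#' a badly wrong estimate collapses the coverage.
#'
#' @param counts observed `counts_ts` (time_h, P, D).
#' @param estimate a `branching_estimate` spanning the counts' time range.
#' @param gamma,apoptosis_rate schedules used in the estimate.
#' @param n_sims number of forward simulations (default 30).
#' @param seed master seed for the forward runs.
#' @param cv,dt simulator settings.
#' @return A list: coverage_P, coverage_D, envelope (data.frame).
#' @export
forward_consistency <- function(counts, estimate, gamma = 1,
                                apoptosis_rate = 0, n_sims = 30L, seed = 1L,
                                cv = 0.3, dt = 0.1) {
  if (nrow(counts) == 0L)
    return(list(coverage_P = NA_real_, coverage_D = NA_real_,
                envelope = data.frame()))
  ok <- !estimate$masked
  if (sum(ok) < 2L)
    stop_cyclekin("estimate has fewer than two usable windows",
                  class = "insufficient_data")
  T_sched <- stats::approxfun(estimate$t_mid[ok], estimate$T[ok], rule = 2)
  ppdd_sched <- stats::approxfun(estimate$t_mid[ok], estimate$ppdd[ok],
                                 rule = 2)
  sch <- schedule_set(T_mean = T_sched, ppdd = ppdd_sched, gamma = gamma,
                      apoptosis_rate = apoptosis_rate, cv = cv)
  t0 <- counts$time_h[1L]
  horizon <- max(counts$time_h) - t0
  m0 <- round(counts$P[1L])
  D0 <- counts$D[1L]
  rec <- min(diff(sort(unique(counts$time_h))))
  Pm <- Dm <- matrix(NA_real_, n_sims, nrow(counts))
  for (s in seq_len(n_sims)) {
    cfg <- sim_config(m0, horizon,
                      schedule_set(T_mean = function(t) T_sched(t + t0),
                                   ppdd = function(t) ppdd_sched(t + t0),
                                   gamma = function(t) sch$gamma(t + t0),
                                   apoptosis_rate = function(t)
                                     sch$apoptosis_rate(t + t0),
                                   cv = cv),
                      seed = derive_seed(seed, 404L, s), dt = dt,
                      record_interval = rec)
    sim <- run_simulation(cfg)
    idx <- vapply(counts$time_h - t0, function(tt)
      which.min(abs(sim$time_h - tt)), integer(1))
    Pm[s, ] <- sim$P[idx]
    Dm[s, ] <- sim$D[idx] + D0
  }
  qs <- function(M) apply(M, 2L, stats::quantile, probs = c(0.05, 0.95))
  qP <- qs(Pm); qD <- qs(Dm)
  env <- data.frame(time_h = counts$time_h,
                    P_lo = qP[1L, ], P_hi = qP[2L, ],
                    D_lo = qD[1L, ], D_hi = qD[2L, ])
  list(
    coverage_P = mean(counts$P >= env$P_lo & counts$P <= env$P_hi),
    coverage_D = mean(counts$D >= env$D_lo & counts$D <= env$D_hi),
    envelope = env)
}

#' Factor-decomposition counterfactual
#'
#' Quantifies how much each schedule (cycle length T, growth fraction
#' gamma, mode of division ppdd), alone or in combination, changes the
#' number of cycling progenitors after `horizon` hours: runs `n_sims`
#' simulations with the baseline schedules, then with the selected factors
#' swapped in from the alternative schedule set, and reports the mean
#' percent change at the horizon relative to all-baseline.
#'
#' @param baseline,alternative two [schedule_set()]s over [0, horizon].
#' @param horizon evaluation time (hours, default 22).
#' @param factors list of character vectors, each a subset of
#'   c("T", "gamma", "ppdd"); defaults to the three singles plus
#'   T+ppdd and all three.
#' @param n_sims simulations per arm (default 30).
#' @param m initial cells per simulation.
#' @param seed,dt simulator settings.
#' @return A data.frame: factors, pct_change, se.
#' @export
factor_decomposition <- function(baseline, alternative, horizon = 22,
                                 factors = list("T", "gamma", "ppdd",
                                                c("T", "ppdd"),
                                                c("T", "gamma", "ppdd")),
                                 n_sims = 30L, m = 500L, seed = 1L,
                                 dt = 0.1) {
  arm_Pc <- function(sch, arm_id) {
    vapply(seq_len(n_sims), function(s) {
      cfg <- sim_config(m, horizon, sch, seed = derive_seed(seed, arm_id, s),
                        dt = dt, record_interval = horizon)
      sim <- run_simulation(cfg)
      sim$P_cycling[nrow(sim)]
    }, numeric(1))
  }
  base_Pc <- arm_Pc(baseline, 0L)
  base_mean <- mean(base_Pc)
  rows <- lapply(seq_along(factors), function(i) {
    fs <- factors[[i]]
    if (!all(fs %in% c("T", "gamma", "ppdd")))
      stop_cyclekin("factors must be subsets of {T, gamma, ppdd}",
                    class = "invalid_parameter")
    sch <- schedule_set(
      T_mean = if ("T" %in% fs) alternative$T_mean else baseline$T_mean,
      ppdd = if ("ppdd" %in% fs) alternative$ppdd else baseline$ppdd,
      gamma = if ("gamma" %in% fs) alternative$gamma else baseline$gamma,
      apoptosis_rate = baseline$apoptosis_rate, cv = baseline$cv)
    Pc <- arm_Pc(sch, i)
    pct <- 100 * (mean(Pc) - base_mean) / base_mean
    se <- 100 * stats::sd(Pc) / sqrt(n_sims) / base_mean
    data.frame(factors = paste(fs, collapse = "+"), pct_change = pct, se = se)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_Pc") <- base_mean
  out
}
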