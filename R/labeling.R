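# In-silico thymidine-analog (EdU/BrdU) labeling layer.  Cells in S phase
# during an active exposure window acquire the label permanently; both
# daughters inherit all labels at division (binary DNA label, no dilution).

#' Define a labeling protocol
#'
#' @param label_name short name for the analog (e.g. "EdU").
#' @param windows exposure intervals: a 2-column matrix or a list of
#'   `c(start, end)` pairs (hours); windows must be non-overlapping with
#'   start < end.
#' @param kind protocol flavour: "cumulative", "pulse" or "dual_second";
#'   informational, the mechanics are identical.
#' @param t_mean optional mean cycle length used to warn when a pulse window
#'   is long relative to the cycle (> T/10).
#' @return An object of class `label_protocol`.
#' @export
label_protocol <- function(label_name, windows,
                           kind = c("cumulative", "pulse", "dual_second"),
                           t_mean = NULL) {
  kind <- match.arg(kind)
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2L)
  if (any(windows[, 2L] <= windows[, 1L]))
    stop_cyclekin("label windows need start < end", class = "invalid_protocol")
  if (nrow(windows) > 1L) {
    o <- order(windows[, 1L])
    windows <- windows[o, , drop = FALSE]
    if (any(windows[-1L, 1L] < windows[-nrow(windows), 2L]))
      stop_cyclekin("label windows must not overlap", class = "invalid_protocol")
  }
  if (kind == "pulse" && !is.null(t_mean) &&
      any(windows[, 2L] - windows[, 1L] > t_mean / 10))
    warning("pulse window longer than T_mean/10; not a short pulse",
            call. = FALSE)
  structure(list(label_name = label_name, windows = windows, kind = kind),
            class = "label_protocol")
}

# Is any part of (t, t + dt] inside an exposure window of the protocol?
window_active <- function(protocol, t, dt) {
  any(protocol$windows[, 1L] < t + dt & protocol$windows[, 2L] > t)
}

# Internal: mark cycling cells (given their progress interval [f0, f1] over
# the step) that traverse S phase while a window is active.  With dt much
# smaller than a phase, treating the whole step as exposed when the window
# overlaps it is accurate to O(dt).
label_in_s <- function(pop, cyc, f0, f1, t, dt, protocols) {
  s_lo <- pop$phase_fractions[1L]
  s_hi <- s_lo + pop$phase_fractions[2L]
  in_s <- f0 < s_hi & f1 > s_lo
  if (!any(in_s)) return(pop)
  for (pr in protocols) {
    if (!window_active(pr, t, dt)) next
    pop <- ensure_label(pop, pr$label_name)
    v <- pop$labels[[pr$label_name]]
    v[cyc[in_s]] <- TRUE
    pop$labels[[pr$label_name]] <- v
  }
  pop
}

# Register a label gate on a population that was initialised without it.
ensure_label <- function(pop, nm) {
  if (is.null(pop$labels[[nm]])) {
    pop$labels[[nm]] <- logical(pop_size(pop))
    pop$D_labels[nm] <- 0
  }
  pop
}

#' Apply labeling to a population for one step
#'
#' Marks every cycling cell whose S phase overlaps `(t, t + dt]` while a
#' protocol window is active.  Quiescent (and retired) cells never acquire
#' labels.  This is the same rule [step_population()] applies internally;
#' exposed for direct use and testing.
#'
#' @param pop a `cell_population`.
#' @param t,dt current time and step (hours).
#' @param protocols list of [label_protocol()] objects.
#' @param schedules a `schedule_set` (for the progression rate).
#' @return The updated population.
#' @export
apply_labeling <- function(pop, t, dt, protocols, schedules) {
  cyc <- which(pop$state == STATE_CYCLING)
  if (!length(cyc) || !length(protocols)) return(pop)
  f0 <- pop$frac[cyc]
  f1 <- pmin(f0 + dt / (pop$rel_len[cyc] * schedules$T_mean(t)), 1)
  label_in_s(pop, cyc, f0, f1, t, dt, protocols)
}

# Fraction of progenitors (cycling + quiescent) positive for all the given
# labels; optionally restricted to cells currently in S phase.
labeled_fraction <- function(pop, labels, s_phase_only = FALSE) {
  n <- pop_size(pop)
  if (n == 0L) return(c(fraction = NA_real_, se = NA_real_, n = 0))
  pos <- rep(TRUE, n)
  for (nm in labels) pos <- pos & pop$labels[[nm]]
  if (s_phase_only)
    pos <- pos & pop$state == STATE_CYCLING &
      phase_of(pop$frac, pop$phase_fractions) == "S"
  p <- sum(pos) / n
  c(fraction = p, se = sqrt(p * (1 - p) / n), n = n)
}

curve_df <- function(rows) {
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

# Rebuild a config with new seed / end / protocols for a replicate arm.
replicate_config <- function(config, seed, t_end, protocols) {
  sim_config(config$initial_count, t_end, config$schedules, seed = seed,
             dt = config$dt, record_interval = min(config$record_interval, t_end),
             protocols = protocols, fate_mode = config$fate_mode,
             modes = config$modes, phase_fractions = config$phase_fractions,
             init_lifetimes = config$init_lifetimes)
}

#' Simulate a cumulative-labeling experiment (C1 design)
#'
#' The analog is added at `label_start` to several identical samples, each
#' fixed at a different time.  By default every fixation time is an
#' independent replicate simulation (fresh seed derived from the master
#' seed); `replicate = "shared"` reads all points off one trajectory
#' instead (for variance studies).
#'
#' @param config a [sim_config()]; its `t_end` is overridden per fixation.
#' @param label_start start of exposure (hours).
#' @param fixation_times fixation times, all > `label_start`.
#' @param replicate "independent" (default) or "shared".
#' @return A `cumulative_curve` data.frame: exposure_h, fraction (labeled
#'   progenitors / all progenitors), se (binomial), n.
#' @export
cumulative_experiment <- function(config, label_start, fixation_times,
                                  replicate = c("independent", "shared")) {
  replicate <- match.arg(replicate)
  if (!length(fixation_times)) {
    out <- data.frame(exposure_h = numeric(0), fraction = numeric(0),
                      se = numeric(0), n = numeric(0))
    class(out) <- c("cumulative_curve", "data.frame")
    return(out)
  }
  if (any(fixation_times <= label_start))
    stop_cyclekin("fixation times must follow label_start",
                  class = "invalid_protocol")
  fixation_times <- sort(fixation_times)
  if (replicate == "shared") {
    pr <- label_protocol("EdU", rbind(c(label_start, max(fixation_times))),
                         "cumulative")
    cfg <- replicate_config(config, derive_seed(config$seed, 101L, 0L),
                            max(fixation_times), list(pr))
    counts <- run_simulation(cfg)
    idx <- vapply(fixation_times, function(ft)
      which.min(abs(counts$time_h - ft)), integer(1))
    p <- counts$P_EdU[idx] / counts$P[idx]
    rows <- lapply(seq_along(idx), function(j) c(
      exposure_h = fixation_times[j] - label_start, fraction = p[j],
      se = sqrt(p[j] * (1 - p[j]) / counts$P[idx[j]]), n = counts$P[idx[j]]))
    return(curve_df(rows))
  }
  rows <- lapply(seq_along(fixation_times), function(i) {
    ft <- fixation_times[i]
    pr <- label_protocol("EdU", rbind(c(label_start, ft)), "cumulative")
    cfg <- replicate_config(config, derive_seed(config$seed, 101L, i), ft,
                            list(pr))
    res <- run_simulation(cfg, return_population = TRUE)
    lf <- labeled_fraction(res$population, "EdU")
    c(exposure_h = ft - label_start, lf)
  })
  curve_df(rows)
}

#' Simulate a dual cumulative-labeling experiment (C2 design)
#'
#' A first analog is given to all samples at the same time; a second analog
#' starts at staggered times; all samples are fixed together.  Reports the
#' double-positive progenitor fraction against the second-label exposure
#' duration.
#'
#' @param config a [sim_config()].
#' @param first_label_start start of the first analog (hours).
#' @param second_label_starts staggered starts of the second analog.
#' @param common_fixation shared fixation time (> all second starts).
#' @return A `cumulative_curve` over second-label exposure duration.
#' @export
dual_cumulative_experiment <- function(config, first_label_start,
                                       second_label_starts, common_fixation) {
  if (any(second_label_starts >= common_fixation))
    stop_cyclekin("second label must start before fixation",
                  class = "invalid_protocol")
  if (any(second_label_starts <= first_label_start))
    stop_cyclekin("second label must start after the first",
                  class = "invalid_protocol")
  second_label_starts <- sort(second_label_starts, decreasing = TRUE)
  rows <- lapply(seq_along(second_label_starts), function(i) {
    s2 <- second_label_starts[i]
    prs <- list(
      label_protocol("A", rbind(c(first_label_start, common_fixation)),
                     "cumulative"),
      label_protocol("B", rbind(c(s2, common_fixation)), "dual_second"))
    cfg <- replicate_config(config, derive_seed(config$seed, 202L, i),
                            common_fixation, prs)
    res <- run_simulation(cfg, return_population = TRUE)
    lf <- labeled_fraction(res$population, c("A", "B"))
    c(exposure_h = common_fixation - s2, lf)
  })
  curve_df(rows)
}

#' Simulate a pulse-chase experiment (PC design)
#'
#' A short pulse of the first analog marks cells in S phase; separate
#' samples are fixed after increasing chase times (measured from the pulse
#' start).  The detector gate identifies labeled cells back in S phase at
#' fixation: either a short second-analog pulse just before fixation
#' ("second_pulse", default) or direct S-phase occupancy ("s_phase").
#'
#' @param config a [sim_config()].
#' @param pulse_at pulse start (hours).
#' @param pulse_width pulse duration (hours, default 0.5, mirroring a 30-min
#'   pulse).
#' @param chase_times chase durations since pulse start; fixation occurs at
#'   `pulse_at + chase`.
#' @param detector "second_pulse" or "s_phase".
#' @param detector_width second-pulse duration (hours).
#' @return A `cumulative_curve`-like data.frame: chase_h, fraction of
#'   progenitors positive for the pulse label and the detector, se, n.
#' @export
pulse_chase_experiment <- function(config, pulse_at, pulse_width = 0.5,
                                   chase_times,
                                   detector = c("second_pulse", "s_phase"),
                                   detector_width = 0.5) {
  detector <- match.arg(detector)
  if (any(chase_times <= pulse_width))
    stop_cyclekin("chase times must exceed the pulse width",
                  class = "invalid_protocol")
  if (max(chase_times) < config$schedules$T_mean(pulse_at))
    warning("chase window shorter than one expected cycle; ",
            "the re-entry peak may be unreachable", call. = FALSE)
  chase_times <- sort(chase_times)
  rows <- lapply(seq_along(chase_times), function(i) {
    ct <- chase_times[i]
    fix <- pulse_at + ct
    prs <- list(label_protocol("A", rbind(c(pulse_at, pulse_at + pulse_width)),
                               "pulse", t_mean = config$schedules$T_mean(pulse_at)))
    if (detector == "second_pulse")
      prs <- c(prs, list(label_protocol(
        "B", rbind(c(max(fix - detector_width, pulse_at + pulse_width), fix)),
        "dual_second")))
    cfg <- replicate_config(config, derive_seed(config$seed, 303L, i), fix, prs)
    res <- run_simulation(cfg, return_population = TRUE)
    lf <- if (detector == "second_pulse")
      labeled_fraction(res$population, c("A", "B"))
    else labeled_fraction(res$population, "A", s_phase_only = TRUE)
    c(chase_h = ct, lf)
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("pulse_chase_curve", "data.frame")
  out
}
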