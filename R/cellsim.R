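# Agent-based simulator of a differentiating progenitor population.
#
# The population is stored column-wise (one vector per cell attribute) for
# speed.  Cycling cells advance a progress fraction f in [0, 1) at rate
# 1 / (r_i * T_mean(t)) per hour, where r_i is a per-cell gamma-distributed
# relative cycle length (mean 1, coefficient of variation cv).  A cell's
# instantaneous cycle length is therefore r_i * T_mean(t): when the schedule
# T_mean(t) changes, all cells rescale proportionally and their phase
# fraction is preserved, so the population-mean cycle length tracks the
# schedule at every time point.  Division fires when f crosses 1.
# Differentiated and apoptotic cells are terminal and are retired into
# counters (they never change phase, divide, or acquire labels).

STATE_CYCLING <- 1L
STATE_QUIESCENT <- 2L

#' Simulation configuration
#'
#' @param initial_count number of starting progenitor cells (m >= 0).
#' @param t_end length of the experiment (hours).
#' @param schedules a [schedule_set()] of time-dependent parameters.
#' @param seed integer seed; the simulator uses R's Mersenne-Twister stream
#'   and identical seeds give bit-identical output.
#' @param dt integration step (hours); must satisfy 0 < dt <= record_interval.
#' @param record_interval spacing of recorded count rows (hours).
#' @param protocols list of [label_protocol()] objects (may be empty).
#' @param fate_mode "independent" draws each daughter's fate independently
#'   with P(progenitor) = (1 + ppdd)/2; "triplet" draws the division type
#'   from explicit (pp, pd, dd) probabilities supplied via `modes`.
#' @param modes for `fate_mode = "triplet"`: numeric vector c(pp, pd, dd)
#'   summing to 1, or a function of time returning such a vector.
#' @param phase_fractions relative lengths of G1, S and G2+M; defaults to
#'   equal thirds.
#' @param init_lifetimes "stationary" (default) starts from the stationary
#'   age structure (length-biased lifetimes, uniform age within the cycle);
#'   "birth_draw" samples initial lifetimes from the plain birth
#'   distribution (a freshly plated cohort).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(initial_count, t_end, schedules = schedule_set(),
                       seed = 1L, dt = 0.1, record_interval = 2,
                       protocols = list(),
                       fate_mode = c("independent", "triplet"), modes = NULL,
                       phase_fractions = c(1, 1, 1) / 3,
                       init_lifetimes = c("stationary", "birth_draw")) {
  fate_mode <- match.arg(fate_mode)
  init_lifetimes <- match.arg(init_lifetimes)
  if (!is.numeric(initial_count) || length(initial_count) != 1L ||
      is.na(initial_count) || initial_count < 0 ||
      initial_count != round(initial_count))
    stop_cyclekin("initial_count must be a non-negative integer",
                  class = "invalid_config")
  if (!(dt > 0 && dt <= record_interval && record_interval <= t_end))
    stop_cyclekin("need 0 < dt <= record_interval <= t_end",
                  class = "invalid_config")
  if (fate_mode == "triplet") {
    if (is.null(modes))
      stop_cyclekin("fate_mode = 'triplet' requires `modes`",
                    class = "invalid_config")
    if (is.numeric(modes)) {
      if (length(modes) != 3L || abs(sum(modes) - 1) > 1e-8 || any(modes < 0))
        stop_cyclekin("modes must be (pp, pd, dd) probabilities summing to 1",
                      class = "invalid_config")
      mm <- modes
      modes <- function(t) mm
    }
  }
  pf <- phase_fractions / sum(phase_fractions)
  if (length(pf) != 3L || any(pf <= 0))
    stop_cyclekin("phase_fractions must be three positive lengths",
                  class = "invalid_config")
  structure(list(
    initial_count = as.integer(initial_count), t_end = t_end,
    schedules = schedules, seed = as.integer(seed), dt = dt,
    record_interval = record_interval, protocols = protocols,
    fate_mode = fate_mode, modes = modes, phase_fractions = pf,
    init_lifetimes = init_lifetimes
  ), class = "sim_config")
}

#' Draw per-cell cycle lengths
#'
#' Cycle lengths are gamma distributed with the requested mean and a standard
#' deviation of `cv` times the mean (shape 1/cv^2, scale mean*cv^2), the
#' dispersion used to mimic intrinsic cell-to-cell variability.  `cv = 0`
#' returns the mean exactly (degenerate distribution).
#'
#' @param n number of draws.
#' @param mean mean cycle length (hours, > 0).
#' @param cv coefficient of variation, 0 <= cv < 1.
#' @return Numeric vector of n positive cycle lengths.
#' @export
draw_cycle_length <- function(n, mean, cv) {
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean <= 0)
    stop_cyclekin("mean cycle length must be > 0", class = "invalid_parameter")
  if (cv < 0 || cv >= 1)
    stop_cyclekin("cv must be in [0, 1)", class = "invalid_parameter")
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep(mean, n))
  stats::rgamma(n, shape = 1 / cv^2, scale = mean * cv^2)
}

# Internal constructor of an empty population container.
new_population <- function(label_names = character(), phase_fractions = c(1, 1, 1) / 3) {
  labels <- stats::setNames(
    lapply(label_names, function(x) logical(0)), label_names)
  structure(list(
    id = integer(0), birth_time = numeric(0), rel_len = numeric(0),
    frac = numeric(0), state = integer(0),
    labels = labels,
    next_id = 1L,
    # retired-compartment counters
    D = 0L, A = 0L, D_labels = stats::setNames(numeric(length(label_names)),
                                               label_names),
    # event bookkeeping
    divisions = 0L, created = 0L, removed = 0L,
    phase_fractions = phase_fractions
  ), class = "cell_population")
}

pop_size <- function(pop) length(pop$id)

pop_keep <- function(pop, keep) {
  pop$id <- pop$id[keep]
  pop$birth_time <- pop$birth_time[keep]
  pop$rel_len <- pop$rel_len[keep]
  pop$frac <- pop$frac[keep]
  pop$state <- pop$state[keep]
  pop$labels <- lapply(pop$labels, function(v) v[keep])
  pop
}

#' Initialise an unsynchronised progenitor population
#'
#' Creates `initial_count` cells with per-cell relative cycle lengths drawn
#' from a gamma distribution (mean `T_mean(0)`, sd `cv * T_mean(0)`) and ages
#' uniform on `[0, cycle_length)` (unsynchronised start).  Each cell starts
#' quiescent with probability `1 - gamma(0)`, otherwise cycling.  Sets the
#' RNG seed from the config, so the whole run is reproducible.
#'
#' @param config a [sim_config()].
#' @return An object of class `cell_population`.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sch <- config$schedules
  validate_schedules(sch, c(0, config$t_end))
  m <- config$initial_count
  label_names <- vapply(config$protocols, function(p) p$label_name, character(1))
  pop <- new_population(label_names, config$phase_fractions)
  if (m == 0L) return(pop)
  T0 <- sch$T_mean(0)
  pop$id <- seq_len(m)
  pop$next_id <- m + 1L
  pop$birth_time <- numeric(m)  # ages assigned via frac; births nominal at 0
  # Stationary start: among cells alive at a random instant, lifetimes are
  # length-biased relative to the birth draw (gamma(k, theta) becomes
  # gamma(k + 1, theta)), and age is uniform within each cell's own cycle.
  # This makes the initial division flux exactly P/T_mean with no transient.
  # init_lifetimes = "birth_draw" samples the plain birth distribution
  # instead (a freshly seeded cohort).
  pop$rel_len <- if (sch$cv > 0 && config$init_lifetimes == "stationary")
    stats::rgamma(m, shape = 1 / sch$cv^2 + 1, scale = sch$cv^2)
  else draw_cycle_length(m, T0, sch$cv) / T0
  pop$frac <- stats::runif(m)
  g0 <- sch$gamma(0)
  pop$state <- ifelse(stats::runif(m) < g0, STATE_CYCLING, STATE_QUIESCENT)
  pop$labels <- stats::setNames(
    lapply(label_names, function(x) logical(m)), label_names)
  pop$created <- m
  pop
}

# Phase from progress fraction, given cumulative phase boundaries.
phase_of <- function(frac, phase_fractions) {
  b1 <- phase_fractions[1L]
  b2 <- phase_fractions[1L] + phase_fractions[2L]
  ifelse(frac < b1, "G1", ifelse(frac < b2, "S", "G2M"))
}

#' View a population as a cell-records data frame
#'
#' Returns one row per live progenitor with its id, birth time, current
#' cycle length (hours), age (hours), phase (G1/S/G2M from equal or
#' configured phase fractions), state, and one logical column per label.
#'
#' @param pop a `cell_population`.
#' @param t current time (hours).
#' @param schedules the `schedule_set` in force (for the current T_mean).
#' @return A data.frame of cell records.
#' @export
population_cells <- function(pop, t, schedules) {
  Tm <- schedules$T_mean(t)
  cl <- pop$rel_len * Tm
  out <- data.frame(
    id = pop$id, birth_time = pop$birth_time,
    cycle_length = cl, age = pop$frac * cl,
    phase = phase_of(pop$frac, pop$phase_fractions),
    state = ifelse(pop$state == STATE_CYCLING, "cycling", "quiescent"),
    stringsAsFactors = FALSE
  )
  for (nm in names(pop$labels)) out[[paste0("label_", nm)]] <- pop$labels[[nm]]
  out
}

#' Draw daughter fates for a set of divisions
#'
#' Under the independent-fates model each daughter becomes a progenitor with
#' probability p = (1 + ppdd)/2 independently of its sister, which reproduces
#' the net mode of division pp - dd = ppdd.  The triplet mode draws the
#' division type from explicit (pp, pd, dd) probabilities instead.
#'
#' @param n number of divisions.
#' @param ppdd net mode of division in [-1, 1] (independent mode).
#' @param fate_mode "independent" or "triplet".
#' @param modes (pp, pd, dd) probabilities for triplet mode.
#' @return n x 2 logical matrix; TRUE = daughter is a progenitor.
#' @export
draw_daughter_fates <- function(n, ppdd, fate_mode = "independent",
                                modes = NULL) {
  if (fate_mode == "independent") {
    if (is.na(ppdd) || ppdd < -1 || ppdd > 1)
      stop_cyclekin("ppdd must lie in [-1, 1]", class = "invalid_parameter")
    p <- (1 + ppdd) / 2
    return(matrix(stats::runif(2L * n) < p, ncol = 2L))
  }
  type <- sample.int(3L, n, replace = TRUE, prob = modes)
  cbind(type != 3L, type == 1L)  # pp: both; pd: first only; dd: neither
}

# Execute divisions for cells whose progress crossed 1 during the step
# ending at time t.  Mothers are removed; each daughter starts at the
# overshoot age with a fresh relative cycle length and inherits the mother's
# full label set.  Differentiated daughters are retired into the D counter.
divide_cells <- function(pop, idx, t, schedules, fate_mode = "independent",
                         modes = NULL) {
  n <- length(idx)
  if (n == 0L) return(pop)
  Tm <- schedules$T_mean(t)
  ppdd_now <- schedules$ppdd(t)
  mode_prob <- if (!is.null(modes)) modes(t) else NULL
  fates <- draw_daughter_fates(n, ppdd_now, fate_mode, mode_prob)

  overshoot_h <- (pop$frac[idx] - 1) * pop$rel_len[idx] * Tm  # hours past division
  rel_new <- draw_cycle_length(2L * n, Tm, schedules$cv) / Tm
  frac_new <- pmin(rep(overshoot_h, 2L) / (rel_new * Tm), 0.999)
  is_prog <- as.vector(fates)

  mother_labels <- lapply(pop$labels, function(v) rep(v[idx], 2L))

  # retire differentiated daughters
  n_diff <- sum(!is_prog)
  pop$D <- pop$D + n_diff
  if (n_diff > 0L && length(pop$D_labels)) {
    for (nm in names(pop$labels))
      pop$D_labels[[nm]] <- pop$D_labels[[nm]] + sum(mother_labels[[nm]][!is_prog])
  }

  # append progenitor daughters
  k <- sum(is_prog)
  if (k > 0L) {
    new_ids <- pop$next_id + seq_len(k) - 1L
    pop$next_id <- pop$next_id + k
    pop$id <- c(pop$id, new_ids)
    pop$birth_time <- c(pop$birth_time, rep(t, k))
    pop$rel_len <- c(pop$rel_len, rel_new[is_prog])
    pop$frac <- c(pop$frac, frac_new[is_prog])
    pop$state <- c(pop$state, rep(STATE_CYCLING, k))
    for (nm in names(pop$labels))
      pop$labels[[nm]] <- c(pop$labels[[nm]], mother_labels[[nm]][is_prog])
  }

  pop$divisions <- pop$divisions + n
  pop$created <- pop$created + 2L * n
  pop$removed <- pop$removed + n
  pop_keep(pop, -idx)
}

# Move cells between cycling and quiescent so that the quiescent pool tracks
# its target share (1 - gamma(t)) of all progenitors.  Entry prefers
# daughters born during the current step (ids >= born_since); re-entry picks
# random quiescent cells.  Exchanges fire only when the integer gap is >= 1,
# so a constant gamma exchanges essentially nothing in homeostasis and the
# quiescent pool stays unlabeled.
track_quiescence <- function(pop, gamma_now, born_since = NULL) {
  n <- pop_size(pop)
  if (n == 0L) return(pop)
  is_cyc <- pop$state == STATE_CYCLING
  q_target <- (1 - gamma_now) * n
  q_now <- n - sum(is_cyc)
  gap <- q_target - q_now
  if (gap >= 1) {
    k <- floor(gap + 0.5)
    cand <- which(is_cyc)
    if (!is.null(born_since)) {
      newborn <- cand[pop$id[cand] >= born_since]
      older <- cand[pop$id[cand] < born_since]
      cand <- c(newborn, if (length(older)) sample(older) else integer(0))
    } else if (length(cand) > 1L) cand <- sample(cand)
    take <- cand[seq_len(min(k, length(cand)))]
    pop$state[take] <- STATE_QUIESCENT
  } else if (gap <= -1) {
    k <- floor(-gap + 0.5)
    cand <- which(!is_cyc)
    if (length(cand) > 1L) cand <- sample(cand)
    take <- cand[seq_len(min(k, length(cand)))]
    pop$state[take] <- STATE_CYCLING
  }
  pop
}

#' Advance the population by one time step
#'
#' Applies, in order: apoptosis of progenitors with probability
#' `1 - exp(-apoptosis_rate(t) * dt)` (retired into the cumulative counter
#' A); ageing of cycling cells; S-phase labeling under the active protocol
#' windows; divisions for cells whose cycle completed within the step; and
#' the quiescence-tracking exchange that keeps the cycling fraction at
#' `gamma(t)`.
#'
#' @param pop a `cell_population`.
#' @param t time at the start of the step (hours).
#' @param dt step length (hours, > 0).
#' @param schedules a `schedule_set`.
#' @param protocols list of [label_protocol()] objects (may be empty).
#' @param fate_mode,modes see [sim_config()].
#' @return The updated `cell_population`.
#' @export
step_population <- function(pop, t, dt, schedules, protocols = list(),
                            fate_mode = "independent", modes = NULL) {
  if (dt <= 0) stop_cyclekin("dt must be > 0", class = "invalid_parameter")
  if (pop_size(pop) == 0L) return(pop)

  # apoptosis hazard on all progenitors (cycling and quiescent)
  rate <- schedules$apoptosis_rate(t)
  if (rate > 0) {
    p_die <- 1 - exp(-rate * dt)
    dies <- stats::runif(pop_size(pop)) < p_die
    k <- sum(dies)
    if (k > 0L) {
      pop$A <- pop$A + k
      pop$removed <- pop$removed + k
      pop <- pop_keep(pop, !dies)
      if (pop_size(pop) == 0L) return(pop)
    }
  }

  cyc <- which(pop$state == STATE_CYCLING)
  first_new_id <- pop$next_id
  if (length(cyc)) {
    Tm <- schedules$T_mean(t)
    f0 <- pop$frac[cyc]
    f1 <- f0 + dt / (pop$rel_len[cyc] * Tm)
    if (length(protocols))
      pop <- label_in_s(pop, cyc, f0, pmin(f1, 1), t, dt, protocols)
    pop$frac[cyc] <- f1
    div_idx <- cyc[f1 >= 1]
    if (length(div_idx))
      pop <- divide_cells(pop, div_idx, t + dt, schedules, fate_mode, modes)
  }

  track_quiescence(pop, schedules$gamma(t + dt), born_since = first_new_id)
}

# One row of the counts table at time t.
counts_row <- function(pop, t) {
  is_cyc <- pop$state == STATE_CYCLING
  row <- data.frame(
    time_h = t,
    P = pop_size(pop),
    P_cycling = sum(is_cyc),
    D = pop$D,
    Q = sum(!is_cyc),
    A = pop$A
  )
  for (nm in names(pop$labels)) {
    row[[paste0("P_", nm)]] <- sum(pop$labels[[nm]])
    row[[paste0("D_", nm)]] <- pop$D_labels[[nm]]
  }
  row
}

#' Run a full simulation
#'
#' Initialises the population from the config (seeding the RNG) and advances
#' it to `t_end`, recording a counts row every `record_interval` hours (0 and
#' `t_end` inclusive).  Identical configs give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param return_population also return the final population (for labeling
#'   experiments that gate on the fixed sample).
#' @return A `counts_ts` data.frame with columns time_h, P (all progenitors),
#'   P_cycling, D, Q, A and one P_/D_ column per label; attributes carry the
#'   config, seed and RNG algorithm.  If `return_population`, a list with
#'   elements `counts` and `population`.
#' @export
run_simulation <- function(config, return_population = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  pop <- init_population(config)
  dt <- config$dt
  n_steps <- max(0L, round(config$t_end / dt))
  rec_every <- max(1L, round(config$record_interval / dt))
  rows <- vector("list", n_steps %/% rec_every + 2L)
  rows[[1L]] <- counts_row(pop, 0)
  ri <- 2L
  for (i in seq_len(n_steps)) {
    t <- (i - 1L) * dt
    pop <- step_population(pop, t, dt, config$schedules, config$protocols,
                           config$fate_mode, config$modes)
    if (i %% rec_every == 0L || i == n_steps) {
      rows[[ri]] <- counts_row(pop, i * dt)
      ri <- ri + 1L
    }
  }
  counts <- do.call(rbind, rows[seq_len(ri - 1L)])
  rownames(counts) <- NULL
  class(counts) <- c("counts_ts", "data.frame")
  attr(counts, "seed") <- config$seed
  attr(counts, "rng_kind") <- RNGkind()[1L]
  attr(counts, "config") <- config
  if (return_population) list(counts = counts, population = pop) else counts
}
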