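# CSV readers/writers, config files, fixtures and run manifests.

#' Read a counts time-series from CSV
#'
#' Requires columns `time_h`, `P` and `D`; `P_cycling`, `Q`, `A`, label
#' gates and standard-error columns are carried through when present.
#' Time must be strictly increasing and counts non-negative; a decreasing
#' `D` column is accepted with a warning (raw data may be noisy; the fits
#' handle it).
#'
#' @param path CSV file path.
#' @return A `counts_ts` data.frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_h", "P", "D")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_cyclekin("counts file %s is missing column(s): %s", path,
                  paste(miss, collapse = ", "), class = "schema_error")
  if (any(diff(df$time_h) <= 0)) {
    bad <- which(diff(df$time_h) <= 0) + 1L
    stop_cyclekin("time_h not strictly increasing at row(s) %s",
                  paste(bad, collapse = ", "), class = "schema_error")
  }
  numcols <- setdiff(names(df), "time_h")
  for (cl in numcols) {
    if (any(df[[cl]] < 0, na.rm = TRUE))
      stop_cyclekin("negative values in column %s (rows %s)", cl,
                    paste(which(df[[cl]] < 0), collapse = ", "),
                    class = "schema_error")
  }
  if (any(diff(df$D) < 0))
    warning("D decreases between some rows; accepted as noisy raw data",
            call. = FALSE)
  class(df) <- c("counts_ts", "data.frame")
  df
}

#' Write a counts time-series to CSV
#'
#' @param counts a `counts_ts` data.frame.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' Write a curve (cumulative or pulse-chase) to CSV
#'
#' @param curve a curve data.frame.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic counts fixture with known ground truth
#'
#' Simulates one of three small canonical datasets and writes `counts.csv`
#' plus `truth.json` (the generating schedules and seed) so estimators can
#' be exercised without any external data:
#' \itemize{
#'   \item `constant`: homeostasis, T = 20 h, pp - dd = 0.
#'   \item `fig2_like`: an expanding-then-saturating culture (pp - dd ramps
#'     0.7 to 0), giving sigmoidal P and D trajectories.
#'   \item `shrinking`: net differentiation (pp - dd = -0.5), a declining
#'     progenitor pool.
#' }
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param dir output directory (created if needed); NULL returns the data
#'   without writing.
#' @param m,t_end simulation size and length.
#' @return A list: counts (`counts_ts`), truth (list), paths (if written).
#' @export
generate_fixture <- function(kind = c("constant", "fig2_like", "shrinking"),
                             seed = 1L, dir = NULL, m = 300L, t_end = 48) {
  kind <- match.arg(kind)
  truth <- switch(kind,
    constant = list(T = 20, ppdd = 0, gamma = 1, apoptosis_rate = 0),
    fig2_like = list(T = 20, ppdd = list(t = c(0, t_end), value = c(0.7, 0)),
                     gamma = 1, apoptosis_rate = 0),
    shrinking = list(T = 20, ppdd = -0.5, gamma = 1, apoptosis_rate = 0))
  sch <- schedule_set(
    T_mean = truth$T,
    ppdd = if (is.list(truth$ppdd)) truth$ppdd else truth$ppdd,
    gamma = truth$gamma, apoptosis_rate = truth$apoptosis_rate)
  cfg <- sim_config(m, t_end, sch, seed = seed, record_interval = 2)
  counts <- run_simulation(cfg)
  truth$kind <- kind
  truth$seed <- seed
  truth$m <- m
  truth$t_end <- t_end
  truth$cv <- sch$cv
  out <- list(counts = counts, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cpath <- file.path(dir, paste0(kind, "_counts.csv"))
    tpath <- file.path(dir, paste0(kind, "_truth.json"))
    write_counts(counts, cpath)
    jsonlite::write_json(truth, tpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    out$paths <- c(counts = cpath, truth = tpath)
  }
  out
}

# Turn a parsed config-file schedule entry into the form schedule_set wants.
config_schedule_entry <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x) && length(x) == 1L) return(x)
  if (is.list(x) && !is.null(x$t) && !is.null(x$value))
    return(list(t = unlist(x$t), value = unlist(x$value)))
  stop_cyclekin("schedule entries must be a number or {t: [...], value: [...]}",
                class = "invalid_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Recognised fields: initial_count (or m), t_end, dt, seed,
#' record_interval, cv, and schedules T, ppdd, gamma, apoptosis_rate given
#' as constants or breakpoint lists `{t: [...], value: [...]}`.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  m <- raw$initial_count %||% raw$m
  if (is.null(m) || is.null(raw$t_end))
    stop_cyclekin("config needs initial_count (or m) and t_end",
                  class = "invalid_config")
  sch <- schedule_set(
    T_mean = config_schedule_entry(raw$T %||% raw$T_mean) %||% 20,
    ppdd = config_schedule_entry(raw$ppdd) %||% 0,
    gamma = config_schedule_entry(raw$gamma) %||% 1,
    apoptosis_rate = config_schedule_entry(raw$apoptosis_rate) %||% 0,
    cv = raw$cv %||% 0.3)
  sim_config(m, raw$t_end, sch,
             seed = raw$seed %||% 1L,
             dt = raw$dt %||% 0.1,
             record_interval = raw$record_interval %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records everything needed to reproduce an output bit-for-bit: the config
#' snapshot (scalars and schedule descriptions), seed, RNG algorithm,
#' package version, timestamp and output paths.
#'
#' @param path manifest JSON path.
#' @param config the `sim_config` (or a plain list snapshot).
#' @param outputs named character vector of output paths.
#' @param extra optional extra fields.
#' @return `path` invisibly.
#' @export
write_run_manifest <- function(path, config, outputs = character(),
                               extra = list()) {
  snap <- if (inherits(config, "sim_config"))
    list(initial_count = config$initial_count, t_end = config$t_end,
         dt = config$dt, seed = config$seed,
         record_interval = config$record_interval,
         cv = config$schedules$cv, fate_mode = config$fate_mode)
  else config
  manifest <- c(list(
    package = "cyclekin",
    version = as.character(utils::packageVersion("cyclekin")),
    rng_kind = RNGkind()[1L],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = snap,
    outputs = as.list(outputs)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
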