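test_that("quiescent cells never incorporate label", {
  sch <- schedule_set(T_mean = 20, gamma = 0)  # everyone quiescent
  cfg <- sim_config(500, 10, sch, seed = 2)
  pop <- init_population(cfg)
  pr <- label_protocol("EdU", rbind(c(0, 10)), "cumulative")
  for (i in 1:50) pop <- apply_labeling(pop, (i - 1) * 0.1, 0.1, list(pr), sch)
  expect_equal(sum(unlist(pop$labels)), 0)
})

test_that("an instantaneous exposure labels one S phase worth of cells", {
  sch <- schedule_set(T_mean = 20, cv = 0)
  cfg <- sim_config(2000, 10, sch, seed = 3)
  pop <- init_population(cfg)
  pr <- label_protocol("EdU", rbind(c(0, 0.1)), "pulse")
  pop <- apply_labeling(pop, 0, 0.1, list(pr), sch)
  frac <- sum(pop$labels$EdU) / 2000
  expect_lt(abs(frac - 1/3), 3 * sqrt(1/3 * 2/3 / 2000) + 0.1 / 20)
})

test_that("a window spanning a full cycle labels every cycling cell", {
  sch <- schedule_set(T_mean = 20, cv = 0)
  cfg <- sim_config(500, 20, sch,
                    protocols = list(label_protocol("EdU", rbind(c(0, 20)))),
                    seed = 4)
  res <- run_simulation(cfg, return_population = TRUE)
  lf <- sum(res$population$labels$EdU) / length(res$population$id)
  expect_equal(lf, 1)
})

test_that("the cumulative curve follows the uniform-age labeling index", {
  sch <- schedule_set(T_mean = 20, cv = 0)
  cfg <- sim_config(2000, 48, sch, seed = 3)
  curve <- cumulative_experiment(cfg, 0, seq(2, 16, 2))
  expected <- li_uniform(curve$exposure_h)
  tol <- 4 * pmax(curve$se, 1e-3) + 0.1 / 20
  expect_true(all(abs(curve$fraction - expected) < tol))
  expect_true(all(diff(curve$fraction) >= 0))  # monotone in exposure
})

test_that("the cumulative plateau equals the growth fraction", {
  sch <- schedule_set(T_mean = 20, gamma = 0.7)
  cfg <- sim_config(2000, 40, sch, seed = 4)
  curve <- cumulative_experiment(cfg, 0, c(30, 35, 40))
  for (i in seq_len(nrow(curve)))
    expect_lt(abs(curve$fraction[i] - 0.7), 3 * curve$se[i])
})

test_that("the early cumulative slope equals growth fraction over cycle length", {
  sch <- schedule_set(T_mean = 20, gamma = 0.7)
  cfg <- sim_config(4000, 40, sch, seed = 21)
  curve <- cumulative_experiment(cfg, 0, seq(2, 8, 2))
  lf <- linear_fit_with_band(curve$exposure_h, curve$fraction, curve$se)
  expect_lt(abs(lf$slope / (0.7 / 20) - 1), 0.10)
})

test_that("label-positive counts never decrease while the population lives", {
  sch <- schedule_set(T_mean = 20, ppdd = 0.2, gamma = 0.8)
  cfg <- sim_config(500, 40, sch,
                    protocols = list(label_protocol("EdU", rbind(c(4, 40)))),
                    seed = 6)
  cc <- run_simulation(cfg)
  total_labeled <- cc$P_EdU + cc$D_EdU
  expect_true(all(diff(total_labeled) >= 0))
  expect_true(all(diff(cc$D) >= 0))
  expect_true(all(diff(cc$A) >= 0))
})

test_that("pulse-chase re-entry peaks one cycle after the pulse", {
  sch <- schedule_set(T_mean = 20, cv = 0)
  cfg <- sim_config(1000, 40, sch, seed = 5)
  curve <- suppressWarnings(
    pulse_chase_experiment(cfg, 2, 0.5, seq(10, 30, 2)))
  fit <- pc_fit(curve)
  expect_lt(abs(fit$T_hat - 20), 2)      # within the grid resolution
  expect_lt(abs(fit$T_S_hat - 20 / 3), 2)
})

test_that("terminal divisions leave no re-entry peak to find", {
  sch <- schedule_set(T_mean = 20, ppdd = -1, cv = 0)
  cfg <- sim_config(1000, 40, sch, seed = 7)
  curve <- suppressWarnings(
    pulse_chase_experiment(cfg, 2, 0.5, seq(10, 30, 4)))
  expect_error(pc_fit(curve), class = "estimation_failure")
})

test_that("the dual cumulative curve follows the same labeling-index law", {
  sch <- schedule_set(T_mean = 20, cv = 0)
  cfg <- sim_config(1000, 30, sch, seed = 6)
  dc <- dual_cumulative_experiment(cfg, 0, 30 - seq(2, 10, 2), 30)
  expected <- li_uniform(dc$exposure_h)
  expect_true(all(abs(dc$fraction - expected) < 4 * dc$se + 0.1 / 20))
})

test_that("degenerate protocols error or return empty curves cleanly", {
  cfg <- sim_config(100, 10, schedule_set(), seed = 1)
  expect_error(cumulative_experiment(cfg, 5, c(4, 6)),
               class = "invalid_protocol")
  empty <- cumulative_experiment(cfg, 0, numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(c1_fit(empty), class = "insufficient_data")
  expect_error(dual_cumulative_experiment(cfg, 0, c(8), 6),
               class = "invalid_protocol")
  expect_error(label_protocol("X", rbind(c(3, 2))),
               class = "invalid_protocol")
  expect_error(label_protocol("X", rbind(c(0, 5), c(4, 8))),
               class = "invalid_protocol")
})
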