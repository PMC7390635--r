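test_that("cycle-length draws have the prescribed gamma moments", {
  expect_equal(draw_cycle_length(5, 20, 0), rep(20, 5))  # degenerate cv = 0
  set.seed(1)
  x <- draw_cycle_length(1e5, 20, 0.3)
  expect_true(all(x > 0))
  expect_equal(mean(x), 20, tolerance = 0.06 / 20)
  expect_equal(sd(x), 6, tolerance = 0.1 / 6)
  expect_error(draw_cycle_length(1, -2, 0.3), class = "invalid_parameter")
  expect_error(draw_cycle_length(1, 20, 1), class = "invalid_parameter")
})

test_that("initialisation is unsynchronised and respects the growth fraction", {
  cfg <- sim_config(10, 10, schedule_set(gamma = 1), seed = 4)
  pop <- init_population(cfg)
  cells <- population_cells(pop, 0, cfg$schedules)
  expect_equal(nrow(cells), 10)
  expect_true(all(cells$state == "cycling"))
  expect_true(all(cells$age >= 0 & cells$age < cells$cycle_length))

  empty <- run_simulation(sim_config(0, 4, schedule_set(), seed = 1))
  expect_true(all(empty$P == 0 & empty$D == 0 & empty$A == 0))

  cfg2 <- sim_config(10000, 10, schedule_set(gamma = 0.5), seed = 7)
  pop2 <- init_population(cfg2)
  q_frac <- sum(pop2$state != 1L) / 10000
  expect_lt(abs(q_frac - 0.5), 3 * sqrt(0.25 / 10000))

  expect_error(sim_config(-5, 10), class = "invalid_config")
  expect_error(sim_config(10, 10, dt = 5, record_interval = 2),
               class = "invalid_config")
})

test_that("phase is assigned by thirds of the progress through the cycle", {
  cfg <- sim_config(500, 10, schedule_set(cv = 0.3), seed = 9)
  pop <- init_population(cfg)
  cells <- population_cells(pop, 0, cfg$schedules)
  frac <- cells$age / cells$cycle_length
  expect_equal(cells$phase,
               ifelse(frac < 1/3, "G1", ifelse(frac < 2/3, "S", "G2M")))
})

test_that("daughter fates reproduce the mode of division", {
  set.seed(2)
  expect_true(all(draw_daughter_fates(50, 1)))    # all proliferative
  expect_true(!any(draw_daughter_fates(50, -1)))  # all differentiative
  f <- draw_daughter_fates(1e4, 0.5)
  pd_frac <- mean(xor(f[, 1], f[, 2]))
  se <- sqrt(0.375 * 0.625 / 1e4)
  expect_lt(abs(pd_frac - 0.375), 3 * se)  # 2 p (1 - p) with p = 0.75
  expect_error(draw_daughter_fates(1, 2), class = "invalid_parameter")
})

test_that("a lone cell at the end of its cycle divides into two cycling daughters", {
  sch <- schedule_set(T_mean = 20, ppdd = 1, cv = 0)
  cfg <- sim_config(1, 10, sch, seed = 3)
  pop <- init_population(cfg)
  pop$frac <- 1 - 0.05 / 20  # age = cycle_length - dt/2
  set.seed(5)
  pop <- step_population(pop, 0, 0.1, sch)
  expect_equal(sum(pop$state == 1L), 2L)
  expect_equal(pop$divisions, 1L)
})

test_that("a fully retired population is a no-op under stepping", {
  sch <- schedule_set()
  cfg <- sim_config(0, 10, sch, seed = 1)
  pop <- init_population(cfg)
  pop$D <- 1L  # one terminally differentiated cell (retired compartment)
  for (i in 1:20) pop <- step_population(pop, (i - 1) * 0.1, 0.1, sch)
  expect_equal(pop$D, 1L)
  expect_equal(pop$divisions, 0L)
})

test_that("apoptosis thins progenitors at the exponential hazard rate", {
  sch <- schedule_set(T_mean = 20, ppdd = 0, gamma = 1,
                      apoptosis_rate = 0.01)
  P48 <- vapply(1:10, function(k) {
    cc <- run_simulation(sim_config(5000, 48, sch, seed = 600 + k))
    cc$P[nrow(cc)]
  }, numeric(1))
  expect_lt(abs(mean(P48) / (5000 * exp(-0.01 * 48)) - 1), 0.05)
})

test_that("deterministic-cycle expansion doubles the pool every cycle", {
  sch <- schedule_set(T_mean = 20, ppdd = 1, cv = 0)
  cc <- run_simulation(sim_config(1000, 40, sch, seed = 9))
  expect_equal(cc$P[nrow(cc)] / cc$P[1], 4, tolerance = 0.01)
})

test_that("homeostasis conserves the expected progenitor count", {
  P48 <- vapply(1:10, function(k) {
    cc <- run_simulation(sim_config(500, 48, schedule_set(), seed = 700 + k))
    cc$P[nrow(cc)]
  }, numeric(1))
  se <- sd(P48) / sqrt(10)
  expect_lt(abs(mean(P48) - 500), 3 * se)
})

test_that("pure terminal division empties the pool into differentiated cells", {
  sch <- schedule_set(T_mean = 20, ppdd = -1, gamma = 1)
  cc <- run_simulation(sim_config(500, 48, sch, seed = 11))
  expect_equal(cc$P[nrow(cc)], 0)
  expect_gte(cc$D[nrow(cc)], 500)
  # once P = 0 no further growth of D
  zero_from <- min(which(cc$P == 0))
  expect_equal(cc$D[zero_from], cc$D[nrow(cc)])
})

test_that("agent dynamics track the continuous forward model", {
  # dP/dt = ppdd * gamma / T * P at moderate net proliferation
  sch <- schedule_set(T_mean = 20, ppdd = 0.2)
  P48 <- vapply(1:10, function(k) {
    cc <- run_simulation(sim_config(500, 48, sch, seed = 800 + k))
    cc$P[nrow(cc)]
  }, numeric(1))
  expect_lt(abs(mean(P48) / ode_P(48, 500, 20, 0.2) - 1), 0.10)
})

test_that("pooled homeostatic runs show no trend in P(t)", {
  dat <- do.call(rbind, lapply(1:10, function(k)
    run_simulation(sim_config(500, 48, schedule_set(), seed = 900 + k))))
  fit <- summary(lm(P ~ time_h, data = dat))
  expect_lt(abs(fit$coefficients[2, 1]), 3 * fit$coefficients[2, 2])
})
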