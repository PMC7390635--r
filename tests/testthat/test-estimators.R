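test_that("C1 inverts exact labeling-index curves", {
  tt <- seq(2, 30, 2)
  # gamma = 0.72, T = 20: f(t) = 0.24 + 0.036 t capped at 0.72
  c1 <- c1_fit(make_curve(tt, pmin(0.24 + 0.036 * tt, 0.72)))
  expect_equal(c1$gamma_hat, 0.72)
  expect_equal(c1$slope, 0.036)
  expect_equal(c1$T_hat, 20)
  # gamma = 1, T = 20
  c1b <- c1_fit(make_curve(tt, li_uniform(tt)))
  expect_equal(c1b$T_hat, 20)
  expect_equal(c1b$gamma_hat, 1)
  # a curve already at plateau has no usable slope
  expect_error(c1_fit(make_curve(tt, rep(0.72, length(tt)))),
               class = "estimation_failure")
  expect_error(c1_fit(make_curve(1:4, 0.1 * (1:4))),
               class = "insufficient_data")
})

test_that("C1 propagates slope and plateau errors in quadrature", {
  tt <- seq(2, 30, 2)
  f <- pmin(0.24 + 0.036 * tt, 0.72)
  se <- 0.01 + 0.002 * tt
  c1 <- c1_fit(make_curve(tt, f, se))
  expect_equal(c1$T_se,
               c1$T_hat * sqrt((c1$gamma_se / c1$gamma_hat)^2 +
                               (c1$slope_se / c1$slope)^2))
})

test_that("C2 recovers cycle and S-phase length from the dual curve", {
  dd <- seq(2, 30, 2)
  c2 <- c2_fit(make_curve(dd, li_uniform(dd)))  # gamma read off the plateau
  expect_equal(c2$T_hat, 20)
  expect_equal(c2$T_S_hat, 20 / 3, tolerance = 1e-8)
  # zero intercept means a vanishing S phase
  c2b <- c2_fit(make_curve(seq(2, 8, 2), 0.05 * seq(2, 8, 2)), gamma = 1)
  expect_equal(c2b$T_S_hat, 0)
  expect_error(c2_fit(make_curve(c(2, 4), c(0.4, 0.5))),
               class = "insufficient_data")
})

test_that("PC locates a synthetic peak to sub-grid precision", {
  ch <- seq(2, 30, 2)
  y <- pmax(0, 1 - abs(ch - 20) / 6.67) * 0.3  # triangular peak at 20
  out <- data.frame(chase_h = ch, fraction = y, se = 0.01, n = 1000)
  fit <- pc_fit(out)
  expect_lt(abs(fit$T_hat - 20), 2)
  # monotone rising curve: the peak is beyond the grid
  mono <- data.frame(chase_h = ch, fraction = 0.01 * ch, se = 0.01, n = 1000)
  expect_error(pc_fit(mono), class = "peak_not_bracketed")
  flat <- data.frame(chase_h = ch, fraction = rep(0, 15), se = 0, n = 1000)
  expect_error(pc_fit(flat), class = "estimation_failure")
})

test_that("BP closed forms hold on exact inputs", {
  # homeostasis: P constant at 500, 300 differentiated cells over 12 h
  est <- bp_estimate(P_fun = function(t) rep(500, length(t)),
                     D_fun = function(t) 25 * t,
                     gamma = 1, grid = c(0, 12))
  expect_equal(est$ppdd, 0)
  expect_equal(est$T, 20)
  # exponential growth at rate 0.025/h with ppdd = 0.5
  est2 <- bp_estimate(P_fun = function(t) 100 * exp(0.025 * t),
                      D_fun = function(t) ode_D(t, 100, 20, 0.5),
                      gamma = 1, grid = c(0, 40), subdivisions = 200)
  expect_equal(est2$ppdd, 0.5, tolerance = 1e-6)
  expect_equal(est2$T, 20, tolerance = 1e-5)
  # no differentiation: every division proliferative
  est3 <- bp_estimate(P_fun = function(t) 100 * exp(0.01 * t),
                      D_fun = function(t) rep(0, length(t)),
                      gamma = 1, grid = c(0, 20))
  expect_equal(est3$ppdd, 1)
})

test_that("BP recovers constant parameters from noise-free model curves", {
  for (pars in list(c(T = 20, ppdd = 0.3), c(T = 14, ppdd = -0.4),
                    c(T = 25, ppdd = 0))) {
    est <- bp_estimate(
      P_fun = function(t) ode_P(t, 500, pars[["T"]], pars[["ppdd"]]),
      D_fun = function(t) ode_D(t, 500, pars[["T"]], pars[["ppdd"]]),
      gamma = 1, grid = seq(0, 48, 1), subdivisions = 100)
    expect_lt(max(abs(est$T / pars[["T"]] - 1)), 1e-3)
    expect_lt(max(abs(est$ppdd - pars[["ppdd"]])), 1e-3)
  }
})

test_that("BP honours apoptosis and growth-fraction corrections", {
  # homeostasis maintained against death: ppdd*gamma/T = phi
  phi <- 0.01; gam <- 0.8; T_true <- 20
  ppdd_true <- phi * T_true / gam
  est <- bp_estimate(
    P_fun = function(t) rep(400, length(t)),
    D_fun = function(t) (1 - ppdd_true) * gam * 400 / T_true * t,
    gamma = gam, apoptosis_rate = phi, grid = seq(0, 40, 2),
    subdivisions = 100)
  expect_equal(est$ppdd, rep(ppdd_true, nrow(est)), tolerance = 1e-9)
  expect_equal(est$T, rep(T_true, nrow(est)), tolerance = 1e-9)
})

test_that("windows without net divisions are masked, not fabricated", {
  est <- suppressWarnings(bp_estimate(
    P_fun = function(t) 500 * exp(-0.05 * t),  # shrinking pool
    D_fun = function(t) rep(0, length(t)),     # and nothing differentiates
    gamma = 1, grid = seq(0, 10, 2)))
  expect_true(all(est$masked))
  expect_true(all(is.na(est$T)))
})

test_that("BP round-trips parameters from stochastic simulations", {
  for (pd in c(0, 0.2)) {
    ests <- vapply(1:10, function(k) {
      cc <- run_simulation(sim_config(500, 48,
                                      schedule_set(T_mean = 20, ppdd = pd),
                                      seed = 200 + k))
      s <- summary(bp_estimate(cc, gamma = 1, grid = c(0, 48),
                               fit = "direct"))
      c(s$T_mean, s$ppdd_mean)
    }, numeric(2))
    expect_lt(abs(mean(ests[1, ]) / 20 - 1), 0.10)
    expect_lt(abs(mean(ests[2, ]) - pd), 0.10)
  }
})

test_that("mode decomposition is exact and inverts the net mode", {
  m0 <- decompose_modes(0)
  expect_equal(unlist(m0[c("pp", "pd", "dd")]), c(pp = 0.25, pd = 0.5, dd = 0.25))
  m1 <- decompose_modes(1)
  expect_equal(unlist(m1[c("pp", "pd", "dd")]), c(pp = 1, pd = 0, dd = 0))
  mh <- decompose_modes(0.5)
  expect_equal(unlist(mh[c("pp", "pd", "dd")]),
               c(pp = 0.5625, pd = 0.375, dd = 0.0625))
  grid <- seq(-1, 1, length.out = 101)
  mm <- decompose_modes(grid)
  expect_equal(mm$pp + mm$pd + mm$dd, rep(1, 101))
  expect_equal(mm$pp - mm$dd, grid)
  expect_error(decompose_modes(1.01), class = "invalid_parameter")
})

test_that("zero standard errors collapse the 50% band onto the estimate", {
  cc <- run_simulation(sim_config(500, 48, schedule_set(), seed = 77))
  cc$P_se <- 0; cc$D_se <- 0
  ci <- suppressWarnings(propagate_ci50(cc, gamma = 1, grid = seq(0, 48, 8)))
  ok <- !ci$masked
  expect_equal(ci$T_lo[ok], ci$T_hi[ok])
  expect_equal(ci$ppdd_lo[ok], ci$ppdd_hi[ok])
})

test_that("inflating the standard errors widens the band monotonically", {
  tt <- seq(0, 48, 2)
  cc <- data.frame(time_h = tt,
                   P = 800 / (1 + exp(-(tt - 24) / 8)),
                   D = 1200 / (1 + exp(-(tt - 28) / 9)))
  widths <- vapply(c(0.03, 0.08), function(s) {
    cc$P_se <- s * cc$P; cc$D_se <- pmax(s * cc$D, 1)
    ci <- suppressWarnings(propagate_ci50(cc, gamma = 1,
                                          grid = seq(8, 40, 8)))
    mean(ci$ppdd_hi - ci$ppdd_lo, na.rm = TRUE)
  }, numeric(1))
  expect_gt(widths[2], widths[1])
})

test_that("the 50% band covers the underlying mode in its model regime", {
  Pf <- function(t) 800 / (1 + exp(-(t - 24) / 8))
  Df <- function(t) 1200 / (1 + exp(-(t - 28) / 9))
  tt <- seq(0, 48, 2)
  truth <- bp_estimate(P_fun = Pf, D_fun = Df, gamma = 1,
                       grid = seq(0, 48, 8))
  set.seed(99)
  hit <- tot <- 0
  for (k in 1:20) {
    P_se <- 0.05 * Pf(tt); D_se <- 0.05 * pmax(Df(tt), 20)
    cc <- data.frame(time_h = tt,
                     P = Pf(tt) + rnorm(length(tt), 0, P_se),
                     D = Df(tt) + rnorm(length(tt), 0, D_se),
                     P_se = P_se, D_se = D_se)
    ci <- suppressWarnings(propagate_ci50(cc, gamma = 1,
                                          grid = seq(0, 48, 8)))
    ok <- !ci$masked & !truth$masked
    hit <- hit + sum(ci$ppdd_lo[ok] <= truth$ppdd[ok] &
                     ci$ppdd_hi[ok] >= truth$ppdd[ok])
    tot <- tot + sum(ok)
  }
  expect_gte(hit / tot, 0.5)
})
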