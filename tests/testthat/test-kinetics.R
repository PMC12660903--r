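test_that("two-step populations honour the initial condition and conservation limit", {
  pop0 <- two_step_populations(0.016, 0.041, 0)
  expect_equal(as.numeric(pop0[1, c("precursor", "intermediate", "product")]),
               c(1, 0, 0))
  late <- two_step_populations(0.016, 0.041, 2000)
  expect_lt(late$precursor, 1e-9)
  expect_lt(late$intermediate, 1e-6)
  expect_equal(late$product, 1, tolerance = 1e-6)
  expect_error(two_step_populations(0.016, 0.041, -1), "non-negative")
  expect_error(two_step_populations(-1, 0.041, 1), "positive")
})

test_that("closed-form populations match a numerical ODE integrator", {
  times <- seq(0, 300, by = 5)
  deriv <- function(t, y, p) {
    list(c(-p$k1 * y[1], p$k1 * y[1] - p$k2 * y[2], p$k2 * y[2]))
  }
  for (k in list(c(0.016, 0.041), c(0.1, 0.1), c(0.5, 0.01))) {
    ode <- deSolve::ode(c(P = 1, I = 0, L = 0), times, deriv,
                        list(k1 = k[1], k2 = k[2]),
                        rtol = 1e-10, atol = 1e-12)
    pop <- two_step_populations(k[1], k[2], times)
    expect_equal(pop$precursor, unname(ode[, "P"]), tolerance = 1e-8)
    expect_equal(pop$intermediate, unname(ode[, "I"]), tolerance = 1e-8)
    expect_equal(pop$product, unname(ode[, "L"]), tolerance = 1e-8)
  }
})

test_that("population conservation holds to 1e-10 and the intermediate peaks on time", {
  times <- seq(0, 500, length.out = 400)
  for (k in list(c(0.016, 0.041), c(0.3, 0.3), c(2, 0.05))) {
    pop <- two_step_populations(k[1], k[2], times)
    total <- pop$precursor + pop$intermediate + pop$product
    expect_lt(max(abs(total - 1)), 1e-10)
    t_star <- intermediate_peak_time(k[1], k[2])
    fine <- two_step_populations(k[1], k[2],
                                 seq(max(0, t_star - 5), t_star + 5,
                                     length.out = 2001))
    expect_equal(fine$time[which.max(fine$intermediate)], t_star,
                 tolerance = 0.02)
  }
})

test_that("noiseless two-step data refit to three significant figures", {
  tc <- make_kinetics_data("two_step", list(k1 = 0.016, k2 = 0.041),
                           seq(0, 180, by = 15))
  fit <- fit_two_step(tc, n_starts = 3)
  expect_equal(fit$k1, 0.016, tolerance = 5e-4)
  expect_equal(fit$k2, 0.041, tolerance = 5e-4)
  expect_false(fit$exchange_ambiguous)
  td <- tidy(fit)
  expect_equal(td$estimate, c(fit$k1, fit$k2))
  expect_true(all(td$std.error >= 0))
})

test_that("noisy replicates recover the rates with small median bias", {
  times <- seq(0, 180, length.out = 12)
  k1_hat <- k2_hat <- numeric(50)
  for (r in 1:50) {
    tc <- make_kinetics_data("two_step", list(k1 = 0.016, k2 = 0.041),
                             times, noise_sigma = 0.02, seed = 500 + r)
    fit <- fit_two_step(tc, n_starts = 2)
    k1_hat[r] <- fit$k1; k2_hat[r] <- fit$k2
  }
  expect_lt(abs(median(k1_hat) - 0.016) / 0.016, 0.05)
  expect_lt(abs(median(k2_hat) - 0.041) / 0.041, 0.05)
})

test_that("with a fast second step the first rate matches a single-exponential fit", {
  times <- seq(0, 200, by = 10)
  tc <- make_kinetics_data("two_step", list(k1 = 0.02, k2 = 2), times)
  fit <- fit_two_step(tc[, c("time", "product")], n_starts = 4)
  # product-only data: exchange-ambiguous, k1 reported as the slower first step
  expect_true(fit$exchange_ambiguous)
  # the pure exponential is only the k2 >> k1 limit, so allow a 2% gap
  exp_fit <- minpack.lm::nlsLM(product ~ 1 - exp(-k * time), data = tc,
                               start = list(k = 0.05))
  expect_equal(fit$k1, unname(coef(exp_fit)["k"]), tolerance = 0.02)
})

test_that("initial slope handles lines, saturating curves, and constants", {
  grid <- seq(0, 9, by = 1)
  line <- tibble::tibble(time = grid, signal = 3.5 * grid + 2)
  expect_equal(initial_slope(line), 3.5, tolerance = 1e-9)
  const <- tibble::tibble(time = grid, signal = rep(4, 10))
  expect_equal(initial_slope(const), 0, tolerance = 1e-12)
  # v (1 - exp(-r t)) has initial slope v r in the small-window limit
  v <- 5; r <- 0.2
  fine <- tibble::tibble(time = seq(0, 0.09, by = 0.01),
                         signal = v * (1 - exp(-r * seq(0, 0.09, by = 0.01))))
  expect_equal(initial_slope(fine), v * r, tolerance = 0.01)
  expect_error(initial_slope(line[1:5, ]), ">= 10")
  # blank subtraction shifts the intercept, not the slope
  expect_equal(initial_slope(line, blank = 2), 3.5, tolerance = 1e-9)
})

test_that("Michaelis-Menten fitting recovers printed-scale parameters exactly", {
  S <- c(4, 8, 12, 16, 24, 32, 64)
  rates <- make_kinetics_data("michaelis_menten",
                              list(vmax = 22.47, km = 192.67), S)
  fit <- fit_michaelis_menten(rates)
  expect_equal(fit$vmax, 22.47, tolerance = 22.47 * 0.01)
  expect_equal(fit$km, 192.67, tolerance = 192.67 * 0.01)
  # on noiseless data Lineweaver-Burk coincides with the nonlinear fit
  expect_equal(fit$vmax_lb, fit$vmax, tolerance = 1e-6)
  expect_equal(fit$km_lb, fit$km, tolerance = 1e-6)
  # definition of KM: v(S = KM) = vmax / 2
  half <- fit$vmax * fit$km / (fit$km + fit$km)
  expect_equal(half, fit$vmax / 2, tolerance = 1e-12)
  expect_error(fit_michaelis_menten(tibble::tibble(S = S, v = 0)), "zero")
})

test_that("relative activity reproduces the mutant/wild-type percentages", {
  ra <- relative_activity(c(vmax = 0.75, km = 7.87),
                          c(vmax = 22.47, km = 192.67))
  expect_equal(ra$percent_rounded[ra$parameter == "vmax"], 3)
  expect_equal(ra$percent_rounded[ra$parameter == "km"], 4)
  same <- relative_activity(c(k1 = 0.016), c(k1 = 0.016))
  expect_equal(same$percent, 100)
  expect_error(relative_activity(c(k1 = 1), c(k1 = 0)), "positive")
})

test_that("the printed rate pairs imply the reported fold changes at full precision", {
  # first step: wild type 0.016 vs mutant 0.003; second step 0.041 vs 0.028
  ra <- relative_activity(c(k1 = 0.003, k2 = 0.028),
                          c(k1 = 0.016, k2 = 0.041))
  expect_equal(ra$wildtype / ra$mutant, c(16 / 3, 41 / 28), tolerance = 1e-12)
})
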