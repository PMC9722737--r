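test_that("windkessel update reduces to the resistor law and matches the closed form", {
  # C = 0: algebraically P = P_out + Q R, exactly
  expect_identical(wk_update(P_prev = 123, Q_n = 0.01, R = 1500, C = 0,
                             dt = 0.05), 15)
  expect_identical(wk_update(7, 0.01, 1500, 0, 0.05, P_out = 2), 17)
  # direct formula evaluation: C R / dt = 2000
  expect_equal(wk_update(0, 1, 1000, 0.1, 0.05), 1000 / 2001)
  # the steady value Q R + P_out is an exact fixed point, and the map is a
  # contraction with factor a/(1+a)
  R <- 1500; C <- 0.51; dt <- 0.05; Q <- 0.00667
  Pstar <- Q * R
  expect_equal(wk_update(Pstar, Q, R, C, dt), Pstar)
  a <- C * R / dt
  P0 <- 0
  expect_equal(abs(wk_update(P0, Q, R, C, dt) - Pstar),
               abs(P0 - Pstar) * a / (1 + a))
  expect_equal(Pstar, 10.005)
  expect_error(wk_update(0, 1, -5, 0.1, 0.05), "'R'")
  expect_error(wk_update(0, 1, 100, 0.1, 0), "'dt'")
})

test_that("total resistance is mean pressure over production", {
  expect_equal(total_resistance_from_physiology(10, 0.00667), 10 / 0.00667)
  expect_equal(signif(total_resistance_from_physiology(10, 0.00667), 3), 1500)
  expect_equal(total_resistance_from_physiology(10, 0.01), 1000)
  expect_equal(total_resistance_from_physiology(22, 0.00667), 22 / 0.00667)
  expect_error(total_resistance_from_physiology(10, 0), "Q_production")
})

test_that("resistance allocation inverts the outflow fractions and recombines in parallel", {
  a <- outlet_allocation(1500, 0.51,
                         q = c(int = 0.2, sp = 0.2, lym = 0.3, av = 0.3),
                         c = c(int = 0.33, sp = 0.67, lym = 0, av = 0))
  R <- allocate_resistances(a)
  expect_equal(R[["int"]], 7500)
  expect_equal(R[["sp"]], 7500)
  expect_equal(R[["lym"]], 5000)  # R_tot / q, not the inconsistent table row
  expect_equal(R[["av"]], 5000)
  expect_equal(1 / sum(1 / R), 1500)   # parallel recombination, machine precision

  single <- outlet_allocation(1500, 0.1, q = c(only = 1), c = c(only = 1))
  expect_equal(allocate_resistances(single)[["only"]], 1500)

  expect_error(outlet_allocation(1500, 0.5,
                                 q = c(int = 0.5, sp = 0.6),
                                 c = c(int = 0.5, sp = 0.5)),
               "sum to 1.*int=0.5")
  expect_error(outlet_allocation(1500, 0.5,
                                 q = c(int = 0, sp = 1),
                                 c = c(int = 0, sp = 1)),
               "omit the outlet")
})

test_that("compliance allocation is proportional and sums to the total", {
  a <- outlet_allocation(1500, 0.51,
                         q = c(int = 0.2, sp = 0.2, lym = 0.3, av = 0.3),
                         c = c(int = 0.11, sp = 0.67, lym = 0.11, av = 0.11))
  C <- allocate_compliances(a)
  expect_equal(C[["sp"]], 0.67 * 0.51)
  expect_equal(sum(C), 0.51)
  expect_equal(C[["int"]], C[["lym"]])
  b <- outlet_allocation(1500, 0.51,
                         q = c(int = 0.5, sp = 0.5),
                         c = c(int = 0, sp = 1))
  expect_equal(allocate_compliances(b)[["int"]], 0)
  expect_error(outlet_allocation(1500, 0.5, q = c(int = 0.5, sp = 0.5),
                                 c = c(int = -0.1, sp = 1.1)),
               ">= 0")
})

test_that("0D integration starts at P0 and honors degenerate inputs", {
  quiet <- list(inlet_source("off", "x", mean_flow = 0))
  m <- zero_d_model(quiet, R_tot = 1500, C_tot = 0.17, P0 = 0)
  tr <- simulate_0d(m, 2)
  expect_equal(nrow(tr), 41L)            # duration/dt + 1 samples
  expect_true(all(tr$pressure == 0))     # zero inflow from rest stays at rest
  expect_equal(tr$time[1], 0)

  m2 <- zero_d_model(quiet, R_tot = 1500, C_tot = 0.17, P0 = 4)
  tr2 <- simulate_0d(m2, 1)
  expect_equal(tr2$pressure[1], 4)
  expect_error(simulate_0d(m, 0.01), "duration")
})

test_that("0D mean decays to Q*R with the exact discrete rate", {
  R <- 1500; C <- 0.17; dt <- 0.05; Q <- 0.00667
  m <- zero_d_model(list(inlet_source("prod", "x", mean_flow = Q)),
                    R_tot = R, C_tot = C, dt = dt, P0 = 25)
  tr <- simulate_0d(m, 50)
  a <- (C * R / dt) / (1 + C * R / dt)
  n <- seq_len(nrow(tr)) - 1L
  expect_equal(tr$pressure, Q * R + (25 - Q * R) * a^n, tolerance = 1e-12)
})

test_that("discrete steady-cycle amplitude matches the backward-difference filter gain", {
  dt <- 0.05
  w <- 2 * pi
  cases <- list(c(R = 100, C = 0.05), c(R = 1500, C = 0.01),
                c(R = 300, C = 0.1))
  for (p in cases) {
    tau <- p[["R"]] * p[["C"]]
    m <- zero_d_model(list(inlet_source("s", "x", amplitude = 1,
                                        frequency = 1)),
                      R_tot = p[["R"]], C_tot = p[["C"]], dt = dt,
                      P0 = 0)
    tr <- simulate_0d(m, 25 * tau + 5)
    amp <- harmonic_amplitude(tr, 1, c(25 * tau, 25 * tau + 5))
    expect_equal(amp, discrete_wk_gain(p[["R"]], p[["C"]], w, dt),
                 tolerance = 0.005)
  }
  # and the discrete gain approaches the continuous-time windkessel gain
  # R/sqrt(1 + (wRC)^2) as dt -> 0
  err <- vapply(c(0.05, 0.01, 0.002), function(d)
    abs(discrete_wk_gain(1500, 0.17, w, d) - continuous_wk_gain(1500, 0.17, w)),
    numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3] / continuous_wk_gain(1500, 0.17, w), 0.005)
})

test_that("pulsation amplitude is half the peak-to-peak excursion", {
  t <- seq(0, 5, by = 0.05)
  sine <- data.frame(time = t, pressure = 3.2 * sin(2 * pi * t))
  expect_equal(pulsation_amplitude(sine, c(0, 5)), 3.2)
  flat <- data.frame(time = t, pressure = rep(9, length(t)))
  expect_equal(pulsation_amplitude(flat, c(0, 5)), 0)
  # 1 Hz and 0.2 Hz components peak together at t = 1.25 and 3.75 s
  two <- data.frame(time = t,
                    pressure = 1.61 * sin(2 * pi * t) +
                      1.58 * sin(2 * pi * 0.2 * t))
  expect_equal(pulsation_amplitude(two, c(0, 5)), 3.19)
  expect_error(pulsation_amplitude(sine, c(10, 11)), "empty window")
})

test_that("compliance tuning interpolates the unique amplitude crossing", {
  src <- default_inlet_sources(respiration = FALSE)
  fit <- tune_total_compliance(src, n_grid = 200)
  # amplitude is strictly decreasing in compliance over the whole grid
  expect_true(all(diff(fit$grid$amplitude) < 0))
  # achieved amplitude at the fitted compliance hits the target
  expect_equal(fit$achieved_amplitude, 5, tolerance = 1e-3)

  # fixed point: targeting the amplitude achieved at a grid value returns
  # that value
  target <- fit$grid$amplitude[100]
  fit2 <- tune_total_compliance(src, target_amplitude = target,
                                n_grid = 200)
  expect_equal(fit2$C_tot, fit$grid$C_tot[100], tolerance = 1e-9)

  # linearity: halving all source amplitudes, the fit returns the
  # compliance whose amplitude under the original sources is twice the
  # target
  half <- lapply(src, function(s) {
    s$amplitude <- s$amplitude / 2
    s$mean_flow <- s$mean_flow / 2
    s
  })
  fit_half <- tune_total_compliance(half, target_amplitude = 2.5,
                                    n_grid = 200)
  expect_equal(fit_half$C_tot, fit$C_tot, tolerance = 1e-6)

  # an unreachable target fails loudly, naming the achieved range
  expect_error(tune_total_compliance(src, target_amplitude = 0.2,
                                     n_grid = 50),
               "achieved range")
  expect_error(tune_total_compliance(src, target_amplitude = 1e6,
                                     n_grid = 50),
               "achieved range")
})
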