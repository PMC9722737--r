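test_that("conduit resistance laws follow laminar first principles", {
  fl <- fluid_properties()
  # circular Poiseuille, computed independently in SI units
  L <- 15e-3; r <- 1.784e-3
  R_si <- 8 * fl$viscosity * L / (pi * r^4)            # Pa.s/m^3
  R_clin <- R_si / (133.322 * 1e6)                     # mmHg.s/ml
  expect_equal(poiseuille_resistance(15, 1.784), R_clin)
  expect_equal(poiseuille_resistance(30, 1.784),
               2 * poiseuille_resistance(15, 1.784))
  expect_equal(poiseuille_resistance(15, 0.892),
               16 * poiseuille_resistance(15, 1.784))
  expect_error(poiseuille_resistance(-1, 1), "length")
  expect_error(poiseuille_resistance(1, 0), "radius")

  # thin annular slit: plane Poiseuille 12 mu L / (l h^3)
  R_slit_si <- 12 * fl$viscosity * 30e-3 / (100e-3 * (1.5e-3)^3)
  expect_equal(slit_resistance(30, 1.5, 100), R_slit_si / (133.322 * 1e6))
  expect_equal(slit_resistance(30, 0.75, 100),
               8 * slit_resistance(30, 1.5, 100))
})

test_that("Reynolds number is rho v D_h / mu and stays laminar at CSF scales", {
  cd <- conduit("probe", "a", "b", resistance = 1, area = 100,
                hydraulic_diameter = 2.93)
  # v = 0.012 m/s over 100 mm^2 corresponds to Q = 1.2 ml/s
  expect_equal(reynolds_number(1.2, cd), 998.2 * 0.012 * 2.93e-3 / 0.001003)
  expect_equal(round(reynolds_number(1.2, cd)), 35)
  expect_equal(reynolds_number(0, cd), 0)
  expect_equal(reynolds_number(2.4, cd), 2 * reynolds_number(1.2, cd))

  # peak aqueduct flow in the default geometry stays deep in the laminar
  # regime (order tens)
  net <- build_case("B")$network
  aq <- net$conduits$aqueduct
  Re <- reynolds_number(6.67e-3 + 0.11, aq, net$fluid)
  expect_gt(Re, 10)
  expect_lt(Re, 100)
})

test_that("network construction validates topology", {
  comps <- list(compartment("a"), compartment("b"))
  link <- conduit("link", "a", "b", resistance = 1, area = 10)
  out <- windkessel_outlet("out", "b", R = 1000, C = 0.1)
  src <- inlet_source("src", "a", mean_flow = 0.01)
  expect_s3_class(hydraulic_network(comps, list(link), list(out), list(src)),
                  "hydraulic_network")
  expect_error(hydraulic_network(comps, list(link), list(), list(src)),
               "at least one outlet")
  expect_error(
    hydraulic_network(comps, list(link),
                      list(windkessel_outlet("out", "nowhere", 1000)),
                      list(src)),
    "unknown compartment 'nowhere'")
  expect_error(
    hydraulic_network(comps, list(), list(out), list(src)),
    "not connected")
  expect_error(
    hydraulic_network(comps, list(conduit("loop", "a", "a",
                                          resistance = 1, area = 1)),
                      list(out), list(src)),
    "self-loop")
})

test_that("a single-compartment network reproduces the 0D recurrence", {
  # constant production into a pure resistor: P = Q R at every step
  net0 <- single_comp_net(R = 1500, C = 0,
                          sources = list(inlet_source("p", "node",
                                                      mean_flow = 0.00667)))
  res0 <- run_network(net0, duration = 2, initial_pressure = 0)
  expect_equal(res0$P_node, rep(10.005, nrow(res0)))

  # sinusoidal inflow with compliance: identical trace to simulate_0d
  net <- single_comp_net(R = 1500, C = 0.17)
  res <- run_network(net, duration = 10, initial_pressure = 0)
  m <- zero_d_model(net$sources, R_tot = 1500, C_tot = 0.17, dt = 0.05,
                    P0 = 0)
  tr <- simulate_0d(m, 10)
  expect_equal(res$P_node, tr$pressure[-1], tolerance = 1e-13)
})

test_that("series conduits produce the expected pressure drop", {
  net <- two_comp_net(r = 5, R = 1500, C = 0.2, Q = 0.01)
  res <- run_network(net, duration = 3, initial_pressure = 0)
  expect_equal(res$P_up - res$P_down, rep(0.01 * 5, nrow(res)),
               tolerance = 1e-12)
  expect_equal(res$Q_link, rep(0.01, nrow(res)), tolerance = 1e-12)
})

test_that("mass is conserved at every node and step", {
  for (id in c("A", "C")) {
    cs <- build_case(id)
    res <- run_network(cs$network, duration = 5)
    resid <- mass_balance_residuals(cs$network, res)
    expect_lt(max(abs(resid)), 1e-10)
  }
  net <- two_comp_net()
  expect_lt(max(abs(mass_balance_residuals(net,
                                           run_network(net, duration = 2)))),
            1e-12)
})

test_that("stored volume accounts exactly for the inflow-absorption imbalance", {
  cs <- build_case("B")
  net <- cs$network
  dt <- 0.05
  res <- run_network(net, duration = 10, dt = dt, initial_pressure = 10)
  inflow <- rowSums(vapply(net$sources, evaluate_source, numeric(nrow(res)),
                           t = res$time))
  absorbed <- rowSums(vapply(net$outlets, function(o)
    (res[[paste0("P_", o$node)]] - o$P_out) / o$R, numeric(nrow(res))))
  stored <- sum(dt * (inflow - absorbed))
  # windkessel states start at the initial node pressure (10 mmHg)
  dP <- vapply(net$outlets, function(o)
    res[[paste0("P_", o$node)]][nrow(res)] - 10, numeric(1))
  C_i <- vapply(net$outlets, `[[`, numeric(1), "C")
  expect_equal(stored, sum(C_i * dP), tolerance = 1e-9)
})

test_that("partitioned coupling matches the monolithic solve", {
  nets <- list(single_comp_net(), two_comp_net(),
               build_case("B")$network, build_case("C")$network)
  for (net in nets) {
    rm_ <- run_network(net, duration = 3, solver = "monolithic")
    rp <- run_network(net, duration = 3, solver = "partitioned")
    pcols <- grep("^P_", names(rm_), value = TRUE)
    expect_lt(max(abs(as.matrix(rm_[pcols]) - as.matrix(rp[pcols]))), 1e-6)
  }
})

test_that("partitioned coupling converges in two iterations on a linear network", {
  net <- single_comp_net()
  st <- network_state(net, 10)
  step <- step_partitioned(net, st, t = 0.05, dt = 0.05)
  expect_lte(step$iterations, 2L)
  # the default four-compartment network is also linear: same bound
  netB <- build_case("B")$network
  stB <- network_state(netB, 10)
  expect_lte(step_partitioned(netB, stB, t = 0.05, dt = 0.05)$iterations, 2L)
})

test_that("explicit coupling (tol = Inf) differs from the implicit answer", {
  net <- build_case("B")$network
  st <- network_state(net, 10)
  imp <- step_monolithic(net, st, t = 0.25, dt = 0.05)
  exp1 <- step_partitioned(net, st, t = 0.25, dt = 0.05, tol = Inf)
  diff <- max(abs(imp$node_pressures - exp1$node_pressures))
  expect_gt(diff, 1e-4)
})

test_that("runs are deterministic and fail without an outlet path", {
  net <- build_case("A")$network
  r1 <- run_network(net, duration = 1)
  r2 <- run_network(net, duration = 1)
  expect_identical(r1, r2)
})

test_that("pulsatile outlet flow follows the compliance distribution", {
  # all-compliant case: outlet flow amplitudes proportional to c_i
  csC <- run_case("C")
  ampC <- csC$metrics$outlet_flow_amplitudes
  c_i <- csC$definition$c
  ratio <- (ampC / ampC[["sp"]]) / (c_i / c_i[["sp"]])
  expect_true(all(abs(ratio[c("int", "lym", "av")] - 1) < 0.05))

  # purely resistive outlets carry (pressure amplitude)/R_i
  csB <- run_case("B")
  w <- csB$result$time >= 20
  p_amp <- pulsation_amplitude(csB$result$P_cranialSAS[w])
  q_amp <- pulsation_amplitude(csB$result$Qout_lym[w])
  expect_equal(q_amp, p_amp / 5000, tolerance = 0.05)
})

test_that("spatial pressure differences are far smaller than temporal swings", {
  csB <- run_case("B")
  m <- csB$metrics
  expect_gt(m$lv_to_sas_pressure_difference_amplitude, 0.005)
  expect_lt(m$lv_to_sas_pressure_difference_amplitude, 0.2)
  expect_lt(m$lv_to_sas_pressure_difference_amplitude,
            0.05 * m$pressure_pulsation_amplitude)
})
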