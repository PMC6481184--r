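# Closed-form flux expressions: channels, pump, cotransporters, driving
# forces, and the per-pathway flux table.

u_bal <- -44.7 / 26.7 # potential of the printed balanced state

test_that("GHK cation flux matches the balanced-state table and the closed form", {
  # Na channel net flux at the printed balanced state (rounded inputs)
  expect_equal(ghk_cation_flux(0.00382, u_bal, 38.0, 140), 1.045,
               tolerance = 0.005)
  # frozen high-precision evaluation of the closed form
  expect_equal(ghk_cation_flux(0.01, -1, 100, 140), 1.63279068,
               tolerance = 1e-8)
  # zero potential, equal concentrations
  expect_identical(ghk_cation_flux(0.37, 0, 120, 120), 0)
  # analytic u -> 0 limit
  expect_equal(ghk_cation_flux(1, 0, 100, 140), 40)
})

test_that("GHK anion flux has the sign that matches the flux-balance table", {
  expect_equal(ghk_anion_flux(0.0091, u_bal, 45.1, 116), -0.437,
               tolerance = 0.005)
  # Nernst equilibrium of an anion: ci = co * exp(u)
  u <- -0.9
  expect_equal(ghk_anion_flux(0.02, u, 116 * exp(u), 116), 0,
               tolerance = 1e-12)
  expect_equal(ghk_anion_flux(1, 0, 100, 140), 40)
})

test_that("unidirectional fluxes are signed, split the net flux, and vanish at p = 0", {
  k_uni <- ghk_unidirectional(0.022, u_bal, 147.0, 5.8, valence = 1)
  expect_equal(k_uni[["influx"]], 0.2627, tolerance = 0.005)
  expect_equal(k_uni[["efflux"]], -1.2505, tolerance = 0.005)
  cl_uni <- ghk_unidirectional(0.0091, u_bal, 45.1, 116, valence = -1)
  expect_equal(cl_uni[["influx"]], 0.4082, tolerance = 0.005)
  expect_equal(cl_uni[["efflux"]], -0.8445, tolerance = 0.005)
  expect_identical(unname(ghk_unidirectional(0, -1.5, 100, 140)), c(0, 0))

  set.seed(42)
  for (i in 1:25) {
    p <- runif(1, 0, 0.1); u <- runif(1, -4, -1e-8)
    ci <- runif(1, 1, 200); co <- runif(1, 1, 200)
    for (val in c(1, -1)) {
      uni <- ghk_unidirectional(p, u, ci, co, valence = val)
      expect_gte(uni[["influx"]], 0)
      expect_lte(uni[["efflux"]], 0)
      net <- if (val == 1) ghk_cation_flux(p, u, ci, co)
             else ghk_anion_flux(p, u, ci, co)
      expect_equal(sum(uni), net, tolerance = 1e-12)
    }
  }
})

test_that("cation GHK flux obeys the flip symmetry J(u, ci, co) = -J(-u, co, ci)", {
  set.seed(7)
  for (i in 1:25) {
    p <- runif(1, 0, 0.1); u <- runif(1, -4, 4)
    ci <- runif(1, 1, 200); co <- runif(1, 1, 200)
    expect_equal(ghk_cation_flux(p, u, ci, co),
                 -ghk_cation_flux(p, -u, co, ci), tolerance = 1e-10)
  }
})

test_that("the u -> 0 branch joins the full GHK expression continuously", {
  p <- 0.01; ci <- 100; co <- 140
  # the full expression stays finite and first-order close to the limit
  for (u in c(1e-4, -1e-4)) {
    full <- ghk_cation_flux(p, u, ci, co)
    lim <- p * (co - ci)
    # first-order deviation bound: |u| * (ci + (co - ci)/2)
    expect_lt(abs(full - lim), abs(u) * (ci + (co - ci) / 2) * 1.01)
  }
  # continuity across the switch threshold
  expect_equal(ghk_cation_flux(p, 9.9e-7, ci, co),
               ghk_cation_flux(p, 1.01e-6, ci, co), tolerance = 1e-5)
  expect_equal(ghk_anion_flux(p, -9.9e-7, ci, co),
               ghk_anion_flux(p, -1.01e-6, ci, co), tolerance = 1e-5)
})

test_that("pump fluxes follow first-order kinetics with Na/K stoichiometry", {
  pf <- pump_fluxes(0.039, 38.0, 1.5)
  expect_equal(pf[["na"]], -1.482, tolerance = 1e-3)
  expect_equal(pf[["k"]], 0.988, tolerance = 1e-3)
  expect_identical(unname(pump_fluxes(0, 50, 1.5)), c(0, 0))
  # electroneutral pump limit: gamma = 1 carries no net charge
  pf1 <- pump_fluxes(0.04, 30, 1)
  expect_equal(pf1[["na"]] + pf1[["k"]], 0)
})

test_that("cotransporter fluxes are product-driven and electroneutral", {
  med <- u937_medium()
  st <- cell_state(38.0, 147.0, 45.1, med)
  ct <- cotransport_fluxes(membrane_params(inc = 3e-5), st, med)
  expect_equal(ct$nc[["net"]], 0.436, tolerance = 0.005)
  expect_equal(ct$nc[["influx"]], 0.4872, tolerance = 0.005)
  expect_equal(ct$nc[["efflux"]], -0.0514, tolerance = 0.005)
  expect_equal(ct$kc[["net"]], 0)
  expect_equal(ct$nkcc[["net"]], 0)

  # all-zero coefficients, and product equilibrium
  ct0 <- cotransport_fluxes(membrane_params(), st, med)
  expect_true(all(unlist(ct0) == 0))
  st_eq <- st
  st_eq$na <- med$na0 * med$cl0 / st$cl
  expect_equal(cotransport_fluxes(membrane_params(inc = 1e-4), st_eq,
                                  med)$nc[["net"]], 0)

  # zero charge contribution in the flux table, by construction
  set.seed(11)
  for (i in 1:10) {
    cs <- random_case()
    ft <- build_flux_table(cs$st, cs$par, cs$med)
    charge <- ft$net["Na", c("NC", "KC", "NKCC")] +
      ft$net["K", c("NC", "KC", "NKCC")] -
      ft$net["Cl", c("NC", "KC", "NKCC")]
    expect_equal(unname(sum(charge)), 0, tolerance = 1e-12)
  }
})

test_that("electrochemical potential differences match the printed state", {
  med <- u937_medium()
  st <- cell_state(38.0, 147.0, 45.1, med)
  st$U <- -44.7
  st$u <- st$U / 26.7
  mu <- electrochemical_potentials(st, med)
  expect_equal(mu[["mun"]], -79.5, tolerance = 0.01)
  expect_equal(mu[["muk"]], 41.7, tolerance = 0.01)
  expect_equal(mu[["mucl"]], 19.4, tolerance = 0.005)

  st0 <- cell_state(140, 60, 45.1, med) # [Na]i = [Na]o
  st0$U <- 0; st0$u <- 0
  expect_equal(electrochemical_potentials(st0, med)[["mun"]], 0)

  st_bad <- st; st_bad$na <- -1
  expect_error(electrochemical_potentials(st_bad, med), "positive")
})

test_that("flux table reproduces the balanced-state decomposition and its identities", {
  med <- u937_medium()
  st <- table2_printed_state()
  ft <- build_flux_table(st, u937_params(), med)
  expect_equal(ft$net["Na", "PUMP"], -1.4811, tolerance = 0.005)
  expect_equal(ft$net["Na", "Channel"], 1.0451, tolerance = 0.005)
  expect_equal(ft$net["Na", "NC"], 0.4359, tolerance = 0.005)
  expect_equal(ft$net["K", "PUMP"], 0.9874, tolerance = 0.005)
  expect_equal(ft$net["Cl", "Channel"], -0.4363, tolerance = 0.005)

  # all-zero parameters give an all-zero table
  st0 <- st; st0$u <- -1; st0$U <- -26.7
  ft0 <- build_flux_table(st0, membrane_params(), med)
  expect_true(all(unlist(ft0) == 0))

  # influx + efflux = net, cell by cell, over random states
  set.seed(23)
  for (i in 1:15) {
    cs <- random_case()
    fti <- build_flux_table(cs$st, cs$par, cs$med)
    expect_equal(fti$influx + fti$efflux, fti$net, tolerance = 1e-12)
  }

  # charge balance of the charge-carrying pathways at the balanced state
  p <- u937_params()
  charge <- ft$net["Na", "Channel"] + ft$net["K", "Channel"] -
    ft$net["Cl", "Channel"] - p$beta * st$na + p$beta * st$na / p$gamma
  expect_lt(abs(charge), 1e-3)
})

test_that("OSOR is the pump share of K influx over the passive pathways", {
  ft <- build_flux_table(table2_printed_state(), u937_params(),
                         u937_medium())
  expect_equal(compute_osor(ft), 3.76, tolerance = 0.005)

  # pump off: OSOR 0
  p0 <- u937_params(); p0 <- membrane_params(beta = 0, gamma = p0$gamma,
                                             pna = p0$pna, pk = p0$pk,
                                             pcl = p0$pcl, inc = p0$inc)
  st <- table2_printed_state()
  expect_equal(compute_osor(build_flux_table(st, p0, u937_medium())), 0)

  # no passive K influx at all: undefined, signalled
  p_na_only <- membrane_params(beta = 0.039, pna = 0.00382)
  expect_error(compute_osor(build_flux_table(st, p_na_only, u937_medium())),
               "undefined")
})
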