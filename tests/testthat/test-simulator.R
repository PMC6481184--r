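# Time integration: pump decay, stepping, published end states, schedules
# and balanced-state detection.

test_that("the pump rate coefficient decays linearly and clamps at zero", {
  expect_equal(beta_at(0.029, 0.000068, 240), 0.01268)
  expect_equal(round(beta_at(0.029, 0.000068, 240), 3), 0.013)
  # the printed intermediate values of the apoptosis run
  expect_equal(round(beta_at(0.029, 0.000068, c(10, 60, 120, 210)), 3),
               c(0.028, 0.025, 0.021, 0.015))
  expect_equal(beta_at(0.05, 0, c(0, 1000)), c(0.05, 0.05))
  expect_equal(beta_at(0.01, 0.001, 20), 0) # past beta0/kb: clamped
})

test_that("the balanced state is a fixed point of the stepper", {
  tc <- run_table2()
  st <- attr(tc, "final_state")
  p <- attr(tc, "final_params")
  dt <- 0.01
  st2 <- step_state(st, p, u937_medium(), dt)
  expect_lt(abs(st2$na - st$na), 1e-3 * dt)
  expect_lt(abs(st2$k - st$k), 1e-3 * dt)
  expect_lt(abs(st2$cl - st$cl), 1e-3 * dt)
})

test_that("all-zero parameters leave the state unchanged", {
  med <- u937_medium()
  st <- cell_state(33, 152, 45, med)
  st2 <- step_state(st, membrane_params(), med, 0.5)
  expect_identical(c(st2$na, st2$k, st2$cl, st2$V),
                   c(st$na, st$k, st$cl, st$V))
  tc <- simulate_cell(st, membrane_params(), med, t_end = 5, dt = 0.1,
                      hp = 10, record_fluxes = FALSE)
  expect_equal(last_row(tc)$na, 33)
  expect_equal(last_row(tc)$k, 152)
  bal <- detect_balance(tc)
  expect_true(bal$balanced)
  expect_lte(bal$time, 1) # at the first emitted sample after t = 0
})

test_that("the high-potential cell converges to the printed balanced state", {
  last <- last_row(run_table2())
  expect_equal(last$U, -44.7, tolerance = 0.005)
  expect_equal(last$na, 38.0, tolerance = 0.005)
  expect_equal(last$k, 147.0, tolerance = 0.005)
  expect_equal(last$cl, 45.1, tolerance = 0.005)
  expect_equal(last$V, 12.51, tolerance = 0.005)
  expect_equal(last$mun, -79.5, tolerance = 0.005)
  expect_equal(last$muk, 41.7, tolerance = 0.005)
  expect_equal(last$mucl, 19.4, tolerance = 0.005)
  bal <- detect_balance(run_table2())
  expect_true(bal$balanced)
  expect_lte(bal$time, 240)
})

test_that("the apoptosis schedule reproduces the printed trajectory", {
  tc <- run_table4()
  last <- last_row(tc)
  expect_equal(last$na, 51.4, tolerance = 0.01)
  expect_equal(last$k, 96.7, tolerance = 0.01)
  expect_equal(last$cl, 24.0, tolerance = 0.01)
  expect_equal(last$U, -42.2, tolerance = 0.005)
  expect_equal(last$V, 7.25, tolerance = 0.005)
  expect_equal(round(last$beta, 3), 0.013)
  # the potential jumps instantaneously when the channels change at t = 0
  expect_equal(tc$U[tc$t == 0], -34.6, tolerance = 0.005)
  # intermediate printed rows, before and after pk steps back to 0.02
  row30 <- tc[abs(tc$t - 30) < 1e-9, ][1, ]
  expect_equal(row30$cl, 24.6, tolerance = 0.005)
  row60 <- tc[abs(tc$t - 60) < 1e-9, ]
  expect_equal(row60$na, 33.8, tolerance = 0.005)
  expect_equal(row60$k, 114.3, tolerance = 0.005)
  expect_equal(row60$U, -44.8, tolerance = 0.005)
  row120 <- tc[abs(tc$t - 120) < 1e-9, ]
  expect_equal(row120$na, 37.7, tolerance = 0.005)
  expect_equal(row120$k, 110.3, tolerance = 0.005)
})

test_that("t_end = 0 yields a single-row time course equal to the initial state", {
  med <- u937_medium()
  tc <- simulate_cell(cell_state(33, 152, 45, med), u937_params(), med,
                      t_end = 0, dt = 0.01, hp = 10)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$na, 33)
  expect_equal(tc$k, 152)
  expect_equal(tc$cl, 45)
  expect_equal(tc$t, 0)
})

test_that("the endpoint is stable under step halving", {
  ends <- lapply(c(0.02, 0.01, 0.005), function(dt) last_row(run_table2(dt)))
  for (ion in c("na", "k", "cl")) {
    expect_lt(abs(ends[[1]][[ion]] - ends[[2]][[ion]]), 0.05)
    expect_lt(abs(ends[[2]][[ion]] - ends[[3]][[ion]]), 0.05)
  }
})

test_that("after a pump stop, K+/Na+ exchange precedes swelling", {
  # low chloride permeability: equal-and-opposite cation exchange through
  # channels keeps total osmolyte content, hence volume, almost constant
  tc <- simulate_cell(fixture_scenario("fig2_pumpstop", pcl = 1e-4),
                      t_end = 60, hp = 500, record_fluxes = FALSE)
  expect_gt(last_row(tc)$na, tc$na[1] + 5) # Na rises
  expect_lt(last_row(tc)$k, tc$k[1] - 5)   # K falls
  dV <- abs(last_row(tc)$V - tc$V[1]) / tc$V[1]
  expect_lt(dV, 0.01)
  d_cations <- abs((last_row(tc)$na + last_row(tc)$k) - (tc$na[1] + tc$k[1]))
  d_na <- abs(last_row(tc)$na - tc$na[1])
  expect_lt(d_cations, 0.1 * d_na)
  # never balanced: the pump-stopped cell keeps drifting
  expect_false(detect_balance(simulate_cell(
    fixture_scenario("fig2_pumpstop", pcl = 1e-3),
    record_fluxes = FALSE))$balanced)
})

test_that("scheduled overrides apply at their event time and not before", {
  med <- u937_medium()
  base <- scenario(med, apoptosis_baseline_params(), na = 32, k = 117,
                   cl = 40, t_end = 40, dt = 0.02, hp = 100)
  with_event <- base
  with_event$schedule <- param_schedule(30, list(list(pk = 0.03)))
  tc0 <- simulate_cell(base, record_fluxes = FALSE)
  tc1 <- simulate_cell(with_event, record_fluxes = FALSE)
  pre <- tc1$t < 30 - 1e-9
  expect_equal(tc1$na[pre], tc0$na[tc0$t < 30 - 1e-9], tolerance = 1e-12)
  expect_equal(tc1$U[pre], tc0$U[tc0$t < 30 - 1e-9], tolerance = 1e-12)
  # and the potential moves at the event
  expect_lt(tc1$U[abs(tc1$t - 30) < 1e-9],
            tc0$U[abs(tc0$t - 30) < 1e-9] - 2)
})

test_that("time courses sample on the hp grid plus event times", {
  tc <- run_table4()
  expect_true(all(c(0, 30, 240) %in% tc$t))
  expect_true(all(diff(tc$t) > 0))
  ft <- attr(tc, "flux_tables")
  expect_equal(length(ft), nrow(tc))
  expect_s3_class(ft[[nrow(tc)]], "flux_table")
})
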