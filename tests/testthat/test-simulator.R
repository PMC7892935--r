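test_that("evaporation sources vanish at equilibrium and have drying signs", {
  s <- saturation_state(333.15)
  # equilibrium: moisture field equal to its equilibrium vapour value
  eq <- evaporation_sources(c = 0.99 * s$cv_sat, T = 333.15, K_vap = 1000,
                            aw = 0.99, cv_sat = s$cv_sat, Sg = 0.5,
                            eps = 0.74, Hevap = 2.454e6)
  expect_equal(eq$Sm, 0); expect_equal(eq$Sh, 0)
  # drying: evaporation removes moisture and cools
  dr <- evaporation_sources(c = 49750, T = 333.15, K_vap = 1e-4, aw = 0.99,
                            cv_sat = s$cv_sat, Sg = 0, eps = 0.74,
                            Hevap = 2.454e6)
  expect_gt(dr$E, 0); expect_lt(dr$Sm, 0); expect_lt(dr$Sh, 0)
  # pore-equilibrium split with empty gas space: E = K_vap * aw * cv_sat
  pe <- evaporation_sources(c = 49750, T = 333.15, K_vap = 1000, aw = 0.99,
                            cv_sat = s$cv_sat, Sg = 0, eps = 0.74,
                            Hevap = 2.454e6,
                            vapour_split = "pore_equilibrium")
  expect_equal(pe$E, 990 * s$cv_sat, tolerance = 1e-12)
})

test_that("darcy velocity is zero when disabled and linear when enabled", {
  expect_equal(darcy_velocity(1000, 1e-14, 0.5, 1e-3, darcy_on = FALSE), 0)
  expect_equal(darcy_velocity(0, 1e-14, 0.5, 1e-3), 0)
  expect_equal(darcy_velocity(1000, 1e-14, 0.5, 1e-3), 5e-9,
               tolerance = 1e-12)
  expect_error(darcy_velocity(1000, NA, 0.5, 1e-3), "permeability")
})

test_that("an equilibrated state is a fixed point of the step", {
  # air at the sample temperature, humidity matching the surface activity,
  # no volumetric evaporation: nothing should change
  cons <- default_constants()
  pb <- property_bundle(cons$c0, cons$T0)
  RH_eq <- 100 * pb$aw
  setup <- drying_setup(
    conditions = drying_conditions(air_state(cons$T0, 0.5, RH_eq),
                                   K_vap = 0, t_max_min = 30))
  state <- march(setup, 5)
  expect_lt(max(abs(state$c - cons$c0)) / cons$c0, 1e-10)
  expect_lt(max(abs(state$T - cons$T0)), 1e-8)
})

test_that("moisture is conserved without evaporation or outgoing flux", {
  # saturated air blocks the surface flux (clamped at zero), K_vap = 0
  setup <- drying_setup(
    conditions = drying_conditions(air_state(333.15, 0.5, 100), K_vap = 0,
                                   t_max_min = 20))
  n <- setup$geometry$n_z
  w <- grid_weights(n)
  env <- injeradry:::.sim_env(setup)
  state <- injeradry:::.init_state(setup)
  total0 <- sum(state$c * w)
  for (i in 1:10) {
    state <- advance(state, setup, env)
    expect_lt(abs(sum(state$c * w) - total0) / total0, 1e-8)
  }
  # and the moisture ratio stays at one for the whole (truncated) run
  expect_warning(cv <- simulate_drying(setup), "truncated")
  expect_true(all(abs(cv$MR - 1) < 1e-8))
  # while the sample still heats up towards the air temperature
  expect_gt(max(cv$T_mean_K), 320)
})

test_that("pure diffusion matches the analytic slab series within 1%", {
  D <- 1e-9
  L <- 0.0039
  setup <- diffusion_setup(D = D, n_z = 81, dt = 5)
  t_probe <- 0.1 * L^2 / D  # 10% of the diffusion time
  n_steps <- round(t_probe / setup$settings$dt)
  state <- march(setup, n_steps)
  z <- seq(0, L, length.out = 81)
  exact <- slab_series(z, n_steps * setup$settings$dt, L, D,
                       c0 = default_constants()$c0, cs = 0)
  err <- max(abs(state$c - exact)) / default_constants()$c0
  expect_lt(err, 0.01)
})

test_that("spatial discretization converges at second order", {
  D <- 1e-9
  L <- 0.0039
  t_probe <- 0.05 * L^2 / D
  err_at <- function(n_z) {
    setup <- diffusion_setup(D = D, n_z = n_z, dt = 0.5)
    n_steps <- round(t_probe / 0.5)
    state <- march(setup, n_steps)
    z <- seq(0, L, length.out = n_z)
    exact <- slab_series(z, n_steps * 0.5, L, D,
                         c0 = default_constants()$c0)
    max(abs(state$c - exact)) / default_constants()$c0
  }
  e <- vapply(c(11, 21, 41), err_at, numeric(1))
  order1 <- log2(e[1] / e[2])
  order2 <- log2(e[2] / e[3])
  expect_gt(order1, 1.8)
  expect_gt(order2, 1.8)
})

test_that("a no-removal configuration keeps the moisture ratio at one", {
  # K_vap = 0 and saturated air: both removal channels off
  setup <- drying_setup(conditions = drying_conditions(
    air_state(333.15, 0.5, 100), K_vap = 0, t_max_min = 15))
  expect_warning(cv <- simulate_drying(setup), "truncated")
  expect_true(all(abs(cv$MR - 1) < 1e-9))
  expect_true(attr(cv, "truncated"))
})

test_that("the default drying run closes its moisture balance", {
  cv <- simulate_drying(ref_setup())
  bal <- attr(cv, "balance")
  expect_lt(abs(bal$closure - 1), 0.01)
  expect_equal(bal$removed_mol_m2,
               bal$evaporated_mol_m2 + bal$boundary_mol_m2,
               tolerance = 1e-6)
})

test_that("drying curves are monotone and temperatures stay bounded", {
  for (cond in list(c(333.15, 0.5, 11), c(323.15, 0.5, 15.7))) {
    cv <- simulate_drying(ref_setup(cond[1], cond[2], cond[3]))
    expect_true(all(diff(cv$MR) <= 1e-12))
    expect_true(all(cv$T_mean_K >= 298.15 - 0.5))
    expect_true(all(cv$T_mean_K <= cond[1] + 0.5))
    expect_true(all(cv$T_center_K >= 298.15 - 0.5))
  }
})

test_that("the solution is time-step independent below five minutes", {
  mr_at <- function(dt) {
    cv <- simulate_drying(ref_setup(settings = solver_settings(dt = dt)))
    stats::approx(cv$t_min, cv$MR, xout = c(20, 40, 60, 80, 100))$y
  }
  m300 <- mr_at(300); m60 <- mr_at(60); m30 <- mr_at(30)
  expect_lt(max(abs(m300 - m30)), 0.01)   # five-minute steps already stable
  expect_lt(max(abs(m60 - m30)), 0.005)   # halving changes MR by < 0.5%
})

test_that("grid refinement converges and the coarsest level is flagged", {
  # smooth diffusion problem: refinement shrinks the change monotonically
  smooth <- drying_setup(
    geometry = sample_geometry(n_z = 41),
    conditions = drying_conditions(air_state(298.15, 0.5, 50), K_vap = 0,
                                   t_max_min = 40),
    settings = solver_settings(dt = 60, diffusivity_model = "constant",
                               D_const = 1e-9, surface_model = "dirichlet",
                               c_surface = 0))
  rep_s <- suppressWarnings(
    independence_study(smooth, grid_levels = c(3, 5, 9, 17, 33),
                       dt_levels = c(300, 120, 60), probe_time_min = 30))
  d <- abs(diff(rep_s$grid$MR_probe))
  expect_true(all(diff(d) < 0))              # monotonically shrinking steps
  expect_false(rep_s$grid$converged[1])      # 3 nodes cannot be converged
  expect_true(rep_s$grid$converged[length(rep_s$grid$converged)])

  # full drying configuration: time-step ladder is independent below 5 min
  rep_d <- independence_study(ref_setup(), grid_levels = c(3, 31, 61),
                              dt_levels = c(300, 120, 60),
                              probe_time_min = 40)
  expect_false(rep_d$grid$converged[1])
  expect_true(all(rep_d$dt$converged))
})

test_that("raising air temperature or velocity shortens the drying time", {
  t_hh <- drying_time(ref_setup(333.15, 0.5, 11))
  t_lh <- drying_time(ref_setup(323.15, 0.5, 15.7))
  t_hl <- drying_time(ref_setup(333.15, 0.25, 11))
  t_ll <- drying_time(ref_setup(323.15, 0.25, 15.7))
  expect_lt(t_hh, t_lh); expect_lt(t_hl, t_ll)   # temperature effect
  expect_lt(t_hh, t_hl); expect_lt(t_lh, t_ll)   # velocity effect
})

test_that("the pore-equilibrium split also dries, with positive sources", {
  setup <- drying_setup(
    conditions = drying_conditions(air_state(333.15, 0.5, 11), K_vap = 0.05,
                                   t_max_min = 20),
    settings = solver_settings(vapour_split = "pore_equilibrium"))
  state0 <- injeradry:::.init_state(setup)
  state <- march(setup, 10)
  w <- grid_weights(setup$geometry$n_z)
  expect_lt(sum(state$c * w), sum(state0$c * w))
  expect_true(all(state$E >= 0))
})

test_that("the step reports Picard failure instead of silently diverging", {
  setup <- ref_setup(settings = solver_settings(max_iter = 2, tol = 1e-10))
  env <- injeradry:::.sim_env(setup)
  state <- injeradry:::.init_state(setup)
  expect_error(advance(state, setup, env), "Picard")
})

test_that("solver settings validate their inputs", {
  expect_error(solver_settings(darcy = TRUE), "kii")
  expect_error(solver_settings(diffusivity_model = "constant"), "D_const")
  expect_error(solver_settings(surface_model = "dirichlet"), "c_surface")
  expect_error(sample_geometry(n_z = 2))
  expect_error(drying_conditions(MR_stop = 1.5))
})
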