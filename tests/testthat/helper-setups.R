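# Shared fixtures: quick solver setups and the analytic slab oracle.

# Reference tunnel-dryer setup (packaged defaults) at a given air condition.
ref_setup <- function(T_air = 333.15, u_air = 0.5, RH = 11, ...) {
  drying_setup(conditions = drying_conditions(air_state(T_air, u_air, RH)),
               ...)
}

# Pure-diffusion configuration: constant diffusivity, fixed surface
# concentration, no evaporation, isothermal air. Used for verification
# against the analytic slab solution.
diffusion_setup <- function(D = 1e-9, n_z = 81, dt = 5, thickness = 0.0039,
                            c_surface = 0) {
  drying_setup(
    geometry = sample_geometry(thickness = thickness, n_z = n_z),
    conditions = drying_conditions(air_state(298.15, 0.5, 50), K_vap = 0,
                                   t_max_min = 1e4),
    settings = solver_settings(dt = dt, diffusivity_model = "constant",
                               D_const = D, surface_model = "dirichlet",
                               c_surface = c_surface))
}

# Analytic solution of the slab with one Dirichlet face (z = 0, value cs),
# one insulated face (z = L), uniform initial value c0, constant D:
# the classical Fourier sine series of the half-slab.
slab_series <- function(z, t, L, D, c0, cs = 0, n_terms = 60) {
  vapply(z, function(zz) {
    n <- 0:(n_terms - 1)
    lam <- (2 * n + 1) * pi / (2 * L)
    s <- sum(4 / ((2 * n + 1) * pi) * sin(lam * zz) * exp(-D * lam^2 * t))
    cs + (c0 - cs) * s
  }, numeric(1))
}

# March a setup for a fixed number of steps, returning the final state.
march <- function(setup, n_steps) {
  env <- injeradry:::.sim_env(setup)
  state <- injeradry:::.init_state(setup)
  for (i in seq_len(n_steps)) state <- advance(state, setup, env)
  state
}

# Volume weights of the through-thickness grid.
grid_weights <- function(n) {
  w <- rep(1, n)
  w[c(1, n)] <- 0.5
  w
}

# A constant-coefficient component table for hand-checkable mixtures.
constant_property_table <- function(rho = NULL, cp = NULL, k = NULL) {
  comps <- c("water", "carbohydrate", "protein", "fat", "fiber", "ash")
  mk <- function(property, vals) {
    data.frame(component = comps, property = property, a0 = vals, a1 = 0,
               a2 = 0, t_min_c = -50, t_max_c = 200)
  }
  rbind(
    mk("density", if (is.null(rho)) rep(1000, 6) else rho),
    mk("specific_heat", if (is.null(cp)) rep(4000, 6) else cp),
    mk("conductivity", if (is.null(k)) rep(0.5, 6) else k)
  )
}
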