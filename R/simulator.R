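#' Sample geometry
#'
#' Slab geometry of the drying sample and its through-thickness grid. The
#' default thickness is 3.9 mm, the scale of the flatbread itself (the
#' methods vignette discusses the reconciliation of the nominal sample
#' dimensions with the recorded ~100 g sample mass and with the latent
#' heat budget of the drying run).
#'
#' @param thickness Sample thickness (m).
#' @param diameter Sample diameter (m).
#' @param mode Grid mode; only `"1D"` (through-thickness) is currently
#'   solved.
#' @param n_z Number of through-thickness nodes (>= 3).
#' @return A `sample_geometry` list.
#' @export
sample_geometry <- function(thickness = 0.0039, diameter = 0.30,
                            mode = "1D", n_z = 61) {
  stopifnot(thickness > 0, diameter > 0, n_z >= 3)
  mode <- match.arg(mode, c("1D"))
  structure(list(thickness = thickness, diameter = diameter, mode = mode,
                 n_z = as.integer(n_z)), class = "sample_geometry")
}

#' Drying conditions
#'
#' The external air state plus the evaporation rate constant and the run
#' termination targets.
#'
#' @param air An [air_state()].
#' @param K_vap Evaporation rate constant (1/s), > 0 (or exactly 0 to
#'   switch the volumetric source off).
#' @param MR_stop Target volume-averaged moisture ratio at which the run
#'   stops (default 0.03).
#' @param t_max_min Maximum simulated time (minutes).
#' @return A `drying_conditions` list.
#' @export
drying_conditions <- function(air = air_state(333.15, 0.5, 11),
                              K_vap = default_constants()$K_vap,
                              MR_stop = 0.03, t_max_min = 600) {
  stopifnot(K_vap >= 0, MR_stop > 0, MR_stop < 1, t_max_min > 0)
  structure(list(air = air, K_vap = K_vap, MR_stop = MR_stop,
                 t_max_min = t_max_min), class = "drying_conditions")
}

#' Solver settings
#'
#' Numerical controls of the finite-volume solver. Time stepping is
#' backward-Euler (L-stable) on the diffusion and conduction operators and
#' trapezoidal (Crank-Nicolson) on the evaporation source and boundary
#' fluxes, with Picard iteration over the property nonlinearity.
#'
#' @param dt Time step (s).
#' @param tol Relative Picard tolerance.
#' @param max_iter Maximum Picard iterations per step.
#' @param relax Picard under-relaxation factor in (0, 1].
#' @param mixture_rule Effective-property rule, `"as_printed"` or
#'   `"corrected"` (see [effective_thermal_props()]).
#' @param vapour_split Vapour concentration entering the evaporation
#'   source: `"total"` (the as-printed reading, the moisture field itself)
#'   or `"pore_equilibrium"` (gas-share equilibrium vapour).
#' @param surface_model Surface moisture boundary condition: `"vle"`
#'   (surface vapour at local vapour-liquid equilibrium,
#'   `Cs = aw * cv_sat(Ts)`), `"robin_c"` (Robin condition directly on the
#'   moisture field, `flux = hm (c_s - C_a)`) or `"dirichlet"` (fixed
#'   surface concentration `c_surface`, for verification).
#' @param bottom_boundary `"insulated"` (sample on a mesh tray, default) or
#'   `"convective"` for the thermal bottom face.
#' @param darcy Logical; include Darcy advection (requires `kii` and
#'   `grad_p`). Off by default: no internal pressure equation is posed.
#' @param kii Intrinsic permeability (m^2), used only when `darcy = TRUE`.
#' @param grad_p Pressure gradient (Pa/m), used only when `darcy = TRUE`.
#' @param diffusivity_model `"state"` (saturation-dependent effective gas
#'   diffusivity) or `"constant"` (fixed `D_const`, for verification).
#' @param D_const Constant diffusivity (m^2/s) for
#'   `diffusivity_model = "constant"`.
#' @param c_surface Fixed surface concentration for
#'   `surface_model = "dirichlet"`.
#' @param char_length Characteristic length for the transfer correlations
#'   (m); defaults to the flow-aligned sample diameter.
#' @return A `solver_settings` list.
#' @export
solver_settings <- function(dt = 60, tol = 1e-6, max_iter = 200, relax = 0.5,
                            mixture_rule = "as_printed",
                            vapour_split = "total",
                            surface_model = "vle",
                            bottom_boundary = "insulated",
                            darcy = FALSE, kii = NA_real_, grad_p = 0,
                            diffusivity_model = "state", D_const = NA_real_,
                            c_surface = NA_real_, char_length = 0.3) {
  stopifnot(dt > 0, tol > 0, max_iter >= 1, relax > 0, relax <= 1)
  mixture_rule <- match.arg(mixture_rule, c("as_printed", "corrected"))
  vapour_split <- match.arg(vapour_split, c("total", "pore_equilibrium"))
  surface_model <- match.arg(surface_model, c("vle", "robin_c", "dirichlet"))
  bottom_boundary <- match.arg(bottom_boundary, c("insulated", "convective"))
  diffusivity_model <- match.arg(diffusivity_model, c("state", "constant"))
  if (darcy && (!is.finite(kii) || kii <= 0)) {
    stop("darcy = TRUE requires a positive intrinsic permeability `kii`",
         call. = FALSE)
  }
  if (diffusivity_model == "constant" && !is.finite(D_const)) {
    stop("diffusivity_model = 'constant' requires `D_const`", call. = FALSE)
  }
  if (surface_model == "dirichlet" && !is.finite(c_surface)) {
    stop("surface_model = 'dirichlet' requires `c_surface`", call. = FALSE)
  }
  structure(list(dt = dt, tol = tol, max_iter = max_iter, relax = relax,
                 mixture_rule = mixture_rule, vapour_split = vapour_split,
                 surface_model = surface_model,
                 bottom_boundary = bottom_boundary, darcy = darcy, kii = kii,
                 grad_p = grad_p, diffusivity_model = diffusivity_model,
                 D_const = D_const, c_surface = c_surface,
                 char_length = char_length),
            class = "solver_settings")
}

#' Full simulation setup
#'
#' Bundles composition, geometry, conditions and solver settings.
#'
#' @param comp A [composition()].
#' @param geometry A [sample_geometry()].
#' @param conditions A [drying_conditions()].
#' @param settings A [solver_settings()].
#' @param constants See [default_constants()].
#' @param fluids See [default_fluid_properties()].
#' @return A `drying_setup` list.
#' @export
drying_setup <- function(comp = default_composition(),
                         geometry = sample_geometry(),
                         conditions = drying_conditions(),
                         settings = solver_settings(),
                         constants = default_constants(),
                         fluids = default_fluid_properties()) {
  structure(list(comp = comp, geometry = geometry, conditions = conditions,
                 settings = settings, constants = constants, fluids = fluids),
            class = "drying_setup")
}

# ---------------------------------------------------------------------------
# fast vectorised property evaluation over the grid
# ---------------------------------------------------------------------------

# Precompute everything that does not change between steps.
.sim_env <- function(setup) {
  models <- .component_models()
  coef_of <- function(property) {
    m <- models[models$property == property, ]
    m <- m[match(.composition_components, m$component), ]
    as.matrix(m[, c("a0", "a1", "a2")])
  }
  x <- unclass(setup$comp)
  list(
    rho_coef = coef_of("density"),
    cp_coef = coef_of("specific_heat"),
    k_coef = coef_of("conductivity"),
    dry = x[-1] / sum(x[-1]),
    constants = setup$constants,
    fluids = setup$fluids,
    settings = setup$settings,
    geometry = setup$geometry,
    conditions = setup$conditions
  )
}

# polynomial evaluation: T (K) vector -> N x 6 matrix of component values
.poly_eval <- function(coefs, T) {
  t <- T - 273.15
  outer(rep(1, length(T)), coefs[, 1]) +
    outer(t, coefs[, 2]) + outer(t^2, coefs[, 3])
}

# Vectorised nodal property evaluation; mirrors property_bundle().
.props_grid <- function(cc, T, env) {
  cc <- pmax(cc, 0)
  pc <- physical_constants()
  eps <- env$constants$epsilon
  fl <- env$fluids
  rho_i <- .poly_eval(env$rho_coef, T)     # N x 6, order of components
  cp_i <- .poly_eval(env$cp_coef, T)
  k_i <- .poly_eval(env$k_coef, T)

  # local composition: fixed dry-matter ratios, water fraction from Xdb
  xw <- rep(0.6, length(T))  # initial guess for the fixed point
  for (it in 1:30) {
    xmat <- cbind(xw, outer(1 - xw, env$dry))
    rho_p <- 1 / rowSums(xmat / rho_i)
    Xdb <- cc * pc$Mw / ((1 - eps) * rho_p)
    xw_new <- Xdb / (1 + Xdb)
    done <- max(abs(xw_new - xw)) < 1e-13
    xw <- xw_new
    if (done) break
  }
  xmat <- cbind(xw, outer(1 - xw, env$dry))
  rho_p <- 1 / rowSums(xmat / rho_i)
  cp_p <- rowSums(xmat * cp_i)
  vfrac <- (xmat / rho_i) / rowSums(xmat / rho_i)
  k_p <- rowSums(vfrac * k_i)

  Xdb <- cc * pc$Mw / ((1 - eps) * rho_p)
  Sw <- pmin(pmax(pc$Mw * cc / (eps * fl$rho_w), 0), 1)
  Sg <- 1 - Sw
  sat <- saturation_state(T)
  aw <- water_activity(pmax(Xdb, 1e-9))
  Xv <- Sg * fl$rho_a / (Sg * fl$rho_a + Sw * fl$rho_w)
  k_f <- fl$k_w - (fl$k_w - fl$k_a) * Xv
  rho_f <- fl$rho_w - (fl$rho_w - fl$rho_a) * Xv
  Cp_f <- fl$cp_w - (fl$cp_w - fl$cp_a) * Xv
  if (env$settings$mixture_rule == "as_printed") {
    k_eff <- eps * k_p + (1 - eps) * k_f
    rhoCp_eff <- rho_p * cp_p - (1 - eps) * rho_f * Cp_f
  } else {
    k_eff <- (1 - eps) * k_p + eps * k_f
    rhoCp_eff <- (1 - eps) * rho_p * cp_p + eps * rho_f * Cp_f
  }
  if (env$settings$diffusivity_model == "constant") {
    D <- rep(env$settings$D_const, length(T))
  } else {
    D <- env$constants$Dva * eps^0.75 * Sg^(10 / 3)
  }
  list(rho_p = rho_p, cp_p = cp_p, k_p = k_p, Xdb = Xdb, Sw = Sw, Sg = Sg,
       aw = aw, cv_sat = sat$cv_sat, D = D, k_eff = k_eff,
       rhoCp_eff = rhoCp_eff)
}

# Thomas algorithm for tridiagonal systems
.thomas <- function(a, b, d, r) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- d[1] / b[1]; dp[1] <- r[1] / b[1]
  if (n > 1) {
    for (i in 2:n) {
      m <- b[i] - a[i] * cp[i - 1]
      cp[i] <- d[i] / m
      dp[i] <- (r[i] - a[i] * dp[i - 1]) / m
    }
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Non-equilibrium evaporation source terms
#'
#' Per-node moisture and heat sources of the drying model. The evaporation
#' rate `E >= 0` (mol/(m^3 s), clamped from below: no condensation) follows
#' one of two rate laws:
#' \describe{
#'   \item{`"total"`}{the as-printed relaxation of the moisture field
#'     toward its equilibrium vapour value,
#'     `E = K_vap * (c - aw * cv_sat)`, giving first-order falling-rate
#'     kinetics while `c` greatly exceeds `aw * cv_sat`;}
#'   \item{`"pore_equilibrium"`}{the non-equilibrium vapour-generation form
#'     `E = K_vap * (aw * cv_sat - c_v)` with the pore vapour share
#'     `c_v = eps * Sg * aw * cv_sat`.}
#' }
#' The moisture source applied to the field is `Sm = -E` (a sink while
#' drying; the evaporated moles leave the domain through the run's source
#' bookkeeping) and the heat source is `Sh = -Hevap * Mv * E`
#' (evaporation cools). Both vanish at vapour-liquid equilibrium.
#'
#' @param c Nodal moisture concentrations (mol/m^3).
#' @param T Nodal temperatures (K; accepted for interface symmetry, the
#'   temperature dependence enters through `cv_sat`).
#' @param K_vap Evaporation rate constant (1/s).
#' @param aw Nodal water activities.
#' @param cv_sat Nodal saturation vapour concentrations (mol/m^3).
#' @param Sg Nodal gas saturations (for the pore split).
#' @param eps Porosity.
#' @param Hevap Latent heat (J/kg).
#' @param vapour_split `"total"` or `"pore_equilibrium"`.
#' @return List with `Sm` (mol/(m^3 s)), `Sh` (W/m^3) and the evaporation
#'   rate `E` (mol/(m^3 s), >= 0).
#' @export
evaporation_sources <- function(c, T, K_vap, aw, cv_sat, Sg, eps, Hevap,
                                vapour_split = "total") {
  Mv <- physical_constants()$Mv
  s_eq <- aw * cv_sat
  if (vapour_split == "total") {
    E <- pmax(K_vap * (c - s_eq), 0)
  } else {
    c_v <- eps * Sg * s_eq
    E <- pmax(K_vap * (s_eq - c_v), 0)
  }
  list(Sm = -E, Sh = -Hevap * Mv * E, E = E)
}

#' Darcy pore velocity
#'
#' `u_i = (kii * kir / mu) * grad_p`; identically zero when the Darcy flag
#' is off (the default; no internal pressure equation is posed).
#'
#' @param grad_p Pressure gradient (Pa/m).
#' @param kii Intrinsic permeability (m^2).
#' @param kir Relative permeability in \[0, 1\].
#' @param mu Fluid viscosity (Pa s).
#' @param darcy_on Logical flag.
#' @return Velocity (m/s).
#' @export
darcy_velocity <- function(grad_p, kii, kir, mu, darcy_on = TRUE) {
  if (!darcy_on) return(grad_p * 0)
  if (!is.finite(kii) || kii <= 0) {
    stop("Darcy advection requires a positive intrinsic permeability",
         call. = FALSE)
  }
  kii * kir / mu * grad_p
}

# initial field state with source bookkeeping attributes
.init_state <- function(setup) {
  n <- setup$geometry$n_z
  env <- .sim_env(setup)
  cc <- rep(setup$constants$c0, n)
  T <- rep(setup$constants$T0, n)
  pr <- .props_grid(cc, T, env)
  src <- evaporation_sources(cc, T, setup$conditions$K_vap, pr$aw, pr$cv_sat,
                             pr$Sg, setup$constants$epsilon,
                             setup$constants$Hevap,
                             setup$settings$vapour_split)
  q <- .surface_flux(cc, T, pr, env)
  list(t = 0, c = cc, T = T, E = src$E, q = q)
}

# surface evaporative molar flux (mol/m^2/s, positive out) at the top face
.surface_flux <- function(cc, T, pr, env) {
  st <- env$settings
  air <- env$conditions$air
  tc <- transfer_coefficients(air, pr$k_eff[1], st$char_length)
  Ca <- far_field_vapour(air)
  if (st$surface_model == "vle") {
    q <- tc$hm * (pr$aw[1] * pr$cv_sat[1] - Ca)
  } else if (st$surface_model == "robin_c") {
    q <- tc$hm * (cc[1] - Ca)
  } else {
    q <- 0 # dirichlet handled in the linear system
  }
  max(q, 0)
}

#' Advance the coupled fields by one time step
#'
#' One implicit step of the coupled moisture-energy system on the
#' through-thickness grid: backward-Euler on the diffusion and conduction
#' operators (harmonic face averaging), trapezoidal treatment of the
#' evaporation source and boundary fluxes, Picard iteration over the
#' property nonlinearity. The top face exchanges heat
#' (`-k dT/dn = hT (Ts - Ta)` plus the surface-evaporation latent load) and
#' moisture (`-D dc/dn = hm (Cs - Ca)`); the bottom face is insulated by
#' default.
#'
#' @param state List with `t` (s), `c`, `T` (nodal vectors) and the source
#'   bookkeeping `E`, `q` from the previous step (see the value).
#' @param setup A [drying_setup()].
#' @param env Internal precomputed environment; leave `NULL`.
#' @return The advanced state, with elements `t`, `c`, `T`, `E` (nodal
#'   evaporation rate), `q` (surface flux), `evaporated` and `boundary`
#'   (mol/m^2 removed during this step through each channel), `picard`
#'   (iterations used).
#' @export
advance <- function(state, setup, env = NULL) {
  if (is.null(env)) env <- .sim_env(setup)
  st <- env$settings
  geo <- env$geometry
  cond <- env$conditions
  cons <- env$constants
  pc <- physical_constants()
  n <- geo$n_z
  dz <- geo$thickness / (n - 1)
  w <- rep(dz, n); w[c(1, n)] <- dz / 2
  dt <- st$dt
  Kv <- cond$K_vap
  air <- cond$air
  Ca <- far_field_vapour(air)

  c_old <- state$c; T_old <- state$T
  E_old <- state$E; q_old <- state$q
  c_it <- c_old; T_it <- T_old

  # constant Darcy advection velocity (optional, upwind)
  u_d <- 0
  if (st$darcy) {
    pr0 <- .props_grid(c_it, T_it, env)
    kr <- permeabilities(pr0$Sw[1], irreducible_saturation(cons$epsilon,
                                                           cons$T0))
    u_d <- darcy_velocity(st$grad_p, st$kii, kr$kwr, env$fluids$mu_w, TRUE)
  }

  converged <- FALSE
  q_new <- q_old
  for (iter in seq_len(st$max_iter)) {
    pr <- .props_grid(c_it, T_it, env)
    s_eq <- pr$aw * pr$cv_sat
    tc <- transfer_coefficients(air, pr$k_eff[1], st$char_length)

    Dn <- pmax(pr$D, 1e-12)
    Df <- 2 * Dn[-n] * Dn[-1] / (Dn[-n] + Dn[-1])   # face harmonic means
    g <- Df / dz                                    # face conductances

    # active evaporation (no condensation): freeze rate where c below eq.
    if (st$vapour_split == "total") {
      kv_node <- ifelse(c_it > s_eq, Kv, 0)
      E_exp <- NULL
    } else {
      # pore_equilibrium: E = Kv * (s_eq - eps*Sg*s_eq), explicit in c
      kv_node <- rep(0, n)
      E_exp <- pmax(Kv * s_eq * (1 - cons$epsilon * pr$Sg), 0)
    }

    a <- numeric(n); b <- numeric(n); d <- numeric(n); r <- numeric(n)
    b <- w / dt
    r <- w / dt * c_old - 0.5 * E_old * w
    a[2:n] <- a[2:n] - g
    d[1:(n - 1)] <- d[1:(n - 1)] - g
    b[1:(n - 1)] <- b[1:(n - 1)] + g
    b[2:n] <- b[2:n] + g
    if (st$vapour_split == "total") {
      b <- b + 0.5 * kv_node * w
      r <- r + 0.5 * kv_node * s_eq * w
    } else {
      r <- r - 0.5 * E_exp * w
    }
    if (u_d != 0) { # first-order upwind advection, explicit
      adv <- u_d * c(0, diff(c_it)) / dz
      r <- r - adv * w
    }

    if (st$surface_model == "vle") {
      # linearize q = hm (aw(c1) cv_sat - Ca) around the current iterate:
      # the aw(c1) feedback is the stiff surface nonlinearity
      q_star <- max(tc$hm * (s_eq[1] - Ca), 0)
      J <- 0
      if (q_star > 0) {
        X1 <- max(pr$Xdb[1], 1e-9)
        gp <- 0.0267 * 1.656 * X1^(-2.656) +
          0.0107 * exp(-1.287 * X1) *
            (1.51 * X1^0.51 - 1.287 * X1^1.51)
        dX_dc <- pc$Mw / ((1 - cons$epsilon) * pr$rho_p[1])
        J <- max(tc$hm * pr$cv_sat[1] * pr$aw[1] * gp * dX_dc, 0)
      }
      b[1] <- b[1] + 0.5 * J
      r[1] <- r[1] - 0.5 * q_old - 0.5 * (q_star - J * c_it[1])
    } else if (st$surface_model == "robin_c") {
      b[1] <- b[1] + 0.5 * tc$hm
      r[1] <- r[1] + 0.5 * tc$hm * Ca - 0.5 * q_old
    } else { # dirichlet
      b[1] <- 1; d[1] <- 0; r[1] <- st$c_surface; a[1] <- 0
    }
    c_new <- .thomas(a, b, d, r)

    # consistent new-time evaporation rate for the energy equation
    if (st$vapour_split == "total") {
      E_new <- kv_node * pmax(c_new - s_eq, 0)
    } else {
      E_new <- E_exp
    }
    E_bar <- 0.5 * (E_old + E_new)
    if (st$surface_model == "vle") {
      q_new <- max(tc$hm * (s_eq[1] - Ca), 0)
    } else if (st$surface_model == "robin_c") {
      q_new <- tc$hm * (c_new[1] - Ca)
    } else q_new <- 0
    q_bar <- 0.5 * (q_old + q_new)

    # energy step (backward Euler, conduction + latent sinks)
    kf <- 2 * pr$k_eff[-n] * pr$k_eff[-1] / (pr$k_eff[-n] + pr$k_eff[-1])
    gk <- kf / dz
    aT <- numeric(n); bT <- numeric(n); dT <- numeric(n); rT <- numeric(n)
    cap <- pr$rhoCp_eff * w / dt
    bT <- cap
    rT <- cap * T_old - cons$Hevap * pc$Mv * E_bar * w
    aT[2:n] <- aT[2:n] - gk
    dT[1:(n - 1)] <- dT[1:(n - 1)] - gk
    bT[1:(n - 1)] <- bT[1:(n - 1)] + gk
    bT[2:n] <- bT[2:n] + gk
    bT[1] <- bT[1] + tc$hT
    rT[1] <- rT[1] + tc$hT * air$T_air - cons$Hevap * pc$Mw * q_bar
    if (st$bottom_boundary == "convective") {
      bT[n] <- bT[n] + tc$hT
      rT[n] <- rT[n] + tc$hT * air$T_air
    }
    T_new <- .thomas(aT, bT, dT, rT)

    dc <- max(abs(c_new - c_it)) / max(cons$c0, 1)
    dTv <- max(abs(T_new - T_it)) / 100
    c_it <- st$relax * c_new + (1 - st$relax) * c_it
    T_it <- st$relax * T_new + (1 - st$relax) * T_it
    if (max(dc, dTv) < st$tol) {
      c_it <- c_new; T_it <- T_new
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "Picard iteration did not converge at t = %.1f s (last residual %.3e)",
      state$t + dt, max(dc, dTv)), call. = FALSE)
  }
  if (any(c_it < -1e-9 * cons$c0)) {
    stop("negative moisture concentration after step", call. = FALSE)
  }
  clipped <- any(c_it < 0)
  c_it <- pmax(c_it, 0)

  list(t = state$t + dt, c = c_it, T = T_it, E = E_new, q = q_new,
       evaporated = sum(E_bar * w) * dt, boundary = q_bar * dt,
       picard = iter, clipped = clipped)
}

#' Equilibrium moisture concentration at the air condition
#'
#' Inverts the sorption isotherm at the air water activity `RH/100` and
#' converts the resulting dry-basis content to a concentration. Used as
#' `Me` in the moisture-ratio definition; near zero for dry hot air.
#'
#' @param air An [air_state()].
#' @param comp A [composition()].
#' @param eps Porosity.
#' @return Moisture concentration (mol/m^3).
#' @export
equilibrium_concentration <- function(air, comp = default_composition(),
                                      eps = default_constants()$epsilon) {
  aw_air <- min(max(air$RH / 100, 1e-4), 0.9999)
  Xdb_e <- equilibrium_moisture_db(aw_air)
  rho_p <- mixture_density(comp, air$T_air)
  Xdb_e * (1 - eps) * rho_p / physical_constants()$Mw
}

#' Run a drying simulation
#'
#' Steps the coupled moisture-energy system until the volume-averaged
#' moisture ratio reaches `MR_stop` or `t_max_min` is exceeded. The
#' moisture ratio is `MR = (c_mean - c_e) / (c_0 - c_e)` with `c_e` the
#' equilibrium concentration at the air condition; `MR(0) = 1` by
#' construction.
#'
#' @param setup A [drying_setup()].
#' @return A [drying_curve()] with columns `t_min`, `MR`, `T_center_K`,
#'   `T_mean_K`, `flux_mol_m2_s`; attributes `balance` (moisture closure
#'   report), `truncated` (logical), `drying_time_min` (interpolated time
#'   to `MR_stop`, `NA` if truncated) and `meta`.
#' @export
#' @examples
#' \donttest{
#' setup <- drying_setup(conditions = drying_conditions(
#'   air_state(333.15, 0.5, 11)))
#' curve <- simulate_drying(setup)
#' attr(curve, "drying_time_min")
#' }
simulate_drying <- function(setup) {
  env <- .sim_env(setup)
  geo <- setup$geometry
  n <- geo$n_z
  dz <- geo$thickness / (n - 1)
  w <- rep(dz, n); w[c(1, n)] <- dz / 2
  state <- .init_state(setup)
  c_e <- equilibrium_concentration(setup$conditions$air, setup$comp,
                                   setup$constants$epsilon)
  c0_mean <- sum(state$c * w) / sum(w)
  mr_of <- function(s) (sum(s$c * w) / sum(w) - c_e) / (c0_mean - c_e)

  n_max <- ceiling(setup$conditions$t_max_min * 60 / setup$settings$dt)
  t_min <- numeric(n_max + 1); MR <- numeric(n_max + 1)
  T_c <- numeric(n_max + 1); T_m <- numeric(n_max + 1)
  fx <- numeric(n_max + 1)
  mid <- (n + 1) %/% 2
  t_min[1] <- 0; MR[1] <- 1
  T_c[1] <- state$T[mid]; T_m[1] <- sum(state$T * w) / sum(w)
  fx[1] <- state$q
  evaporated <- 0; boundary <- 0
  k <- 1
  truncated <- TRUE
  while (k <= n_max) {
    state <- advance(state, setup, env)
    k <- k + 1
    t_min[k] <- state$t / 60
    MR[k] <- mr_of(state)
    T_c[k] <- state$T[mid]
    T_m[k] <- sum(state$T * w) / sum(w)
    fx[k] <- state$q
    evaporated <- evaporated + state$evaporated
    boundary <- boundary + state$boundary
    if (MR[k] <= setup$conditions$MR_stop) { truncated <- FALSE; break }
  }
  idx <- seq_len(k)
  removed <- (c0_mean - sum(state$c * w) / sum(w)) * sum(w)
  closure <- if (removed > 0) (evaporated + boundary) / removed else 1
  dt_time <- NA_real_
  if (!truncated) {
    # linear interpolation of the MR_stop crossing
    i <- k
    dt_time <- t_min[i - 1] + (t_min[i] - t_min[i - 1]) *
      (MR[i - 1] - setup$conditions$MR_stop) / (MR[i - 1] - MR[i])
  } else {
    warning("t_max reached before MR_stop; curve truncated", call. = FALSE)
  }
  curve <- drying_curve(
    t = t_min[idx], MR = MR[idx], T_center = T_c[idx],
    meta = list(conditions = setup$conditions, source = "simulated",
                Mo = NA_real_, Me = NA_real_, time_unit = "min"))
  curve$T_mean_K <- T_m[idx]
  curve$flux_mol_m2_s <- fx[idx]
  attr(curve, "balance") <- list(removed_mol_m2 = removed,
                                 evaporated_mol_m2 = evaporated,
                                 boundary_mol_m2 = boundary,
                                 closure = closure)
  attr(curve, "truncated") <- truncated
  attr(curve, "drying_time_min") <- dt_time
  curve
}

#' Drying time to a target moisture ratio
#'
#' @param setup A [drying_setup()].
#' @return Time (minutes) at which the volume-averaged moisture ratio first
#'   reaches `MR_stop` (linearly interpolated), or `NA` if not reached.
#' @export
drying_time <- function(setup) {
  attr(simulate_drying(setup), "drying_time_min")
}

#' Grid and time-step independence study
#'
#' Reruns a setup over ladders of node counts and time steps and probes the
#' moisture ratio at a fixed time. A level is flagged converged when it
#' differs from the next-finer level by less than `threshold` (relative).
#'
#' @param setup A [drying_setup()].
#' @param grid_levels Integer vector of node counts (>= 3 levels
#'   recommended).
#' @param dt_levels Numeric vector of time steps (s).
#' @param probe_time_min Probe time (minutes).
#' @param threshold Relative convergence threshold (default 0.005).
#' @return List of two data.frames (`grid`, `dt`) with the probed MR and a
#'   `converged` flag per level.
#' @export
independence_study <- function(setup, grid_levels = c(9, 17, 33, 61),
                               dt_levels = c(300, 120, 60, 30),
                               probe_time_min = NULL, threshold = 0.005) {
  probe <- function(stp) {
    cv <- simulate_drying(stp)
    tm <- if (is.null(probe_time_min)) max(cv$t_min) * 0.5 else probe_time_min
    stats::approx(cv$t_min, cv$MR, xout = min(tm, max(cv$t_min)))$y
  }
  run_grid <- vapply(grid_levels, function(nz) {
    g <- setup$geometry; g$n_z <- as.integer(nz)
    probe(drying_setup(setup$comp, g, setup$conditions, setup$settings,
                       setup$constants, setup$fluids))
  }, numeric(1))
  run_dt <- vapply(dt_levels, function(dt) {
    s <- setup$settings; s$dt <- dt
    probe(drying_setup(setup$comp, setup$geometry, setup$conditions, s,
                       setup$constants, setup$fluids))
  }, numeric(1))
  flag <- function(v) {
    d <- c(abs(diff(v)) / pmax(abs(v[-1]), 1e-12), NA)
    conv <- d < threshold
    conv[length(v)] <- isTRUE(conv[length(v) - 1])
    conv
  }
  list(
    grid = data.frame(n_z = grid_levels, MR_probe = run_grid,
                      converged = flag(run_grid)),
    dt = data.frame(dt_s = dt_levels, MR_probe = run_dt,
                    converged = flag(run_dt))
  )
}
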