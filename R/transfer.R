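#' Air state at the sample boundary
#'
#' Bundles the drying-air condition (temperature, velocity, relative
#' humidity, pressure) with the constant dry-air properties used by the
#' transfer correlations. Humidity affects only the far-field vapour
#' concentration (`RH/100 * cv_sat(T_air)`), not the dry-air constants.
#'
#' @param T_air Air temperature (K).
#' @param u_air Air velocity (m/s).
#' @param RH Relative humidity (percent, in \[0, 100\]).
#' @param p_atm Ambient pressure (Pa).
#' @param fluids Constant fluid properties, see
#'   [default_fluid_properties()].
#' @return An `air_state` list.
#' @export
#' @examples
#' air_state(333.15, 0.5, 11)
air_state <- function(T_air, u_air, RH, p_atm = 101325,
                      fluids = default_fluid_properties()) {
  stopifnot(T_air > 0, u_air > 0, RH >= 0, RH <= 100, p_atm > 0)
  structure(list(
    T_air = T_air, u_air = u_air, RH = RH, p_atm = p_atm,
    rho_a = fluids$rho_a, mu_a = fluids$mu_a, cp_a = fluids$cp_a,
    k_a = fluids$k_a, D_a = fluids$D_a
  ), class = "air_state")
}

#' Far-field vapour concentration of the drying air
#'
#' `C_a = (RH / 100) * cv_sat(T_air)` (mol/m^3).
#'
#' @param air An [air_state()].
#' @return Vapour concentration (mol/m^3).
#' @export
far_field_vapour <- function(air) {
  air$RH / 100 * saturation_state(air$T_air)$cv_sat
}

#' Reynolds, Prandtl and Schmidt numbers
#'
#' `Re = rho_a u_a L / mu_a`, `Pr = cp_a mu_a / k_a`,
#' `Sc = mu_a / (rho_a D_a)`.
#'
#' @param air An [air_state()].
#' @param L Characteristic length (m); the flow-aligned sample dimension
#'   (the 0.30 m diameter by default).
#' @return List with `Re`, `Pr`, `Sc`.
#' @export
#' @examples
#' dimensionless_numbers(air_state(333.15, 0.5, 11), 0.3)
dimensionless_numbers <- function(air, L) {
  stopifnot(L > 0)
  if (air$mu_a <= 0 || air$D_a <= 0 || air$k_a <= 0) {
    stop("air viscosity, diffusivity and conductivity must be positive",
         call. = FALSE)
  }
  list(Re = air$rho_a * air$u_air * L / air$mu_a,
       Pr = air$cp_a * air$mu_a / air$k_a,
       Sc = air$mu_a / (air$rho_a * air$D_a))
}

#' Convective heat transfer coefficient
#'
#' Flat-plate Nusselt correlation with the effective conductivity of the
#' sample as the scaling conductivity:
#' laminar branch (`Re < 5e5`)
#' `hT = 2 k_eff / L * 0.3387 Re^(1/2) Pr^(1/3) /
#'       (1 + (0.0468/Pr)^(2/3))^(1/3)`;
#' turbulent branch (`Re >= 5e5`)
#' `hT = 2 k_eff / L * Pr^(1/3) (0.037 Re^(4/5) - 871)`.
#' The laminar form is assigned to sub-critical Reynolds numbers (the
#' standard convention); at the tunnel-dryer conditions `Re ~ 1e4` the
#' laminar branch is always taken.
#'
#' @param Re Reynolds number (> 0).
#' @param Pr Prandtl number (> 0).
#' @param k_eff Effective thermal conductivity of the sample (W/(m K)).
#' @param L Characteristic length (m).
#' @return Heat transfer coefficient (W/(m^2 K)).
#' @export
heat_transfer_coefficient <- function(Re, Pr, k_eff, L) {
  stopifnot(Re > 0, Pr > 0, k_eff > 0, L > 0)
  if (Re < 5e5) {
    nu <- 0.3387 * sqrt(Re) * Pr^(1 / 3) / (1 + (0.0468 / Pr)^(2 / 3))^(1 / 3)
  } else {
    nu <- Pr^(1 / 3) * (0.037 * Re^(4 / 5) - 871)
    if (nu <= 0) {
      stop("turbulent-branch correlation produced a non-positive coefficient",
           call. = FALSE)
    }
  }
  2 * k_eff / L * nu
}

#' Convective mass transfer coefficient
#'
#' Sherwood-type correlation
#' `hm = (D_a / L) * (2 + 0.552 Re^(1/2) Sc^(1/3))`, reducing to the
#' stagnant limit `2 D_a / L` as `Re -> 0`.
#'
#' @param Re Reynolds number (> 0).
#' @param Sc Schmidt number (> 0).
#' @param D_a Air-side vapour diffusivity (m^2/s).
#' @param L Characteristic length (m).
#' @return Mass transfer coefficient (m/s).
#' @export
mass_transfer_coefficient <- function(Re, Sc, D_a, L) {
  stopifnot(Re > 0, Sc > 0, D_a > 0, L > 0)
  D_a / L * (2 + 0.552 * sqrt(Re) * Sc^(1 / 3))
}

#' Boundary transfer coefficients for a drying condition
#'
#' Convenience wrapper evaluating [dimensionless_numbers()],
#' [heat_transfer_coefficient()] and [mass_transfer_coefficient()] at one
#' air state.
#'
#' @param air An [air_state()].
#' @param k_eff Effective sample conductivity (W/(m K)).
#' @param L Characteristic length (m).
#' @return List with `Re`, `Pr`, `Sc`, `hT` (W/(m^2 K)), `hm` (m/s), `L`.
#' @export
transfer_coefficients <- function(air, k_eff, L = 0.3) {
  dn <- dimensionless_numbers(air, L)
  list(Re = dn$Re, Pr = dn$Pr, Sc = dn$Sc,
       hT = heat_transfer_coefficient(dn$Re, dn$Pr, k_eff, L),
       hm = mass_transfer_coefficient(dn$Re, dn$Sc, air$D_a, L),
       L = L)
}
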