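#' Physical constants used throughout the package
#'
#' Universal gas constant and the molecular masses of liquid water and water
#' vapour. These are standard values; they are exposed so that every module
#' draws them from one place.
#'
#' @return Named list with elements `R` (J/(mol K)), `Mw` (kg/mol, liquid
#'   water) and `Mv` (kg/mol, water vapour).
#' @export
#' @examples
#' physical_constants()$R
physical_constants <- function() {
  list(R = 8.314, Mw = 0.018, Mv = 0.018)
}

#' Default proximate composition of fresh injera
#'
#' Wet-basis mass fractions (water, carbohydrate, protein, fat, fiber, ash)
#' of the fermented teff flatbread, from proximate analysis. The raw
#' fractions sum slightly above one (independent assays); [composition()]
#' normalises them on construction.
#'
#' @return A `composition` object.
#' @export
default_composition <- function() {
  composition(x_water = 0.608, x_carb = 0.3126, x_protein = 0.0485,
              x_fat = 0.0046, x_fiber = 0.0163, x_ash = 0.0183)
}

#' Default model constants for the drying simulation
#'
#' Constant inputs of the coupled model: water-air and vapour-air binary
#' diffusivities, latent heat of evaporation, sample porosity, initial
#' sample temperature and moisture concentration, and ambient pressure.
#'
#' `c0` is the nominal initial moisture concentration of the moist sample.
#' `K_vap` is the evaporation rate constant of the non-equilibrium source
#' term; it is the one free constant of the model and its default was fixed
#' once by matching the reference drying time at 333.15 K / 0.5 m/s / RH 11%
#' (see [calibrate_kvap()] and the package vignette).
#'
#' @return Named list of constants (SI units).
#' @export
default_constants <- function() {
  list(
    Dwa     = 2.6e-5,    # water-air diffusivity, m^2/s
    Dva     = 2.6e-5,    # vapour-air diffusivity, m^2/s
    Hevap   = 2.454e6,   # latent heat of evaporation, J/kg
    epsilon = 0.74,      # sample porosity, -
    c0      = 49750,     # initial moisture concentration, mol/m^3
    T0      = 298.15,    # initial sample temperature, K
    p_atm   = 101325,    # ambient pressure, Pa
    K_vap   = kvap_default()
  )
}

# Frozen product of the one-point calibration at the reference drying
# condition (see calibrate_kvap). Same order as the first-order rate implied
# by the reported Henderson-Pabis kinetics (0.0189 1/min = 3.15e-4 1/s).
kvap_default <- function() 1.34987015e-4

#' Default dry-air and liquid-water bulk properties
#'
#' Constant fluid properties used for the air-side transfer correlations and
#' for the pore-fluid blends of the effective thermal properties: density,
#' specific heat, conductivity, viscosity and the air-side vapour
#' diffusivity.
#'
#' @return Named list with `rho_a`, `rho_w` (kg/m^3), `cp_a`, `cp_w`
#'   (J/(kg K)), `k_a`, `k_w` (W/(m K)), `mu_a`, `mu_w` (Pa s), `D_a`
#'   (m^2/s).
#' @export
default_fluid_properties <- function() {
  list(
    rho_a = 1.25, rho_w = 998,
    cp_a = 1000, cp_w = 1000,
    k_a = 0.0285, k_w = 0.59,
    mu_a = 1.81e-5, mu_w = 1.002e-3,
    D_a = 2.6e-5
  )
}

# Temperature validity window enforced by the property models (K).
T_RANGE_MIN <- 273.15
T_RANGE_MAX <- 473.15

.check_temperature <- function(T, what = "temperature") {
  if (any(!is.finite(T)) || any(T < T_RANGE_MIN) || any(T > T_RANGE_MAX)) {
    stop(sprintf("%s out of the supported range [%.2f, %.2f] K", what,
                 T_RANGE_MIN, T_RANGE_MAX), call. = FALSE)
  }
  invisible(TRUE)
}
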