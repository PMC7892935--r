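#' Load and validate a run configuration
#'
#' Reads a structured plain-text (YAML) configuration with sections
#' `composition`, `geometry`, `air`, `solver`, `kinetics` and `synthetic`,
#' validates keys and unit suffixes, and fills every missing key with the
#' packaged defaults (proximate composition, tunnel-dryer air conditions,
#' porosity 0.74, and the documented solver settings). An empty file (or
#' `path = NULL`) therefore yields the full default configuration:
#' air at 333.15 K, 0.5 m/s, RH 11%.
#'
#' Keys carry unit suffixes (`_K`, `_m`, `_m_s`, `_pct`, `_min`, `_s`,
#' `_Pa`, `_per_s`); unknown keys and wrong suffixes are rejected with a
#' message naming the key.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A `run_config` list with elements `comp`, `geometry`,
#'   `conditions`, `settings`, `constants`, `fluids`, `kinetics`,
#'   `synthetic`, `schema_version` and `config_hash`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  hash <- "defaults"
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    hash <- unname(tools::md5sum(path))
  }
  known <- list(
    composition = c("x_water", "x_carb", "x_protein", "x_fat", "x_fiber",
                    "x_ash"),
    geometry = c("thickness_m", "diameter_m", "n_z"),
    air = c("T_air_K", "u_air_m_s", "RH_pct", "p_atm_Pa"),
    solver = c("dt_s", "tol", "max_iter", "mixture_rule", "vapour_split",
               "surface_model", "bottom_boundary", "K_vap_per_s",
               "MR_stop", "t_max_min", "epsilon", "c0_mol_m3", "T0_K",
               "char_length_m"),
    kinetics = c("models", "half_thickness_m"),
    synthetic = c("mass_g", "mass_sd_g", "temp_sd_K", "mass_interval_min",
                  "temp_interval_min", "seed")
  )
  bad_sections <- setdiff(names(raw), c(names(known), "schema_version"))
  if (length(bad_sections)) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(known)) {
    extra <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(extra)) {
      stop(sprintf(
        "unknown key(s) in [%s]: %s (expected one of: %s; units by suffix)",
        sec, paste(extra, collapse = ", "),
        paste(known[[sec]], collapse = ", ")), call. = FALSE)
    }
  }
  gv <- function(sec, key, default) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) default else v
  }

  cons <- default_constants()
  cons$epsilon <- gv("solver", "epsilon", cons$epsilon)
  cons$c0 <- gv("solver", "c0_mol_m3", cons$c0)
  cons$T0 <- gv("solver", "T0_K", cons$T0)
  cons$K_vap <- gv("solver", "K_vap_per_s", cons$K_vap)

  comp <- composition(
    x_water = gv("composition", "x_water", 0.608),
    x_carb = gv("composition", "x_carb", 0.3126),
    x_protein = gv("composition", "x_protein", 0.0485),
    x_fat = gv("composition", "x_fat", 0.0046),
    x_fiber = gv("composition", "x_fiber", 0.0163),
    x_ash = gv("composition", "x_ash", 0.0183))

  geometry <- sample_geometry(
    thickness = gv("geometry", "thickness_m", 0.0039),
    diameter = gv("geometry", "diameter_m", 0.30),
    n_z = gv("geometry", "n_z", 61))

  air <- air_state(
    T_air = gv("air", "T_air_K", 333.15),
    u_air = gv("air", "u_air_m_s", 0.5),
    RH = gv("air", "RH_pct", 11),
    p_atm = gv("air", "p_atm_Pa", cons$p_atm))

  conditions <- drying_conditions(
    air = air, K_vap = cons$K_vap,
    MR_stop = gv("solver", "MR_stop", 0.03),
    t_max_min = gv("solver", "t_max_min", 600))

  settings <- solver_settings(
    dt = gv("solver", "dt_s", 60),
    tol = gv("solver", "tol", 1e-6),
    max_iter = gv("solver", "max_iter", 200),
    mixture_rule = gv("solver", "mixture_rule", "as_printed"),
    vapour_split = gv("solver", "vapour_split", "total"),
    surface_model = gv("solver", "surface_model", "vle"),
    bottom_boundary = gv("solver", "bottom_boundary", "insulated"),
    char_length = gv("solver", "char_length_m", 0.3))

  structure(list(
    comp = comp, geometry = geometry, conditions = conditions,
    settings = settings, constants = cons,
    fluids = default_fluid_properties(),
    kinetics = list(
      models = gv("kinetics", "models", names(.kinetics_models())),
      half_thickness_m = gv("kinetics", "half_thickness_m", 0.015)),
    synthetic = list(
      mass_g = gv("synthetic", "mass_g", 100),
      mass_sd_g = gv("synthetic", "mass_sd_g", 0.1),
      temp_sd_K = gv("synthetic", "temp_sd_K", 1.0),
      mass_interval_min = gv("synthetic", "mass_interval_min", 1),
      temp_interval_min = gv("synthetic", "temp_interval_min", 15),
      seed = gv("synthetic", "seed", 1)),
    schema_version = if (is.null(raw$schema_version)) "1.0" else
      raw$schema_version,
    config_hash = hash
  ), class = "run_config")
}

#' Dump a run configuration back to YAML
#'
#' Writes the resolved configuration (every key explicit) so that
#' load -> dump -> load is idempotent.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  x <- unclass(config$comp)
  out <- list(
    schema_version = config$schema_version,
    composition = list(x_water = x[["water"]], x_carb = x[["carbohydrate"]],
                       x_protein = x[["protein"]], x_fat = x[["fat"]],
                       x_fiber = x[["fiber"]], x_ash = x[["ash"]]),
    geometry = list(thickness_m = config$geometry$thickness,
                    diameter_m = config$geometry$diameter,
                    n_z = config$geometry$n_z),
    air = list(T_air_K = config$conditions$air$T_air,
               u_air_m_s = config$conditions$air$u_air,
               RH_pct = config$conditions$air$RH,
               p_atm_Pa = config$conditions$air$p_atm),
    solver = list(dt_s = config$settings$dt, tol = config$settings$tol,
                  max_iter = config$settings$max_iter,
                  mixture_rule = config$settings$mixture_rule,
                  vapour_split = config$settings$vapour_split,
                  surface_model = config$settings$surface_model,
                  bottom_boundary = config$settings$bottom_boundary,
                  K_vap_per_s = config$constants$K_vap,
                  MR_stop = config$conditions$MR_stop,
                  t_max_min = config$conditions$t_max_min,
                  epsilon = config$constants$epsilon,
                  c0_mol_m3 = config$constants$c0,
                  T0_K = config$constants$T0,
                  char_length_m = config$settings$char_length),
    kinetics = config$kinetics,
    synthetic = config$synthetic
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Dump all thermophysical properties at one temperature
#'
#' Evaluates the full property bundle at the configured composition and a
#' given temperature (at the initial moisture concentration) -- the
#' programmatic equivalent of a "properties at temperature" report.
#'
#' @param T Temperature (K).
#' @param config A `run_config` (defaults to the packaged defaults).
#' @return Named list of property values.
#' @export
properties_at_temperature <- function(T, config = load_config()) {
  property_bundle(config$constants$c0, T, comp = config$comp,
                  constants = config$constants, fluids = config$fluids,
                  rule = config$settings$mixture_rule)
}

#' Run the full drying-analysis pipeline
#'
#' Executes simulate -> kinetics fitting and ranking -> effective
#' diffusivity -> report for one configuration, optionally writing the
#' curve (CSV), the fits (JSON) and a run report (JSON, including the
#' moisture balance, the config hash and the solver flags) to an output
#' directory. Stage errors propagate with the stage name prefixed.
#'
#' @param config A `run_config` from [load_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List with `curve`, `fits` (ranked), `Deff_m2_s`,
#'   `drying_time_min`, `report`.
#' @export
pipeline_run <- function(config, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  setup <- drying_setup(config$comp, config$geometry, config$conditions,
                        config$settings, config$constants, config$fluids)
  curve <- stage("simulate", simulate_drying(setup))
  fits <- stage("fit-kinetics", rank_models(curve, config$kinetics$models))
  deff <- stage("deff", effective_diffusivity_slope(
    curve, config$kinetics$half_thickness_m))
  report <- list(
    config_hash = config$config_hash,
    schema_version = config$schema_version,
    flags = list(mixture_rule = config$settings$mixture_rule,
                 vapour_split = config$settings$vapour_split,
                 surface_model = config$settings$surface_model,
                 bottom_boundary = config$settings$bottom_boundary),
    drying_time_min = attr(curve, "drying_time_min"),
    truncated = attr(curve, "truncated"),
    balance = attr(curve, "balance"),
    best_model = fits[[1]]$model,
    Deff_m2_s = deff
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(as.data.frame(curve),
                           config_hash = config$config_hash),
                     file.path(out_dir, "curve.csv"), row.names = FALSE)
    fit_dump <- lapply(fits, function(f) {
      list(model = f$model, constants = as.list(f$constants), R2 = f$R2,
           RMSE = f$RMSE, n_obs = f$n_obs)
    })
    jsonlite::write_json(list(config_hash = config$config_hash,
                              fits = fit_dump),
                         file.path(out_dir, "fits.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(curve = curve, fits = fits, Deff_m2_s = deff,
       drying_time_min = attr(curve, "drying_time_min"), report = report)
}
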