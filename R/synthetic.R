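#' Specification of a pseudo-experimental tunnel-dryer run
#'
#' Describes the measurement structure of the tunnel-dryer experiment: a
#' ~100 g sample on a balance with a continuous mass record (default every
#' minute), centre temperature sampled every 15 min by a thermocouple of
#' +/- 1 K accuracy, at a given air condition.
#'
#' @param air An [air_state()].
#' @param mass_g Initial sample mass (g).
#' @param Mwb0 Initial wet-basis moisture content (kg/kg).
#' @param mass_interval_min Mass record interval (minutes).
#' @param temp_interval_min Temperature record interval (minutes).
#' @param mass_sd_g Balance noise SD (g); default 0.1 (balance-grade).
#' @param temp_sd_K Thermocouple noise SD (K); default 1.0.
#' @param duration_min Record duration (minutes); `NULL` to follow the
#'   truth curve's extent.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(air = air_state(333.15, 0.5, 11), mass_g = 100,
                            Mwb0 = 0.608, mass_interval_min = 1,
                            temp_interval_min = 15, mass_sd_g = 0.1,
                            temp_sd_K = 1.0, duration_min = NULL) {
  stopifnot(mass_g > 0, Mwb0 > 0, Mwb0 < 1, mass_interval_min > 0,
            temp_interval_min > 0, mass_sd_g >= 0, temp_sd_K >= 0)
  structure(list(air = air, mass_g = mass_g, Mwb0 = Mwb0,
                 mass_interval_min = mass_interval_min,
                 temp_interval_min = temp_interval_min,
                 mass_sd_g = mass_sd_g, temp_sd_K = temp_sd_K,
                 duration_min = duration_min), class = "experiment_spec")
}

#' Closed-form kinetics truth model
#'
#' A truth curve defined by one of the thin-layer models, for generator
#' runs that do not need the PDE simulator.
#'
#' @param model Model name, see [fit_kinetics()].
#' @param constants Named constants of the model (rates per minute,
#'   negative for decay).
#' @return A function `MR(t_min)`.
#' @export
kinetics_truth <- function(model = "henderson_pabis",
                           constants = c(alpha = 1, rate = -0.0189)) {
  spec <- .kinetics_models()[[model]]
  if (is.null(spec)) stop("unknown kinetics model", call. = FALSE)
  function(t) spec$predict(t, as.list(constants))
}

#' Generate a pseudo-experimental drying dataset
#'
#' Samples a truth moisture-ratio curve (either a [simulate_drying()] run
#' or a closed-form kinetics model) at the spec's record intervals and adds
#' seeded Gaussian measurement noise: balance noise on the mass record and
#' thermocouple noise on the centre temperature. Masses never go below the
#' dry mass; with zero noise SDs the output equals the truth at the sample
#' times exactly.
#'
#' @param spec An [experiment_spec()].
#' @param truth Either a [drying_curve()] (e.g. from [simulate_drying()])
#'   or a function `MR(t_min)` (e.g. from [kinetics_truth()]).
#' @param seed Integer seed; the output is a deterministic function of
#'   (spec, truth, seed).
#' @return List with `raw` (data.frame `t_min`, `mass_g`, `T_center_K` --
#'   the temperature column is `NA` between thermocouple readings) and
#'   `curve` (a [drying_curve()] derived from the noisy masses via
#'   [moisture_ratio_series()]).
#' @export
#' @examples
#' gen <- generate_experiment(experiment_spec(duration_min = 120),
#'                            kinetics_truth(), seed = 42)
#' head(gen$raw)
generate_experiment <- function(spec, truth, seed = 1) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (inherits(truth, "drying_curve")) {
    tmax <- if (is.null(spec$duration_min)) max(truth$t_min) else
      spec$duration_min
    mr_fun <- function(t) {
      stats::approx(truth$t_min, truth$MR, xout = t, rule = 2)$y
    }
    tc_fun <- if ("T_center_K" %in% names(truth)) {
      function(t) stats::approx(truth$t_min, truth$T_center_K, xout = t,
                                rule = 2)$y
    } else function(t) rep(NA_real_, length(t))
  } else if (is.function(truth)) {
    if (is.null(spec$duration_min)) {
      stop("duration_min required with a closed-form truth model",
           call. = FALSE)
    }
    tmax <- spec$duration_min
    mr_fun <- truth
    tc_fun <- function(t) rep(NA_real_, length(t))
  } else {
    stop("truth must be a drying_curve or a function of time",
         call. = FALSE)
  }
  t <- seq(0, tmax, by = spec$mass_interval_min)
  m_water0 <- spec$mass_g * spec$Mwb0
  m_dry <- spec$mass_g - m_water0
  mr_true <- pmin(pmax(mr_fun(t), 0), 1)
  mass_true <- m_dry + m_water0 * mr_true

  set.seed(as.integer(seed))
  mass <- pmax(mass_true + stats::rnorm(length(t), 0, spec$mass_sd_g), m_dry)
  mass[1] <- max(mass[1], m_dry + 1e-9)
  t_temp <- seq(0, tmax, by = spec$temp_interval_min)
  T_read <- tc_fun(t_temp) + stats::rnorm(length(t_temp), 0, spec$temp_sd_K)

  raw <- data.frame(t_min = t, mass_g = mass, T_center_K = NA_real_)
  idx <- match(round(t_temp, 9), round(t, 9))
  raw$T_center_K[idx[!is.na(idx)]] <- T_read[!is.na(idx)]

  curve <- moisture_ratio_series(
    t, pmin(mass, m_dry + 1.05 * m_water0), Mo = mass[1], Me = m_dry,
    meta = list(conditions = spec$air, source = "synthetic", seed = seed))
  list(raw = raw, curve = curve)
}

#' Generate a balanced factorial table of drying rates
#'
#' Emulates a 2x2 (or larger) air-temperature x air-velocity factorial
#' drying study with replicates: per-cell true drying rates (either
#' supplied or built from additive factor effects) plus seeded Gaussian
#' replicate noise. The output feeds [anova_two_way()].
#'
#' @param T_levels Air temperatures (K).
#' @param u_levels Air velocities (m/s).
#' @param replicates Replicates per cell (>= 2).
#' @param base_rate Baseline drying rate (1/min).
#' @param T_effect Additive rate increment per temperature level step.
#' @param u_effect Additive rate increment per velocity level step.
#' @param interaction Additive increment applied to the highest (T, u)
#'   cell combination product (scaled by level indices).
#' @param noise_sd Replicate noise SD (1/min).
#' @param seed Integer seed.
#' @param cell_rates Optional matrix (length(T_levels) x length(u_levels))
#'   of true cell means overriding the additive construction.
#' @return Data frame with columns `T_air`, `u_air`, `replicate`, `rate`.
#' @export
generate_factorial <- function(T_levels = c(323.15, 333.15),
                               u_levels = c(0.25, 0.5), replicates = 3,
                               base_rate = 0.015, T_effect = 0.004,
                               u_effect = 0.002, interaction = 0,
                               noise_sd = 0.001, seed = 1,
                               cell_rates = NULL) {
  stopifnot(replicates >= 2, noise_sd >= 0)
  a <- length(T_levels); b <- length(u_levels)
  if (is.null(cell_rates)) {
    cell_rates <- outer(seq_len(a) - 1, seq_len(b) - 1, function(i, j) {
      base_rate + T_effect * i + u_effect * j + interaction * i * j
    })
  }
  stopifnot(all(dim(cell_rates) == c(a, b)))
  grid <- expand.grid(ti = seq_len(a), ui = seq_len(b),
                      replicate = seq_len(replicates))
  set.seed(as.integer(seed))
  rate <- cell_rates[cbind(grid$ti, grid$ui)] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  data.frame(T_air = T_levels[grid$ti], u_air = u_levels[grid$ui],
             replicate = grid$replicate, rate = rate)
}
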