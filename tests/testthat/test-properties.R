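test_that("mixture density matches the harmonic-mean oracle", {
  # hand-checkable constants
  tab <- constant_property_table(rho = c(998, 2000, 1300, 900, 1300, 2400))
  comp1 <- composition(1, 0, 0, 0, 0, 0)
  expect_equal(mixture_density(comp1, 300, tab), 998)
  comp2 <- composition(0.5, 0.5, 0, 0, 0, 0)
  tab2 <- constant_property_table(rho = c(1000, 2000, 1, 1, 1, 1))
  expect_equal(mixture_density(comp2, 300, tab2),
               1 / (0.5 / 1000 + 0.5 / 2000), tolerance = 1e-12)

  # term-by-term oracle over random compositions with the shipped models
  set.seed(11)
  models <- component_property_models()
  for (i in 1:100) {
    x <- stats::runif(6)
    x <- x / sum(x)
    comp <- composition(x[1], x[2], x[3], x[4], x[5], x[6])
    T <- stats::runif(1, 293.15, 353.15)
    rho_i <- vapply(
      c("water", "carbohydrate", "protein", "fat", "fiber", "ash"),
      component_property, numeric(1), property = "density", T = T)
    expect_equal(mixture_density(comp, T), 1 / sum(unclass(comp) / rho_i),
                 tolerance = 1e-12)
  }
})

test_that("mixture density reproduces the reported fresh-sample value", {
  rho <- mixture_density(default_composition(), 323.15)
  expect_lt(abs(rho - 1136.49) / 1136.49, 0.02)
  # density decreases with temperature over the drying range
  expect_gt(rho, mixture_density(default_composition(), 333.15))
})

test_that("mixture specific heat is the mass-weighted mean and is bounded", {
  tab <- constant_property_table(cp = c(4180, 1600, 1, 1, 1, 1))
  comp <- composition(0.6, 0.4, 0, 0, 0, 0)
  expect_equal(mixture_specific_heat(comp, 300, tab), 3148)
  tab1 <- constant_property_table(cp = c(4180, 1, 1, 1, 1, 1))
  expect_equal(mixture_specific_heat(composition(1, 0, 0, 0, 0, 0), 300,
                                     tab1), 4180)
  cp_i <- vapply(c("water", "carbohydrate", "protein", "fat", "fiber",
                   "ash"), component_property, numeric(1),
                 property = "specific_heat", T = 323.15)
  cp <- mixture_specific_heat(default_composition(), 323.15)
  expect_gte(cp, min(cp_i)); expect_lte(cp, max(cp_i))
})

test_that("conductivity uses volume fractions that sum to one", {
  # equal densities: volume = mass fractions
  tab <- constant_property_table(rho = rep(1000, 6),
                                 k = c(0.6, 0.2, 1, 1, 1, 1))
  comp <- composition(0.5, 0.5, 0, 0, 0, 0)
  expect_equal(mixture_conductivity(comp, 300, tab), 0.4, tolerance = 1e-12)
  expect_equal(sum(volume_fractions(default_composition(), 323.15)), 1,
               tolerance = 1e-12)
  tabk <- constant_property_table(k = c(0.61, 1, 1, 1, 1, 1))
  expect_equal(mixture_conductivity(composition(1, 0, 0, 0, 0, 0), 300,
                                    tabk), 0.61)
})

test_that("porosity follows the printed relation and rejects bad geometry", {
  expect_equal(porosity(1000, 1000), 0)
  expect_equal(porosity(260, 1000), 0.74)
  expect_error(porosity(1200, 1000), "porosity")
  expect_error(porosity(-1, 1000), "positive")
})

test_that("water activity has correct limits and is strictly increasing", {
  expect_gt(water_activity(100), 0.999)
  expect_lt(water_activity(0.01), 1e-6)
  # frozen from direct term-by-term evaluation of the isotherm
  expect_equal(water_activity(1.551), 0.98996, tolerance = 1e-4)
  x <- exp(seq(log(0.01), log(100), length.out = 400))
  expect_true(all(diff(water_activity(x)) > 0))
  expect_error(water_activity(0), "positive")
  expect_error(water_activity(-1), "positive")
})

test_that("equilibrium moisture inverts the isotherm", {
  for (aw in c(0.11, 0.5, 0.9)) {
    expect_equal(water_activity(equilibrium_moisture_db(aw)), aw,
                 tolerance = 1e-8)
  }
})

test_that("saturation state is consistent, increasing and smooth", {
  s <- saturation_state(373.15)
  # frozen from term-by-term evaluation; steam tables give ~101.3 kPa
  expect_equal(s$pv_sat, 102916, tolerance = 1e-4)
  expect_lt(abs(s$pv_sat - 101325) / 101325, 0.02)
  T <- seq(283.15, 373.15, by = 0.5)
  out <- saturation_state(T)
  expect_equal(out$cv_sat * physical_constants()$R * T, out$pv_sat,
               tolerance = 1e-12)
  expect_true(all(diff(out$pv_sat) > 0))
  expect_true(all(diff(out$cv_sat) > 0))
  # C1 smoothness: second differences of log-pressure stay tiny
  expect_lt(max(abs(diff(diff(log(out$pv_sat))))), 5e-4)
  expect_gt(saturation_state(333.15)$pv_sat, saturation_state(323.15)$pv_sat)
  expect_error(saturation_state(200), "range")
  expect_error(saturation_state(500), "range")
})

test_that("moisture conversions are exact inverses", {
  expect_equal(moisture_conversions(0, 0.74, 1136), list(Mwb = 0, Xdb = 0))
  c0 <- moisture_from_wet_basis(0.608, 1136)
  conv <- moisture_conversions(c0, 0.74, 1136)
  expect_equal(conv$Mwb, 0.608, tolerance = 1e-12)
  expect_equal(conv$Xdb, 0.608 / 0.26, tolerance = 1e-12)  # ~2.338
  expect_error(moisture_conversions(10, 1, 1136), "porosity")
  expect_error(moisture_conversions(-1, 0.74, 1136), "non-negative")
})

test_that("effective gas diffusivity follows the saturation power law", {
  expect_equal(effective_gas_diffusivity(0.74, 0, 2.6e-5), 0)
  expect_equal(effective_gas_diffusivity(1, 1, 2.6e-5), 2.6e-5)
  expect_equal(effective_gas_diffusivity(0.74, 1, 2.6e-5),
               2.6e-5 * 0.74^0.75, tolerance = 1e-12)  # ~2.07e-5
})

test_that("relative permeabilities are clamped, piecewise and bounded", {
  expect_equal(permeabilities(0.005, 0.005)$kwr, 0)
  p1 <- permeabilities(1, 0.005)
  expect_equal(p1$kwr, 1); expect_equal(p1$kgr, 0)
  p2 <- permeabilities(0.5, 0.005)
  expect_equal(p2$kwr, ((0.5 - 0.005) / 0.995)^3, tolerance = 1e-12)
  expect_equal(p2$kgr, 0.45, tolerance = 1e-12)
  grid <- expand.grid(Sw = seq(0, 1, by = 0.01), Sir = c(0, 0.005, 0.2))
  kr <- permeabilities(grid$Sw, grid$Sir[1])
  for (sir in unique(grid$Sir)) {
    kr <- permeabilities(seq(0, 1, by = 0.01), sir)
    expect_true(all(kr$kwr >= 0 & kr$kwr <= 1))
    expect_true(all(kr$kgr >= 0 & kr$kgr <= 1))
    expect_true(all(kr$kwr + kr$kgr <= 1.12))
  }
})

test_that("irreducible saturation has the right value and trends", {
  expect_equal(irreducible_saturation(0.74, 298.15), 0.00543,
               tolerance = 1e-2)
  expect_lt(irreducible_saturation(0.999, 298.15), 1e-3)
  eps <- seq(0.3, 0.95, by = 0.05)
  sir <- vapply(eps, irreducible_saturation, numeric(1), T0 = 298.15)
  expect_true(all(diff(sir) < 0))
})

test_that("effective thermal properties blend fluids by vapour fraction", {
  comp <- default_composition()
  fl <- default_fluid_properties()
  th0 <- effective_thermal_props(comp, 323.15, 0.74, Xv = 0)
  expect_equal(th0$k_f, fl$k_w)
  expect_equal(th0$rho_f, fl$rho_w)
  expect_equal(th0$Cp_f, fl$cp_w)
  th1 <- effective_thermal_props(comp, 323.15, 0.74, Xv = 1)
  expect_equal(th1$k_f, fl$k_a)
  expect_equal(th1$rho_f, fl$rho_a)
  # frozen hand blend at Xv = 0.95
  th <- effective_thermal_props(comp, 323.15, 0.74, Xv = 0.95)
  expect_equal(th$k_f, 0.056575, tolerance = 1e-9)  # 0.59 - 0.5615*0.95
  kp <- mixture_conductivity(comp, 323.15)
  expect_equal(th$k_eff, 0.74 * kp + 0.26 * th$k_f, tolerance = 1e-12)
  thc <- effective_thermal_props(comp, 323.15, 0.74, Xv = 0.95,
                                 rule = "corrected")
  expect_equal(thc$k_eff, 0.26 * kp + 0.74 * th$k_f, tolerance = 1e-12)
  expect_gt(thc$rhoCp_eff, 0)
})

test_that("all bundled properties are positive and finite over the range", {
  for (T in c(313.15, 323.15, 333.15)) {
    for (cc in c(49750, 20000, 3000)) {
      pb <- property_bundle(cc, T)
      num <- unlist(pb[c("rho_in", "cp_in", "k_in", "pv_sat", "cv_sat",
                         "rhoCp_eff", "k_eff", "rho_f", "Cp_f", "k_f")])
      expect_true(all(is.finite(num)) && all(num > 0))
      expect_true(pb$aw > 0 && pb$aw <= 1)
      expect_true(pb$Sw >= 0 && pb$Sw <= 1 && pb$Sg >= 0 && pb$Sg <= 1)
    }
  }
})

test_that("vectorised grid properties agree with the scalar bundle", {
  setup <- ref_setup()
  env <- injeradry:::.sim_env(setup)
  set.seed(3)
  cc <- stats::runif(8, 500, 49750)
  T <- stats::runif(8, 300, 330)
  pg <- injeradry:::.props_grid(cc, T, env)
  for (i in seq_along(cc)) {
    pb <- property_bundle(cc[i], T[i])
    expect_equal(pg$rho_p[i], pb$rho_in, tolerance = 1e-10)
    expect_equal(pg$aw[i], pb$aw, tolerance = 1e-10)
    expect_equal(pg$D[i], pb$D, tolerance = 1e-10)
    expect_equal(pg$k_eff[i], pb$k_eff, tolerance = 1e-10)
    expect_equal(pg$rhoCp_eff[i], pb$rhoCp_eff, tolerance = 1e-10)
  }
})

test_that("component property evaluation rejects bad input", {
  expect_error(component_property("plastic", "density", 300), "unknown")
  expect_error(component_property("water", "density", 500), "range")
  tab <- component_property_models()
  expect_true(all(c("component", "property", "a0") %in% names(tab)))
})

test_that("composition validates and normalises fractions", {
  comp <- default_composition()
  expect_equal(sum(unclass(comp)), 1, tolerance = 1e-12)
  expect_error(composition(0.5, 0.1, 0, 0, 0, 0), "sum")
  expect_error(composition(1.2, 0, 0, 0, 0, -0.2), "\\[0, 1\\]")
})

test_that("reported bulk cp is flagged as a soft inconsistency", {
  expect_warning(check_reported_properties(), "3676")
})
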