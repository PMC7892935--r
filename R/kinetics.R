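#' Drying curve container
#'
#' A time series of moisture ratio with optional centre temperature; the
#' common currency of the simulator, the kinetics fitter and the synthetic
#' generator. Time is in minutes throughout the kinetics layer (the PDE
#' solver works in seconds internally; the conversion happens at this
#' boundary and the unit is recorded in the metadata).
#'
#' @param t Time (minutes), strictly increasing, starting at 0.
#' @param MR Moisture ratio, `MR[1]` in \[0.95, 1.05\], all values in
#'   \[0, 1.05\].
#' @param T_center Optional centre temperature (K).
#' @param meta List of metadata (conditions, source, `Mo`, `Me`,
#'   `time_unit`).
#' @return A `drying_curve` data.frame with columns `t_min`, `MR` and
#'   optionally `T_center_K`.
#' @export
drying_curve <- function(t, MR, T_center = NULL, meta = list()) {
  if (length(t) != length(MR)) stop("t and MR lengths differ", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (MR[1] < 0.95 || MR[1] > 1.05) {
    stop("MR[1] must lie in [0.95, 1.05]", call. = FALSE)
  }
  if (any(MR < -1e-9) || any(MR > 1.05)) {
    stop("MR values must lie in [0, 1.05]", call. = FALSE)
  }
  df <- data.frame(t_min = t, MR = pmax(MR, 0))
  if (!is.null(T_center)) df$T_center_K <- T_center
  meta$time_unit <- if (is.null(meta$time_unit)) "min" else meta$time_unit
  structure(df, class = c("drying_curve", "data.frame"), meta = meta)
}

#' @export
print.drying_curve <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Drying curve (%s): %d points, t = %.1f..%.1f min\n",
              if (is.null(m$source)) "unknown" else m$source, nrow(x),
              min(x$t_min), max(x$t_min)))
  dtm <- attr(x, "drying_time_min")
  if (!is.null(dtm) && is.finite(dtm)) {
    cat(sprintf("  time to MR_stop: %.1f min\n", dtm))
  }
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4))
  invisible(x)
}

#' Moisture ratio series from recorded moisture contents
#'
#' `MR_i = (M_i - Me) / (Mo - Me)`, forced to start exactly at 1. `M` may
#' be any moisture measure proportional to water mass (mass of sample,
#' wet-basis content, concentration) as long as `Mo` and `Me` are on the
#' same scale.
#'
#' @param t Time (minutes), strictly increasing.
#' @param M Recorded moisture measure at each time.
#' @param Mo Initial moisture measure (`> Me`).
#' @param Me Equilibrium moisture measure (`>= 0`).
#' @param T_center Optional centre temperature (K).
#' @param meta Metadata list.
#' @return A [drying_curve()].
#' @export
#' @examples
#' moisture_ratio_series(0:2, c(0.608, 0.329, 0.05), Mo = 0.608, Me = 0.05)
moisture_ratio_series <- function(t, M, Mo, Me = 0, T_center = NULL,
                                  meta = list()) {
  if (Mo <= Me) stop("degenerate curve: Mo must exceed Me", call. = FALSE)
  if (Me < 0) stop("Me must be non-negative", call. = FALSE)
  MR <- (M - Me) / (Mo - Me)
  MR[1] <- 1
  meta$Mo <- Mo; meta$Me <- Me
  drying_curve(t, pmin(pmax(MR, 0), 1.05), T_center = T_center, meta = meta)
}

# thin-layer model registry: prediction functions of (t, pars), starting
# values and the number of parameters
.kinetics_models <- function() {
  list(
    henderson_pabis = list(
      n_par = 2,
      start = c(alpha = 1, rate = -0.02),
      predict = function(t, p) p[["alpha"]] * exp(p[["rate"]] * t),
      formula = "MR = alpha * exp(rate * t)"
    ),
    page = list(
      n_par = 2,
      start = c(rate = -0.02, n = 1),
      predict = function(t, p) exp(p[["rate"]] * t^p[["n"]]),
      formula = "MR = exp(rate * t^n)"
    ),
    two_term = list(
      n_par = 4,
      start = c(beta1 = 0.7, rate1 = -0.02, beta2 = 0.3, rate2 = -0.005),
      predict = function(t, p) {
        p[["beta1"]] * exp(p[["rate1"]] * t) +
          p[["beta2"]] * exp(p[["rate2"]] * t)
      },
      formula = "MR = beta1 * exp(rate1 * t) + beta2 * exp(rate2 * t)"
    )
  )
}

#' Goodness-of-fit statistics
#'
#' `RMSE = sqrt(sum((x_i - y_i)^2) / n)` and `R^2 = r^2`, the square of the
#' Pearson correlation coefficient between the two series.
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values (same length, >= 2 points).
#' @return List with `R2` and `RMSE`.
#' @export
#' @examples
#' goodness(c(1, 0.5, 0.2), c(0.9, 0.55, 0.25))
goodness <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) {
    stop("observed and predicted series must have equal length",
         call. = FALSE)
  }
  if (length(y_obs) < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(y_obs) == 0 || stats::sd(y_pred) == 0) {
    stop("R^2 undefined: zero variance in a series", call. = FALSE)
  }
  list(R2 = stats::cor(y_obs, y_pred)^2,
       RMSE = sqrt(mean((y_obs - y_pred)^2)))
}

#' Fit a thin-layer drying-kinetics model
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of a semi-empirical
#' thin-layer model to a drying curve. Rate constants are per minute and
#' reported with their sign (negative exponential decay), matching the
#' usual tabulation of these models.
#'
#' @param curve A [drying_curve()] (time in minutes).
#' @param model `"henderson_pabis"` (`MR = alpha exp(rate t)`), `"page"`
#'   (`MR = exp(rate t^n)`) or `"two_term"`
#'   (`MR = beta1 exp(rate1 t) + beta2 exp(rate2 t)`).
#' @param start Optional named starting values overriding the documented
#'   defaults.
#' @return A `kinetics_fit` list: `model`, `constants` (named), `R2`,
#'   `RMSE`, `n_obs`, `fitted`.
#' @export
#' @examples
#' cv <- drying_curve(0:100, exp(-0.0189 * 0:100))
#' fit_kinetics(cv, "henderson_pabis")$constants
fit_kinetics <- function(curve, model = c("henderson_pabis", "page",
                                          "two_term"), start = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "drying_curve"))
  spec <- .kinetics_models()[[model]]
  t <- curve$t_min; MR <- curve$MR
  if (length(t) < spec$n_par + 2) {
    stop("too few points for the requested model", call. = FALSE)
  }
  p0 <- spec$start
  if (!is.null(start)) p0[names(start)] <- start
  # page model: t^n undefined at t = 0 for the gradient; drop exact zeros
  resid_fn <- function(p) {
    names(p) <- names(p0)
    MR - spec$predict(t, as.list(p))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unname(p0), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf("kinetics fit failed for %s: %s", model,
                   conditionMessage(e)), call. = FALSE)
    })
  if (fit$info %in% c(0, 9)) {
    stop(sprintf("kinetics fit did not converge for %s (deviance %.3e)",
                 model, fit$deviance), call. = FALSE)
  }
  pars <- stats::setNames(fit$par, names(p0))
  pred <- spec$predict(t, as.list(pars))
  gof <- goodness(MR, pred)
  structure(list(model = model, constants = pars, R2 = gof$R2,
                 RMSE = gof$RMSE, n_obs = length(t), fitted = pred,
                 formula = spec$formula, n_par = spec$n_par),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s):\n", x$model, x$formula))
  print(round(x$constants, 5))
  cat(sprintf("  R2 = %.4f, RMSE = %.4f (n = %d)\n", x$R2, x$RMSE, x$n_obs))
  invisible(x)
}

#' Fit and rank the thin-layer models
#'
#' Fits every registered model to a curve and orders them by descending
#' `R^2` then ascending RMSE. Fits whose `R^2` differ by less than
#' `tie_tol` (default 1e-3, below the precision at which these statistics
#' are meaningfully compared) are treated as tied and the model with fewer
#' parameters ranks first.
#'
#' @param curve A [drying_curve()].
#' @param models Character vector of model names (default: all three).
#' @param tie_tol `R^2` tie tolerance.
#' @return List of `kinetics_fit` objects, best first; failures are
#'   dropped (at least 3 successful fits required).
#' @export
rank_models <- function(curve, models = names(.kinetics_models()),
                        tie_tol = 1e-3) {
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_kinetics(curve, m), error = function(e) NULL)
    if (!is.null(f)) fits[[m]] <- f
  }
  if (length(fits) < 3) {
    stop("fewer than 3 models fitted successfully", call. = FALSE)
  }
  r2 <- vapply(fits, `[[`, numeric(1), "R2")
  rmse <- vapply(fits, `[[`, numeric(1), "RMSE")
  npar <- vapply(fits, `[[`, numeric(1), "n_par")
  # group near-ties on R2, then order by (R2 group, RMSE, parsimony)
  o <- order(-r2)
  grp <- numeric(length(o)); g <- 1; grp[o[1]] <- 1
  if (length(o) > 1) {
    for (i in 2:length(o)) {
      if (r2[o[i - 1]] - r2[o[i]] > tie_tol) g <- g + 1
      grp[o[i]] <- g
    }
  }
  fits[order(grp, npar, rmse)]
}

#' Effective moisture diffusivity by the slope method
#'
#' First-term Fickian slab extraction: least-squares slope `k` of
#' `ln MR` against time (seconds) over the window `MR` in
#' \[`mr_window[1]`, `mr_window[2]`\], then `Deff = |k| L^2 / pi^2` with
#' `L` the half-thickness of a slab exchanging through both faces.
#'
#' @param curve A [drying_curve()] reaching below `mr_window[1]`... the
#'   lower window edge; at least 4 points must fall inside the window.
#' @param half_thickness Slab half-thickness `L` (m), default 0.015.
#' @param mr_window Fitting window on MR, default `c(0.05, 0.7)`
#'   (lower, upper).
#' @return Effective diffusivity (m^2/s).
#' @export
#' @examples
#' t <- 0:200
#' cv <- drying_curve(t, exp(-pi^2 * 1e-8 * t * 60 / 0.015^2))
#' effective_diffusivity_slope(cv, 0.015)
effective_diffusivity_slope <- function(curve, half_thickness = 0.015,
                                        mr_window = c(0.05, 0.7)) {
  stopifnot(inherits(curve, "drying_curve"), half_thickness > 0)
  lo <- min(mr_window); hi <- max(mr_window)
  if (min(curve$MR) > 0.2) {
    stop("curve does not reach MR < 0.2; slope window empty", call. = FALSE)
  }
  sel <- curve$MR >= lo & curve$MR <= hi & curve$MR > 0
  if (sum(sel) < 4) {
    stop("fewer than 4 points inside the slope-fitting window",
         call. = FALSE)
  }
  t_s <- curve$t_min[sel] * 60
  k <- unname(stats::coef(stats::lm(log(curve$MR[sel]) ~ t_s))[2])
  abs(k) * half_thickness^2 / pi^2
}

#' Balanced two-factor ANOVA with interaction
#'
#' Fixed-effects two-way analysis of variance computed from first
#' principles (explicit sums of squares) for a balanced factorial design,
#' e.g. drying rates over air-temperature x air-velocity cells with
#' replicates. Degenerate zero sums of squares (identical cells) give
#' `F = 0`, `p = 1`.
#'
#' @param data Data frame with the response and two factor columns.
#' @param response Name of the response column.
#' @param factor_a,factor_b Names of the two factor columns.
#' @return Data frame with rows `factor_a`, `factor_b`, `interaction`,
#'   `residuals` and columns `df`, `sum_sq`, `mean_sq`, `F`, `p`.
#' @export
anova_two_way <- function(data, response = "rate", factor_a = "T_air",
                          factor_b = "u_air") {
  y <- data[[response]]
  A <- factor(data[[factor_a]]); B <- factor(data[[factor_b]])
  if (any(is.na(y))) stop("missing responses", call. = FALSE)
  tab <- table(A, B)
  if (length(unique(as.vector(tab))) != 1L) {
    stop("unbalanced design: equal replication per cell required",
         call. = FALSE)
  }
  r <- unique(as.vector(tab))
  if (r < 2) stop("at least 2 replicates per cell required", call. = FALSE)
  a <- nlevels(A); b <- nlevels(B)
  if (a < 2 || b < 2) stop("at least 2 levels per factor required",
                           call. = FALSE)
  g <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_a <- b * r * sum((mA - g)^2)
  ss_b <- a * r * sum((mB - g)^2)
  ss_ab <- r * sum((mAB - outer(mA - g, mB - g, `+`) - g)^2)
  ss_e <- sum((y - mAB[cbind(A, B)])^2)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (r - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  ms <- ss / df
  Fv <- ms[1:3] / ms[4]
  # identical cells: 0/0 -> define F = 0, p = 1
  Fv[!is.finite(Fv) | ss[1:3] < 1e-300] <- 0
  p <- stats::pf(Fv, df[1:3], df[4], lower.tail = FALSE)
  p[Fv == 0] <- 1
  data.frame(
    term = c(factor_a, factor_b, "interaction", "residuals"),
    df = df, sum_sq = ss, mean_sq = ms,
    F = c(Fv, NA), p = c(p, NA)
  )
}

#' Mean moisture removal rate of a drying curve
#'
#' The response variable used in the factorial analysis: mean `-dMR/dt`
#' over the first `window_min` minutes (default 60), i.e.
#' `(MR(0) - MR(window)) / window` in 1/min.
#'
#' @param curve A [drying_curve()].
#' @param window_min Averaging window (minutes).
#' @return Drying rate (1/min).
#' @export
drying_rate <- function(curve, window_min = 60) {
  tmax <- min(window_min, max(curve$t_min))
  mr_end <- stats::approx(curve$t_min, curve$MR, xout = tmax)$y
  (curve$MR[1] - mr_end) / tmax
}
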