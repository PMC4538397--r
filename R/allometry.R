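# Moist-forest allometric constants. Kept as data, not hard-wired into the
# functions, so alternative calibrations can be swapped in via `coef`.
CHAVE_H <- c(a = 0.0673, b = 0.976)        # AGB = a * (rho * D^2 * H)^b
CHAVE_NOH <- c(c0 = -1.803, cE = -0.976,   # ln AGB = c0 + cE*E + cr*ln rho +
               cr = 0.976, cd = 2.673,     #          cd*ln D + cd2*(ln D)^2
               cd2 = -0.0299)
CHAVE_HD <- c(h0 = 0.893, hd = 0.760, hd2 = -0.0340)  # ln H = h0 - E + ...

#' Tree above-ground biomass from diameter, height and wood density
#'
#' Pantropical moist-forest allometry on the compound variable
#' \eqn{\rho D^2 H}: \eqn{AGB = a (\rho D^2 H)^b} with default
#' \eqn{a = 0.0673}, \eqn{b = 0.976}, giving dry mass in kg for DBH in cm,
#' height in m and wood specific gravity in g/cm3.
#'
#' @param dbh DBH in cm (> 0).
#' @param height total tree height in m (> 0).
#' @param wd wood specific gravity in g/cm3 (> 0).
#' @param coef optional override `c(a = , b = )`.
#' @return AGB in kg (vectorised).
#' @export
agb_with_height <- function(dbh, height, wd, coef = NULL) {
  cf <- resolve_coef(coef, CHAVE_H)
  stopifnot(length(dbh) == length(height) || length(height) == 1 ||
              length(dbh) == 1)
  if (any(dbh <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE) ||
      any(wd <= 0, na.rm = TRUE)) {
    stop("dbh, height and wd must all be > 0", call. = FALSE)
  }
  cf[["a"]] * (wd * dbh^2 * height)^cf[["b"]]
}

#' Tree above-ground biomass without height, via an environmental stress proxy
#'
#' Height-free moist-forest allometry
#' \eqn{AGB = \exp(c_0 + c_E E + c_r \ln\rho + c_d \ln D + c_{d2} (\ln D)^2)}
#' where `E` is the dimensionless environmental stress covariate of the
#' height-free pantropical model (larger `E`, shorter trees, lower biomass at
#' equal diameter). Consistent within a few percent with
#' [agb_with_height()] evaluated at the height implied by the matching
#' `E`-dependent height-diameter relation ([env_height()]).
#'
#' @param dbh DBH in cm.
#' @param wd wood specific gravity in g/cm3.
#' @param env_stress dimensionless stress covariate `E` (around 0 for wet
#'   Central African sites; roughly -0.2 to 0.5 pantropically).
#' @param coef optional override `c(c0, cE, cr, cd, cd2)`.
#' @return AGB in kg (vectorised).
#' @export
agb_without_height <- function(dbh, wd, env_stress, coef = NULL) {
  if (missing(env_stress) || is.null(env_stress) || anyNA(env_stress)) {
    stop("env_stress (E) is required for the height-free allometry",
         call. = FALSE)
  }
  cf <- resolve_coef(coef, CHAVE_NOH)
  if (any(dbh <= 0, na.rm = TRUE) || any(wd <= 0, na.rm = TRUE)) {
    stop("dbh and wd must be > 0", call. = FALSE)
  }
  ld <- log(dbh)
  exp(cf[["c0"]] + cf[["cE"]] * env_stress + cf[["cr"]] * log(wd) +
        cf[["cd"]] * ld + cf[["cd2"]] * ld^2)
}

#' Expected tree height under the E-dependent pantropical H-D relation
#'
#' @param dbh DBH in cm.
#' @param env_stress dimensionless stress covariate `E`.
#' @return Height in m.
#' @export
env_height <- function(dbh, env_stress) {
  ld <- log(dbh)
  exp(CHAVE_HD[["h0"]] - env_stress + CHAVE_HD[["hd"]] * ld +
        CHAVE_HD[["hd2"]] * ld^2)
}

resolve_coef <- function(coef, default) {
  if (is.null(coef)) return(default)
  if (is.null(names(coef)) && length(coef) == length(default)) {
    names(coef) <- names(default)
  }
  out <- default
  out[names(coef)] <- coef
  out
}

# ---- height-diameter allometries ------------------------------------------

HD_FORMS <- c("power", "michaelis_menten", "weibull")

#' Fit a site-specific height-diameter allometry
#'
#' Supported forms: `power` \eqn{H = a D^b} (fitted by log-log least squares),
#' `michaelis_menten` \eqn{H = a D / (b + D)} and `weibull`
#' \eqn{H = a (1 - e^{-b D^c})} (fitted by Levenberg-Marquardt nonlinear
#' least squares). `"auto"` fits all three and keeps the form with the
#' smallest log-scale residual standard deviation. The power fit stores
#' median-scale coefficients; the lognormal half-variance back-correction is
#' applied at prediction time (see [predict_height()]).
#'
#' @param dbh,height paired vectors (cm, m); `NA` heights are dropped.
#' @param form one of `"power"`, `"michaelis_menten"`, `"weibull"`, `"auto"`.
#' @param site_id label stored on the model.
#' @param min_n minimum number of height observations (default 20).
#' @return An `hd_model`: list with `site_id`, `form`, `coef`,
#'   `residual_sd` (sd of log-scale residuals) and `n`.
#' @export
fit_hd_model <- function(dbh, height, form = c("power", "michaelis_menten",
                                               "weibull", "auto"),
                         site_id = NA_character_, min_n = 20) {
  form <- match.arg(form)
  keep <- !is.na(dbh) & !is.na(height)
  dbh <- dbh[keep]; height <- height[keep]
  if (length(dbh) < min_n) {
    stop("need at least ", min_n, " stems with measured height (got ",
         length(dbh), ")", call. = FALSE)
  }
  if (any(dbh <= 0) || any(height <= 0)) {
    stop("dbh and height must be > 0", call. = FALSE)
  }
  if (form == "auto") {
    fits <- lapply(HD_FORMS, function(f) {
      tryCatch(fit_hd_model(dbh, height, f, site_id, min_n),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("no height-diameter form converged", call. = FALSE)
    return(fits[[which.min(vapply(fits, `[[`, 0, "residual_sd"))]])
  }
  if (form == "power") {
    fit <- stats::lm(log(height) ~ log(dbh))
    cf <- c(a = exp(unname(stats::coef(fit)[1])),
            b = unname(stats::coef(fit)[2]))
    pred <- cf[["a"]] * dbh^cf[["b"]]
  } else if (form == "michaelis_menten") {
    start <- list(a = max(height) * 1.3, b = stats::median(dbh))
    fit <- tryCatch(
      minpack.lm::nlsLM(height ~ a * dbh / (b + dbh), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("michaelis_menten height-diameter fit failed ",
                               "to converge: ", conditionMessage(e),
                               call. = FALSE))
    cf <- stats::coef(fit)
    pred <- stats::predict(fit)
  } else {
    start <- list(a = max(height), b = 0.03, c = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(height ~ a * (1 - exp(-b * dbh^c)), start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("weibull height-diameter fit failed to ",
                               "converge: ", conditionMessage(e),
                               call. = FALSE))
    cf <- stats::coef(fit)
    pred <- stats::predict(fit)
  }
  out <- list(site_id = site_id, form = form, coef = cf,
              residual_sd = stats::sd(log(height) - log(pred)),
              n = length(dbh))
  class(out) <- "hd_model"
  # invariants: positive, nondecreasing over the census range
  grid <- predict_height(out, seq(10, 300, by = 5))
  if (any(grid <= 0) || any(diff(grid) < -1e-8)) {
    stop("fitted ", form, " height model violates positivity/monotonicity ",
         "over DBH 10-300 cm", call. = FALSE)
  }
  out
}

#' @export
print.hd_model <- function(x, ...) {
  cat("hd_model [", x$form, "] site=", x$site_id, ", n=", x$n, "\n  coef: ",
      paste(names(x$coef), signif(x$coef, 4), sep = "=", collapse = ", "),
      "\n  residual sd (log scale): ", signif(x$residual_sd, 3), "\n",
      sep = "")
  invisible(x)
}

#' Predict tree height from DBH
#'
#' @param model an [fit_hd_model()] object.
#' @param dbh DBH in cm.
#' @param correct_bias apply the lognormal half-variance correction
#'   \eqn{\exp(\sigma^2/2)} to power-form (log-fitted) predictions so that
#'   predictions target the conditional mean rather than the median. Default
#'   `TRUE`.
#' @return Heights in m.
#' @export
predict_height <- function(model, dbh, correct_bias = TRUE) {
  stopifnot(inherits(model, "hd_model"))
  cf <- model$coef
  h <- switch(model$form,
    power = cf[["a"]] * dbh^cf[["b"]],
    michaelis_menten = cf[["a"]] * dbh / (cf[["b"]] + dbh),
    weibull = cf[["a"]] * (1 - exp(-cf[["b"]] * dbh^cf[["c"]])))
  if (model$form == "power" && correct_bias && is.finite(model$residual_sd)) {
    h <- h * exp(model$residual_sd^2 / 2)
  }
  h
}

#' Fill tree-level AGB across an inventory
#'
#' With `mode = "with_height"`, missing heights are first predicted from the
#' site's height-diameter model (fitted from the site's measured heights when
#' no model is supplied), then [agb_with_height()] is applied. With
#' `mode = "without_height"` the height-free allometry is used with a per-site
#' (or scalar) `env_stress`.
#'
#' @param inv a `forest_inventory` with `wd` assigned.
#' @param mode `"with_height"` or `"without_height"`.
#' @param hd_models optional named list of `hd_model`s keyed by site id.
#' @param hd_form form passed to [fit_hd_model()] when fitting per site.
#' @param env_stress scalar or named vector (by site) of `E` values, required
#'   for `without_height`.
#' @param coef optional allometry coefficient override.
#' @return The inventory with `agb_kg` (and, in `with_height` mode,
#'   `height_m`) filled.
#' @export
compute_agb <- function(inv, mode = c("with_height", "without_height"),
                        hd_models = NULL, hd_form = "power",
                        env_stress = NULL, coef = NULL) {
  mode <- match.arg(mode)
  if (anyNA(inv$wd)) {
    stop("assign wood density before computing AGB", call. = FALSE)
  }
  if (mode == "without_height") {
    if (is.null(env_stress)) {
      stop("env_stress is required for mode = 'without_height'",
           call. = FALSE)
    }
    e <- if (!is.null(names(env_stress))) {
      unname(env_stress[inv$site])
    } else {
      rep_len(env_stress, nrow(inv))
    }
    if (anyNA(e)) stop("env_stress missing for some site(s)", call. = FALSE)
    inv$agb_kg <- agb_without_height(inv$dbh_cm, inv$wd, e, coef = coef)
    return(inv)
  }
  need_h <- is.na(inv$height_m)
  if (any(need_h)) {
    for (s in unique(inv$site[need_h])) {
      model <- if (!is.null(hd_models) && s %in% names(hd_models)) {
        hd_models[[s]]
      } else {
        rows <- inv$site == s & !is.na(inv$height_m)
        if (!any(rows)) {
          stop("site ", s, " has no measured heights and no hd_model",
               call. = FALSE)
        }
        fit_hd_model(inv$dbh_cm[rows], inv$height_m[rows], form = hd_form,
                     site_id = s)
      }
      rows <- inv$site == s & need_h
      inv$height_m[rows] <- predict_height(model, inv$dbh_cm[rows])
    }
  }
  inv$agb_kg <- agb_with_height(inv$dbh_cm, inv$height_m, inv$wd, coef = coef)
  inv
}
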