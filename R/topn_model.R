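# Intercept-free power models predicting total plot AGB from the AGB of the
# N largest trees, meta-models of the coefficients over N, and site-wise
# leave-one-out cross-validation.

#' Per-plot top-N summaries for model fitting
#'
#' @param inv a `forest_inventory` with `agb_kg` filled.
#' @param n number of largest trees (scalar).
#' @return data.frame with one row per plot: `site`, `plot`, `n`,
#'   `agb_topn` (kg/ha), `agb_tot` (kg/ha), `richness_topn`, `species_tot`.
#'   Plots are 1 ha, so per-plot kg equals kg/ha.
#' @export
plot_topn_table <- function(inv, n) {
  stopifnot(length(n) == 1, n >= 1)
  plots <- split_plots(inv)
  rows <- lapply(plots, function(p) {
    cur <- cumulative_curve(p)
    i <- min(n, nrow(cur))
    data.frame(site = p$site[1], plot = p$plot[1], n = n,
               agb_topn = cur$topn_agb_kg[i],
               agb_tot = attr(cur, "agb_tot"),
               richness_topn = cur$richness[i],
               species_tot = attr(cur, "species_tot"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the intercept-free power model AGB_TOT = alpha * AGB_topN^beta
#'
#' Nonlinear least squares on the natural scale (so the residual standard
#' error is interpretable in kg/ha), started from an ordinary log-log
#' regression. When the log-log start already interpolates the data (zero
#' residuals, e.g. the identity limit where the N largest trees are the whole
#' plot) it is returned directly: alpha = 1, beta = 1 and R-squared = 1
#' exactly in that limit.
#'
#' @param agb_topn per-plot AGB of the N largest trees, kg/ha (> 0).
#' @param agb_tot per-plot total AGB, kg/ha (> 0).
#' @param n the N the predictor corresponds to (stored on the model).
#' @param min_plots minimum number of plots (default 5).
#' @return A `power_model`: list with `n`, `alpha`, `beta`, `se` (standard
#'   errors, NA for degenerate/exact fits), `r2` (about the observed mean),
#'   `rse` (kg/ha), `rser` (rse / mean observed), `n_plots`.
#' @export
fit_power_model <- function(agb_topn, agb_tot, n = NA_integer_,
                            min_plots = 5) {
  keep <- !is.na(agb_topn) & !is.na(agb_tot)
  x <- agb_topn[keep]; y <- agb_tot[keep]
  if (length(x) < min_plots) {
    stop("need at least ", min_plots, " plots (got ", length(x), ")",
         call. = FALSE)
  }
  if (any(x <= 0) || any(y <= 0)) {
    stop("AGB values must be > 0", call. = FALSE)
  }
  if (all(x == y)) {
    # identity limit: the N largest trees are the whole plot everywhere
    return(new_power_model(n, 1, 1,
                           se = c(alpha = NA_real_, beta = NA_real_),
                           x = x, y = y))
  }
  if (stats::var(log(x)) < .Machine$double.eps) {
    # constant predictor: beta unidentifiable; pin beta = 1
    start <- c(alpha = exp(mean(log(y) - log(x))), beta = 1)
  } else {
    ll <- stats::lm(log(y) ~ log(x))
    start <- c(alpha = exp(unname(stats::coef(ll)[1])),
               beta = unname(stats::coef(ll)[2]))
  }
  res0 <- y - start[["alpha"]] * x^start[["beta"]]
  if (sum(res0^2) <= (1e-12 * sum(y^2))) {
    return(new_power_model(n, start[["alpha"]], start[["beta"]],
                           se = c(alpha = NA_real_, beta = NA_real_),
                           x = x, y = y))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ alpha * x^beta, start = as.list(start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      cond <- simpleError(paste0(
        "power model (n=", n, ") failed to converge: ", conditionMessage(e),
        "; log-log fallback alpha=", signif(start[["alpha"]], 6),
        ", beta=", signif(start[["beta"]], 6)))
      cond$fallback <- start
      stop(cond)
    })
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(alpha = NA_real_, beta = NA_real_))
  new_power_model(n, cf[["alpha"]], cf[["beta"]],
                  se = c(alpha = unname(se[1]), beta = unname(se[2])),
                  x = x, y = y)
}

new_power_model <- function(n, alpha, beta, se, x, y) {
  pred <- alpha * x^beta
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  rse <- sqrt(ss_res / max(length(y) - 2, 1))
  out <- list(n = as.integer(n), alpha = alpha, beta = beta, se = se,
              r2 = 1 - ss_res / ss_tot, rse = rse, rser = rse / mean(y),
              n_plots = length(y))
  class(out) <- "power_model"
  out
}

#' @export
print.power_model <- function(x, ...) {
  cat("power_model (no intercept): AGB_TOT = alpha * AGB_top", x$n,
      "^beta\n", sep = "")
  cat(sprintf("  alpha = %.5g, beta = %.5g  (n_plots = %d)\n",
              x$alpha, x$beta, x$n_plots))
  cat(sprintf("  R2 = %.4f, RSE = %.4g kg/ha, RSEr = %.1f%%\n",
              x$r2, x$rse, 100 * x$rser))
  invisible(x)
}

#' Fit power models over a range of N
#'
#' @param inv a `forest_inventory` with `agb_kg` filled.
#' @param n_values integer vector of N values (default 5..100).
#' @param min_plots passed to [fit_power_model()].
#' @return Named list of `power_model`s (names = N).
#' @export
fit_power_models <- function(inv, n_values = 5:100, min_plots = 5) {
  curves <- lapply(split_plots(inv), cumulative_curve)
  tot <- vapply(curves, attr, 0, "agb_tot")
  models <- lapply(n_values, function(n) {
    topn <- vapply(curves, function(cur) cur$topn_agb_kg[min(n, nrow(cur))], 0)
    fit_power_model(topn, tot, n = n, min_plots = min_plots)
  })
  names(models) <- n_values
  models
}

#' Fit the generic meta-model of the power coefficients over N
#'
#' From per-N power-model fits, models the multiplier as a power law in N,
#' \eqn{\alpha(N) = a N^b} (intercept-free least squares), and the exponent
#' with a saturating three-parameter Weibull growth curve
#' \eqn{\beta(N) = k_1 (1 - e^{-k_2 N^{k_3}})}. Predictions are refused
#' outside the fitted validity range (default N in 5..100).
#'
#' @param models list of `power_model`s spanning the validity range.
#' @param beta_start start values for the Weibull fit, default
#'   `c(k1 = 1, k2 = 0.1, k3 = 1)`; override when convergence fails.
#' @return A `generic_model`: list with `alpha_coeffs` (a, b),
#'   `beta_coeffs` (k1, k2, k3), `valid_range`, `alpha_r2`, `beta_r2` and
#'   the fitted per-N table `by_n`.
#' @export
fit_generic_model <- function(models, beta_start = c(k1 = 1, k2 = 0.1,
                                                     k3 = 1)) {
  stopifnot(length(models) >= 10)
  i <- vapply(models, `[[`, 0L, "n")
  alpha <- vapply(models, `[[`, 0, "alpha")
  beta <- vapply(models, `[[`, 0, "beta")
  if (length(unique(i)) < 10) {
    stop("need at least 10 distinct N values", call. = FALSE)
  }
  # alpha(i) = a * i^b, log-log exact since alpha > 0
  la <- stats::lm(log(alpha) ~ log(i))
  a_start <- c(a = exp(unname(stats::coef(la)[1])),
               b = unname(stats::coef(la)[2]))
  afit <- minpack.lm::nls.lm(
    par = as.list(a_start),
    fn = function(p) alpha - p$a * i^p$b,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  acf <- unlist(afit$par)
  # nls.lm (residual-function interface) rather than nlsLM: a saturating
  # Weibull on a near-flat beta(N) series converges with k2 effectively at
  # its asymptote, where the model-object constructor rejects the singular
  # Jacobian even though the fit itself is fine.
  bfit <- tryCatch(
    minpack.lm::nls.lm(
      par = as.list(beta_start),
      fn = function(p) beta - p$k1 * (1 - exp(-p$k2 * i^p$k3)),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000)),
    error = function(e) {
      stop("Weibull fit of beta(N) did not converge: ", conditionMessage(e),
           "; supply beta_start overrides", call. = FALSE)
    })
  if (bfit$info < 1 || bfit$info > 4) {
    stop("Weibull fit of beta(N) did not converge (", bfit$message,
         "); supply beta_start overrides", call. = FALSE)
  }
  bcf <- unlist(bfit$par)
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  apred <- acf[["a"]] * i^acf[["b"]]
  bpred <- bcf[["k1"]] * (1 - exp(-bcf[["k2"]] * i^bcf[["k3"]]))
  out <- list(alpha_coeffs = c(a = acf[["a"]], b = acf[["b"]]),
              beta_coeffs = c(k1 = bcf[["k1"]], k2 = bcf[["k2"]],
                              k3 = bcf[["k3"]]),
              valid_range = range(i),
              alpha_r2 = r2(alpha, apred), beta_r2 = r2(beta, bpred),
              by_n = data.frame(n = i, alpha = alpha, beta = beta,
                                alpha_fit = apred, beta_fit = bpred))
  class(out) <- "generic_model"
  out
}

#' @export
print.generic_model <- function(x, ...) {
  cat("generic_model over N in [", x$valid_range[1], ", ", x$valid_range[2],
      "]\n", sep = "")
  cat(sprintf("  alpha(N) = %.5g * N^%.5g   (R2 = %.4f)\n",
              x$alpha_coeffs[["a"]], x$alpha_coeffs[["b"]], x$alpha_r2))
  cat(sprintf("  beta(N)  = %.5g * (1 - exp(-%.5g * N^%.5g))   (R2 = %.4f)\n",
              x$beta_coeffs[["k1"]], x$beta_coeffs[["k2"]],
              x$beta_coeffs[["k3"]], x$beta_r2))
  invisible(x)
}

#' Coefficients of the generic model at a given N
#'
#' @param model a `generic_model`.
#' @param n number of largest trees.
#' @return Named vector `c(alpha = , beta = )`.
#' @export
generic_coefficients <- function(model, n) {
  stopifnot(inherits(model, "generic_model"))
  if (any(n < model$valid_range[1] | n > model$valid_range[2])) {
    stop("N outside the model's validity range [", model$valid_range[1],
         ", ", model$valid_range[2], "]", call. = FALSE)
  }
  c(alpha = model$alpha_coeffs[["a"]] * n^model$alpha_coeffs[["b"]],
    beta = model$beta_coeffs[["k1"]] *
      (1 - exp(-model$beta_coeffs[["k2"]] * n^model$beta_coeffs[["k3"]])))
}

#' Predict total plot AGB from top-N AGB
#'
#' @param model a `power_model` or `generic_model`.
#' @param agb_topn AGB of the N largest trees, kg/ha (> 0).
#' @param n number of largest trees; required for a `generic_model`, checked
#'   against the stored N for a `power_model` when supplied.
#' @return Predicted AGB_TOT in kg/ha.
#' @export
predict_agb_tot <- function(model, agb_topn, n = NULL) {
  if (any(agb_topn <= 0, na.rm = TRUE)) {
    stop("agb_topn must be > 0", call. = FALSE)
  }
  if (inherits(model, "power_model")) {
    if (!is.null(n) && !is.na(model$n) && n != model$n) {
      stop("model was fitted at N = ", model$n, ", not N = ", n,
           call. = FALSE)
    }
    return(model$alpha * agb_topn^model$beta)
  }
  if (inherits(model, "generic_model")) {
    if (is.null(n)) stop("n is required with a generic_model", call. = FALSE)
    cf <- generic_coefficients(model, n)
    return(cf[["alpha"]] * agb_topn^cf[["beta"]])
  }
  stop("model must be a power_model or generic_model", call. = FALSE)
}

#' Site-wise leave-one-out cross-validation of the top-N model
#'
#' Each site in turn is held out; the power model is fitted on all remaining
#' plots pooled, and the held-out site's plots are predicted. Reported per
#' site: Pearson correlation between predicted and observed AGB_TOT, the
#' mean absolute relative error (`bias_abs`, the headline bias) and the mean
#' signed relative error (`bias_signed`).
#'
#' @param topn_table a [plot_topn_table()] data.frame (or any data.frame with
#'   `site`, `agb_topn`, `agb_tot`).
#' @param min_plots minimum plots a site needs to be validated; smaller sites
#'   are excluded from hold-out with a warning (they still inform fits).
#' @return A `loocv_result`: list with `by_site` data.frame (`site`,
#'   `n_plots`, `pearson_r`, `bias_abs`, `bias_signed`) and scalar averages
#'   `mean_r`, `mean_bias_abs`, `mean_bias_signed`.
#' @export
loocv_by_site <- function(topn_table, min_plots = 2) {
  sites <- unique(topn_table$site)
  if (length(sites) < 3) {
    stop("need at least 3 sites for site-wise cross-validation",
         call. = FALSE)
  }
  counts <- table(topn_table$site)
  small <- names(counts)[counts < min_plots]
  if (length(small)) {
    warning("site(s) with fewer than ", min_plots,
            " plots excluded from hold-out: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  held <- setdiff(sites, small)
  n_val <- if (!is.null(topn_table$n)) topn_table$n[1] else NA_integer_
  rows <- lapply(held, function(s) {
    train <- topn_table[topn_table$site != s, ]
    test <- topn_table[topn_table$site == s, ]
    fit <- fit_power_model(train$agb_topn, train$agb_tot, n = n_val)
    pred <- predict_agb_tot(fit, test$agb_topn)
    rel <- (pred - test$agb_tot) / test$agb_tot
    r <- if (stats::sd(pred) > 0 && stats::sd(test$agb_tot) > 0) {
      stats::cor(pred, test$agb_tot)
    } else NA_real_
    data.frame(site = s, n_plots = nrow(test), pearson_r = r,
               bias_abs = mean(abs(rel)), bias_signed = mean(rel))
  })
  by_site <- do.call(rbind, rows)
  out <- list(by_site = by_site,
              mean_r = mean(by_site$pearson_r, na.rm = TRUE),
              mean_bias_abs = mean(by_site$bias_abs),
              mean_bias_signed = mean(by_site$bias_signed))
  class(out) <- "loocv_result"
  out
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("site-wise leave-one-out cross-validation\n")
  print(x$by_site, row.names = FALSE)
  cat(sprintf("  mean Pearson r = %.3f, mean |bias| = %.1f%%, mean signed bias = %.1f%%\n",
              x$mean_r, 100 * x$mean_bias_abs, 100 * x$mean_bias_signed))
  invisible(x)
}

#' Linear prediction of total species richness from top-N richness
#'
#' Ordinary least squares `species_tot ~ richness_topn`, fitted per site and
#' pooled. Sites whose predictor has (near-)zero variance are flagged
#' degenerate: slope and R-squared are not identifiable there.
#'
#' @param topn_table a [plot_topn_table()] data.frame with `richness_topn`
#'   and `species_tot`.
#' @param min_plots minimum plots per fit (default 5).
#' @return list with `pooled` (lm fit summary: `intercept`, `slope`, `r2`,
#'   `n`) and `by_site` data.frame (`site`, `intercept`, `slope`, `r2`, `n`,
#'   `degenerate`).
#' @export
fit_richness_model <- function(topn_table, min_plots = 5) {
  fit_one <- function(df) {
    if (nrow(df) < min_plots) {
      stop("need at least ", min_plots, " plots (got ", nrow(df), ")",
           call. = FALSE)
    }
    if (stats::var(df$richness_topn) < .Machine$double.eps) {
      return(data.frame(intercept = NA_real_, slope = NA_real_,
                        r2 = NA_real_, n = nrow(df), degenerate = TRUE))
    }
    fit <- stats::lm(species_tot ~ richness_topn, data = df)
    data.frame(intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               r2 = summary(fit)$r.squared, n = nrow(df),
               degenerate = FALSE)
  }
  pooled <- fit_one(topn_table)
  per_site <- lapply(split(topn_table, topn_table$site), function(df) {
    tryCatch(fit_one(df), error = function(e) {
      data.frame(intercept = NA_real_, slope = NA_real_, r2 = NA_real_,
                 n = nrow(df), degenerate = TRUE)
    })
  })
  by_site <- do.call(rbind, per_site)
  by_site <- data.frame(site = names(per_site), by_site, row.names = NULL)
  list(pooled = pooled, by_site = by_site)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `power_model` or `generic_model`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- unclass(model)
  payload$class <- class(model)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
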