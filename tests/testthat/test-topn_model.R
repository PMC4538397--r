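test_that("noise-free pairs recover the generating power law exactly", {
  x <- seq(1e5, 6e5, length.out = 12)
  fit <- fit_power_model(x, 1.3 * x^0.95, n = 20)
  expect_equal(fit$alpha, 1.3, tolerance = 1e-6)
  expect_equal(fit$beta, 0.95, tolerance = 1e-6)
  expect_equal(fit$r2, 1)
  expect_error(fit_power_model(x[1:3], (1.3 * x^0.95)[1:3]), "at least 5")
  expect_error(fit_power_model(x, -x), "> 0")
})

test_that("the identity limit returns alpha = beta = 1 and R2 = 1 exactly", {
  set.seed(4)
  tot <- exp(rnorm(15, 13, 0.3))
  fit <- fit_power_model(tot, tot, n = 999)
  expect_identical(fit$alpha, 1)
  expect_identical(fit$beta, 1)
  expect_identical(fit$r2, 1)
})

test_that("fits under multiplicative lognormal noise cover the truth", {
  set.seed(118)
  x <- exp(rnorm(175, 12.5, 0.4))
  y <- 1.3 * x^0.95 * exp(rnorm(175, 0, 0.15))
  fit <- fit_power_model(x, y, n = 20)
  # the fit's own 95% intervals cover the generator values
  expect_lt(abs(fit$beta - 0.95), 1.96 * fit$se[["beta"]])
  expect_lt(abs(fit$alpha - 1.3), 1.96 * fit$se[["alpha"]])
  # cross-check against an independent log-log regression on the same draws
  ll <- stats::lm(log(y) ~ log(x))
  expect_equal(fit$beta, unname(coef(ll)[2]), tolerance = 0.05)
  expect_equal(fit$rser, fit$rse / mean(y))
})

test_that("generic meta-model recovers exact coefficient trajectories", {
  n_vals <- seq(5, 100, by = 5)
  models <- lapply(n_vals, function(n) {
    list(n = as.integer(n), alpha = 2 * n^-0.3, beta = 1.0)
  })
  gm <- fit_generic_model(models)
  expect_equal(unname(gm$alpha_coeffs), c(2, -0.3), tolerance = 1e-6)
  # constant beta = 1 is reproduced across the whole validity range
  expect_lt(max(abs(gm$by_n$beta_fit - 1)), 1e-3)
  cf <- generic_coefficients(gm, 50)
  expect_equal(unname(cf[["alpha"]]), 2 * 50^-0.3, tolerance = 1e-6)
  expect_error(fit_generic_model(models[1:5]), "length")
})

test_that("meta-model predictions track smooth per-N fits within 5%", {
  set.seed(91)
  n_vals <- seq(5, 100, by = 5)
  models <- lapply(n_vals, function(n) {
    list(n = as.integer(n),
         alpha = 3.5 * n^-0.35 * exp(rnorm(1, 0, 0.01)),
         beta = 0.98 * (1 - exp(-0.9 * n^0.8)) + rnorm(1, 0, 0.002))
  })
  gm <- fit_generic_model(models)
  expect_lt(max(abs(gm$by_n$alpha_fit / gm$by_n$alpha - 1)), 0.05)
  expect_lt(max(abs(gm$by_n$beta_fit / gm$by_n$beta - 1)), 0.05)
  expect_gt(gm$alpha_r2, 0.95)
})

test_that("prediction applies the power law and honours the validity range", {
  pm <- fit_power_model(seq(1e5, 2e5, length.out = 6),
                        seq(1e5, 2e5, length.out = 6), n = 10)
  expect_equal(predict_agb_tot(pm, 200000), 200000)
  pm$alpha <- 2; pm$beta <- 0.5
  expect_equal(predict_agb_tot(pm, 10000), 200)
  n_vals <- seq(5, 100, by = 5)
  gm <- fit_generic_model(lapply(n_vals, function(n) {
    list(n = as.integer(n), alpha = 2 * n^-0.3, beta = 0.95)
  }))
  expect_error(predict_agb_tot(gm, 2e5, n = 3), "validity range")
  expect_error(predict_agb_tot(gm, 2e5), "required")
  expect_error(predict_agb_tot(pm, -1), "> 0")
})

test_that("site-wise LOOCV is perfect when all sites share the generating law", {
  tab <- exact_law_table(alpha = 1.4, beta = 0.96)
  res <- loocv_by_site(tab)
  expect_equal(res$by_site$pearson_r, rep(1, 5), tolerance = 1e-9)
  expect_equal(res$mean_bias_abs, 0, tolerance = 1e-9)
  expect_equal(res$mean_bias_signed, 0, tolerance = 1e-9)
})

test_that("a site shifted off the shared law shows the largest LOOCV bias", {
  tab <- exact_law_table()
  shift <- tab$site == "S03"
  tab$agb_tot[shift] <- tab$agb_tot[shift] * 1.5
  res <- loocv_by_site(tab)
  bias <- res$by_site$bias_abs[match(sprintf("S%02d", 1:5),
                                     res$by_site$site)]
  expect_equal(which.max(bias), 3)
  # predictions undershoot a site inflated by x1.5 by roughly 1/3
  expect_equal(res$by_site$bias_abs[res$by_site$site == "S03"],
               1 - 1 / 1.5, tolerance = 0.1)
})

test_that("LOOCV preconditions: 3+ sites, small sites excluded with warning", {
  tab <- exact_law_table(n_sites = 2)
  expect_error(loocv_by_site(tab), "3 sites")
  tab3 <- exact_law_table(n_sites = 3)
  tab3 <- rbind(tab3, data.frame(site = "S99", plot = "p01", n = 20,
                                 agb_topn = 3e5, agb_tot = 4e5))
  expect_warning(res <- loocv_by_site(tab3), "S99")
  expect_false("S99" %in% res$by_site$site)
})

test_that("richness regression recovers exact and noisy site-level lines", {
  df <- data.frame(site = "A", richness_topn = 1:10,
                   species_tot = 2 * (1:10) + 10)
  fit <- suppressWarnings(fit_richness_model(df))  # lm warns on exact fits
  expect_equal(fit$pooled$slope, 2)
  expect_equal(fit$pooled$intercept, 10)
  expect_equal(fit$pooled$r2, 1)

  flat <- data.frame(site = "A", richness_topn = rep(5, 8),
                     species_tot = 100 + (1:8))
  expect_true(fit_richness_model(flat)$pooled$degenerate)

  set.seed(8)
  multi <- do.call(rbind, lapply(1:3, function(s) {
    x <- sample(5:25, 30, replace = TRUE)
    data.frame(site = paste0("S", s), richness_topn = x,
               species_tot = (2 + s) * x + 20 * s + rnorm(30, 0, 1))
  }))
  fit2 <- fit_richness_model(multi)
  expect_equal(fit2$by_site$slope, 2 + 1:3, tolerance = 0.1)
})

test_that("fitted models serialize to JSON with their coefficients", {
  x <- seq(1e5, 6e5, length.out = 12)
  fit <- fit_power_model(x, 1.3 * x^0.95, n = 20)
  js <- jsonlite::fromJSON(model_to_json(fit))
  expect_equal(js$alpha, 1.3, tolerance = 1e-6)
  expect_equal(js$n, 20)
  expect_equal(js$class[1], "power_model")
})
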