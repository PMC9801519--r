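test_that("posterior probabilities and inclusion identities hold exactly", {
  df <- make_table(80, 4, seed = 1, beta = c(0.5, 0.2, 0, 0), noise = 0.7)
  fit <- bma_lm(y ~ x1 + x2 + x3 + x4, df)
  expect_equal(sum(fit$pmp), 1, tolerance = 1e-10)
  expect_equal(sum(fit$model_size_distribution), 1, tolerance = 1e-10)
  # pip_j equals an independent sum of pmp over models containing j
  for (j in 1:4) {
    contains_j <- vapply(fit$models, function(m) j %in% m, logical(1))
    expect_equal(unname(fit$pip[j]), sum(fit$pmp[contains_j]),
                 tolerance = 1e-12)
  }
  # post_mean_j equals the pmp-weighted conditional means
  for (j in 1:4) {
    m1 <- sum(vapply(seq_along(fit$fits), function(i) {
      f <- fit$fits[[i]]
      if (j %in% f$model) fit$pmp[i] * f$coef_mean[match(j, f$model)] else 0
    }, numeric(1)))
    expect_equal(unname(fit$post_mean[j]), m1, tolerance = 1e-12)
  }
})

test_that("permuting covariate columns permutes the summaries identically", {
  df <- make_table(60, 3, seed = 2, beta = c(0.4, -0.3, 0), noise = 0.6)
  f1 <- bma_lm(y ~ x1 + x2 + x3, df)
  f2 <- bma_lm(y ~ x3 + x1 + x2, df)
  perm <- c("x1", "x2", "x3")
  expect_equal(f1$pip[perm], f2$pip[perm], tolerance = 1e-12)
  expect_equal(f1$post_mean[perm], f2$post_mean[perm], tolerance = 1e-12)
  expect_equal(f1$post_sd[perm], f2$post_sd[perm], tolerance = 1e-12)
})

test_that("the null model takes over as the prior scale grows (Lindley-Bartlett)", {
  df <- make_table(100, 3, seed = 3, beta = c(0.3, 0, 0), noise = 0.8)
  null_pmp <- vapply(c(1e2, 1e4, 1e8), function(g) {
    bma_lm(y ~ x1 + x2 + x3, df, g_rule = "fixed", g = g)$pmp[1]
  }, numeric(1))
  expect_true(all(diff(null_pmp) > 0))
  expect_gt(null_pmp[3], 0.99)
})

test_that("coef, predict, fitted and residuals are mutually consistent on the raw scale", {
  df <- make_table(70, 2, seed = 4, beta = c(0.6, 0), noise = 0.5,
                   intercept = 4.7)
  fit <- bma_lm(y ~ x1 + x2, df)
  cf <- coef(fit)
  expect_named(cf, c("(Intercept)", "x1", "x2"))
  manual <- cf[1] + as.matrix(df[c("x1", "x2")]) %*% cf[-1]
  expect_equal(unname(fitted(fit)), unname(drop(manual)), tolerance = 1e-10)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, newdata = df[3:7, ]), fitted(fit)[3:7],
               tolerance = 1e-12)
  expect_equal(residuals(fit), df$y - fitted(fit))
  expect_error(predict(fit, newdata = df["x1"]), "x2")
})

test_that("a study_table can be fit directly and formula terms are validated", {
  tab <- generate_stage(scenario_preset("pure_null", seed = 1, n = 300))
  fit <- bma_lm(data = tab)
  expect_s3_class(fit, "bma_lm")
  expect_equal(fit$s, 5)
  expect_equal(fit$stage_label, "junior")
})

test_that("print, summary and plot methods run and report the fit", {
  df <- make_table(60, 2, seed = 5, beta = c(0.8, 0), noise = 0.5)
  fit <- bma_lm(y ~ x1 + x2, df)
  expect_output(print(fit), "32|4 models|models")
  s <- summary(fit, top_m = 2)
  expect_s3_class(s, "summary.bma_lm")
  expect_equal(nrow(s$top_models), 2)
  expect_output(print(s), "BMA estimation results")
  expect_equal(s$variable_table$variable[1], "x1")   # sorted by PIP
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("simulate draws posterior-predictive outcomes reproducibly", {
  df <- make_table(50, 2, seed = 6, beta = c(0.5, 0), noise = 0.6)
  fit <- bma_lm(y ~ x1 + x2, df)
  s1 <- simulate(fit, nsim = 3, seed = 9)
  s2 <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(50, 3))
  expect_false(identical(s1[[1]], s1[[2]]))
  # noise scale of the draws is in the right ballpark
  expect_equal(sd(s1[[1]]), sd(df$y), tolerance = 0.5)
})

test_that("the optional MC3 cross-check attaches a convergent trace", {
  df <- make_table(100, 3, seed = 7, beta = c(0.5, 0, 0), noise = 0.6)
  fit <- bma_lm(y ~ x1 + x2 + x3, df, mc3 = TRUE,
                mc3_control = mc3_settings(30000, 3000, seed = 4))
  expect_s3_class(fit$trace, "mc3_trace")
  expect_lt(fit$convergence$tv_distance, 0.02)
})
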