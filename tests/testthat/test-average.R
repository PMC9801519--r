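test_that("a variable in one model with pmp 0.5 and conditional mean 0.02 averages to 0.01", {
  ctab <- center_table(study_table(make_table(30, 1, seed = 1), "y"))
  f0 <- gprior_fit(ctab, integer(0))
  f1 <- gprior_fit(ctab, 1L)
  f1$coef_mean[] <- 0.02          # pin the conditional mean for the identity
  res <- bma_average(list(f0, f1), c(0.5, 0.5))
  expect_equal(unname(res$post_mean["x1"]), 0.01)
  expect_equal(unname(res$pip["x1"]), 0.5)
})

test_that("identical duplicated covariates get identical PIPs over their exchangeable models", {
  df <- make_table(40, 2, seed = 2, beta = c(0.5, 0), noise = 0.7)
  df$x2 <- df$x1                  # exact duplicate; the joint model is singular
  ctab <- center_table(study_table(df, "y"))
  fits <- lapply(list(integer(0), 1L, 2L), function(m) gprior_fit(ctab, m))
  pmp <- posterior_model_probs(fits)
  res <- bma_average(fits, pmp)
  expect_equal(unname(res$pip["x1"]), unname(res$pip["x2"]), tolerance = 1e-10)
  expect_equal(unname(res$post_mean["x1"]), unname(res$post_mean["x2"]),
               tolerance = 1e-10)
})

test_that("averaged summaries match an independent brute-force loop over all models", {
  df <- make_table(40, 3, seed = 3, beta = c(0.4, 0, -0.2), noise = 0.8)
  g <- 40
  fit <- bma_lm(y ~ x1 + x2 + x3, df, g_rule = "fixed", g = g)
  oracle <- brute_force_bma(df, "y", g = g)
  expect_equal(fit$pip, oracle$pip, tolerance = 1e-8)
  expect_equal(fit$post_mean, oracle$post_mean, tolerance = 1e-8)
  expect_equal(fit$post_sd, oracle$post_sd, tolerance = 1e-8)
})

test_that("the within-model variance form drops the between-model term", {
  df <- make_table(50, 2, seed = 4, beta = c(0.5, 0.1), noise = 0.6)
  total <- bma_lm(y ~ x1 + x2, df, variance = "total")
  within <- bma_lm(y ~ x1 + x2, df, variance = "within")
  expect_true(all(within$post_sd <= total$post_sd + 1e-12))
  # within form equals the pmp-weighted conditional variances exactly
  wv <- sapply(seq_len(2), function(j) {
    sum(vapply(seq_along(total$fits), function(i) {
      f <- total$fits[[i]]
      if (j %in% f$model) total$pmp[i] * f$coef_var[match(j, f$model)] else 0
    }, numeric(1)))
  })
  expect_equal(unname(within$post_sd^2), wv, tolerance = 1e-12)
})

test_that("a never-included variable has pip 0 and sign consistency 1", {
  ctab <- center_table(study_table(make_table(30, 2, seed = 5), "y"))
  fits <- lapply(list(integer(0), 1L), function(m) gprior_fit(ctab, m))
  res <- bma_average(fits, posterior_model_probs(fits))
  expect_equal(unname(res$pip["x2"]), 0)
  expect_equal(unname(res$sign_consistency["x2"]), 1)
  expect_true(all(res$sign_consistency >= 0 & res$sign_consistency <= 1))
})

test_that("sign consistency approaches 1 for a strong effect", {
  df <- make_table(200, 2, seed = 6, beta = c(1, 0), noise = 0.5)
  fit <- bma_lm(y ~ x1 + x2, df)
  expect_gt(fit$sign_consistency["x1"], 0.999)
})

test_that("mismatched fits and pmp lengths are rejected", {
  ctab <- center_table(study_table(make_table(30, 1, seed = 7), "y"))
  fits <- list(gprior_fit(ctab, integer(0)), gprior_fit(ctab, 1L))
  expect_error(bma_average(fits, c(1, 0, 0)), "lengths differ")
})

test_that("model-size distribution handles point-mass and uniform posteriors", {
  models <- enumerate_models(2)
  expect_equal(unname(model_size_distribution(c(1, 0, 0, 0), models)),
               c(1, 0, 0))
  expect_equal(unname(model_size_distribution(rep(0.25, 4), models)),
               c(0.25, 0.5, 0.25))
  expect_error(model_size_distribution(c(0.5, 0.5), models), "lengths differ")
})

test_that("a strong single effect puts the posterior size mode at 1", {
  tab <- generate_stage(scenario_preset("strong_single", seed = 31))
  fit <- bma_lm(data = tab)
  sizes <- fit$model_size_distribution
  expect_equal(sum(sizes), 1, tolerance = 1e-10)
  expect_equal(names(which.max(sizes)), "1")
})
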