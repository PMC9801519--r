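test_that("all shipped presets are valid scenarios", {
  expect_setequal(scenario_names(),
                  c("junior_paper", "senior_paper", "primary_null",
                    "strong_single", "pure_null"))
  for (nm in scenario_names()) {
    sc <- scenario_preset(nm)
    expect_s3_class(sc, "stage_scenario")
    expect_gt(sc$n, 0)
    expect_true(all(sc$covariates$sd > 0))
  }
  expect_error(scenario_preset("nope"), "unknown preset")
})

test_that("generation is deterministic in the seed and leaves the caller's RNG alone", {
  sc <- scenario_preset("pure_null", seed = 5)
  t1 <- generate_stage(sc, as = "data.frame")
  t2 <- generate_stage(sc, as = "data.frame")
  expect_identical(t1, t2)
  t3 <- generate_stage(scenario_preset("pure_null", seed = 6),
                       as = "data.frame")
  expect_false(identical(t1$acuity, t3$acuity))

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_stage(sc)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a noise-free scenario is exactly linear and recovers the coefficients", {
  covs <- data.frame(name = c("a", "b"), mean = c(5, 10), sd = c(1, 2),
                     support = "positive")
  sc <- stage_scenario("junior", n = 300, covariates = covs,
                       true_beta = c(a = 0.3, b = -0.1),
                       intercept = 4.6, noise_sd = 0, seed = 8)
  df <- generate_stage(sc, as = "data.frame")
  f <- lm(acuity ~ a + b, df)
  expect_equal(unname(coef(f)), c(4.6, 0.3, -0.1), tolerance = 1e-10)
  r2 <- suppressWarnings(summary(f)$r.squared)   # lm warns on perfect fits
  expect_equal(r2, 1, tolerance = 1e-10)
})

test_that("junior preset reproduces the target exercise and outcome moments", {
  df <- generate_stage(scenario_preset("junior_paper", seed = 13),
                       as = "data.frame")
  expect_equal(nrow(df), 8191)
  expect_equal(mean(df$exercise), 2.72, tolerance = 0.05)
  expect_equal(sd(df$exercise), 1.01, tolerance = 0.05)
  expect_equal(sd(df$acuity), 0.61, tolerance = 0.03)
  expect_true(all(df$exercise >= 0 & df$exercise <= 7))
  expect_true(all(df$exercise == round(df$exercise)))
})

test_that("continuous covariate moments stay within three standard errors", {
  df <- generate_stage(scenario_preset("junior_paper", seed = 17),
                       as = "data.frame")
  sc <- scenario_preset("junior_paper")
  for (v in c("bullying", "m_stress", "diet")) {
    spec <- sc$covariates[sc$covariates$name == v, ]
    se <- spec$sd / sqrt(nrow(df))
    expect_lt(abs(mean(df[[v]]) - spec$mean), 3 * se)
  }
})

test_that("infeasible scenario parameters are rejected", {
  covs <- data.frame(name = "exercise", mean = 9, sd = 1, support = "days07")
  expect_error(stage_scenario("junior", 100, covs, c(exercise = 0),
                              4.6, 0.6), "infeasible mean")
  covs2 <- data.frame(name = "a", mean = 5, sd = -1, support = "positive")
  expect_error(stage_scenario("junior", 100, covs2, c(a = 0), 4.6, 0.6),
               "SDs must be > 0")
  covs3 <- data.frame(name = c("a", "a"), mean = 5, sd = 1,
                      support = "positive")
  expect_error(stage_scenario("junior", 100, covs3, NULL, 4.6, 0.6),
               "unique")
  covs4 <- data.frame(name = "a", mean = 5, sd = 1, support = "positive")
  expect_error(stage_scenario("junior", 100, covs4, c(zz = 1), 4.6, 0.6),
               "zz")
})

test_that("replicates are independent, seeded sequentially and reproducible", {
  sc <- scenario_preset("pure_null", seed = 40, n = 200)
  reps <- replicate_study(sc, 3, base_seed = 40)
  expect_length(reps, 3)
  one <- generate_stage(sc)
  expect_identical(reps[[1]]$outcome, one$outcome)
  sc3 <- sc; sc3$seed <- 42L
  expect_identical(reps[[3]]$outcome, generate_stage(sc3)$outcome)
  expect_false(identical(reps[[1]]$outcome, reps[[2]]$outcome))
  expect_error(replicate_study(sc, 0), "n_reps")
})
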