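test_that("cognitive scores are built per cohort and standardised", {
  panel <- fixture_panel()
  cg <- cognitive_scores(panel)
  expect_equal(nrow(cg), nrow(panel$data))
  cohorts <- sub("_.*$", "", panel$data$group)
  for (ch in unique(cohorts)) {
    v <- cg$cognitive[cohorts == ch]
    expect_lt(abs(mean(v)), 1e-8)
    expect_lt(abs(sd(v) - 1), 1e-8)
  }
})

test_that("two-step regression recovers signed skill coefficients", {
  panel <- fixture_panel()
  scores <- fixture_scores()
  covs <- vapply(small_spec()$covariates, `[[`, "", "name")
  f <- two_step_regression(panel, "tried_smoking", covs, "BCS_M",
                           B = 100, seed = 5, refit_measurement = FALSE,
                           scores = scores)
  # generator: externalising lowers smoking, internalising raises it
  expect_lt(f$coefficients["ext"], 0)
  expect_gt(f$coefficients["int"], 0)
  expect_true(all(f$se[c("ext", "int")] > 0))
  expect_equal(f$n, sum(panel$data$group == "BCS_M"))

  # same seed reproduces the bootstrap SEs exactly
  f2 <- two_step_regression(panel, "tried_smoking", covs, "BCS_M",
                            B = 100, seed = 5, refit_measurement = FALSE,
                            scores = scores)
  expect_identical(f$se, f2$se)
  expect_error(two_step_regression(panel, "nope", covs, "BCS_M", B = 100),
               "not present")
})

test_that("estimates track an attenuation oracle from an independent panel", {
  # EBM scores are shrunken, so the regression target is the attenuated
  # coefficient; the oracle is the same two-step estimator on a large
  # independent panel from the same DGP
  covs <- vapply(small_spec()$covariates, `[[`, "", "name")
  run_once <- function(seed, n) {
    spec <- small_spec(n)
    panel <- generate_panel(spec, seed = seed)
    mom <- lapply(spec$groups, function(g) sample_moments(panel, g))
    names(mom) <- spec$groups
    fit <- fit_dwls(build_model(spec$meta, spec$groups,
                                "thresholds_loadings"), mom,
                    compute_robust = FALSE, check_identification = FALSE)
    sc <- ebm_scores(fit, panel)
    two_step_regression(panel, "bmi", covs, "MCS_F", B = 100, seed = seed,
                        refit_measurement = FALSE, scores = sc)
  }
  oracle <- run_once(901, 4000L)
  test_fit <- run_once(902, 1200L)
  z <- abs(test_fit$coefficients["ext"] - oracle$coefficients["ext"]) /
    sqrt(test_fit$se["ext"]^2 + oracle$se["ext"]^2)
  expect_lt(z, 3)
})

test_that("dropping the cognitive column is a pure column toggle", {
  panel <- fixture_panel()
  scores <- fixture_scores()
  covs <- c("mother_educ", "smoked_preg")
  f_no <- two_step_regression(panel, "bmi", covs, "BCS_F", B = 100, seed = 2,
                              refit_measurement = FALSE, scores = scores)
  # removing the cognitive measures entirely must not change the
  # without-cognition specification
  panel2 <- panel
  panel2$data <- panel2$data[setdiff(names(panel2$data),
                                     grep("^cog_", names(panel2$data),
                                          value = TRUE))]
  f_no2 <- two_step_regression(panel2, "bmi", covs, "BCS_F", B = 100,
                               seed = 2, refit_measurement = FALSE,
                               scores = scores)
  expect_equal(f_no$coefficients, f_no2$coefficients)
  f_cg <- two_step_regression(panel, "bmi", covs, "BCS_F", B = 100, seed = 2,
                              refit_measurement = FALSE, scores = scores,
                              include_cognitive = TRUE)
  expect_true("cognitive" %in% names(f_cg$coefficients))
  expect_false("cognitive" %in% names(f_no$coefficients))
})

test_that("coefficient equality testing is paired and calibrated at extremes", {
  panel <- fixture_panel()
  scores <- fixture_scores()
  covs <- c("mother_educ", "smoked_preg")
  fa <- two_step_regression(panel, "bmi", covs, "BCS_M", B = 100, seed = 3,
                            refit_measurement = FALSE, scores = scores)
  fb <- two_step_regression(panel, "bmi", covs, "BCS_F", B = 100, seed = 3,
                            refit_measurement = FALSE, scores = scores)
  # a fit against itself: percentile rule gives p = 1, difference 0
  self <- coefficient_equality_test(fa, fa, "ext", method = "percentile")
  expect_equal(self$p.value, 1)
  expect_equal(self$difference, 0)
  res <- coefficient_equality_test(fa, fb, "ext")
  expect_true(res$p.value >= 0 && res$p.value <= 1)

  # strongly different coefficients are detected
  d <- panel$data
  sc2 <- scores
  y <- 0.1 * sc2$ext + rnorm(nrow(sc2), 0, 0.4)
  y[sc2$group == "BCS_F"] <- 0.6 * sc2$ext[sc2$group == "BCS_F"] +
    rnorm(sum(sc2$group == "BCS_F"), 0, 0.4)
  panel3 <- panel
  panel3$data$ycustom <- y[match(panel3$data$child_id, sc2$child_id)]
  ga <- two_step_regression(panel3, "ycustom", covs, "BCS_M", B = 100,
                            seed = 4, refit_measurement = FALSE,
                            scores = scores)
  gb <- two_step_regression(panel3, "ycustom", covs, "BCS_F", B = 100,
                            seed = 4, refit_measurement = FALSE,
                            scores = scores)
  expect_lt(coefficient_equality_test(ga, gb, "ext")$p.value, 0.05)

  fb_short <- fb; fb_short$replicates <- fb$replicates[1:50, , drop = FALSE]
  expect_error(coefficient_equality_test(fa, fb_short, "ext"), "mismatched")
})

test_that("the measurement-refit bootstrap runs and differs from the fast mode", {
  spec <- small_spec(400L)
  panel <- generate_panel(spec, seed = 61)
  covs <- c("mother_educ", "smoked_preg")
  f <- two_step_regression(panel, "bmi", covs, "BCS_M", B = 100, seed = 6,
                           refit_measurement = TRUE)
  expect_true(all(is.finite(f$se)))
  expect_lte(f$n_dropped, 5)
})
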