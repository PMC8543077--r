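meta11 <- socioemotional_items()
g4 <- c("BCS_M", "BCS_F", "MCS_M", "MCS_F")

test_that("free-parameter counts follow the constraint ladder", {
  # enumeration oracle from the category counts: per group, 11 loadings +
  # sum(K_i - 1) thresholds + 1 factor correlation under the configural model
  n_thr <- sum(meta11$n_categories - 1L)
  expect_equal(n_thr, 19)
  per_group <- 11 + n_thr + 1
  cfg <- build_model(meta11, g4, "configural")
  expect_equal(cfg$npar, 4 * per_group)
  expect_equal(cfg$npar, 124)

  counts <- vapply(c("configural", "thresholds", "thresholds_loadings",
                     "thresholds_loadings_intercepts"), function(l)
                       build_model(meta11, g4, l)$npar, 0L)
  # thresholds level is a reparameterisation of configural (equal count);
  # counts strictly decrease once loadings and intercepts are constrained
  expect_equal(unname(counts[1]), unname(counts[2]))
  expect_true(all(diff(unname(counts[2:4])) < 0))
})

test_that("constraint sets nest along the ladder", {
  for (lev in c("thresholds", "thresholds_loadings",
                "thresholds_loadings_intercepts")) {
    pt <- build_model(meta11, g4, lev)$ptable
    # shared thresholds: each tau parameter id appears once per group
    tau_ids <- pt$free[pt$type == "tau" & pt$free > 0]
    expect_true(all(table(tau_ids) == 4))
  }
  pt <- build_model(meta11, g4, "thresholds_loadings")$ptable
  lam_ids <- pt$free[pt$type == "lambda"]
  expect_true(all(table(lam_ids) == 4))
  # intercepts free only off-reference below the intercept level
  expect_true(all(pt$free[pt$type == "nu" & pt$group == "BCS_M"] == 0))
  expect_true(all(pt$free[pt$type == "nu" & pt$group != "BCS_M"] > 0))
  pt_i <- build_model(meta11, g4, "thresholds_loadings_intercepts")$ptable
  expect_true(all(pt_i$free[pt_i$type == "nu"] == 0))
  expect_true(all(pt_i$free[pt_i$type == "kappa" & pt_i$group != "BCS_M"] > 0))
})

test_that("single-group configural is a plain one-group CFA", {
  ms <- build_model(meta11, "BCS_M", "configural")
  expect_equal(ms$npar, 31)
  expect_true(all(table(ms$ptable$free[ms$ptable$free > 0]) == 1))
})

test_that("anchored parameterisation requires declared reference items", {
  expect_error(build_model(meta11, g4, "configural", "anchored"),
               "reference items")
  expect_error(build_model(meta11, g4, "configural", "anchored",
                           anchor_items = c(1, 2)), "both factors")
  ms <- build_model(meta11, g4, "configural", "anchored",
                    anchor_items = c(1, 7))
  lam1 <- ms$ptable[ms$ptable$type == "lambda" & ms$ptable$item %in% c(1, 7), ]
  expect_true(all(lam1$free == 0) && all(lam1$value == 1))
})

test_that("population moments from a configural-compatible truth fit perfectly", {
  spec <- small_spec(1000L, invariant = TRUE)
  pm <- lapply(g4, function(g) population_moments(spec, g))
  names(pm) <- g4
  fit <- fit_dwls(build_model(meta11, g4, "configural"), pm,
                  compute_robust = FALSE)
  expect_lt(fit$T_dwls, 1e-10)
  # standardised loadings in the reference group equal the generating values
  gp <- group_parameters(fit, "BCS_M")
  expect_lt(max(abs(gp$lambda / gp$sigma - spec$measurement$BCS_M$lambda)),
            1e-6)
})

test_that("delta, theta and anchored configural fits are equivalent", {
  mom <- fixture_moments()
  f_th <- fit_dwls(build_model(meta11, g4, "configural", "theta"), mom)
  f_de <- fit_dwls(build_model(meta11, g4, "configural", "delta"), mom)
  f_an <- fit_dwls(build_model(meta11, g4, "configural", "anchored",
                               anchor_items = c(1, 7)), mom)
  expect_lt(abs(f_th$T_dwls - f_de$T_dwls), 1e-6 * max(1, f_th$T_dwls))
  expect_lt(abs(f_th$T_dwls - f_an$T_dwls), 1e-6 * max(1, f_th$T_dwls))
  expect_lt(max(abs(unlist(f_th$implied) - unlist(f_de$implied))), 1e-6)
  expect_lt(max(abs(unlist(f_th$implied) - unlist(f_an$implied))), 1e-6)
})

test_that("thresholds-only model is statistically equivalent to configural", {
  mom <- fixture_moments()
  f_c <- fit_dwls(build_model(meta11, g4, "configural"), mom)
  f_t <- fit_dwls(build_model(meta11, g4, "thresholds"), mom)
  expect_lt(abs(f_c$T_dwls - f_t$T_dwls), 1e-6 * max(1, f_c$T_dwls))
  expect_lt(abs(f_c$stat - f_t$stat), 1e-4 * max(1, f_c$stat))
})

test_that("unidentified models are caught by the Jacobian rank check", {
  # a one-item factor: its loading and the factor correlation enter every
  # moment only through their product, so the Jacobian is rank-deficient
  keep <- c(1, 2, 7)
  meta3 <- meta11[keep, ]
  meta3$item_id <- 1:3
  ms <- build_model(meta3, "G", "configural")
  mom <- fixture_moments()[["BCS_M"]]
  small <- structure(list(
    group = "G", n = mom$n, meta = meta3,
    thresholds = mom$thresholds[keep],
    rho = mom$rho[keep, keep],
    stats = c(unlist(mom$thresholds[keep]),
              mom$rho[keep, keep][upper.tri(diag(3))]),
    acov = diag(1e-4, 9)), class = "sample_moments")
  expect_error(fit_dwls(ms, list(G = small)), "not identified")
})

test_that("fitting requires moments for every model group", {
  mom <- fixture_moments()
  expect_error(fit_dwls(build_model(meta11, c(g4, "XX"), "configural"),
                        mom), "no sample moments")
})

test_that("scaled difference of a model against itself is zero", {
  mom <- fixture_moments()
  f <- fit_dwls(build_model(meta11, g4, "configural"), mom)
  d <- scaled_chisq_diff(f, f)
  expect_equal(d$stat, 0)
  expect_equal(d$df, 0)
  expect_equal(d$p.value, 1)
})

test_that("misspecification statistic grows linearly with n", {
  # intercept-shifted DGP fitted under full intercept invariance: the scaled
  # statistic's noncentrality should roughly double when n doubles
  stat_at <- function(n, seed) {
    spec <- small_spec(n)
    panel <- generate_panel(spec, seed = seed)
    mom <- lapply(g4, function(g) sample_moments(panel, g))
    names(mom) <- g4
    f <- fit_dwls(build_model(meta11, g4, "thresholds_loadings_intercepts"),
                  mom, check_identification = FALSE)
    c(f$stat, f$df_adj)
  }
  s1 <- stat_at(1500, 61)
  s2 <- stat_at(3000, 62)
  ratio <- (s2[1] - s2[2]) / (s1[1] - s1[2])
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})

test_that("sandwich standard errors track the sampling variation", {
  # single-group configural model: SD of estimates across replications
  # should be close to the mean reported SE
  spec <- small_spec(900L, invariant = TRUE)
  spec$groups <- "BCS_M"; spec$n <- c(BCS_M = 900L)
  spec$measurement <- spec$measurement["BCS_M"]
  spec$beta[] <- 0
  ms <- build_model(meta11, "BCS_M", "configural")
  R <- 200
  est <- matrix(NA_real_, R, ms$npar)
  ses <- matrix(NA_real_, R, ms$npar)
  for (r in seq_len(R)) {
    panel <- generate_panel(spec, seed = 300 + r)
    mom <- list(BCS_M = sample_moments(panel, "BCS_M"))
    f <- fit_dwls(ms, mom, check_identification = FALSE)
    est[r, ] <- f$par
    ses[r, ] <- f$se
  }
  emp_sd <- apply(est, 2, sd)
  mean_se <- colMeans(ses)
  ratio <- emp_sd / mean_se
  expect_true(all(ratio > 0.75 & ratio < 1.25))
})
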