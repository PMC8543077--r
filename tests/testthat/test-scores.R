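test_that("reference-group scores are standardised and finite", {
  sc <- fixture_scores()
  ref <- sc[sc$group == "BCS_M" & sc$converged, ]
  expect_lt(abs(sd(ref$ext) - 1), 1e-6)
  expect_lt(abs(sd(ref$int) - 1), 1e-6)
  expect_lt(abs(mean(ref$ext)), 1e-6)
  expect_true(all(is.finite(sc$ext[sc$converged])))
})

test_that("a symmetric child under symmetric parameters scores near zero", {
  # all-3-category variant so every item has a middle category whose
  # probability is an even function of the latent skill
  spec <- small_spec(400L, invariant = TRUE)
  spec$meta$n_categories[] <- 3L
  for (g in spec$groups) {
    m <- spec$measurement[[g]]
    m$tau <- replicate(11, c(-0.6, 0.6), simplify = FALSE)
    m$Phi <- diag(2)
    m$kappa <- c(0, 0)
    spec$measurement[[g]] <- m
  }
  pm <- lapply(spec$groups, function(g) population_moments(spec, g))
  names(pm) <- spec$groups
  fit <- fit_dwls(build_model(spec$meta, spec$groups, "thresholds_loadings"),
                  pm, check_identification = FALSE)
  rows <- do.call(rbind, lapply(seq_along(spec$groups), function(i) {
    d <- data.frame(child_id = i, group = spec$groups[i])
    for (j in 1:11) d[[paste0("item_", j)]] <- 1L   # middle category
    d
  }))
  panel <- as_item_panel(rows, spec$meta)
  sc <- ebm_scores(fit, panel, standardise = FALSE)
  expect_true(all(abs(sc$ext) < 0.05) && all(abs(sc$int) < 0.05))
})

test_that("scores match the posterior grid maximiser", {
  sc <- fixture_scores()
  panel <- fixture_panel()
  fit <- fixture_loading_fit()
  scl <- attr(sc, "scaling")
  set.seed(12)
  ids <- sample(nrow(panel$data), 25)
  for (id in ids) {
    x <- as.integer(panel$data[id, paste0("item_", 1:11)])
    g <- panel$data$group[id]
    gd <- grid_ebm(fit, panel$meta, x, g)
    raw <- c(sc$ext[id] * scl$sd["ext"] + scl$mean["ext"],
             sc$int[id] * scl$sd["int"] + scl$mean["int"])
    expect_lt(max(abs(raw - gd)), 0.02)
  }
})

test_that("scores recover the generating latent skills", {
  panel <- fixture_panel()
  sc <- fixture_scores()
  th <- attr(panel, "theta")
  expect_gt(cor(sc$ext, th[, 1]), 0.75)
  expect_gt(cor(sc$int, th[, 2]), 0.75)
})

test_that("quantile gaps telescope and reject bad quantiles", {
  sc <- fixture_scores()
  g <- quantile_gaps(sc, "ext")
  for (gr in unique(g$group)) {
    v <- function(s) g$value[g$group == gr & g$statistic == s]
    expect_equal(v("q90-q10"), v("q90-q50") + v("q50-q10"), tolerance = 1e-12)
  }
  expect_error(quantile_gaps(sc, "ext", pairs = list(c(100, 10))),
               "strictly inside")
})

test_that("location shifts leave every dispersion comparison unchanged", {
  sc <- fixture_scores()
  shifted <- sc
  shifted$ext[shifted$group == "MCS_M"] <-
    shifted$ext[shifted$group == "MCS_M"] + 5
  g0 <- quantile_gaps(sc, "ext")
  g1 <- quantile_gaps(shifted, "ext")
  expect_equal(g0$value, g1$value, tolerance = 1e-12)
  # KS between subgroups of the shifted group is unchanged
  m <- sc$ext[sc$group == "MCS_M"]
  half <- seq_along(m) %% 2 == 0
  k0 <- ks_between(m[half], m[!half])
  k1 <- ks_between(m[half] + 5, m[!half] + 5)
  expect_equal(k0$D, k1$D)
  # normalised covariate gap tables are location-free too
  panel <- fixture_panel()
  d0 <- merge(sc, panel$data[c("child_id", "mother_educ")], by = "child_id")
  d1 <- merge(shifted, panel$data[c("child_id", "mother_educ")],
              by = "child_id")
  t0 <- group_gap_table(d0, "mother_educ", 0, B = 100, seed = 4)
  t1 <- group_gap_table(d1, "mother_educ", 0, B = 100, seed = 4)
  expect_equal(t0$gap, t1$gap, tolerance = 1e-12)
})

test_that("bootstrap intervals are deterministic and honest about width", {
  sc <- fixture_scores()
  stat <- function(d) c(gap = unname(
    quantile(d$ext[d$group == "BCS_M"], 0.9) -
      quantile(d$ext[d$group == "BCS_M"], 0.1)))
  b1 <- bootstrap_ci(sc, stat, B = 150, seed = 7, strata = "group")
  b2 <- bootstrap_ci(sc, stat, B = 150, seed = 7, strata = "group")
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$replicates, b2$replicates)
  # a constant statistic has a zero-width interval
  b3 <- bootstrap_ci(sc, function(d) c(k = 1), B = 100, seed = 1)
  expect_equal(unname(diff(b3$ci[1, ])), 0)
})

test_that("KS comparisons behave at the boundaries and match the ECDF oracle", {
  x <- rnorm(300)
  self <- ks_between(x, x)
  expect_equal(self$D, 0)
  expect_equal(self$p.value, 1)
  set.seed(2)
  a <- rnorm(5000); b <- rnorm(5000, 0, 1.5)
  expect_lt(ks_between(a, b)$p.value, 0.001)
  # brute-force max ECDF difference on small samples
  set.seed(3)
  for (r in 1:3) {
    u <- rnorm(150); v <- rnorm(180, 0.3)
    pts <- sort(c(u, v))
    d_oracle <- max(abs(ecdf(u)(pts) - ecdf(v)(pts)))
    expect_equal(ks_between(u, v)$D, d_oracle, tolerance = 1e-12)
  }
  expect_warning(ks_between(rnorm(5), rnorm(50)), "fewer than 10")
})

test_that("covariate gap tables recover generator gradients on true skills", {
  # pass the generator's true latent skills as the scores, so the education
  # gradient is read off without EBM shrinkage
  spec <- small_spec(4000L, invariant = TRUE)
  spec$beta[] <- 0
  spec$beta["mother_educ", ] <- c(0.3, 0.3)
  panel <- generate_panel(spec, seed = 30, keep_latent = TRUE)
  th <- attr(panel, "theta")
  d <- data.frame(child_id = panel$data$child_id, group = panel$data$group,
                  ext = th[, 1], int = th[, 2],
                  mother_educ = panel$data$mother_educ)
  tab <- group_gap_table(d, "mother_educ", 0, value = "ext",
                         B = 200, seed = 5)
  est <- tab[tab$category == "1", ]
  expect_true(all(est$lo < 0.3 & est$hi > 0.3))
  expect_true(all(tab$gap[tab$category == "0"] == 0))
  expect_error(group_gap_table(d, "mother_educ", 9, B = 100), "absent")
})
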