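# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# paper-like spec scaled down to n per group for module tests
small_spec <- function(n = 700L, invariant = FALSE) {
  spec <- default_generator_spec(invariant = invariant)
  spec$n[] <- n
  spec
}

fixture_panel <- function()
  fixture("panel", function()
    generate_panel(small_spec(700L), seed = 101, keep_latent = TRUE))

fixture_moments <- function()
  fixture("moments", function() {
    p <- fixture_panel()
    m <- lapply(p$groups, function(g) sample_moments(p, g, min_n = 100))
    names(m) <- p$groups
    m
  })

fixture_loading_fit <- function()
  fixture("loading_fit", function()
    fit_dwls(build_model(fixture_panel()$meta, fixture_panel()$groups,
                         "thresholds_loadings"),
             fixture_moments(), check_identification = FALSE))

fixture_scores <- function()
  fixture("scores", function()
    ebm_scores(fixture_loading_fit(), fixture_panel()))

# brute-force grid maximiser of the bivariate-normal multinomial likelihood
grid_polychoric <- function(tab, thresholds, step = 0.001) {
  grid <- seq(-0.999, 0.999, by = step)
  nz <- tab > 0
  ll <- vapply(grid, function(r) {
    P <- cohortskills:::bvn_cell_probs(thresholds[[1]], thresholds[[2]], r)
    sum(tab[nz] * log(pmax(P[nz], 1e-300)))
  }, 0)
  grid[which.max(ll)]
}

# brute-force EBM posterior grid maximiser for one child
grid_ebm <- function(fit, meta, x, group, step = 0.01, lim = 4) {
  par <- group_parameters(fit, group)
  fac <- ifelse(meta$factor == "EXT", 1L, 2L)
  grid <- seq(-lim, lim, by = step)
  llf <- function(thf, f) {
    s <- 0
    for (i in which(fac == f)) {
      tv <- c(-Inf, par$tau[[i]], Inf)
      sdp <- sqrt(max(par$psi[i], 1e-6))
      b <- (tv[x[i] + 2] - par$nu[i] - par$lambda[i] * thf) / sdp
      a <- (tv[x[i] + 1] - par$nu[i] - par$lambda[i] * thf) / sdp
      s <- s + log(pmax(pnorm(b) - pnorm(a), 1e-300))
    }
    s
  }
  le <- vapply(grid, llf, 0, f = 1L)
  li <- vapply(grid, llf, 0, f = 2L)
  Pinv <- solve(par$Phi)
  d1 <- grid - par$kappa[1]
  d2 <- grid - par$kappa[2]
  post <- outer(le, li, "+") -
    0.5 * (Pinv[1, 1] * outer(d1^2, rep(1, length(grid))) +
             Pinv[2, 2] * outer(rep(1, length(grid)), d2^2) +
             2 * Pinv[1, 2] * outer(d1, d2))
  ix <- which(post == max(post), arr.ind = TRUE)[1, ]
  c(grid[ix[1]], grid[ix[2]])
}
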