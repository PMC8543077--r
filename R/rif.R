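#' Recentered influence function values
#'
#' Per-observation RIF of a distributional statistic. For a quantile
#' \eqn{q_\tau}: \eqn{RIF_i = q_\tau + (\tau - 1\{y_i \le q_\tau\})/\hat f(q_\tau)}
#' with a kernel density estimate at the quantile; for a quantile gap, the
#' difference of the two quantile RIFs; for the variance,
#' \eqn{RIF_i = (y_i - \bar y)^2}. The sample (weighted) mean of the RIF
#' equals the statistic.
#'
#' @param y numeric outcomes.
#' @param statistic `"variance"` or `"qHI-qLO"` (e.g. `"q90-q10"`).
#' @param weights optional non-negative observation weights.
#' @param kernel `"gaussian"` or `"epanechnikov"` for the density at the
#'   quantile.
#' @param bw bandwidth; default Silverman's rule on the (weighted) sample.
#' @param density_floor error if the density estimate falls below this.
#' @return numeric vector of RIF values.
#' @export
rif_values <- function(y, statistic, weights = NULL,
                       kernel = c("gaussian", "epanechnikov"), bw = NULL,
                       density_floor = 1e-6) {
  kernel <- match.arg(kernel)
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (statistic == "variance") {
    mu <- weighted.mean(y, weights)
    return((y - mu)^2)
  }
  taus <- parse_quantile_statistic(statistic)
  if (n < 100) stop("quantile RIFs need n >= 100 for density estimation")
  if (is.null(bw)) bw <- silverman_bw(y, weights)
  rif_q <- function(tau) {
    q <- weighted_quantile(y, weights, tau)
    f <- kernel_density_at(y, weights, q, bw, kernel)
    if (f < density_floor)
      stop("density too thin at quantile ", tau, " (f = ",
           format(f, digits = 3), ")")
    q + (tau - (y <= q)) / f
  }
  rif_q(taus[1]) - rif_q(taus[2])
}

parse_quantile_statistic <- function(statistic) {
  m <- regmatches(statistic,
                  regexec("^q([0-9]+)-q([0-9]+)$", statistic))[[1]]
  if (length(m) != 3)
    stop("unknown statistic '", statistic,
         "'; use 'variance' or 'qHI-qLO' like 'q90-q10'")
  taus <- as.numeric(m[2:3]) / 100
  if (any(taus <= 0) || any(taus >= 1)) stop("quantiles must lie in (0, 1)")
  taus
}

weighted_quantile <- function(y, w, tau) {
  if (all(w == w[1])) return(quantile(y, tau, type = 7, names = FALSE))
  o <- order(y)
  ys <- y[o]; ws <- w[o]
  cp <- (cumsum(ws) - 0.5 * ws) / sum(ws)
  approx(cp, ys, xout = tau, rule = 2)$y
}

silverman_bw <- function(y, w) {
  sw <- sum(w)
  mu <- weighted.mean(y, w)
  s <- sqrt(sum(w * (y - mu)^2) / sw)
  q <- c(weighted_quantile(y, w, 0.25), weighted_quantile(y, w, 0.75))
  n_eff <- sw^2 / sum(w^2)
  0.9 * min(s, (q[2] - q[1]) / 1.34) * n_eff^(-1/5)
}

kernel_density_at <- function(y, w, at, bw, kernel) {
  u <- (at - y) / bw
  kv <- if (kernel == "gaussian") dnorm(u)
  else 0.75 * pmax(1 - u^2, 0)
  sum(w * kv) / (sum(w) * bw)
}

#' Logit reweighting towards a target group's covariate distribution
#'
#' Fits a logit of target-group membership on the covariates over the pooled
#' two-group sample and returns, for each source observation, a weight
#' proportional to the propensity odds \eqn{p(x)/(1-p(x))}, normalised so the
#' weights sum to the source sample size. Reweighted source covariate means
#' then match the target's (the defining balance property). Propensities are
#' trimmed into \[0.01, 0.99\]; trimming more than 2% warns.
#'
#' @param X data frame or matrix of covariates (pooled, both groups).
#' @param group vector of group labels aligned with `X`.
#' @param source,target the two group labels; weights are for `source` rows.
#' @param trim propensity trimming bounds.
#' @return numeric weight vector of length `sum(group == source)`, with
#'   attributes `n_trimmed` and `propensity_model`.
#' @export
reweight <- function(X, group, source, target, trim = c(0.01, 0.99)) {
  X <- as.data.frame(X)
  keep <- group %in% c(source, target)
  X <- X[keep, , drop = FALSE]
  group <- group[keep]
  d <- cbind(.target = as.integer(group == target), X)
  fit <- suppressWarnings(glm(.target ~ ., data = d, family = binomial()))
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE))
    stop("propensity logit did not converge (possible perfect separation)")
  p <- fitted(fit)
  n_trim <- sum(p < trim[1] | p > trim[2])
  if (n_trim > 0.02 * length(p))
    warning(n_trim, " of ", length(p),
            " propensities trimmed to [", trim[1], ", ", trim[2], "]")
  p <- pmin(pmax(p, trim[1]), trim[2])
  is_src <- group == source
  w <- (p / (1 - p))[is_src]
  w <- w * sum(is_src) / sum(w)
  structure(w, n_trimmed = n_trim, propensity_model = coef(fit))
}

#' Reweighted RIF Oaxaca-Blinder decomposition of a distributional change
#'
#' Two-stage decomposition of the change in a distributional statistic
#' between a source group (e.g. the earlier cohort) and a target group: a
#' logit-reweighted counterfactual (source reweighted to the target's
#' covariate distribution) splits the total change into a composition and a
#' coefficient effect; RIF regressions then split each into per-covariate
#' contributions, with a specification error (for the composition stage) and
#' a reweighting error (for the coefficient stage) as diagnostics:
#' \deqn{\Delta = \underbrace{(\bar X_C - \bar X_0)'\beta_0}_{composition}
#'  + \underbrace{\bar X_C'(\beta_C - \beta_0)}_{spec.\ error}
#'  + \underbrace{\bar X_1'(\beta_1 - \beta_C)}_{coefficient}
#'  + \underbrace{(\bar X_1 - \bar X_C)'\beta_C}_{rew.\ error},}
#' which adds up exactly (the total is the difference in mean RIF). The
#' source group's coefficients are the reference coefficients for the
#' composition split.
#'
#' @param data data frame with the outcome, a group column and covariates.
#' @param outcome outcome column name (a score).
#' @param group group column name.
#' @param source,target the two group labels (change measured target minus
#'   source).
#' @param covariates character vector of covariate column names.
#' @param statistic `"variance"` or `"qHI-qLO"`.
#' @param kernel,bw passed to [rif_values()].
#' @return object of class `rif_decomposition`: components `total`,
#'   `composition`, `spec_error`, `coefficient`, `reweight_error`; `detail`
#'   (per-covariate contributions, including the intercept row for the
#'   coefficient part); `balance` diagnostics; `weights`.
#' @export
rif_decompose <- function(data, outcome, group, source, target, covariates,
                          statistic = "q90-q10",
                          kernel = "gaussian", bw = NULL) {
  miss <- setdiff(c(outcome, group, covariates), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d0 <- data[data[[group]] == source, , drop = FALSE]
  d1 <- data[data[[group]] == target, , drop = FALSE]
  if (!nrow(d0) || !nrow(d1)) stop("both groups must be present")

  Xf <- function(d) {
    M <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(lapply(d[covariates], as.numeric))))
    colnames(M) <- c("(Intercept)", covariates)
    M
  }
  X0 <- Xf(d0); X1 <- Xf(d1)
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) {
    dep <- colnames(X0)[qrX$pivot[(qrX$rank + 1):ncol(X0)]]
    stop("collinear covariates: ", paste(dep, collapse = ", "))
  }

  w <- reweight(rbind(d0[covariates], d1[covariates]),
                c(rep(source, nrow(d0)), rep(target, nrow(d1))),
                source, target)

  y0 <- d0[[outcome]]; y1 <- d1[[outcome]]
  r0 <- rif_values(y0, statistic, kernel = kernel, bw = bw)
  r1 <- rif_values(y1, statistic, kernel = kernel, bw = bw)
  rC <- rif_values(y0, statistic, weights = w, kernel = kernel, bw = bw)

  b0 <- qr.coef(qrX, r0)
  bC <- lm.wfit(X0, rC, w)$coefficients
  b1 <- qr.coef(qr(X1), r1)

  xb0 <- colMeans(X0)
  xb1 <- colMeans(X1)
  xbC <- colSums(X0 * w) / sum(w)

  comp_detail <- (xbC - xb0) * b0
  coef_detail <- xb1 * (b1 - bC)
  composition <- sum(comp_detail)
  spec_error <- sum(xbC * (bC - b0))
  coefficient <- sum(coef_detail)
  reweight_error <- sum((xb1 - xbC) * bC)
  total <- sum(xb1 * b1) - sum(xb0 * b0)   # = mean RIF difference

  balance <- data.frame(
    covariate = covariates,
    source_mean = xb0[covariates],
    target_mean = xb1[covariates],
    reweighted_mean = xbC[covariates],
    row.names = NULL)

  structure(list(statistic = statistic, source = source, target = target,
                 total = total, composition = composition,
                 spec_error = spec_error, coefficient = coefficient,
                 reweight_error = reweight_error,
                 detail = data.frame(covariate = names(b0),
                                     composition = unname(comp_detail),
                                     coefficient = unname(coef_detail)),
                 balance = balance, weights = w),
            class = "rif_decomposition")
}

#' @export
print.rif_decomposition <- function(x, ...) {
  cat("<rif_decomposition> ", x$statistic, ": ", x$source, " -> ", x$target,
      "\n", sep = "")
  v <- c(total = x$total, composition = x$composition,
         spec_error = x$spec_error, coefficient = x$coefficient,
         reweight_error = x$reweight_error)
  print(round(v, 4))
  invisible(x)
}

#' Bootstrap the entire RIF decomposition
#'
#' Resamples children within group and re-runs reweighting, RIF estimation
#' and the Oaxaca-Blinder split on each replicate; returns SEs and percentile
#' p-values (two-sided, sign-based) per component.
#'
#' @inheritParams rif_decompose
#' @param B replications (>= 100).
#' @param seed seed.
#' @return list: `estimate` (the full-sample `rif_decomposition`), `se`,
#'   `p.value`, `replicates`.
#' @export
bootstrap_decomposition <- function(data, outcome, group, source, target,
                                    covariates, statistic = "q90-q10",
                                    B = 500, seed = 1, kernel = "gaussian") {
  stopifnot(B >= 100)
  est <- rif_decompose(data, outcome, group, source, target, covariates,
                       statistic, kernel = kernel)
  stat_fn <- function(d) {
    r <- rif_decompose(d, outcome, group, source, target, covariates,
                       statistic, kernel = kernel)
    c(total = r$total, composition = r$composition,
      spec_error = r$spec_error, coefficient = r$coefficient,
      reweight_error = r$reweight_error)
  }
  bs <- bootstrap_ci(data, stat_fn, B = B, seed = seed, strata = group)
  pv <- vapply(colnames(bs$replicates), function(cn) {
    r <- bs$replicates[, cn]
    r <- r[is.finite(r)]
    min(1, 2 * min(mean(r <= 0), mean(r >= 0)))
  }, 0)
  list(estimate = est, se = bs$se, p.value = pv, replicates = bs$replicates,
       ci = bs$ci)
}
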