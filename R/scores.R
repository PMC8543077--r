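#' Empirical Bayes Modal factor scores
#'
#' For each child, the score is the posterior mode of the latent skills
#' \eqn{\theta = (\theta_{EXT}, \theta_{INT})}: the maximiser of the ordinal
#' probit likelihood of the child's responses, given their group's
#' measurement parameters, times the group's normal factor prior
#' \eqn{N(\kappa_g, \Phi_g)}. Group-specific intercepts and factor
#' covariances are used (intercepts are not assumed invariant). Scores are
#' reported in reference-group standard deviation units: the reference
#' group's scores are centred and scaled to mean 0, SD 1, and every other
#' group is transformed with the same constants.
#'
#' @param fit a converged `mi_fit` (typically at the threshold+loading
#'   invariance level).
#' @param panel an `item_panel`; its groups must all appear in the fit.
#' @param reference reference group for standardisation (default: the model
#'   spec's reference).
#' @param standardise divide by the reference group's score SD (and centre at
#'   its mean).
#' @return a `score_set` data frame: `child_id`, `group`, `ext`, `int`,
#'   `converged`; attributes `scaling` (reference mean/sd used).
#' @export
ebm_scores <- function(fit, panel, reference = NULL, standardise = TRUE) {
  stopifnot(inherits(fit, "mi_fit"))
  if (!fit$converged) stop("measurement model fit has not converged")
  groups <- unique(panel$data$group)
  extra <- setdiff(groups, fit$spec$groups)
  if (length(extra))
    stop("panel group(s) not in the fitted model: ",
         paste(extra, collapse = ", "))
  if (is.null(reference)) reference <- fit$spec$reference
  meta <- panel$meta
  cols <- item_cols(meta)
  fac <- ifelse(meta$factor == "EXT", 1L, 2L)
  J <- nrow(meta)

  score_one_group <- function(g, X) {
    par <- group_parameters(fit, g)
    sdpsi <- sqrt(pmax(par$psi, 1e-6))
    Phinv <- solve(par$Phi)
    # per item, per category: bounds (a, b) on the latent response scale
    bounds <- lapply(seq_len(J), function(i) {
      tv <- c(-Inf, par$tau[[i]], Inf)
      cbind(a = tv[-length(tv)], b = tv[-1])
    })
    neg_post <- function(th, x) {
      z <- par$nu + par$lambda * th[fac]
      lp <- 0
      for (i in seq_len(J)) {
        s <- x[i] + 1L
        b <- (bounds[[i]][s, 2] - z[i]) / sdpsi[i]
        a <- (bounds[[i]][s, 1] - z[i]) / sdpsi[i]
        lp <- lp + log(pmax(pnorm(b) - pnorm(a), 1e-300))
      }
      dev <- th - par$kappa
      -(lp - 0.5 * sum(dev * (Phinv %*% dev)))
    }
    # d log p_i / d theta_f = -(lambda_i/sd_i) (phi(b) - phi(a)) / p_i
    neg_grad <- function(th, x) {
      z <- par$nu + par$lambda * th[fac]
      glp <- -as.vector(Phinv %*% (th - par$kappa))
      for (i in seq_len(J)) {
        s <- x[i] + 1L
        b <- (bounds[[i]][s, 2] - z[i]) / sdpsi[i]
        a <- (bounds[[i]][s, 1] - z[i]) / sdpsi[i]
        p <- pmax(pnorm(b) - pnorm(a), 1e-300)
        glp[fac[i]] <- glp[fac[i]] -
          (par$lambda[i] / sdpsi[i]) * (dnorm(b) - dnorm(a)) / p
      }
      -glp
    }
    # deduplicate response patterns, then damped Newton on all patterns at
    # once (the ordinal-probit log-posterior is concave in theta)
    key <- apply(X, 1, paste, collapse = ",")
    ux <- X[!duplicated(key), , drop = FALSE]
    ukey <- key[!duplicated(key)]
    m_pat <- nrow(ux)
    th <- matrix(rep(par$kappa, each = m_pat), m_pat, 2)
    conv <- rep(FALSE, m_pat)
    lo_b <- lapply(seq_len(J), function(i) bounds[[i]][ux[, i] + 1L, 1])
    hi_b <- lapply(seq_len(J), function(i) bounds[[i]][ux[, i] + 1L, 2])
    for (iter in seq_len(100)) {
      g1 <- -t(Phinv %*% (t(th) - par$kappa))       # m x 2 prior gradient
      h11 <- rep(-Phinv[1, 1], m_pat)
      h22 <- rep(-Phinv[2, 2], m_pat)
      h12 <- rep(-Phinv[1, 2], m_pat)
      for (i in seq_len(J)) {
        z <- par$nu[i] + par$lambda[i] * th[, fac[i]]
        b <- (hi_b[[i]] - z) / sdpsi[i]
        a <- (lo_b[[i]] - z) / sdpsi[i]
        p <- pmax(pnorm(b) - pnorm(a), 1e-300)
        db <- dnorm(b); da <- dnorm(a)
        r1 <- (db - da) / p
        gi <- -(par$lambda[i] / sdpsi[i]) * r1
        bphib <- ifelse(is.finite(b), b * db, 0)
        aphia <- ifelse(is.finite(a), a * da, 0)
        hi <- -(par$lambda[i] / sdpsi[i])^2 * ((bphib - aphia) / p + r1^2)
        if (fac[i] == 1L) { g1[, 1] <- g1[, 1] + gi; h11 <- h11 + hi }
        else { g1[, 2] <- g1[, 2] + gi; h22 <- h22 + hi }
      }
      gmax <- pmax(abs(g1[, 1]), abs(g1[, 2]))
      conv <- gmax < 1e-9
      if (all(conv)) break
      det <- h11 * h22 - h12^2
      det[abs(det) < 1e-12] <- -1e-12
      step1 <- (h22 * g1[, 1] - h12 * g1[, 2]) / det
      step2 <- (h11 * g1[, 2] - h12 * g1[, 1]) / det
      damp <- if (iter <= 3) 0.8 else 1
      # cap steps to keep the iteration inside a sane region
      step1 <- pmin(pmax(-step1 * damp, -1.5), 1.5)
      step2 <- pmin(pmax(-step2 * damp, -1.5), 1.5)
      upd <- !conv
      th[upd, 1] <- th[upd, 1] + step1[upd]
      th[upd, 2] <- th[upd, 2] + step2[upd]
    }
    # fallback: per-pattern BFGS for anything Newton left unconverged
    for (r in which(!conv)) {
      o <- tryCatch(
        optim(par$kappa, neg_post, gr = neg_grad, x = ux[r, ],
              method = "BFGS", control = list(maxit = 200, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(o) && o$convergence == 0 && all(is.finite(o$par))) {
        th[r, ] <- o$par
        conv[r] <- TRUE
      } else th[r, ] <- NA_real_
    }
    m <- match(key, ukey)
    list(theta = th[m, , drop = FALSE], converged = conv[m])
  }

  out <- list()
  for (g in groups) {
    sub <- panel$data[panel$data$group == g, , drop = FALSE]
    X <- as.matrix(sub[cols])
    sc <- score_one_group(g, X)
    out[[g]] <- data.frame(child_id = sub$child_id, group = g,
                           ext = sc$theta[, 1], int = sc$theta[, 2],
                           converged = sc$converged,
                           stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, out)
  rownames(scores) <- NULL

  scaling <- list(mean = c(ext = 0, int = 0), sd = c(ext = 1, int = 1))
  if (standardise) {
    if (!reference %in% scores$group)
      stop("reference group ", reference, " has no scores to standardise on")
    ref <- scores[scores$group == reference & scores$converged, ]
    scaling$mean <- c(ext = mean(ref$ext), int = mean(ref$int))
    scaling$sd <- c(ext = sd(ref$ext), int = sd(ref$int))
    scores$ext <- (scores$ext - scaling$mean["ext"]) / scaling$sd["ext"]
    scores$int <- (scores$int - scaling$mean["int"]) / scaling$sd["int"]
  }
  structure(scores, scaling = scaling, reference = reference,
            class = c("score_set", "data.frame"))
}

#' Quantile gaps of score distributions by group
#'
#' Sample-quantile differences (linear-interpolation quantiles, the common
#' default convention) for the requested percentile pairs, plus the variance,
#' per group.
#'
#' @param scores a `score_set` or data frame with `group` and score columns.
#' @param value score column to analyse (`"ext"` or `"int"`).
#' @param pairs list of percentile pairs `c(hi, lo)` in percent.
#' @param min_n smallest admissible group size.
#' @return data frame: `group`, `statistic` (e.g. `"q90-q10"`, `"variance"`),
#'   `value`.
#' @export
quantile_gaps <- function(scores, value = "ext",
                          pairs = list(c(90, 10), c(75, 25), c(50, 10),
                                       c(90, 50)),
                          min_n = 50) {
  for (pr in pairs)
    if (any(pr <= 0) || any(pr >= 100))
      stop("quantiles must lie strictly inside (0, 100)")
  out <- list()
  for (g in unique(scores$group)) {
    y <- scores[[value]][scores$group == g]
    y <- y[is.finite(y)]
    if (length(y) < min_n)
      stop("group ", g, " has fewer than ", min_n, " scores")
    for (pr in pairs) {
      q <- quantile(y, probs = pr / 100, type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, statistic = paste0("q", pr[1], "-q", pr[2]),
        value = q[1] - q[2])
    }
    out[[length(out) + 1L]] <- data.frame(group = g, statistic = "variance",
                                          value = var(y))
  }
  do.call(rbind, out)
}

#' Stratified nonparametric bootstrap percentile intervals
#'
#' Resamples rows with replacement (within strata when given), applies the
#' statistic, and returns percentile intervals, bootstrap SEs and the
#' replicate matrix. Deterministic given the seed. Replicates on which the
#' statistic fails are dropped and counted; more than 1% failures is an
#' error.
#'
#' @param data data frame of resampling units (children).
#' @param statistic function of a data frame returning a named numeric
#'   vector.
#' @param B number of replications (>= 100).
#' @param seed integer seed.
#' @param strata optional column name to stratify resampling on.
#' @param level confidence level.
#' @return list: `estimate`, `ci` (matrix lo/hi), `se`, `replicates`,
#'   `n_failed`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000, seed = 1, strata = NULL,
                         level = 0.95) {
  stopifnot(B >= 100)
  est <- statistic(data)
  idx_by <- if (is.null(strata)) list(seq_len(nrow(data)))
    else split(seq_len(nrow(data)), data[[strata]])
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  reps <- matrix(NA_real_, B, length(est))
  colnames(reps) <- names(est)
  failed <- 0L
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    r <- tryCatch(statistic(data[take, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(r) || length(r) != length(est) || any(!is.finite(r)))
      failed <- failed + 1L
    else reps[b, ] <- r
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (failed > 0.01 * B)
    stop("bootstrap failed on ", failed, " of ", B, " replicates")
  a <- (1 - level) / 2
  ci <- t(apply(reps, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  colnames(ci) <- c("lo", "hi")
  list(estimate = est, ci = ci,
       se = apply(reps, 2, sd, na.rm = TRUE),
       replicates = reps, n_failed = failed)
}

#' Two-sample Kolmogorov-Smirnov comparison of score distributions
#'
#' @param a,b numeric score vectors for the two groups.
#' @return list with `D` and `p.value` (asymptotic; exact when either sample
#'   has fewer than 10 observations, with a warning).
#' @export
ks_between <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  small <- min(length(a), length(b)) < 10
  if (small)
    warning("fewer than 10 observations; exact small-sample p-value used")
  kt <- suppressWarnings(ks.test(a, b, exact = if (small) TRUE else NULL))
  list(D = unname(kt$statistic), p.value = kt$p.value)
}

#' Mean score gaps by covariate category, normalised to a reference category
#'
#' Within each group, the mean score per category of a categorical covariate
#' is reported relative to the reference category (whose gap is 0 by
#' construction), with stratified bootstrap intervals. Absolute cross-group
#' score levels are never reported: when intercept invariance fails, score
#' locations are not comparable across cohorts, but within-group gradients
#' are.
#'
#' @param scores a `score_set` merged with covariates (must contain `group`,
#'   the score column and the covariate column).
#' @param covariate covariate column name (categorical).
#' @param reference_category category to normalise to.
#' @param value score column.
#' @param B bootstrap replications.
#' @param seed seed.
#' @return data frame: `group`, `category`, `gap`, `lo`, `hi`.
#' @export
group_gap_table <- function(scores, covariate, reference_category,
                            value = "ext", B = 200, seed = 1) {
  out <- list()
  for (g in unique(scores$group)) {
    sub <- scores[scores$group == g, , drop = FALSE]
    cats <- unique(as.character(sub[[covariate]]))
    if (!as.character(reference_category) %in% cats)
      stop("reference category '", reference_category,
           "' absent in group ", g)
    stat <- function(d) {
      mref <- mean(d[[value]][d[[covariate]] == reference_category])
      vapply(cats, function(cc)
        mean(d[[value]][d[[covariate]] == cc]) - mref, 0)
    }
    bs <- bootstrap_ci(sub, stat, B = max(B, 100), seed = seed)
    out[[g]] <- data.frame(group = g, category = cats,
                           gap = unname(bs$estimate),
                           lo = unname(bs$ci[, "lo"]),
                           hi = unname(bs$ci[, "hi"]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
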