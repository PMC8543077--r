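#' Build a constrained multiple-group ordinal factor model
#'
#' Constructs the parameter table of a two-factor congeneric ordinal factor
#' model (items 1-6 on EXT, 7-11 on INT) at one of the invariance levels of
#' the ladder, with the identification normalisations of the Wu-Estabrook
#' scheme:
#'
#' * `configural`: loadings and thresholds free per group; all groups have
#'   factor means 0, factor variances 1, intercepts 0 and unit scales
#'   (theta: unit error variances; delta: unit latent-response variances;
#'   anchored: marker loadings fixed to 1 with free factor covariance).
#' * `thresholds`: thresholds equal across groups; intercepts and (for
#'   3-category items) latent-response scales freed in non-reference groups.
#'   Statistically equivalent to the configural model when items have at most
#'   3 categories.
#' * `thresholds_loadings`: loadings also equal; full factor covariance,
#'   intercepts and scales freed in non-reference groups. Licenses
#'   cross-group comparison of latent variances.
#' * `thresholds_loadings_intercepts`: intercepts fixed to zero in every
#'   group; factor means freed in non-reference groups. Licenses comparison
#'   of latent means as well.
#'
#' @param meta item metadata.
#' @param groups character vector of groups (>= 2 for cross-group levels).
#' @param level invariance level, see above.
#' @param parameterisation `"theta"`, `"delta"` or `"anchored"`
#'   (configural only; higher levels use the reference-group delta scheme).
#' @param reference reference group label.
#' @param anchor_items integer vector of two item ids (EXT, INT markers),
#'   required for the anchored parameterisation.
#' @return object of class `mi_model_spec` with the explicit parameter table
#'   (`ptable`), free-parameter count (`npar`) and bookkeeping for the
#'   implied-moment map.
#' @export
build_model <- function(meta, groups,
                        level = c("configural", "thresholds",
                                  "thresholds_loadings",
                                  "thresholds_loadings_intercepts",
                                  "baseline"),
                        parameterisation = c("theta", "delta", "anchored"),
                        reference = groups[1], anchor_items = NULL) {
  level <- match.arg(level)
  parameterisation <- match.arg(parameterisation)
  validate_item_meta(meta)
  stopifnot(reference %in% groups)
  if (level != "configural" && level != "baseline" && length(groups) < 2)
    stop("invariance requires >= 2 groups")
  if (parameterisation == "anchored") {
    if (level != "configural")
      stop("anchored parameterisation is only offered for the configural model")
    if (is.null(anchor_items) || length(anchor_items) != 2)
      stop("anchored parameterisation needs two declared reference items ",
           "(one per factor)")
    af <- meta$factor[match(anchor_items, meta$item_id)]
    if (!setequal(af, c("EXT", "INT")))
      stop("anchor items must cover both factors")
  }

  J <- nrow(meta)
  rows <- list()
  pid <- 0L
  newpar <- function() { pid <<- pid + 1L; pid }
  add <- function(group, type, item, sub, free, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, type = type, item = item, sub = sub,
      free = free, value = value, stringsAsFactors = FALSE)

  # deterministic, slightly varied start values avoid symmetric degeneracies
  lam_start <- 0.55 + 0.015 * seq_len(J)
  tau_start <- lapply(seq_len(J), function(i)
    if (meta$n_categories[i] == 3) c(-1, 0.2) else -0.6)

  shared_tau <- level %in% c("thresholds", "thresholds_loadings",
                             "thresholds_loadings_intercepts")
  shared_lam <- level %in% c("thresholds_loadings",
                             "thresholds_loadings_intercepts")
  tau_ids <- if (shared_tau)
    lapply(seq_len(J), function(i)
      vapply(seq_len(meta$n_categories[i] - 1L), function(s) newpar(), 0L))
  lam_ids <- if (shared_lam) vapply(seq_len(J), function(i) newpar(), 0L)

  for (g in groups) {
    is_ref <- identical(g, reference)
    for (i in seq_len(J)) {
      # loadings
      if (level == "baseline") {
        add(g, "lambda", i, 1L, 0L, 0)
      } else if (shared_lam) {
        add(g, "lambda", i, 1L, lam_ids[i], lam_start[i])
      } else if (parameterisation == "anchored" && meta$item_id[i] %in% anchor_items) {
        add(g, "lambda", i, 1L, 0L, 1)
      } else {
        add(g, "lambda", i, 1L, newpar(), lam_start[i])
      }
      # thresholds
      for (s in seq_len(meta$n_categories[i] - 1L))
        add(g, "tau", i, s, if (shared_tau) tau_ids[[i]][s] else newpar(),
            tau_start[[i]][s])
      # intercepts
      nu_free <- !is_ref && level %in% c("thresholds", "thresholds_loadings")
      add(g, "nu", i, 1L, if (nu_free) newpar() else 0L, 0)
      # latent-response scale: one row per item, either psi- or sigma-type
      if (level == "configural" && parameterisation == "theta") {
        add(g, "psi", i, 1L, 0L, 1)
      } else {
        sig_free <- !is_ref &&
          ((level == "thresholds" && meta$n_categories[i] == 3L) ||
             level %in% c("thresholds_loadings",
                          "thresholds_loadings_intercepts"))
        add(g, "sigma", i, 1L, if (sig_free) newpar() else 0L, 1)
      }
    }
    # factor means
    kap_free <- !is_ref && level == "thresholds_loadings_intercepts"
    add(g, "kappa", NA_integer_, 1L, if (kap_free) newpar() else 0L, 0)
    add(g, "kappa", NA_integer_, 2L, if (kap_free) newpar() else 0L, 0)
    # factor covariance: sub 1 = var EXT, 2 = var INT, 3 = covariance
    phi_diag_free <- if (level == "baseline") FALSE
      else if (level %in% c("configural", "thresholds"))
        parameterisation == "anchored"
      else !is_ref
    add(g, "phi", NA_integer_, 1L, if (phi_diag_free) newpar() else 0L,
        if (parameterisation == "anchored") 0.36 else 1)
    add(g, "phi", NA_integer_, 2L, if (phi_diag_free) newpar() else 0L,
        if (parameterisation == "anchored") 0.36 else 1)
    cov_free <- level != "baseline"
    add(g, "phi", NA_integer_, 3L, if (cov_free) newpar() else 0L,
        if (parameterisation == "anchored") 0.15
        else if (cov_free) 0.4 else 0)
  }

  ptable <- do.call(rbind, rows)
  out <- structure(list(meta = meta, groups = groups, reference = reference,
                        level = level, parameterisation = parameterisation,
                        anchor_items = anchor_items,
                        ptable = ptable, npar = pid),
                   class = "mi_model_spec")
  out$layout <- compile_layout(out)
  out
}

# precompiled integer indices into ptable$value for fast implied moments
compile_layout <- function(mspec) {
  pt <- mspec$ptable
  meta <- mspec$meta
  J <- nrow(meta)
  fac <- ifelse(meta$factor == "EXT", 1L, 2L)
  pairs <- pair_index(J)
  lapply(setNames(mspec$groups, mspec$groups), function(g) {
    ing <- pt$group == g
    byi <- function(type) {
      r <- which(ing & pt$type == type)
      r[order(pt$item[r])]
    }
    tau_rows <- which(ing & pt$type == "tau")
    tau_rows <- tau_rows[order(pt$item[tau_rows], pt$sub[tau_rows])]
    list(
      lambda = byi("lambda"), nu = byi("nu"),
      kappa = {r <- which(ing & pt$type == "kappa"); r[order(pt$sub[r])]},
      phi = {r <- which(ing & pt$type == "phi"); r[order(pt$sub[r])]},
      scale = if (any(ing & pt$type == "psi")) byi("psi") else byi("sigma"),
      scale_is_psi = any(ing & pt$type == "psi"),
      tau = tau_rows,
      tau_item = rep(seq_len(J), meta$n_categories - 1L),
      fac = fac, pairs = pairs)
  })
}

#' @export
print.mi_model_spec <- function(x, ...) {
  cat("<mi_model_spec> level ", x$level, " (", x$parameterisation,
      "), ", length(x$groups), " groups, ", x$npar, " free parameters\n",
      sep = "")
  invisible(x)
}

# start-value vector from the parameter table (first occurrence per id)
start_values <- function(mspec) {
  pt <- mspec$ptable
  p <- numeric(mspec$npar)
  for (id in seq_len(mspec$npar))
    p[id] <- pt$value[match(id, pt$free)]
  p
}

# substitute free values into the table's value column
fill_values <- function(mspec, p) {
  pt <- mspec$ptable
  sel <- pt$free > 0L
  pt$value[sel] <- p[pt$free[sel]]
  pt
}

# model-implied stacked statistics (thresholds then correlations) per group
implied_stats <- function(mspec, p) {
  v <- mspec$ptable$value
  sel <- mspec$ptable$free > 0L
  v[sel] <- p[mspec$ptable$free[sel]]
  out <- list()
  for (g in mspec$groups) {
    L <- mspec$layout[[g]]
    lam <- v[L$lambda]
    nu <- v[L$nu]
    kap <- v[L$kappa]
    phv <- v[L$phi]                       # var EXT, var INT, covariance
    phi_diag <- phv[1:2]
    fac <- L$fac
    lvar <- lam^2 * phi_diag[fac]
    sig <- if (L$scale_is_psi) sqrt(pmax(lvar + v[L$scale], 1e-10))
    else pmax(v[L$scale], 1e-6)
    mu <- nu + lam * kap[fac]
    taus <- (v[L$tau] - mu[L$tau_item]) / sig[L$tau_item]
    i1 <- L$pairs[, 1]; i2 <- L$pairs[, 2]
    phi_of <- function(f1, f2) ifelse(f1 == f2, phi_diag[f1], phv[3])
    rr <- lam[i1] * lam[i2] * phi_of(fac[i1], fac[i2]) / (sig[i1] * sig[i2])
    out[[g]] <- c(taus, rr)
  }
  out
}

# stacked implied vector across groups
implied_vector <- function(mspec, p)
  unlist(implied_stats(mspec, p), use.names = FALSE)

# finite-difference Jacobian of the implied-moment map
implied_jacobian <- function(mspec, p, h = 1e-6) {
  f0 <- implied_vector(mspec, p)
  Jm <- matrix(0, length(f0), length(p))
  for (k in seq_along(p)) {
    hk <- h * max(1, abs(p[k]))
    pp <- p; pp[k] <- pp[k] + hk
    pm <- p; pm[k] <- pm[k] - hk
    Jm[, k] <- (implied_vector(mspec, pp) - implied_vector(mspec, pm)) / (2 * hk)
  }
  Jm
}

#' Fit a multiple-group ordinal factor model by diagonally weighted least squares
#'
#' Minimises \eqn{\sum_c (s_c - \sigma_c(p))' \mathrm{diag}(W_c)^{-1}
#' (s_c - \sigma_c(p))} where \eqn{s_c} stacks the group's estimated
#' thresholds and polychoric correlations and \eqn{W_c} is its full
#' asymptotic covariance matrix, by Levenberg-Marquardt on the weighted
#' residual vector. The full weight matrix is then used for sandwich standard
#' errors and the mean-and-variance-adjusted (WLSMV) test statistic.
#'
#' @param mspec a `mi_model_spec` from [build_model()].
#' @param moments named list of `sample_moments`, one per model group.
#' @param compute_robust compute the scaled statistic, adjusted df and robust
#'   SEs (requires the full asymptotic covariance; disable for speed in inner
#'   bootstrap loops).
#' @param check_identification verify the Jacobian of the implied-moment map
#'   has full column rank at the start values.
#' @param start optional start values overriding the defaults.
#' @return object of class `mi_fit`.
#' @export
fit_dwls <- function(mspec, moments, compute_robust = TRUE,
                     check_identification = TRUE, start = NULL) {
  stopifnot(inherits(mspec, "mi_model_spec"))
  missing_g <- setdiff(mspec$groups, names(moments))
  if (length(missing_g))
    stop("no sample moments for group(s): ", paste(missing_g, collapse = ", "))
  moments <- moments[mspec$groups]

  s <- unlist(lapply(moments, `[[`, "stats"), use.names = FALSE)
  w <- unlist(lapply(moments, function(m) pmax(diag(m$acov), 1e-12)),
              use.names = FALSE)
  sw <- sqrt(w)
  stat_names <- unlist(lapply(moments, function(m)
    paste0(m$group, ".", names(m$stats))), use.names = FALSE)

  p0 <- if (is.null(start)) start_values(mspec) else start
  # seed shared/free thresholds with observed values (reference group first)
  pt <- mspec$ptable
  for (g in rev(mspec$groups)) {      # reference last so it wins for shared ids
    m <- moments[[g]]
    tsub <- which(pt$group == g & pt$type == "tau" & pt$free > 0L)
    for (r in tsub)
      p0[pt$free[r]] <- m$thresholds[[pt$item[r]]][pt$sub[r]]
  }
  gref <- mspec$reference
  tsub <- which(pt$group == gref & pt$type == "tau" & pt$free > 0L)
  for (r in tsub)
    p0[pt$free[r]] <- moments[[gref]]$thresholds[[pt$item[r]]][pt$sub[r]]

  if (mspec$npar > 0 && check_identification) {
    J0 <- implied_jacobian(mspec, p0)
    qrJ <- qr(J0 / sw)
    if (qrJ$rank < mspec$npar) {
      null_ids <- sort(qrJ$pivot[(qrJ$rank + 1):mspec$npar])
      stop("model not identified: Jacobian rank ", qrJ$rank, " < ",
           mspec$npar, " free parameters; deficient directions involve ",
           "parameter id(s) ", paste(null_ids, collapse = ", "))
    }
  }

  resid_fn <- function(p) (implied_vector(mspec, p) - s) / sw

  solve_from <- function(p_start) {
    lm_fit <- minpack.lm::nls.lm(
      par = p_start, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-14, ptol = 1e-12, gtol = 1e-12))
    if (!lm_fit$info %in% 1:4)
      stop("DWLS optimisation did not converge (nls.lm info = ", lm_fit$info,
           ", message: ", lm_fit$message, ")")
    lm_fit$par
  }
  # relative gradient criterion: |g_k| scaled by the curvature and objective
  grel_at <- function(p_hat, r_hat, Jac) {
    if (mspec$npar == 0) return(0)
    grad <- -2 * crossprod(Jac / sw, r_hat)
    gscale <- pmax(2 * sqrt(colSums((Jac / sw)^2) * max(sum(r_hat^2), 1)), 1)
    max(abs(grad) / gscale)
  }

  if (mspec$npar > 0) {
    p_hat <- solve_from(p0)
    r_hat <- resid_fn(p_hat)
    Jac <- implied_jacobian(mspec, p_hat)
    grel <- grel_at(p_hat, r_hat, Jac)
    restarts <- 0L
    while (grel >= 1e-4 && restarts < 2L) {   # polish with a fresh trust region
      restarts <- restarts + 1L
      p_hat <- solve_from(p_hat)
      r_hat <- resid_fn(p_hat)
      Jac <- implied_jacobian(mspec, p_hat)
      grel <- grel_at(p_hat, r_hat, Jac)
    }
  } else {
    p_hat <- numeric(0)
    r_hat <- resid_fn(p_hat)
    Jac <- matrix(0, length(s), 0)
    grel <- 0
  }
  T_dwls <- sum(r_hat^2)
  grad <- if (mspec$npar > 0) -2 * crossprod(Jac / sw, r_hat) else numeric(0)
  gnorm <- if (length(grad)) max(abs(grad)) else 0
  converged <- grel < 1e-4

  n_total <- sum(vapply(moments, `[[`, 0, "n"))
  fit <- list(spec = mspec, par = p_hat, T_dwls = T_dwls,
              df = length(s) - mspec$npar,
              residuals = setNames(implied_vector(mspec, p_hat) - s,
                                   stat_names),
              stat_names = stat_names, s = s, w = w,
              gradient_norm = gnorm, gradient_rel = grel,
              converged = converged,
              n = vapply(moments, `[[`, 0, "n"), n_total = n_total,
              implied = implied_stats(mspec, p_hat))
  class(fit) <- "mi_fit"

  if (compute_robust) fit <- robust_test(fit, moments, Jac = Jac)
  fit
}

#' Robust (mean-and-variance-adjusted) test statistic and sandwich SEs
#'
#' Uses the full asymptotic covariance matrix \eqn{\Gamma} of the stacked
#' sample statistics: the DWLS discrepancy is asymptotically a mixture
#' \eqn{\sum \alpha_i z_i^2} with \eqn{\alpha_i} the eigenvalues of
#' \eqn{U\Gamma}; matching its first two moments to a scaled chi-square gives
#' the WLSMV statistic `stat` with fractional `df`. Standard errors are
#' sandwich-corrected.
#'
#' @param fit a `mi_fit`.
#' @param moments the `sample_moments` list used in fitting.
#' @param Jac optionally, a precomputed Jacobian at the estimate.
#' @return the fit, augmented with `stat`, `df_adj`, `scaling`, `p.value`,
#'   `se`, `U`, `Gamma`, `Delta`.
#' @export
robust_test <- function(fit, moments, Jac = NULL) {
  stopifnot(inherits(fit, "mi_fit"))
  moments <- moments[fit$spec$groups]
  if (is.null(Jac))
    Jac <- if (fit$spec$npar > 0) implied_jacobian(fit$spec, fit$par) else
      matrix(0, length(fit$s), 0)
  Gamma <- as.matrix(Matrix_bdiag(lapply(moments, `[[`, "acov")))
  ev_min <- min(eigen(Gamma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(diag(Gamma)))
    stop("full weight matrix is not positive semi-definite ",
         "(moment estimation failure)")
  Winv <- 1 / fit$w
  if (fit$spec$npar > 0) {
    A <- crossprod(Jac, Jac * Winv)            # Delta' W^-1 Delta
    Ainv <- solve(A)
    WD <- Jac * Winv                           # W^-1 Delta
    U <- diag(Winv) - WD %*% Ainv %*% t(WD)
    # sandwich covariance of the estimates
    Vcov <- Ainv %*% crossprod(WD, Gamma %*% WD) %*% Ainv
    se <- sqrt(pmax(diag(Vcov), 0))
  } else {
    U <- diag(Winv)
    Vcov <- matrix(0, 0, 0)
    se <- numeric(0)
  }
  M <- U %*% Gamma
  tr1 <- sum(diag(M))
  tr2 <- sum(M * t(M))
  if (fit$df == 0 || tr1 <= 0 || tr2 <= 0) {
    stat <- 0; df_adj <- 0; scaling <- NA_real_; pval <- 1
  } else {
    scaling <- tr2 / tr1
    df_adj <- tr1^2 / tr2
    stat <- fit$T_dwls / scaling
    pval <- pchisq(stat, df_adj, lower.tail = FALSE)
  }
  fit$stat <- stat
  fit$df_adj <- df_adj
  fit$scaling <- scaling
  fit$p.value <- pval
  fit$se <- se
  fit$vcov <- Vcov
  fit$U <- U
  fit$Gamma <- Gamma
  fit$Delta <- Jac
  fit
}

Matrix_bdiag <- function(mats) {
  ns <- vapply(mats, nrow, 0L)
  N <- sum(ns)
  out <- matrix(0, N, N)
  at <- 0L
  for (m in mats) {
    idx <- at + seq_len(nrow(m))
    out[idx, idx] <- m
    at <- at + nrow(m)
  }
  out
}

#' Scaled chi-square difference test between nested DWLS fits
#'
#' Mean-and-variance-adjusted difference statistic computed from the
#' difference of the two models' residual-weight operators; the plain
#' (unscaled) difference is reported alongside.
#'
#' @param fit_restricted,fit_full nested `mi_fit`s on identical moments.
#' @return list with `stat`, `df`, `p.value`, `raw_diff`.
#' @export
scaled_chisq_diff <- function(fit_restricted, fit_full) {
  if (!isTRUE(all.equal(fit_restricted$s, fit_full$s)))
    stop("models were fitted to different moment sets")
  Md <- (fit_restricted$U - fit_full$U) %*% fit_restricted$Gamma
  tr1 <- sum(diag(Md))
  tr2 <- sum(Md * t(Md))
  raw <- fit_restricted$T_dwls - fit_full$T_dwls
  if (tr1 <= 1e-10 || tr2 <= 1e-12)
    return(list(stat = 0, df = 0, p.value = 1, raw_diff = raw))
  df_d <- tr1^2 / tr2
  stat <- max(raw, 0) / (tr2 / tr1)
  list(stat = stat, df = df_d,
       p.value = pchisq(stat, df_d, lower.tail = FALSE), raw_diff = raw)
}

#' Extract per-group measurement parameters from a fitted model
#'
#' Returns the group's loadings, intercepts, thresholds, factor mean, factor
#' covariance, latent-response scales and implied error variances on the
#' latent-response metric (the scale on which scores are estimated).
#'
#' @param fit a `mi_fit`.
#' @param group group label.
#' @return list with `lambda`, `nu`, `tau`, `kappa`, `Phi`, `sigma`, `psi`.
#' @export
group_parameters <- function(fit, group) {
  mspec <- fit$spec
  stopifnot(group %in% mspec$groups)
  pt <- fill_values(mspec, fit$par)
  sub <- pt[pt$group == group, ]
  meta <- mspec$meta
  J <- nrow(meta)
  fac <- ifelse(meta$factor == "EXT", 1L, 2L)
  lam <- sub$value[sub$type == "lambda"][order(sub$item[sub$type == "lambda"])]
  nu <- sub$value[sub$type == "nu"][order(sub$item[sub$type == "nu"])]
  kap <- sub$value[sub$type == "kappa"][order(sub$sub[sub$type == "kappa"])]
  phv <- sub$value[sub$type == "phi"][order(sub$sub[sub$type == "phi"])]
  Phi <- matrix(c(phv[1], phv[3], phv[3], phv[2]), 2, 2)
  lvar <- lam^2 * diag(Phi)[fac]
  if (any(sub$type == "psi")) {
    psi <- sub$value[sub$type == "psi"][order(sub$item[sub$type == "psi"])]
    sig <- sqrt(lvar + psi)
  } else {
    sig <- sub$value[sub$type == "sigma"][order(sub$item[sub$type == "sigma"])]
    psi <- sig^2 - lvar
  }
  tsub <- sub[sub$type == "tau", ]
  tau <- lapply(seq_len(J), function(i)
    tsub$value[tsub$item == i][order(tsub$sub[tsub$item == i])])
  list(lambda = lam, nu = nu, tau = tau, kappa = kap, Phi = Phi,
       sigma = sig, psi = psi)
}

#' Tidy parameter table of a fitted model
#'
#' @param fit a `mi_fit`.
#' @return data frame with columns `group`, `type`, `item`, `sub`,
#'   `estimate`, `se` (NA for fixed parameters), `free`.
#' @export
parameter_table <- function(fit) {
  pt <- fill_values(fit$spec, fit$par)
  se <- rep(NA_real_, nrow(pt))
  if (!is.null(fit$se) && length(fit$se))
    se[pt$free > 0L] <- fit$se[pt$free[pt$free > 0L]]
  data.frame(group = pt$group, type = pt$type, item = pt$item, sub = pt$sub,
             estimate = pt$value, se = se, free = pt$free > 0L)
}

#' @export
print.mi_fit <- function(x, ...) {
  cat("<mi_fit> level ", x$spec$level, ", groups ",
      length(x$spec$groups), ", npar ", x$spec$npar,
      ", df ", x$df, "\n", sep = "")
  cat("  DWLS discrepancy ", format(x$T_dwls, digits = 6), sep = "")
  if (!is.null(x$stat))
    cat("; scaled statistic ", format(x$stat, digits = 6),
        " on ", format(x$df_adj, digits = 4), " adjusted df (p = ",
        format(x$p.value, digits = 3), ")", sep = "")
  cat("\n  converged: ", x$converged,
      " (gradient max ", format(x$gradient_norm, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Population moments implied by a generator specification
#'
#' Analytic thresholds and latent-response correlations for one group of a
#' `generator_spec` (no sampling noise), packaged like [sample_moments()]
#' with an identity asymptotic covariance scaled by `acov_scale`. Useful for
#' perfect-fit and equivalence checks.
#'
#' @param spec a `generator_spec`.
#' @param group group label.
#' @param n nominal sample size to attach.
#' @param acov_scale diagonal value of the nominal asymptotic covariance.
#' @return a `sample_moments` object.
#' @export
population_moments <- function(spec, group, n = 1e6, acov_scale = 1e-4) {
  meta <- spec$meta
  m <- spec$measurement[[group]]
  J <- nrow(meta)
  fac <- ifelse(meta$factor == "EXT", 1L, 2L)
  lvar <- m$lambda^2 * diag(m$Phi)[fac]
  sig <- sqrt(lvar + m$psi)
  mu <- m$nu + m$lambda * m$kappa[fac]
  taus <- lapply(seq_len(J), function(i) (m$tau[[i]] - mu[i]) / sig[i])
  pairs <- pair_index(J)
  rho_mat <- diag(J)
  rho_vec <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- m$lambda[i] * m$lambda[j] * m$Phi[fac[i], fac[j]] / (sig[i] * sig[j])
    rho_vec[p] <- r
    rho_mat[i, j] <- rho_mat[j, i] <- r
  }
  th_names <- unlist(lapply(seq_len(J), function(i)
    paste0("tau_", meta$item_id[i], "_", seq_len(meta$n_categories[i] - 1L))))
  rho_names <- apply(pairs, 1, function(ij)
    paste0("rho_", meta$item_id[ij[1]], "_", meta$item_id[ij[2]]))
  stats <- c(unlist(taus), rho_vec)
  names(stats) <- c(th_names, rho_names)
  acov <- diag(acov_scale, length(stats))
  dimnames(acov) <- list(names(stats), names(stats))
  structure(list(group = group, n = n, thresholds = taus, rho = rho_mat,
                 stats = stats, acov = acov, meta = meta,
                 near_singular = setNames(logical(nrow(pairs)), rho_names)),
            class = "sample_moments")
}
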