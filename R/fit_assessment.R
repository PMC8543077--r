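#' Default cutoff configuration for invariance decisions
#'
#' A rejection is flagged when any enabled cutoff trips relative to the
#' configural model: a drop in CFI of 0.010 or more, a rise in RMSEA of
#' 0.010 or more (the categorical-data rule; the laxer 0.015 continuous-data
#' rule can be set instead), or a rise in SRMR of 0.010 or more. All values
#' are configuration, not constants.
#'
#' @param cfi,rmsea,srmr cutoffs (set a component to `NA` to disable it).
#' @return named list of cutoffs.
#' @export
invariance_cutoffs <- function(cfi = 0.010, rmsea = 0.010, srmr = 0.010) {
  list(cfi = cfi, rmsea = rmsea, srmr = srmr)
}

#' Approximate fit indices for a fitted model
#'
#' CFI, TLI, RMSEA (with 90% CI), SRMR, McDonald's noncentrality index (MFI)
#' and Gamma-hat, computed from the scaled (mean-and-variance-adjusted)
#' statistic and its adjusted degrees of freedom. The baseline is the
#' independence model (free thresholds, zero loadings) on the same moments.
#'
#' @param fit a `mi_fit` with robust statistics.
#' @param baseline the independence-model `mi_fit` on the same moments.
#' @return named list of indices; `cfi`/`tli` are `NA` with
#'   `baseline_degenerate = TRUE` when the baseline statistic does not exceed
#'   its df.
#' @export
afi <- function(fit, baseline) {
  stopifnot(inherits(fit, "mi_fit"), !is.null(fit$stat))
  T_ <- fit$stat; df <- fit$df_adj
  Tb <- baseline$stat; dfb <- baseline$df_adj
  n <- fit$n_total
  d <- max(T_ - df, 0)
  db <- max(Tb - dfb, 0)
  degenerate <- Tb <= dfb
  cfi <- if (degenerate) NA_real_ else 1 - d / max(d, db)
  tli <- if (degenerate || df == 0) NA_real_ else
    ((Tb / dfb) - (T_ / df)) / ((Tb / dfb) - 1)
  rmsea <- if (df > 0) sqrt(max((T_ - df) / (df * (n - 1)), 0)) else 0
  rmsea_ci <- rmsea_interval(T_, df, n)
  # SRMR over the correlation residuals (already on a standardised metric)
  corr_idx <- grepl("\\.rho_", fit$stat_names)
  srmr <- sqrt(mean(fit$residuals[corr_idx]^2))
  mfi <- exp(-0.5 * d / n)
  J <- nrow(fit$spec$meta)
  gamma_hat <- J / (J + 2 * d / (n - 1))
  list(chisq = T_, df = df, pvalue = fit$p.value,
       cfi = cfi, tli = tli, rmsea = rmsea,
       rmsea_lo = rmsea_ci[1], rmsea_hi = rmsea_ci[2],
       srmr = srmr, mfi = mfi, gamma_hat = gamma_hat,
       baseline_degenerate = degenerate)
}

# 90% RMSEA confidence interval via noncentrality inversion
rmsea_interval <- function(T_, df, n) {
  if (df <= 0 || !is.finite(T_)) return(c(NA_real_, NA_real_))
  ncp_root <- function(prob) {
    if (pchisq(T_, df, ncp = 0) < prob) return(0)
    hi <- max(T_ * 2, df * 2, 10)
    while (pchisq(T_, df, ncp = hi) > prob) hi <- hi * 2
    uniroot(function(nc) pchisq(T_, df, ncp = nc) - prob,
            c(0, hi), tol = 1e-8)$root
  }
  lo <- ncp_root(0.95)
  hi <- ncp_root(0.05)
  sqrt(pmax(c(lo, hi) / (df * (n - 1)), 0))
}

#' Compare nested invariance models against the configural model
#'
#' Builds the delta-AFI table and renders the per-level decision: a level is
#' flagged "rejected" when any enabled cutoff trips. The decision is a pure
#' function of the delta table and the cutoff configuration.
#'
#' @param afis named list of AFI lists (from [afi()]); must include
#'   `"configural"`.
#' @param cutoffs cutoff configuration, see [invariance_cutoffs()].
#' @return data frame with one row per non-configural level: deltas and a
#'   logical `rejected`.
#' @export
compare_nested <- function(afis, cutoffs = invariance_cutoffs()) {
  stopifnot("configural" %in% names(afis), length(afis) >= 2)
  base <- afis$configural
  lv <- setdiff(names(afis), "configural")
  out <- do.call(rbind, lapply(lv, function(l) {
    a <- afis[[l]]
    d_cfi <- a$cfi - base$cfi
    d_rmsea <- a$rmsea - base$rmsea
    d_srmr <- a$srmr - base$srmr
    rejected <-
      (!is.na(cutoffs$cfi) && !is.na(d_cfi) && d_cfi <= -cutoffs$cfi) ||
      (!is.na(cutoffs$rmsea) && d_rmsea >= cutoffs$rmsea) ||
      (!is.na(cutoffs$srmr) && d_srmr >= cutoffs$srmr)
    data.frame(level = l, d_cfi = d_cfi, d_rmsea = d_rmsea, d_srmr = d_srmr,
               rejected = rejected, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the measurement-invariance ladder
#'
#' Estimates sample moments per group, fits the independence baseline and the
#' four nested invariance levels, computes AFIs and delta decisions, and
#' reports the highest invariance level attained (walking up from
#' `thresholds` while no cutoff trips). A failed member marks the ladder
#' incomplete; partial results are returned.
#'
#' @param panel an `item_panel`.
#' @param meta item metadata (defaults to the panel's).
#' @param groups groups to include (default: all panel groups).
#' @param reference reference group (default: first group).
#' @param cutoffs decision cutoffs, see [invariance_cutoffs()].
#' @param min_n group-size floor passed to [sample_moments()].
#' @param moments optionally, precomputed `sample_moments` list (skips the
#'   polychoric stage).
#' @return object of class `invariance_ladder`: `fits`, `afis`, `delta`
#'   (decision table), `highest_level`, `scaled_diffs`, `complete`,
#'   `mean_comparisons_permitted`.
#' @export
run_ladder <- function(panel, meta = NULL, groups = NULL, reference = NULL,
                       cutoffs = invariance_cutoffs(), min_n = 200,
                       moments = NULL) {
  if (is.null(meta)) meta <- panel$meta
  if (is.null(groups)) groups <- panel$groups
  if (length(groups) < 2) stop("invariance requires >= 2 groups")
  if (is.null(reference)) reference <- groups[1]
  if (is.null(moments)) {
    moments <- lapply(groups, function(g) sample_moments(panel, g, min_n))
    names(moments) <- groups
  }
  levels <- c("configural", "thresholds", "thresholds_loadings",
              "thresholds_loadings_intercepts")
  fits <- list(); afis <- list(); complete <- TRUE
  base_fit <- fit_dwls(build_model(meta, groups, "baseline",
                                   reference = reference),
                       moments, check_identification = FALSE)
  prev_T <- -Inf
  for (lev in levels) {
    f <- tryCatch(
      fit_dwls(build_model(meta, groups, lev, reference = reference),
               moments, check_identification = FALSE),
      error = function(e) e)
    if (inherits(f, "error") || !f$converged) {
      warning("ladder incomplete: ", lev, " did not converge")
      complete <- FALSE
      break
    }
    # constraint supersets imply a non-decreasing minimised discrepancy
    if (f$T_dwls < prev_T - 1e-6 * max(1, prev_T))
      warning("discrepancy decreased from the previous (less constrained) ",
              "level at ", lev, "; check convergence")
    prev_T <- max(prev_T, f$T_dwls)
    fits[[lev]] <- f
    afis[[lev]] <- afi(f, base_fit)
  }
  delta <- if (length(afis) >= 2) compare_nested(afis, cutoffs) else NULL
  highest <- "configural"
  if (!is.null(delta)) {
    for (lev in levels[-1]) {
      row <- delta[delta$level == lev, ]
      if (nrow(row) == 0 || row$rejected) break
      highest <- lev
    }
  }
  sdiffs <- list()
  for (lev in intersect(levels[-1], names(fits)))
    sdiffs[[lev]] <- scaled_chisq_diff(fits[[lev]], fits$configural)
  structure(list(fits = fits, baseline = base_fit, afis = afis,
                 delta = delta, scaled_diffs = sdiffs,
                 highest_level = highest, complete = complete,
                 cutoffs = cutoffs, groups = groups, reference = reference,
                 moments = moments,
                 mean_comparisons_permitted =
                   highest == "thresholds_loadings_intercepts",
                 variance_comparisons_permitted =
                   highest %in% c("thresholds_loadings",
                                  "thresholds_loadings_intercepts")),
            class = "invariance_ladder")
}

#' @export
print.invariance_ladder <- function(x, ...) {
  cat("<invariance_ladder> groups:", paste(x$groups, collapse = ", "),
      "(reference", paste0(x$reference, ")"), "\n")
  print(ladder_summary(x), digits = 4)
  cat("highest level attained:", x$highest_level, "\n")
  cat(if (x$mean_comparisons_permitted)
    "latent MEAN comparisons permitted\n"
    else "latent MEAN comparisons refused (intercept invariance not attained)\n")
  cat(if (x$variance_comparisons_permitted)
    "latent VARIANCE comparisons permitted\n"
    else "latent VARIANCE comparisons refused\n")
  invisible(x)
}

#' One-row-per-model summary of a ladder
#'
#' @param ladder an `invariance_ladder`.
#' @return data frame: level, scaled chi-square, adjusted df, p, CFI, TLI,
#'   RMSEA, SRMR, MFI, Gamma-hat.
#' @export
ladder_summary <- function(ladder) {
  do.call(rbind, lapply(names(ladder$afis), function(l) {
    a <- ladder$afis[[l]]
    data.frame(level = l, chisq = a$chisq, df = a$df, p = a$pvalue,
               cfi = a$cfi, tli = a$tli, rmsea = a$rmsea, srmr = a$srmr,
               mfi = a$mfi, gamma_hat = a$gamma_hat,
               stringsAsFactors = FALSE)
  }))
}
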