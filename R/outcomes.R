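#' Per-cohort one-factor cognitive scores
#'
#' Aggregates the panel's continuous cognitive measures into a single factor
#' score per child, separately by cohort: a one-factor ULS extraction on the
#' within-cohort correlation matrix of the standardised measures, scored by
#' the regression (Thomson) method and standardised within cohort. Cognitive
#' scores are deliberately NOT comparable across cohorts (each cohort's
#' battery and scale are its own).
#'
#' @param panel an `item_panel` whose data contain `cog_*` columns.
#' @param cohort_of function mapping a group label to its cohort label
#'   (default: the prefix before the underscore, e.g. `"BCS_M"` -> `"BCS"`).
#' @return data frame `child_id`, `cognitive` (within-cohort standardised).
#' @export
cognitive_scores <- function(panel,
                             cohort_of = function(g) sub("_.*$", "", g)) {
  cogcols <- grep("^cog_", names(panel$data), value = TRUE)
  if (length(cogcols) < 2)
    stop("panel has fewer than 2 cognitive measure columns (cog_*)")
  cohorts <- vapply(as.character(panel$data$group), cohort_of, "")
  out <- data.frame(child_id = panel$data$child_id,
                    cognitive = NA_real_)
  for (ch in unique(cohorts)) {
    sel <- cohorts == ch
    Z <- scale(as.matrix(panel$data[sel, cogcols]))
    R <- cor(Z)
    e <- eigen(R, symmetric = TRUE)
    # one-factor ULS via the first principal factor with iterated communalities
    h <- rep(0.5, ncol(R))
    for (it in 1:50) {
      Rh <- R; diag(Rh) <- h
      e <- eigen(Rh, symmetric = TRUE)
      L <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
      hn <- pmin(L^2, 0.995)
      if (max(abs(hn - h)) < 1e-8) break
      h <- hn
    }
    sc <- as.vector(Z %*% solve(R, L))       # Thomson regression scores
    out$cognitive[sel] <- as.vector(scale(sc))
  }
  out
}

#' Two-step outcome regression with measurement-stage bootstrap
#'
#' Regresses a later outcome on the estimated externalising and
#' internalising scores (optionally plus the cognitive score) and covariates,
#' within one group, by least squares (binary outcomes are run as linear
#' probability models). Standard errors come from a bootstrap in which every
#' replicate resamples children within all groups, re-fits the multi-group
#' measurement model, re-scores, and re-runs the regression — so the factor
#' estimation stage's uncertainty is carried into the SEs. Replicates whose
#' measurement stage fails are dropped and counted.
#'
#' @param panel an `item_panel` with outcome and covariate columns.
#' @param outcome outcome column name.
#' @param covariates covariate column names.
#' @param group group whose regression is wanted.
#' @param include_cognitive add the per-cohort cognitive score regressor.
#' @param level invariance level of the measurement model used for scoring.
#' @param B bootstrap replications (>= 100).
#' @param seed seed.
#' @param refit_measurement if `FALSE`, the bootstrap resamples scores
#'   without re-fitting the measurement model (fast approximation).
#' @param scores optionally, precomputed full-sample scores.
#' @param fit optionally, a precomputed full-sample measurement fit.
#' @return object of class `outcome_fit`: `coefficients`, `se` (bootstrap),
#'   `replicates`, `n`, `adj_r_squared`, `outcome`, `group`.
#' @export
two_step_regression <- function(panel, outcome, covariates, group,
                                include_cognitive = FALSE,
                                level = "thresholds_loadings",
                                B = 200, seed = 1,
                                refit_measurement = TRUE,
                                scores = NULL, fit = NULL) {
  stopifnot(B >= 100)
  if (!outcome %in% names(panel$data)) stop("outcome not present: ", outcome)
  groups <- panel$groups
  meta <- panel$meta

  fit_and_score <- function(pan) {
    mom <- lapply(groups, function(g) sample_moments(pan, g, min_n = 50))
    names(mom) <- groups
    f <- fit_dwls(build_model(meta, groups, level), mom,
                  compute_robust = FALSE, check_identification = FALSE)
    ebm_scores(f, pan)
  }

  regress <- function(pan, sc) {
    d <- pan$data[pan$data$group == group, , drop = FALSE]
    d <- merge(d, sc[c("child_id", "ext", "int", "converged")],
               by = "child_id")
    regs <- c("ext", "int")
    if (include_cognitive) {
      cg <- cognitive_scores(pan)
      d <- merge(d, cg, by = "child_id")
      regs <- c(regs, "cognitive")
    }
    fml <- reformulate(c(regs, covariates), response = outcome)
    cc <- complete.cases(d[c(outcome, regs, covariates)])
    d <- d[cc & d$converged, , drop = FALSE]
    if (length(unique(d[[outcome]])) < 2)
      stop("outcome '", outcome, "' is constant in group ", group)
    lmfit <- lm(fml, data = d)
    list(coef = coef(lmfit), n = nrow(d),
         adj_r2 = summary(lmfit)$adj.r.squared)
  }

  if (is.null(scores)) {
    if (is.null(fit)) {
      scores <- fit_and_score(panel)
    } else scores <- ebm_scores(fit, panel)
  }
  full <- regress(panel, scores)

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  reps <- matrix(NA_real_, B, length(full$coef))
  colnames(reps) <- names(full$coef)
  idx_by <- split(seq_len(nrow(panel$data)), panel$data$group)
  dropped <- 0L
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    pan_b <- panel
    pan_b$data <- panel$data[take, , drop = FALSE]
    pan_b$data$child_id <- seq_len(nrow(pan_b$data))   # unique ids
    r <- tryCatch({
      sc_b <- if (refit_measurement) fit_and_score(pan_b) else {
        sb <- scores[take, , drop = FALSE]
        sb$child_id <- pan_b$data$child_id
        sb
      }
      regress(pan_b, sc_b)$coef
    }, error = function(e) NULL)
    if (is.null(r) || length(r) != length(full$coef)) dropped <- dropped + 1L
    else reps[b, ] <- r
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (dropped > 0.05 * B)
    stop("measurement stage failed on ", dropped, " of ", B, " replicates")

  structure(list(coefficients = full$coef,
                 se = apply(reps, 2, sd, na.rm = TRUE),
                 replicates = reps, n = full$n,
                 adj_r_squared = full$adj_r2,
                 n_dropped = dropped,
                 outcome = outcome, group = group,
                 include_cognitive = include_cognitive),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("<outcome_fit> ", x$outcome, " in ", x$group, " (n = ", x$n,
      ", adj R^2 = ", round(x$adj_r_squared, 3), ")\n", sep = "")
  print(round(cbind(estimate = x$coefficients, boot_se = x$se), 4))
  invisible(x)
}

#' Cross-group equality test for a regression coefficient
#'
#' Tests equality of one regressor's coefficient between two `outcome_fit`s
#' using the bootstrap distribution of the coefficient difference, pairing
#' draws by replicate. `method = "normal"` uses a z-test with the bootstrap
#' SE of the difference; `method = "percentile"` uses the sign-based
#' two-sided percentile rule (a fit tested against itself gives p = 1).
#'
#' @param fit_a,fit_b `outcome_fit` objects with the same regressor and the
#'   same number of bootstrap replicates.
#' @param regressor coefficient name to compare.
#' @param method `"normal"` or `"percentile"`.
#' @return list with `difference`, `se`, `p.value`.
#' @export
coefficient_equality_test <- function(fit_a, fit_b, regressor,
                                      method = c("normal", "percentile")) {
  method <- match.arg(method)
  stopifnot(regressor %in% names(fit_a$coefficients),
            regressor %in% names(fit_b$coefficients))
  ra <- fit_a$replicates[, regressor]
  rb <- fit_b$replicates[, regressor]
  if (length(ra) != length(rb))
    stop("mismatched bootstrap replicate counts: ",
         length(ra), " vs ", length(rb))
  d_hat <- unname(fit_a$coefficients[regressor] -
                    fit_b$coefficients[regressor])
  dd <- ra - rb
  dd <- dd[is.finite(dd)]
  if (method == "normal") {
    se <- sd(dd)
    p <- if (se == 0) as.numeric(d_hat != 0) else
      2 * pnorm(-abs(d_hat) / se)
  } else {
    se <- sd(dd)
    p <- min(1, 2 * min(mean(dd <= 0), mean(dd >= 0)))
  }
  list(difference = d_hat, se = se, p.value = p)
}

#' Tidy outcome-regression table across groups
#'
#' @param fits list of `outcome_fit`s.
#' @return data frame: outcome, group, regressor, estimate, se, n, adj R^2.
#' @export
outcomes_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(outcome = f$outcome, group = f$group,
               regressor = names(f$coefficients),
               estimate = unname(f$coefficients), se = unname(f$se),
               n = f$n, adj_r_squared = f$adj_r_squared,
               row.names = NULL)))
}
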