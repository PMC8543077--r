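#' Specification of the synthetic two-cohort generator
#'
#' Bundles everything needed to simulate per-child ordinal item responses with
#' the structure the analysis assumes: per-group measurement parameters
#' (loadings, intercepts, thresholds, error variances, factor means and
#' covariances), a covariate model, structural coefficients mapping covariates
#' to latent skill means, and an outcome model.
#'
#' The latent model per child j in group c is
#' \deqn{\theta_j = \kappa_c + B'(x_j - E_c x) + e_j,\quad
#'       X^*_{ij} = \nu_{ic} + \lambda_{ic}'\theta_j + u_{ij},\quad
#'       u_{ij} \sim N(0, \psi_{ic}),}
#' with \eqn{e_j} normal and its covariance chosen so that
#' \eqn{Var(\theta_j) = \Phi_c} exactly. Items are discretised by the group's
#' thresholds; responses come out on the analysis coding (0 = worst).
#'
#' @param meta item metadata, see [socioemotional_items()].
#' @param groups character vector of group labels (first is the reference).
#' @param n named integer vector of group sizes.
#' @param measurement named list (one entry per group) of lists with elements
#'   `lambda` (11), `nu` (11), `tau` (list of increasing threshold vectors),
#'   `psi` (11, positive), `kappa` (2), `Phi` (2x2 PD).
#' @param covariates list of covariate definitions: each a list with `name`,
#'   `type` ("bernoulli" or "normal") and per-group parameters `p` or
#'   `mean`/`sd` (named by group, recycled if unnamed).
#' @param beta matrix (n_covariates x 2) of structural coefficients on centred
#'   covariates, columns EXT and INT; rownames must match covariate names.
#' @param outcomes list of outcome definitions: `name`, `type` ("continuous"
#'   or "binary"), `intercept` (named by group or scalar), `coef_theta` (2),
#'   `coef_cog` (scalar), `coef_cov` (named vector), `sd` (continuous only).
#' @param cognitive list with `n_measures`, `loading`, `coef_theta` (2) for
#'   the per-cohort continuous cognitive measures.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(meta, groups, n, measurement, covariates,
                           beta, outcomes = list(), cognitive = NULL) {
  validate_item_meta(meta)
  stopifnot(length(groups) >= 1, all(groups %in% names(n)),
            all(groups %in% names(measurement)))
  for (g in groups) {
    m <- measurement[[g]]
    J <- nrow(meta)
    stopifnot(length(m$lambda) == J, length(m$nu) == J,
              length(m$tau) == J, length(m$psi) == J,
              length(m$kappa) == 2, all(dim(m$Phi) == c(2, 2)))
    if (any(m$psi <= 0)) stop("psi must be positive in group ", g)
    if (!isTRUE(all.equal(m$Phi, t(m$Phi))) ||
        any(eigen(m$Phi, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("Phi must be symmetric positive-definite in group ", g)
    for (i in seq_len(J)) {
      tv <- m$tau[[i]]
      if (length(tv) != meta$n_categories[i] - 1L)
        stop("item ", i, " needs ", meta$n_categories[i] - 1, " thresholds")
      if (is.unsorted(tv, strictly = TRUE))
        stop("thresholds must be strictly increasing for item ", i)
    }
  }
  cn <- vapply(covariates, `[[`, "", "name")
  if (!is.null(beta)) {
    stopifnot(nrow(beta) == length(cn), ncol(beta) == 2)
    rownames(beta) <- cn
  }
  structure(list(meta = meta, groups = groups, n = n,
                 measurement = measurement, covariates = covariates,
                 beta = beta, outcomes = outcomes, cognitive = cognitive),
            class = "generator_spec")
}

group_par <- function(x, g, default = NULL) {
  if (is.null(x)) return(default)
  if (!is.null(names(x)) && g %in% names(x)) return(x[[g]])
  if (length(x) == 1L) return(x[[1L]])
  x
}

#' Paper-like default generator specification
#'
#' Two cohorts (BCS 1970, MCS 2000/1) by gender, sizes 9545 and 5572 split
#' into `BCS_M` = 4800, `BCS_F` = 4745, `MCS_M` = 2800, `MCS_F` = 2772, with
#' `BCS_M` the reference group. Loadings (standardised metric) lie in
#' 0.5-0.8; thresholds give realistic skewed category splits; the MCS factor
#' SDs are 20% larger than the BCS (wider skill dispersion in the later
#' cohort); cohort-level covariate distributions follow the published summary
#' statistics of the two studies; covariate effects on skills are signed as
#' found there (maternal education positive, smoking in pregnancy negative,
#' ...). By default the MCS groups carry reporting shifts of +/-0.2 on the
#' intercepts of items 1, 4, 7 and 10, so threshold+loading invariance holds
#' but intercept invariance fails; set `invariant = TRUE` for a fully
#' invariant population.
#'
#' @param invariant if `TRUE`, omit the MCS intercept shifts.
#' @return a `generator_spec`.
#' @export
default_generator_spec <- function(invariant = FALSE) {
  meta <- socioemotional_items()
  groups <- c("BCS_M", "BCS_F", "MCS_M", "MCS_F")
  n <- c(BCS_M = 4800L, BCS_F = 4745L, MCS_M = 2800L, MCS_F = 2772L)

  lambda <- c(0.75, 0.70, 0.65, 0.72, 0.60, 0.55,
              0.68, 0.62, 0.55, 0.70, 0.50)
  psi <- 1 - lambda^2     # reference group has unit-variance latent responses
  tau <- list(c(-1.10, 0.10), c(-1.00, 0.20), c(-1.30, -0.10), c(-0.95, 0.25),
              -0.80, -0.70,
              c(-1.05, 0.15), c(-1.00, 0.05), c(-0.90, 0.30), c(-1.20, 0.00),
              -0.85)
  corr <- matrix(c(1, 0.5, 0.5, 1), 2)
  sd_mcs <- 1.2
  Phi_bcs <- corr
  Phi_mcs <- diag(c(sd_mcs, sd_mcs)) %*% corr %*% diag(c(sd_mcs, sd_mcs))
  kappa <- list(BCS_M = c(0, 0), BCS_F = c(0.15, 0.05),
                MCS_M = c(0.05, 0.00), MCS_F = c(0.20, 0.05))

  measurement <- lapply(groups, function(g) {
    list(lambda = lambda, nu = rep(0, 11), tau = tau, psi = psi,
         kappa = kappa[[g]],
         Phi = if (grepl("^MCS", g)) Phi_mcs else Phi_bcs)
  })
  names(measurement) <- groups

  bern <- function(name, p_bcs, p_mcs)
    list(name = name, type = "bernoulli",
         p = c(BCS_M = p_bcs, BCS_F = p_bcs, MCS_M = p_mcs, MCS_F = p_mcs))
  covariates <- list(
    bern("mother_educ", 0.38, 0.57),
    bern("mother_employed", 0.42, 0.62),
    bern("unmarried", 0.05, 0.36),
    bern("nonwhite", 0.03, 0.11),
    bern("firstborn", 0.38, 0.42),
    bern("smoked_preg", 0.39, 0.20),
    bern("father_blue_collar", 0.61, 0.41),
    bern("no_father", 0.05, 0.17),
    list(name = "mother_age", type = "normal",
         mean = c(BCS_M = 25.9, BCS_F = 25.9, MCS_M = 29.4, MCS_F = 29.4),
         sd = c(BCS_M = 5.35, BCS_F = 5.35, MCS_M = 5.67, MCS_F = 5.67)),
    list(name = "birthweight", type = "normal",
         mean = c(BCS_M = 3.31, BCS_F = 3.31, MCS_M = 3.38, MCS_F = 3.38),
         sd = c(BCS_M = 0.53, BCS_F = 0.53, MCS_M = 0.58, MCS_F = 0.58))
  )
  beta <- rbind(
    mother_educ        = c(0.25, 0.20),
    mother_employed    = c(0.05, 0.05),
    unmarried          = c(-0.15, -0.10),
    nonwhite           = c(0.00, 0.00),
    firstborn          = c(0.08, 0.05),
    smoked_preg        = c(-0.20, -0.12),
    father_blue_collar = c(-0.10, -0.08),
    no_father          = c(-0.12, -0.10),
    mother_age         = c(0.012, 0.008),
    birthweight        = c(0.10, 0.06)
  )
  colnames(beta) <- c("EXT", "INT")

  outcomes <- list(
    list(name = "tried_smoking", type = "binary",
         intercept = c(BCS_M = 0.52, BCS_F = 0.58, MCS_M = 0.12, MCS_F = 0.15),
         coef_theta = c(-0.07, 0.04), coef_cog = 0.01,
         coef_cov = c(smoked_preg = 0.08, mother_educ = -0.05)),
    list(name = "bmi", type = "continuous",
         intercept = c(BCS_M = 20.9, BCS_F = 21.2, MCS_M = 20.7, MCS_F = 21.6),
         coef_theta = c(-0.20, 0.10), coef_cog = 0.00,
         coef_cov = c(birthweight = 0.50), sd = 2.5)
  )
  cognitive <- list(n_measures = 4L, loading = 0.7, coef_theta = c(0.3, 0.3))

  spec <- generator_spec(meta, groups, n, measurement, covariates, beta,
                         outcomes, cognitive)
  if (!invariant) {
    shifts <- c("1" = 0.2, "4" = -0.2, "7" = 0.2, "10" = -0.2)
    spec <- inject_noninvariance(spec, "MCS_M", intercept_shift = shifts)
    spec <- inject_noninvariance(spec, "MCS_F", intercept_shift = shifts)
  }
  spec
}

#' Inject measurement non-invariance into a generator specification
#'
#' Returns a new specification in which only the target group's intercepts
#' (and optionally loadings) differ; this simulates reporting shifts, i.e.
#' raters in the target group assessing the same latent behaviour differently.
#'
#' @param spec a `generator_spec`.
#' @param target_group group label to perturb.
#' @param intercept_shift named numeric vector of additive intercept shifts;
#'   names are item ids.
#' @param loading_scale named numeric vector of multiplicative loading
#'   factors; names are item ids.
#' @return modified `generator_spec`.
#' @export
inject_noninvariance <- function(spec, target_group,
                                 intercept_shift = numeric(),
                                 loading_scale = numeric()) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!target_group %in% spec$groups)
    stop("unknown target group: ", target_group)
  ids <- as.character(spec$meta$item_id)
  for (nm in names(intercept_shift))
    if (!nm %in% ids) stop("intercept shift on undeclared item: ", nm)
  for (nm in names(loading_scale))
    if (!nm %in% ids) stop("loading scale on undeclared item: ", nm)
  m <- spec$measurement[[target_group]]
  idx <- match(names(intercept_shift), ids)
  m$nu[idx] <- m$nu[idx] + unname(intercept_shift)
  idx <- match(names(loading_scale), ids)
  m$lambda[idx] <- m$lambda[idx] * unname(loading_scale)
  spec$measurement[[target_group]] <- m
  spec
}

# population mean/var of each covariate in a group
covariate_moments <- function(spec, g) {
  mu <- vapply(spec$covariates, function(cv) {
    if (cv$type == "bernoulli") group_par(cv$p, g) else group_par(cv$mean, g)
  }, 0)
  v <- vapply(spec$covariates, function(cv) {
    if (cv$type == "bernoulli") {
      p <- group_par(cv$p, g); p * (1 - p)
    } else group_par(cv$sd, g)^2
  }, 0)
  names(mu) <- names(v) <- vapply(spec$covariates, `[[`, "", "name")
  list(mean = mu, var = v)
}

#' Generate a synthetic cohort panel
#'
#' Draws covariates, latent skills given covariates, latent item responses,
#' and discretises them by the group thresholds; then draws cognitive
#' measures and outcomes. Deterministic given `seed`.
#'
#' @param spec a `generator_spec`.
#' @param seed integer seed.
#' @param keep_latent if `TRUE`, attach the pre-discretisation latent
#'   responses and true factor scores as attributes `"latent_x"` and
#'   `"theta"` (for moment checks and recovery tests).
#' @return an `item_panel`; responses are already on the analysis coding.
#' @export
generate_panel <- function(spec, seed, keep_latent = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed)
  meta <- spec$meta
  J <- nrow(meta)
  fac_idx <- ifelse(meta$factor == "EXT", 1L, 2L)
  rows <- list(); latents <- list(); thetas <- list()
  id0 <- 0L
  for (g in spec$groups) {
    n <- spec$n[[g]]
    m <- spec$measurement[[g]]

    # covariates (independent draws within group)
    X <- matrix(0, n, length(spec$covariates))
    colnames(X) <- vapply(spec$covariates, `[[`, "", "name")
    for (k in seq_along(spec$covariates)) {
      cv <- spec$covariates[[k]]
      X[, k] <- if (cv$type == "bernoulli")
        stats::rbinom(n, 1L, group_par(cv$p, g))
      else stats::rnorm(n, group_par(cv$mean, g), group_par(cv$sd, g))
    }

    # latent skills: mean from centred covariates, residual cov so that
    # Var(theta) equals the target Phi exactly (covariates are independent)
    cm <- covariate_moments(spec, g)
    Xc <- sweep(X, 2, cm$mean)
    mu_theta <- if (is.null(spec$beta)) matrix(0, n, 2) else Xc %*% spec$beta
    expl <- if (is.null(spec$beta)) matrix(0, 2, 2) else
      t(spec$beta) %*% (spec$beta * cm$var)
    Phi_res <- m$Phi - expl
    ev <- eigen(Phi_res, symmetric = TRUE)
    if (any(ev$values <= 0))
      stop("structural coefficients explain more variance than Phi allows in ",
           g)
    Lhalf <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
    theta <- sweep(mu_theta + matrix(stats::rnorm(2 * n), n, 2) %*% Lhalf,
                   2, -m$kappa)  # add kappa
    colnames(theta) <- c("EXT", "INT")

    # latent item responses and discretisation
    lam <- m$lambda
    Xstar <- matrix(rep(m$nu, each = n), n, J) +
      theta[, fac_idx] * matrix(rep(lam, each = n), n, J) +
      matrix(stats::rnorm(n * J), n, J) *
      matrix(rep(sqrt(m$psi), each = n), n, J)
    items <- matrix(0L, n, J)
    for (i in seq_len(J)) {
      tv <- m$tau[[i]]
      items[, i] <- findInterval(Xstar[, i], tv)
    }
    colnames(items) <- item_cols(meta)

    df <- data.frame(child_id = id0 + seq_len(n), group = g,
                     items, X, stringsAsFactors = FALSE)

    # cognitive measures (per-cohort scale, not cross-cohort comparable)
    if (!is.null(spec$cognitive)) {
      cg <- spec$cognitive
      a <- cg$coef_theta
      resv <- 1 - (a[1]^2 * m$Phi[1, 1] + a[2]^2 * m$Phi[2, 2] +
                     2 * a[1] * a[2] * m$Phi[1, 2])
      resv <- max(resv, 0.1)
      theta_cog <- theta %*% a + stats::rnorm(n, 0, sqrt(resv))
      for (q in seq_len(cg$n_measures))
        df[[paste0("cog_", q)]] <- cg$loading * theta_cog +
          stats::rnorm(n, 0, sqrt(1 - cg$loading^2))
    }

    # outcomes
    for (oc in spec$outcomes) {
      lin <- group_par(oc$intercept, g) +
        theta %*% oc$coef_theta +
        (if (!is.null(spec$cognitive) && !is.null(oc$coef_cog))
          oc$coef_cog * theta_cog else 0)
      for (nm in names(oc$coef_cov))
        lin <- lin + oc$coef_cov[[nm]] * Xc[, nm]
      df[[oc$name]] <- if (oc$type == "binary")
        stats::rbinom(n, 1L, pmin(pmax(lin, 0.02), 0.98))
      else as.numeric(lin + stats::rnorm(n, 0, oc$sd))
    }

    rows[[g]] <- df
    if (keep_latent) {
      latents[[g]] <- Xstar
      thetas[[g]] <- theta
    }
    id0 <- id0 + n
  }
  all_rows <- do.call(rbind, rows)
  rownames(all_rows) <- NULL
  panel <- as_item_panel(all_rows, meta = meta, recode_map = NULL,
                         groups = spec$groups)
  if (keep_latent) {
    attr(panel, "latent_x") <- do.call(rbind, latents)
    attr(panel, "theta") <- do.call(rbind, thetas)
  }
  panel
}

#' Serialise / read a generator specification (YAML)
#'
#' Round-trips a `generator_spec` through YAML so simulation conditions can be
#' declared in configuration files.
#' @param spec a `generator_spec`.
#' @param path file path.
#' @export
write_generator_spec <- function(spec, path) {
  ser <- list(
    groups = spec$groups,
    n = as.list(spec$n),
    meta = spec$meta,
    measurement = lapply(spec$measurement, function(m)
      list(lambda = m$lambda, nu = m$nu, tau = m$tau, psi = m$psi,
           kappa = m$kappa, Phi = as.vector(m$Phi))),
    covariates = lapply(spec$covariates, function(cv) {
      for (f in c("p", "mean", "sd")) if (!is.null(cv[[f]]))
        cv[[f]] <- as.list(cv[[f]])   # yaml drops atomic-vector names
      cv
    }),
    beta = if (is.null(spec$beta)) NULL else
      list(values = as.vector(spec$beta), rows = rownames(spec$beta)),
    outcomes = lapply(spec$outcomes, function(oc) {
      for (f in c("intercept", "coef_cov")) if (!is.null(oc[[f]]))
        oc[[f]] <- as.list(oc[[f]])
      oc
    }),
    cognitive = spec$cognitive
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  ser <- yaml::read_yaml(path)
  meta <- as.data.frame(ser$meta, stringsAsFactors = FALSE)
  n <- unlist(ser$n)
  measurement <- lapply(ser$measurement, function(m)
    list(lambda = unlist(m$lambda), nu = unlist(m$nu),
         tau = lapply(m$tau, unlist), psi = unlist(m$psi),
         kappa = unlist(m$kappa), Phi = matrix(unlist(m$Phi), 2, 2)))
  covariates <- lapply(ser$covariates, function(cv) {
    for (f in c("p", "mean", "sd")) if (!is.null(cv[[f]]))
      cv[[f]] <- unlist(cv[[f]])
    cv
  })
  beta <- if (is.null(ser$beta)) NULL else {
    b <- matrix(unlist(ser$beta$values), ncol = 2)
    rownames(b) <- unlist(ser$beta$rows); colnames(b) <- c("EXT", "INT")
    b
  }
  outcomes <- lapply(ser$outcomes, function(oc) {
    for (f in c("intercept", "coef_theta", "coef_cov")) if (!is.null(oc[[f]]))
      oc[[f]] <- unlist(oc[[f]])
    oc
  })
  cognitive <- if (is.null(ser$cognitive)) NULL else {
    cg <- ser$cognitive; cg$coef_theta <- unlist(cg$coef_theta); cg
  }
  generator_spec(meta, unlist(ser$groups), n, measurement, covariates, beta,
                 outcomes, cognitive)
}
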