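#' Number-of-factors diagnostics on a polychoric correlation matrix
#'
#' A standard psychometric battery: Kaiser's eigenvalue-greater-than-one
#' rule, Horn's parallel analysis (95th percentile of eigenvalues from
#' simulated uncorrelated data of the same dimensions), Velicer's minimum
#' average partial (MAP), and the optimal-coordinates scree rule.
#'
#' @param moments a `sample_moments` object (its polychoric matrix and n are
#'   used).
#' @param methods subset of `c("kaiser", "parallel", "map", "scree_oc")`.
#' @param n_rep parallel-analysis replications.
#' @param seed seed for the parallel-analysis resampling (deterministic).
#' @return named integer vector of retained-factor counts.
#' @export
suggest_n_factors <- function(moments,
                              methods = c("kaiser", "parallel", "map",
                                          "scree_oc"),
                              n_rep = 100, seed = 171) {
  bad <- setdiff(methods, c("kaiser", "parallel", "map", "scree_oc"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  R <- moments$rho
  n <- moments$n
  J <- ncol(R)
  ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  out <- integer(0)
  for (m in methods) {
    out[m] <- switch(
      m,
      kaiser = sum(ev > 1),
      parallel = {
        old <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv()) else NULL
        set.seed(seed)
        sim <- replicate(n_rep, {
          X <- matrix(rnorm(n * J), n, J)
          sort(eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
        })
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        thr <- apply(sim, 1, quantile, probs = 0.95)
        # count leading eigenvalues above the resampling threshold
        above <- ev > thr
        if (all(above)) J else sum(cumprod(above))
      },
      map = velicer_map(R),
      scree_oc = scree_optimal_coordinates(ev)
    )
  }
  out
}

# Velicer's minimum average partial
velicer_map <- function(R) {
  J <- ncol(R)
  e <- eigen(R, symmetric = TRUE)
  load <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  fm <- numeric(J - 1)
  fm0 <- (sum(R^2) - J) / (J * (J - 1))
  for (k in seq_len(J - 1)) {
    A <- load[, 1:k, drop = FALSE]
    Rstar <- R - A %*% t(A)
    d <- sqrt(pmax(diag(Rstar), 1e-12))
    Rpart <- Rstar / outer(d, d)
    fm[k] <- (sum(Rpart^2) - J) / (J * (J - 1))
  }
  if (all(fm0 <= fm)) 0L else which.min(fm)
}

# optimal-coordinates scree rule
scree_optimal_coordinates <- function(ev) {
  J <- length(ev)
  n_oc <- 0L
  for (i in seq_len(J - 2)) {
    slope <- (ev[J] - ev[i + 1]) / (J - (i + 1))
    pred <- ev[J] + slope * (i - J)   # line through (i+1, ev[i+1]) and (J, ev[J])
    if (ev[i] > pred + 1e-8) n_oc <- i else break
  }
  n_oc
}

#' Exploratory factor analysis on a polychoric matrix
#'
#' Minimum-residual (ULS) extraction: uniquenesses are chosen to minimise the
#' squared discarded eigenvalues of the reduced correlation matrix, the
#' loading matrix is the rank-k eigen-approximation, and (optionally) an
#' oblique quartimin (oblimin) rotation is applied by gradient projection.
#'
#' @param moments a `sample_moments`.
#' @param k number of factors (<= 5).
#' @param rotation `"oblimin"`, `"geomin"` or `"none"`.
#' @return object of class `efa_solution`: `loadings` (rotated), `Phi`
#'   (factor correlations), `eigenvalues`, `communalities`, `uniquenesses`,
#'   `heywood` flag, `one_item_factors` ("untestable-for-invariance" flag per
#'   factor), `fitted` (model-implied correlation matrix).
#' @export
efa_fit <- function(moments, k, rotation = c("oblimin", "geomin", "none")) {
  rotation <- match.arg(rotation)
  R <- moments$rho
  J <- ncol(R)
  stopifnot(k >= 1, k <= 5)
  ev_all <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)

  extract <- function(psi) {
    e <- eigen(R - diag(psi, J), symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    list(L = L, tail = e$values[-seq_len(k)])
  }
  obj <- function(psi) sum(extract(psi)$tail^2)
  psi0 <- pmax(1 - 0.5 * apply(R^2, 1, function(r) max(r[r < 1])), 0.2)
  opt <- nlminb(psi0, obj, lower = 1e-4, upper = 1)
  psi <- opt$par
  L <- extract(psi)$L
  heywood <- any(psi <= 1.1e-4) || any(rowSums(L^2) > 1 + 1e-6)
  if (heywood) warning("Heywood case: communality at or above 1")

  Phi <- diag(k)
  Lrot <- L
  if (rotation != "none" && k > 1) {
    rot <- gp_oblique(L, criterion = rotation)
    Lrot <- rot$loadings
    Phi <- rot$Phi
    # sign convention: dominant direction positive per factor
    sgn <- sign(colSums(Lrot^3))
    sgn[sgn == 0] <- 1
    Lrot <- sweep(Lrot, 2, sgn, `*`)
    Phi <- diag(sgn) %*% Phi %*% diag(sgn)
  }
  fitted <- Lrot %*% Phi %*% t(Lrot)
  diag(fitted) <- 1
  one_item <- colSums(abs(Lrot) > 0.3) <= 1
  structure(list(k = k, loadings = Lrot, Phi = Phi,
                 eigenvalues = ev_all, communalities = rowSums(L^2),
                 uniquenesses = psi, heywood = heywood,
                 one_item_factors = one_item, fitted = fitted,
                 rotation = rotation, crit_value = opt$objective),
            class = "efa_solution")
}

#' @export
print.efa_solution <- function(x, ...) {
  cat("<efa_solution> k =", x$k, "rotation =", x$rotation, "\n")
  print(round(x$loadings, 3))
  if (x$k > 1) { cat("factor correlations:\n"); print(round(x$Phi, 3)) }
  if (any(x$one_item_factors))
    cat("note: factor(s)", which(x$one_item_factors),
        "have a single salient item (untestable-for-invariance)\n")
  invisible(x)
}

# quartimin / geomin criterion value and gradient
rot_criterion <- function(L, criterion, geomin_eps = 0.01) {
  if (criterion == "oblimin") {          # quartimin (oblimin with gamma = 0)
    L2 <- L^2
    k <- ncol(L)
    N <- matrix(1, k, k) - diag(k)
    list(f = sum(L2 * (L2 %*% N)) / 4, G = L * (L2 %*% N))
  } else {                               # geomin
    k <- ncol(L)
    L2 <- L^2 + geomin_eps
    pro <- exp(rowMeans(log(L2)))
    list(f = sum(pro), G = (2 / k) * (L / L2) * pro)
  }
}

# gradient-projection oblique rotation (Jennrich-style)
gp_oblique <- function(A, criterion = "oblimin", maxit = 500, eps = 1e-6) {
  k <- ncol(A)
  Tmat <- diag(k)
  al <- 1
  L <- A %*% t(solve(Tmat))
  vg <- rot_criterion(L, criterion)
  f <- vg$f
  G <- -t(t(L) %*% vg$G %*% solve(Tmat))
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 1:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      L <- A %*% t(solve(Tt))
      vg_new <- rot_criterion(L, criterion)
      if (vg_new$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vg_new$f
    G <- -t(t(L) %*% vg_new$G %*% solve(Tmat))
  }
  list(loadings = A %*% t(solve(Tmat)), Phi = crossprod(Tmat), f = f,
       iterations = iter)
}

#' Tidy EFA report tables
#'
#' @param moments a `sample_moments`.
#' @param ks factor counts to fit.
#' @param rotation rotation for multi-factor solutions.
#' @return list of data frames: `eigenvalues`, `retention`, `loadings` (one
#'   block per k).
#' @export
run_efa <- function(moments, ks = 1:3, rotation = "oblimin") {
  ret <- suggest_n_factors(moments)
  sols <- lapply(ks, function(k)
    efa_fit(moments, k, if (k == 1) "none" else rotation))
  names(sols) <- paste0("k", ks)
  loads <- do.call(rbind, lapply(seq_along(ks), function(ii) {
    s <- sols[[ii]]
    data.frame(k = ks[ii], item_id = rep(moments$meta$item_id, s$k),
               factor = rep(seq_len(s$k), each = nrow(s$loadings)),
               loading = as.vector(s$loadings))
  }))
  list(eigenvalues = data.frame(component = seq_along(sols[[1]]$eigenvalues),
                                eigenvalue = sols[[1]]$eigenvalues),
       retention = data.frame(method = names(ret), n_factors = unname(ret)),
       loadings = loads, solutions = sols)
}
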