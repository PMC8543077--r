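#' Threshold estimates for one ordinal item
#'
#' Stage-1 of the two-step polychoric estimator: thresholds are inverse
#' normal CDF values of the cumulative category proportions, assuming a
#' standard-normal latent response.
#'
#' @param counts integer vector of category counts (categories 0..K-1).
#' @return numeric vector of K-1 strictly increasing thresholds.
#' @export
estimate_thresholds <- function(counts) {
  K <- length(counts)
  if (sum(counts > 0) < 2L)
    stop("degenerate item: fewer than 2 observed categories")
  p <- cumsum(counts)[-K] / sum(counts)
  tau <- qnorm(p)
  stopifnot(!is.unsorted(tau, strictly = TRUE))
  tau
}

# bivariate-normal cell probabilities for thresholds ta, tb at correlation rho
# returns (length(ta)+1) x (length(tb)+1) matrix
bvn_cell_probs <- function(ta, tb, rho) {
  a <- c(-Inf, ta, Inf)
  b <- c(-Inf, tb, Inf)
  A <- length(a); B <- length(b)
  G <- matrix(pbvnorm(rep(a, times = B), rep(b, each = A), rho), A, B)
  G[A, ] <- pnorm(b)          # exact marginals at +Inf
  G[, B] <- pnorm(a)
  G[A, B] <- 1
  P <- G[-1, -1, drop = FALSE] - G[-A, -1, drop = FALSE] -
    G[-1, -B, drop = FALSE] + G[-A, -B, drop = FALSE]
  pmax(P, 0)
}

# derivative of the cell probabilities wrt rho (Plackett's identity)
bvn_cell_dprobs_drho <- function(ta, tb, rho) {
  a <- c(-Inf, ta, Inf)
  b <- c(-Inf, tb, Inf)
  A <- length(a); B <- length(b)
  G <- matrix(dbvnorm(rep(a, times = B), rep(b, each = A), rho), A, B)
  G[-1, -1, drop = FALSE] - G[-A, -1, drop = FALSE] -
    G[-1, -B, drop = FALSE] + G[-A, -B, drop = FALSE]
}

#' Polychoric correlation from a two-way table
#'
#' Stage-2 of the two-step (Olsson-style) estimator: with thresholds fixed,
#' the bivariate-normal multinomial likelihood is maximised over the latent
#' correlation by derivative-free bracketing on (-0.999, 0.999).
#'
#' @param table two-way contingency table (matrix of counts), rows = item A
#'   categories, columns = item B categories.
#' @param thresholds optional list of two threshold vectors; computed from
#'   the table margins when `NULL`.
#' @param bound search bound on |rho|.
#' @param tol optimiser tolerance.
#' @return estimated correlation, with attributes `loglik` and
#'   `near_singular` (TRUE when the estimate lies at the search bound).
#' @export
polychoric_corr <- function(table, thresholds = NULL, bound = 0.999,
                            tol = 1e-8) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2 ||
      sum(rowSums(table) > 0) < 2 || sum(colSums(table) > 0) < 2)
    stop("table must have at least 2 occupied rows and columns")
  if (is.null(thresholds))
    thresholds <- list(estimate_thresholds(rowSums(table)),
                       estimate_thresholds(colSums(table)))
  ta <- thresholds[[1]]; tb <- thresholds[[2]]
  nz <- table > 0
  ll <- function(rho) {
    P <- bvn_cell_probs(ta, tb, rho)
    sum(table[nz] * log(pmax(P[nz], 1e-300)))
  }
  opt <- stats::optimize(ll, c(-bound, bound), maximum = TRUE, tol = tol)
  rho <- opt$maximum
  near <- abs(rho) > bound - 1e-4
  if (near) rho <- sign(rho) * bound
  structure(rho, loglik = opt$objective, near_singular = near)
}

pair_index <- function(J) {
  out <- NULL
  for (i in seq_len(J - 1)) for (j in (i + 1):J)
    out <- rbind(out, c(i, j))
  out
}

#' Sample moments of an ordinal item panel for one group
#'
#' Computes stage-1 thresholds, all pairwise polychoric correlations, and the
#' asymptotic covariance matrix of the stacked (thresholds, correlations)
#' estimate by the estimating-equation / influence-function method: each
#' statistic's influence function is evaluated per child (the correlation
#' influence functions carry the delta-method correction for the estimated
#' thresholds) and the asymptotic covariance is the sample covariance of the
#' stacked influence functions divided by n.
#'
#' @param panel an `item_panel`.
#' @param group group label.
#' @param min_n smallest admissible group size.
#' @return object of class `sample_moments`: thresholds (list), `rho`
#'   (correlation matrix), `stats` (stacked estimate vector), `acov`,
#'   `n`, `near_singular` (pair flags).
#' @export
sample_moments <- function(panel, group, min_n = 200) {
  stopifnot(inherits(panel, "item_panel"))
  meta <- panel$meta
  J <- nrow(meta)
  cols <- item_cols(meta)
  X <- as.matrix(panel$data[panel$data$group == group, cols, drop = FALSE])
  n <- nrow(X)
  if (n < min_n)
    stop("group ", group, " has n = ", n, " below the floor of ", min_n)

  # stage 1: thresholds + their influence functions
  taus <- vector("list", J)
  th_names <- character(0)
  IF_tau <- list()
  for (i in seq_len(J)) {
    K <- meta$n_categories[i]
    counts <- tabulate(X[, i] + 1L, nbins = K)
    if (sum(counts > 0) < 2L)
      stop("degenerate item ", meta$item_id[i], " in group ", group)
    taus[[i]] <- estimate_thresholds(counts)
    for (s in seq_len(K - 1)) {
      p <- sum(counts[1:s]) / n
      IF_tau[[length(IF_tau) + 1L]] <-
        ((X[, i] <= s - 1) - p) / dnorm(taus[[i]][s])
      th_names <- c(th_names, paste0("tau_", meta$item_id[i], "_", s))
    }
  }
  IF_tau <- do.call(cbind, IF_tau)
  tau_offsets <- c(0, cumsum(meta$n_categories - 1L))  # start index per item

  # stage 2: pairwise correlations + corrected influence functions
  pairs <- pair_index(J)
  np <- nrow(pairs)
  rho_mat <- diag(J)
  rho_vec <- numeric(np)
  rho_names <- character(np)
  IF_rho <- matrix(0, n, np)
  near <- logical(np)
  h <- 1e-5
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    A <- meta$n_categories[i]; B <- meta$n_categories[j]
    code <- X[, i] * B + X[, j]          # 0-based row-major cell code
    tab <- matrix(tabulate(code + 1L, nbins = A * B), A, B, byrow = TRUE)
    idx <- cbind(X[, i] + 1L, X[, j] + 1L)
    if (sum(rowSums(tab) > 0) < 2 || sum(colSums(tab) > 0) < 2)
      stop("pair (", meta$item_id[i], ",", meta$item_id[j],
           ") has an empty margin; polychoric inestimable")
    r_hat <- polychoric_corr(tab, thresholds = list(taus[[i]], taus[[j]]))
    near[p] <- attr(r_hat, "near_singular")
    rho <- as.numeric(r_hat)
    rho_vec[p] <- rho
    rho_mat[i, j] <- rho_mat[j, i] <- rho
    rho_names[p] <- paste0("rho_", meta$item_id[i], "_", meta$item_id[j])

    # per-cell score d log pi / d rho and mean-score derivatives
    cell_score <- function(ta, tb, r) {
      P <- bvn_cell_probs(ta, tb, r)
      D <- bvn_cell_dprobs_drho(ta, tb, r)
      D / pmax(P, 1e-300)
    }
    gbar <- function(ta, tb, r) {
      S <- cell_score(ta, tb, r)
      sum(tab * S) / n
    }
    # H = d gbar / d rho (central FD on the analytic score)
    Hr <- (gbar(taus[[i]], taus[[j]], rho + h) -
             gbar(taus[[i]], taus[[j]], rho - h)) / (2 * h)
    # G_t = d gbar / d tau_t for each threshold of items i and j
    S0 <- cell_score(taus[[i]], taus[[j]], rho)
    s_j <- S0[idx]
    corr_term <- numeric(n)
    for (item in c(i, j)) {
      tv <- taus[[item]]
      for (s in seq_along(tv)) {
        ta2 <- taus[[i]]; tb2 <- taus[[j]]
        if (item == i) ta2[s] <- ta2[s] + h else tb2[s] <- tb2[s] + h
        gp <- gbar(ta2, tb2, rho)
        ta2 <- taus[[i]]; tb2 <- taus[[j]]
        if (item == i) ta2[s] <- ta2[s] - h else tb2[s] <- tb2[s] - h
        gm <- gbar(ta2, tb2, rho)
        Gt <- (gp - gm) / (2 * h)
        col <- tau_offsets[item] + s
        corr_term <- corr_term + Gt * IF_tau[, col]
      }
    }
    IF_rho[, p] <- -(s_j + corr_term) / Hr
  }

  IFs <- cbind(IF_tau, IF_rho)
  colnames(IFs) <- c(th_names, rho_names)
  IFs <- sweep(IFs, 2, colMeans(IFs))
  acov <- crossprod(IFs) / (n * n)

  stats <- c(unlist(taus), rho_vec)
  names(stats) <- c(th_names, rho_names)

  structure(list(group = group, n = n, thresholds = taus, rho = rho_mat,
                 stats = stats, acov = acov, meta = meta,
                 near_singular = setNames(near, rho_names)),
            class = "sample_moments")
}

#' @export
print.sample_moments <- function(x, ...) {
  cat("<sample_moments> group ", x$group, ", n = ", x$n, ", ",
      length(x$stats), " statistics\n", sep = "")
  invisible(x)
}

#' Export sample moments to a tidy long table
#'
#' @param moments a `sample_moments` object or list of them.
#' @return data frame with columns `group`, `stat_type`, `index1`, `index2`,
#'   `estimate`, `se`.
#' @export
moments_table <- function(moments) {
  if (inherits(moments, "sample_moments")) moments <- list(moments)
  do.call(rbind, lapply(moments, function(m) {
    nm <- names(m$stats)
    parts <- strsplit(nm, "_")
    data.frame(
      group = m$group,
      stat_type = vapply(parts, `[[`, "", 1),
      index1 = as.integer(vapply(parts, `[[`, "", 2)),
      index2 = as.integer(vapply(parts, `[[`, "", 3)),
      estimate = unname(m$stats),
      se = sqrt(pmax(diag(m$acov), 0)))
  }))
}
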