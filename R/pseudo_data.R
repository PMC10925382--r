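#' Reconstruct pseudo-data from a Gram matrix
#'
#' Given the `(p+1) x (p+1)` Gram matrix of `[X, Y]` (response last) and
#' the sample size `n`, builds matrices \eqn{\check X} (`n x p`) and
#' \eqn{\check Y} (length `n`) whose Gram matrix equals the input
#' exactly. Any such reconstruction yields knockoff statistics with the
#' same conditional distribution as the original data, so the choice of
#' completion is immaterial; here the eigen-decomposition route is used:
#' rows are \eqn{\Lambda^{1/2} Q^\top} padded with zero rows up to `n`.
#'
#' @param gram Symmetric PSD `(p+1) x (p+1)` matrix, `Y` in the last
#'   row/column.
#' @param n Sample size; must be at least the rank of `gram`.
#' @param tol Eigenvalue tolerance: values below `-tol * max(eig)` are an
#'   error, small negatives are clipped to zero.
#' @return Object of class `pseudo_data`: list with `x_check`, `y_check`,
#'   `gram_in`, `n`, `p`, and `recon_error` (max abs Gram mismatch).
#' @export
reconstruct_pseudo_data <- function(gram, n, tol = 1e-8) {
  gram <- as.matrix(gram)
  k <- nrow(gram)
  if (k != ncol(gram)) stop("gram must be square")
  if (max(abs(gram - t(gram))) > 1e-6 * max(1, max(abs(gram)))) {
    stop("gram is asymmetric beyond tolerance")
  }
  gram <- (gram + t(gram)) / 2
  ev <- eigen(gram, symmetric = TRUE)
  scale <- max(ev$values, 1)
  if (min(ev$values) < -tol * scale) {
    stop("gram is not positive semi-definite (min eigenvalue = ",
         format(min(ev$values)), ")")
  }
  lam <- pmax(ev$values, 0)
  rank <- sum(lam > tol * scale)
  if (n < rank) {
    stop("sample size smaller than Gram rank (n = ", n,
         ", rank = ", rank, ")")
  }
  rows <- sqrt(lam) * t(ev$vectors)       # k x k, rows are Lambda^{1/2} Q'
  full <- matrix(0, n, k)
  # eigenvalues are sorted decreasing, so rows beyond the rank are zero;
  # when n < k only those informative rows are kept
  keep <- min(n, k)
  full[seq_len(keep), ] <- rows[seq_len(keep), , drop = FALSE]
  recon_error <- max(abs(crossprod(full) - gram))
  structure(
    list(x_check = full[, -k, drop = FALSE], y_check = full[, k],
         gram_in = gram, n = n, p = k - 1L, recon_error = recon_error),
    class = "pseudo_data")
}

#' @export
print.pseudo_data <- function(x, ...) {
  cat("Pseudo-data: n =", x$n, ", p =", x$p,
      ", Gram reconstruction error =", format(x$recon_error), "\n")
  invisible(x)
}

importance_result <- function(W, method, beta = NULL, lambda = NULL) {
  structure(list(W = W, method = method, beta = beta, lambda = lambda),
            class = "importance")
}

#' @export
print.importance <- function(x, ...) {
  cat("Importance statistics (", x$method, "): p =", length(x$W),
      if (!is.null(x$lambda)) paste0(", lambda = ", format(x$lambda)),
      "\n")
  invisible(x)
}

# Augment pseudo-data with sampled knockoff columns and return the pieces
# every penalized statistic needs: the stacked design, its Gram matrix,
# the score vector and ||Y||^2.
augment_pseudo <- function(pd, params, E = NULL) {
  x_tilde <- sample_knockoff_matrix(pd$x_check, params, E = E)
  A <- cbind(pd$x_check, x_tilde)
  list(A = A, G = crossprod(A), d = drop(crossprod(A, pd$y_check)),
       yty = sum(pd$y_check^2))
}

# Collapse an (M+1)p coefficient vector into importance output: signed
# differences for M = 1, per-copy absolute scores for the multi-knockoff
# filter otherwise.
collapse_coefficients <- function(beta, p, M, barless = FALSE) {
  if (M == 1) {
    if (barless) beta[seq_len(p)] - beta[p + seq_len(p)]
    else abs(beta[seq_len(p)]) - abs(beta[p + seq_len(p)])
  } else {
    matrix(abs(beta), p, M + 1)
  }
}

#' Lasso coefficient difference statistic at a fixed penalty
#'
#' Samples knockoffs of the reconstructed data, solves
#' \deqn{\hat\beta(\lambda) = \arg\min_\beta \tfrac12 \|\check Y -
#'   [\check X\ \tilde{\check X}]\beta\|_2^2 + \lambda \|\beta\|_1}
#' (no `1/n` factor in the quadratic term) and returns
#' \eqn{W_j = |\hat\beta_j| - |\hat\beta_{j+p}|}.
#'
#' @param pd A `pseudo_data` object.
#' @param params A `knockoff_params` object.
#' @param lambda Fixed penalty level (>= 0).
#' @param E Optional knockoff noise matrix (deterministic checks).
#' @param barless If `TRUE`, drop the absolute values
#'   (`W_j = beta_j - beta_{j+p}`); both versions are flip-sign valid.
#' @return An `importance` object.
#' @export
lasso_cd_statistic <- function(pd, params, lambda, E = NULL,
                               barless = FALSE) {
  stopifnot(lambda >= 0)
  aug <- augment_pseudo(pd, params, E = E)
  fit <- gram_lasso(aug$G, aug$d, lambda)
  W <- collapse_coefficients(fit$beta, pd$p, params$M, barless)
  importance_result(W, "lasso-cd", beta = fit$beta, lambda = lambda)
}

# Shared front door to the compiled coordinate-descent solver with
# convergence checking.
gram_lasso <- function(C, d, lambda, beta0 = NULL, tol = 1e-8,
                      max_sweeps = 10000L) {
  m <- length(d)
  if (any(diag(C) <= 0)) {
    stop("quadratic form has nonpositive diagonal entries; ",
         "add a ridge before solving")
  }
  if (is.null(beta0)) beta0 <- numeric(m)
  fit <- gram_lasso_cd(C, d, lambda, beta0, tol, as.integer(max_sweeps))
  if (!fit$converged) {
    stop("coordinate descent did not converge within ", fit$sweeps,
         " sweeps at lambda = ", format(lambda))
  }
  fit$beta <- drop(fit$beta)
  fit
}

#' Square-root-lasso penalty level from the augmented Gram matrix
#'
#' Computes \eqn{\lambda = \kappa\, E[\|A^\top \epsilon\|_\infty /
#' \|\epsilon\|_2]} by Monte Carlo, where `A` is any `n x 2p` matrix with
#' \eqn{A^\top A} equal to the supplied Gram matrix and \eqn{\epsilon \sim
#' N(0, I_n)}. By rotational invariance only the Gram matrix matters, so
#' the expectation is evaluated through its eigen-factorization without
#' forming `A`.
#'
#' @param gram_aug Gram matrix of the augmented design `[X, X~]`.
#' @param n Number of rows of the (implicit) design.
#' @param kappa Unitless multiplier (default 0.3).
#' @param mc_samples Number of Monte Carlo draws (default 200).
#' @return Penalty value (scalar).
#' @export
sqrt_lasso_lambda <- function(gram_aug, n, kappa = 0.3, mc_samples = 200) {
  stopifnot(kappa > 0, mc_samples >= 1)
  gram_aug <- (gram_aug + t(gram_aug)) / 2
  k <- nrow(gram_aug)
  ev <- eigen(gram_aug, symmetric = TRUE)
  scale <- max(ev$values, 1)
  if (min(ev$values) < -1e-8 * scale) {
    stop("augmented Gram matrix is not PSD")
  }
  lam <- pmax(ev$values, 0)
  rank <- sum(lam > 1e-12 * scale)
  if (n < rank) stop("n is smaller than the rank of the Gram matrix")
  sqrt_lam <- sqrt(lam)
  Emat <- matrix(rnorm(k * mc_samples), k, mc_samples)
  # A' eps = Q (sqrt(Lambda) * eps_k); ||eps||^2 adds n - k more d.f.
  numer <- apply(abs(ev$vectors %*% (sqrt_lam * Emat)), 2, max)
  extra <- if (n > k) rchisq(mc_samples, df = n - k) else 0
  denom <- sqrt(colSums(Emat^2) + extra)
  kappa * mean(numer / denom)
}

#' Square-root-lasso importance statistic
#'
#' Solves the square-root lasso on the augmented pseudo-data,
#' \deqn{\hat\beta \in \arg\min_\beta \|\check Y - [\check X\
#'   \tilde{\check X}]\beta\|_2 + \lambda \|\beta\|_1,}
#' with \eqn{\lambda} from [sqrt_lasso_lambda()] unless supplied. The
#' solver is the scaled-lasso fixed point iteration: alternate
#' \eqn{\beta \leftarrow} coordinate-descent lasso at penalty
#' \eqn{\lambda \hat\sigma} and \eqn{\hat\sigma \leftarrow \|\check Y -
#' A\beta\|_2}, which converges to the square-root-lasso solution. The
#' residual norm is evaluated from Gram quantities only.
#'
#' @inheritParams lasso_cd_statistic
#' @param kappa,mc_samples Passed to [sqrt_lasso_lambda()].
#' @param lambda Optional pre-resolved penalty (unitless scale).
#' @param max_iter Maximum fixed-point iterations.
#' @return An `importance` object; `lambda` holds the unitless penalty
#'   and the residual scale is attached as attribute `"sigma"`.
#' @export
sqrt_lasso_statistic <- function(pd, params, kappa = 0.3,
                                 mc_samples = 200, lambda = NULL,
                                 E = NULL, barless = FALSE,
                                 max_iter = 100) {
  aug <- augment_pseudo(pd, params, E = E)
  if (is.null(lambda)) {
    lambda <- sqrt_lasso_lambda(aug$G, pd$n, kappa, mc_samples)
  }
  m <- length(aug$d)
  beta <- numeric(m)
  sigma <- sqrt(aug$yty)
  if (sigma == 0) {
    W <- collapse_coefficients(beta, pd$p, params$M, barless)
    out <- importance_result(W, "sqrt-lasso", beta = beta, lambda = lambda)
    attr(out, "sigma") <- 0
    return(out)
  }
  # coefficient-scale tolerance: W only needs precision far below the
  # knockoff threshold granularity
  cd_tol <- max(1e-8, 1e-5 * max(abs(aug$d)) / mean(diag(aug$G)))
  trail <- numeric(0)  # recent sigma iterates for Aitken acceleration
  for (it in seq_len(max_iter)) {
    fit <- gram_lasso_cd(aug$G, aug$d, lambda * sigma, beta, cd_tol, 2000L)
    beta <- drop(fit$beta)
    rss <- max(aug$yty - 2 * sum(aug$d * beta) +
                 drop(crossprod(beta, aug$G %*% beta)), 0)
    sigma_new <- sqrt(rss)
    if (abs(sigma_new - sigma) < 1e-6 * max(sigma, 1)) {
      sigma <- sigma_new
      break
    }
    trail <- c(trail, sigma_new)
    if (length(trail) >= 3) {
      # Aitken delta-squared extrapolation of the linearly convergent
      # sigma sequence
      k <- length(trail)
      d1 <- trail[k] - trail[k - 1]
      d2 <- trail[k] - 2 * trail[k - 1] + trail[k - 2]
      if (d2 != 0) {
        acc <- trail[k] - d1^2 / d2
        if (is.finite(acc) && acc > 0) sigma_new <- acc
      }
      trail <- numeric(0)
    }
    sigma <- sigma_new
    if (sigma < 1e-12 * sqrt(aug$yty)) break  # essentially perfect fit
  }
  W <- collapse_coefficients(beta, pd$p, params$M, barless)
  out <- importance_result(W, "sqrt-lasso", beta = beta, lambda = lambda)
  attr(out, "sigma") <- sigma
  out
}

#' Lasso-max (entry value) importance statistic
#'
#' For each augmented column, computes the largest penalty at which its
#' coefficient first becomes nonzero along the lasso path of
#' \eqn{\tfrac12\|\check Y - A\beta\|_2^2 + \lambda\|\beta\|_1}, then
#' contrasts original and knockoff entry values:
#' \eqn{W_j = \sup\{\lambda : \hat\beta_j(\lambda) \ne 0\} -
#' \sup\{\lambda : \hat\beta_{j+p}(\lambda) \ne 0\}}. Entry points are
#' located on a log-spaced grid from \eqn{\lambda_{\max} = \|A^\top
#' \check Y\|_\infty} and refined by interval bisection to a relative
#' tolerance.
#'
#' @inheritParams lasso_cd_statistic
#' @param n_grid Number of grid points (default 100).
#' @param min_ratio Smallest grid value relative to lambda_max
#'   (default 1e-3).
#' @param refine_tol Relative bisection tolerance on each entry value
#'   (default 1e-3).
#' @return An `importance` object; `beta` holds the per-column entry
#'   values.
#' @export
lasso_max_statistic <- function(pd, params, n_grid = 100,
                                min_ratio = 1e-3, refine_tol = 1e-3,
                                E = NULL, barless = FALSE) {
  aug <- augment_pseudo(pd, params, E = E)
  p <- pd$p
  M <- params$M
  groups <- matrix(seq_len((M + 1) * p), p, M + 1)
  entries <- lasso_entry_values(aug$G, aug$d, n_grid, min_ratio,
                                refine_tol, groups = groups)
  W <- if (M == 1) {
    entries[seq_len(p)] - entries[p + seq_len(p)]
  } else {
    matrix(entries, p, M + 1)
  }
  importance_result(W, "lasso-max", beta = entries)
}

# Entry values of every column along the lasso path on Gram inputs.
# Grid pass with warm starts, then shared-interval bisection: columns
# whose entry lies in the same grid cell are refined together, so each
# bisection solve serves all of them. When `groups` is given (rows =
# original/knockoff index tuples), bisection is spent only on groups
# whose members enter in the same grid cell -- the sign of the entry
# contrast is already decided for all other groups, and their entry
# values are reported at grid (cell-midpoint) resolution.
lasso_entry_values <- function(G, d, n_grid = 100, min_ratio = 1e-3,
                               refine_tol = 1e-3, groups = NULL) {
  m <- length(d)
  lam_max <- max(abs(d))
  if (lam_max == 0) return(numeric(m))
  grid <- exp(seq(log(lam_max), log(lam_max * min_ratio),
                  length.out = n_grid))
  # entry detection only needs the support, not 1e-8 coefficients: use a
  # tolerance scaled to the coefficient magnitude lambda_max / diag(G)
  cd_tol <- 1e-4 * lam_max / mean(diag(G))
  cd_sweeps <- 1000L
  path <- gram_lasso_path(G, d, grid, cd_tol, cd_sweeps)
  nz <- path != 0
  first_idx <- apply(nz, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  entries <- numeric(m)
  # columns entering exactly at the top of the grid: entry value is the
  # KKT crossing |d_j| (active at lambda just below it)
  entries[!is.na(first_idx) & first_idx == 1] <-
    abs(d[!is.na(first_idx) & first_idx == 1])
  refine <- function(lo, hi, cols, warm) {
    # invariant: every col in cols is zero at hi, nonzero at lo
    while (hi / lo - 1 > refine_tol && length(cols)) {
      mid <- sqrt(lo * hi)
      beta_mid <- drop(gram_lasso_cd(G, d, mid, warm, cd_tol,
                                     cd_sweeps)$beta)
      in_mid <- beta_mid[cols] != 0
      if (any(in_mid) && any(!in_mid)) {
        # split: entered columns live in [mid, hi], the rest in [lo, mid]
        entries[cols[in_mid]] <<- refine_interval(mid, hi, cols[in_mid],
                                                  beta_mid)
        cols <- cols[!in_mid]
        hi <- mid
        warm <- beta_mid
      } else if (all(in_mid)) {
        lo <- mid
        warm <- beta_mid
      } else {
        hi <- mid
        warm <- beta_mid
      }
    }
    entries[cols] <<- sqrt(lo * hi)
    invisible(NULL)
  }
  refine_interval <- function(lo, hi, cols, warm) {
    refine(lo, hi, cols, warm)
    entries[cols]
  }
  todo <- which(!is.na(first_idx) & first_idx > 1)
  if (!is.null(groups)) {
    ambiguous <- integer(0)
    for (r in seq_len(nrow(groups))) {
      g <- groups[r, ]
      fi <- first_idx[g]
      if (anyDuplicated(fi[!is.na(fi)])) ambiguous <- c(ambiguous, g)
    }
    # grid-resolution entries (geometric cell midpoints) for the rest
    rest <- setdiff(todo, ambiguous)
    entries[rest] <- sqrt(grid[first_idx[rest]] * grid[first_idx[rest] - 1])
    todo <- intersect(todo, ambiguous)
  }
  for (i in sort(unique(first_idx[todo]))) {
    cols <- todo[first_idx[todo] == i]
    refine(grid[i], grid[i - 1], cols, path[, i])
  }
  entries
}

#' GhostKnockoffs with penalized regression, known empirical covariance
#'
#' End-to-end selection when the full Gram matrix is released
#' (\eqn{X^\top X} along with \eqn{X^\top Y}, \eqn{\|Y\|_2^2}, `n`):
#' reconstructs pseudo-data with the same Gram matrix, samples knockoffs
#' of it, computes the chosen penalized-regression importance statistic
#' and applies the knockoff filter. The procedure is statistically
#' equivalent to running the individual-level knockoff procedure with the
#' same statistic.
#'
#' @param stats `summary_stats` with `gram_xx` present.
#' @param sigma Feature covariance matrix.
#' @param statistic `"sqrtlasso"`, `"lassomax"`, or `"lassocd"`.
#' @param q Target FDR level.
#' @param lambda Fixed penalty (required for `"lassocd"`; optional
#'   override for `"sqrtlasso"`).
#' @param kappa,mc_samples Square-root-lasso tuning (defaults 0.3, 200).
#' @param M Number of knockoff copies.
#' @param params Optional precomputed `knockoff_params`.
#' @param offset Knockoff filter offset.
#' @param barless Drop absolute values in the coefficient contrast.
#' @return A `selection` object with the importance statistics attached.
#' @export
gk_knowncov <- function(stats, sigma,
                        statistic = c("sqrtlasso", "lassomax", "lassocd"),
                        q = 0.2, lambda = NULL, kappa = 0.3,
                        mc_samples = 200, M = 1, params = NULL,
                        offset = 1, barless = FALSE) {
  statistic <- match.arg(statistic)
  if (is.null(stats$gram_xx)) {
    stop("gk_knowncov requires the empirical Gram matrix X'X; ",
         "use gk_pseudolasso or gk_marginal when it is unavailable")
  }
  if (is.null(params)) params <- knockoff_transform(sigma, M = M)
  gram_full <- rbind(cbind(stats$gram_xx, stats$zs),
                     c(stats$zs, stats$yty))
  pd <- reconstruct_pseudo_data(gram_full, stats$n)
  imp <- switch(statistic,
    sqrtlasso = sqrt_lasso_statistic(pd, params, kappa = kappa,
                                     mc_samples = mc_samples,
                                     lambda = lambda, barless = barless),
    lassomax = lasso_max_statistic(pd, params, barless = barless),
    lassocd = {
      if (is.null(lambda)) stop("statistic 'lassocd' needs a fixed lambda")
      lasso_cd_statistic(pd, params, lambda, barless = barless)
    })
  sel <- if (M == 1) {
    knockoff_threshold(imp$W, q, offset)
  } else {
    multi_knockoff_filter(imp$W, q)
  }
  sel$method <- paste0("gk-", statistic)
  sel$importance <- imp
  sel$ids <- stats$ids
  sel
}
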