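#' Precompute the pseudo-lasso system matrices
#'
#' The quadratic form of the pseudo-lasso depends only on the knockoff
#' construction, not on the data: \eqn{C_0} is the
#' \eqn{(M+1)p \times (M+1)p} block matrix with \eqn{\Sigma} on the
#' diagonal blocks and \eqn{\Sigma - D} off the diagonal, and
#' \eqn{C = C_0 + c I} adds a small ridge for numerical stability
#' (swap-invariance is preserved for any `c`). Precomputing these -- plus
#' a symmetric square root of \eqn{C_0} for noise sampling and a Cholesky
#' factor of `C` -- lets many replications share the expensive pieces.
#'
#' @param params A `knockoff_params` object.
#' @param c_ridge Ridge constant; default `1e-4 * mean(diag(sigma))`.
#' @return List with `C`, `C0`, `C0_half`, `chol_C`, `c_ridge`, `p`, `M`.
#' @export
pseudo_system_matrices <- function(params, c_ridge = NULL) {
  sigma <- params$sigma
  p <- params$p
  M <- params$M
  if (is.null(c_ridge)) c_ridge <- 1e-4 * mean(diag(sigma))
  off <- sigma - diag(params$s, p)
  k <- (M + 1) * p
  C0 <- matrix(0, k, k)
  for (a in seq_len(M + 1)) {
    for (b in seq_len(M + 1)) {
      idx_a <- (a - 1) * p + seq_len(p)
      idx_b <- (b - 1) * p + seq_len(p)
      C0[idx_a, idx_b] <- if (a == b) sigma else off
    }
  }
  ev <- eigen(C0, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  C0_half <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  C <- C0 + c_ridge * diag(k)
  chol_C <- chol(C)
  list(C = C, C0 = C0, C0_half = C0_half, chol_C = chol_C,
       c_ridge = c_ridge, p = p, M = M)
}

#' Assemble the pseudo-lasso system from summary statistics
#'
#' Combines the observed scores and the sampled knockoff scores into the
#' linear term \eqn{d = \frac{1}{n}[z_s; \tilde z_s]} of the
#' population-covariance quadratic program
#' \deqn{\min_\beta \tfrac12 \beta^\top C \beta - d^\top \beta +
#'   \lambda \|\beta\|_1.}
#' `C` is S-swap invariant by construction: permuting original/knockoff
#' entries of `d` permutes the solution identically, which yields the
#' flip-sign property and hence FDR control.
#'
#' @param stats A `summary_stats` object.
#' @param params A `knockoff_params` object.
#' @param z_tilde Knockoff scores from [sample_ghost_scores()].
#' @param c_ridge Ridge constant (see [pseudo_system_matrices()]).
#' @param matrices Optional precomputed [pseudo_system_matrices()] output.
#' @return Object of class `pseudo_system`.
#' @export
build_pseudo_system <- function(stats, params, z_tilde, c_ridge = NULL,
                                matrices = NULL) {
  stopifnot(inherits(stats, "summary_stats"),
            inherits(params, "knockoff_params"))
  if (stats$p != params$p) stop("dimension mismatch between stats and params")
  if (length(z_tilde) != params$M * params$p) {
    stop("z_tilde has length ", length(z_tilde), ", expected ",
         params$M * params$p)
  }
  if (is.null(matrices)) matrices <- pseudo_system_matrices(params, c_ridge)
  d <- c(stats$zs, z_tilde) / stats$n
  structure(
    c(matrices,
      list(d = d, n = stats$n, yty = stats$yty,
           w = c(stats$zs, z_tilde))),
    class = "pseudo_system")
}

#' @export
print.pseudo_system <- function(x, ...) {
  cat("Pseudo-lasso system: p =", x$p, ", M =", x$M,
      ", ridge =", format(x$c_ridge), ", n =", x$n, "\n")
  invisible(x)
}

#' Solve the pseudo-lasso at a fixed penalty
#'
#' Coordinate descent on \eqn{\tfrac12 \beta^\top C \beta - d^\top \beta
#' + \lambda\|\beta\|_1}; convergence when the largest coefficient change
#' in a sweep drops below `1e-8` (at most `1e4` sweeps). When
#' \eqn{\Sigma = I} and \eqn{D = I} (no ridge) the program separates and
#' the solution is the coordinatewise soft-threshold of `d`.
#'
#' @param system A `pseudo_system` object.
#' @param lambda Penalty level (>= 0).
#' @param barless Drop absolute values in the coefficient contrast.
#' @return An `importance` object (`W`, full coefficient vector, lambda).
#' @export
solve_pseudo_lasso <- function(system, lambda, barless = FALSE) {
  stopifnot(lambda >= 0)
  fit <- gram_lasso(system$C, system$d, lambda)
  W <- collapse_coefficients(fit$beta, system$p, system$M, barless)
  importance_result(W, "pseudo-lasso", beta = fit$beta, lambda = lambda)
}

#' Moment-based noise-scale estimate from summary statistics
#'
#' Estimates the residual standard deviation \eqn{\sigma} of a
#' homogeneous Gaussian linear model using only \eqn{\|Y\|_2^2}, the
#' scores `w = [z_s; z_tilde]`, and the population covariance blocks:
#' \deqn{\hat\sigma_0^2 = \max\Big(\frac{k+n+1}{n(n+1)}\|Y\|_2^2 -
#'   \frac{1}{n(n+1)} w^\top C^{-1} w,\ 0\Big)}
#' with `k = (M+1)p` (the estimator targets \eqn{\sigma^2}; the square
#' root is returned, clipped at zero). `C` is the ridge-stabilized block
#' matrix, guaranteeing invertibility.
#'
#' @param system A `pseudo_system` object (carries `w` and `yty`).
#' @return Nonnegative scalar \eqn{\hat\sigma_0}.
#' @export
sigma_hat_summary <- function(system) {
  n <- system$n
  k <- length(system$w)
  quad <- sum(system$w * backsolve(system$chol_C,
    forwardsolve(t(system$chol_C), system$w)))
  v <- (k + n + 1) / (n * (n + 1)) * system$yty - quad / (n * (n + 1))
  sqrt(max(v, 0))
}

#' Lasso-min penalty rule
#'
#' \eqn{\lambda = \kappa \cdot \frac{\hat\sigma_0}{n} \cdot
#' E\|R^\top \epsilon\|_\infty}, the expected minimum penalty that shrinks
#' all coefficients to zero under the global null, scaled by
#' \eqn{\kappa \in (0, 1]}. `R` has i.i.d. \eqn{N(0, C_0)} rows and
#' \eqn{\epsilon \sim N(0, I_n)}; since \eqn{R^\top\epsilon \overset{d}{=}
#' \|\epsilon\|_2 \cdot N(0, C_0)}, the expectation is a numerical
#' constant of \eqn{(C_0, n)} estimated by Monte Carlo and reusable
#' across replications via `e_inf`.
#'
#' @param system A `pseudo_system` object.
#' @param kappa Multiplier in (0, 1], default 0.6.
#' @param mc_samples Monte Carlo draws (default 200).
#' @param sigma_hat Optional precomputed [sigma_hat_summary()] value.
#' @param e_inf Optional precomputed \eqn{E\|R^\top\epsilon\|_\infty}.
#' @return Penalty value, with attributes `"sigma_hat"` and `"e_inf"`.
#' @export
lambda_lasso_min <- function(system, kappa = 0.6, mc_samples = 200,
                             sigma_hat = NULL, e_inf = NULL) {
  stopifnot(kappa > 0, kappa <= 1)
  if (is.null(sigma_hat)) sigma_hat <- sigma_hat_summary(system)
  if (is.null(e_inf)) {
    e_inf <- estimate_e_inf(system$C0_half, system$n, mc_samples)
  }
  lambda <- kappa * sigma_hat / system$n * e_inf
  attr(lambda, "sigma_hat") <- sigma_hat
  attr(lambda, "e_inf") <- e_inf
  lambda
}

# Monte Carlo estimate of E || R' eps ||_inf with R rows iid N(0, C0)
# and eps ~ N(0, I_n), using R' eps =d ||eps|| * C0^{1/2} g.
estimate_e_inf <- function(C0_half, n, mc_samples = 200) {
  k <- nrow(C0_half)
  G <- matrix(rnorm(k * mc_samples), k, mc_samples)
  maxima <- apply(abs(C0_half %*% G), 2, max)
  mean(sqrt(rchisq(mc_samples, df = n)) * maxima)
}

#' Pseudo-summary-statistics penalty rule
#'
#' Splits the summary statistics into independent pseudo-training and
#' pseudo-validation pieces (sample sizes \eqn{n_t = 0.8n},
#' \eqn{n_v = 0.2n}):
#' \deqn{r_t = r + \sqrt{n_v / (n\, n_t)}\, R, \quad R \sim N(0, C_0),
#'   \qquad r_v = \frac{1}{n_v}(n r - n_t r_t),}
#' fits the pseudo-lasso path on the training statistics over a
#' log-linear grid of `n_grid` candidates from \eqn{\lambda_{\max} =
#' \|d\|_\infty} down to \eqn{\lambda_{\max}} `* min_ratio`, and picks
#' the \eqn{\lambda} maximizing the validation criterion
#' \eqn{f(\lambda) = \hat\beta^\top r_v / \sqrt{\hat\beta^\top C_0
#' \hat\beta}} (an approximation of the predictive correlation on the
#' validation split; \eqn{f = -\infty} for \eqn{\hat\beta = 0}).
#'
#' @param system A `pseudo_system` object.
#' @param n_grid Grid size (default 100).
#' @param min_ratio Smallest grid value relative to the maximum
#'   (default 1e-3).
#' @param train_frac Training fraction (default 0.8).
#' @param R Optional pre-drawn `N(0, C0)` noise vector (zero noise makes
#'   training and validation statistics coincide with `d` exactly).
#' @return Penalty value, with attributes `"grid"` and `"f_values"`.
#' @export
lambda_pseudo_sum <- function(system, n_grid = 100, min_ratio = 1e-3,
                              train_frac = 0.8, R = NULL) {
  n <- system$n
  nt <- train_frac * n
  nv <- n - nt
  r <- system$d
  if (is.null(R)) {
    # the split noise carries the response scale sqrt(||Y||^2 / n) (unity
    # for a standardized response), so that the training statistics have
    # the variance of statistics computed from n_t samples
    R <- sqrt(system$yty / n) * drop(system$C0_half %*% rnorm(length(r)))
  }
  rt <- r + sqrt(nv / (n * nt)) * R
  rv <- (n * r - nt * rt) / nv
  lam_max <- max(abs(system$d))
  if (lam_max == 0) {
    warning("zero score vector; returning lambda = 0")
    return(0)
  }
  grid <- exp(seq(log(lam_max), log(lam_max * min_ratio),
                  length.out = n_grid))
  path <- gram_lasso_path(system$C, rt, grid)
  f_values <- vapply(seq_len(n_grid), function(l) {
    beta <- path[, l]
    if (all(beta == 0)) return(-Inf)
    denom <- sqrt(drop(crossprod(beta, system$C0 %*% beta)))
    if (denom == 0) return(-Inf)
    sum(beta * rv) / denom
  }, numeric(1))
  if (all(!is.finite(f_values))) {
    warning("all candidate penalties give a null fit; ",
            "returning the largest grid value")
    lambda <- grid[1]
  } else {
    lambda <- grid[which.max(f_values)]
  }
  attr(lambda, "grid") <- grid
  attr(lambda, "f_values") <- f_values
  lambda
}

#' GhostKnockoffs with the pseudo-lasso statistic
#'
#' End-to-end selection when only \eqn{X^\top Y}, \eqn{\|Y\|_2^2}, `n`
#' and \eqn{\Sigma} are available: samples knockoff scores, builds the
#' population-covariance pseudo-lasso system, resolves the penalty by the
#' chosen policy, solves the program and applies the knockoff filter
#' (multi-knockoff filter when `M > 1`).
#'
#' @param stats A `summary_stats` object.
#' @param sigma Feature covariance matrix.
#' @param q Target FDR level.
#' @param lambda Penalty policy: `"lasso-min"`, `"pseudo-sum"`, or a
#'   fixed nonnegative number.
#' @param M Number of knockoff copies.
#' @param kappa Lasso-min multiplier (default 0.6).
#' @param mc_samples Monte Carlo draws for the lasso-min expectation.
#' @param c_ridge Ridge constant for the block matrix.
#' @param params,matrices Optional precomputed construction pieces
#'   (reused across replications).
#' @param e_inf Optional precomputed lasso-min expectation constant.
#' @param offset Knockoff filter offset.
#' @param barless Drop absolute values in the coefficient contrast.
#' @return A `selection` object with importance statistics and the
#'   resolved penalty attached.
#' @export
gk_pseudolasso <- function(stats, sigma, q = 0.2, lambda = "lasso-min",
                           M = 1, kappa = 0.6, mc_samples = 200,
                           c_ridge = NULL, params = NULL,
                           matrices = NULL, e_inf = NULL, offset = 1,
                           barless = FALSE) {
  if (is.null(params)) params <- knockoff_transform(sigma, M = M)
  z_tilde <- sample_ghost_scores(stats, params)
  system <- build_pseudo_system(stats, params, z_tilde,
                                c_ridge = c_ridge, matrices = matrices)
  lambda_val <- if (is.numeric(lambda)) {
    lambda
  } else if (identical(lambda, "lasso-min")) {
    lambda_lasso_min(system, kappa = kappa, mc_samples = mc_samples,
                     e_inf = e_inf)
  } else if (identical(lambda, "pseudo-sum")) {
    lambda_pseudo_sum(system)
  } else {
    stop("lambda must be a number, 'lasso-min', or 'pseudo-sum'")
  }
  imp <- solve_pseudo_lasso(system, as.numeric(lambda_val),
                            barless = barless)
  sel <- if (M == 1) {
    knockoff_threshold(imp$W, q, offset)
  } else {
    multi_knockoff_filter(imp$W, q)
  }
  sel$method <- paste0("gk-pseudolasso-",
                       if (is.numeric(lambda)) "fixed" else lambda)
  sel$importance <- imp
  sel$lambda <- as.numeric(lambda_val)
  sel$ids <- stats$ids
  sel
}
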