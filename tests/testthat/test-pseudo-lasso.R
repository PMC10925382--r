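test_that("pseudo system blocks and ridge behave as constructed", {
  set.seed(301)
  p <- 3
  stats <- summary_stats(c(3, -1, 2), yty = 25, n = 100)
  # Sigma = D = I: C0 = identity, off-diagonal blocks vanish
  params <- knockoff_transform(diag(p), s = rep(1, p))
  zt <- sample_ghost_scores(stats, params)
  sys <- build_pseudo_system(stats, params, zt, c_ridge = 0.01)
  expect_equal(sys$C0, diag(2 * p), tolerance = 1e-10)
  expect_equal(sys$C, diag(2 * p) * 1.01, tolerance = 1e-10)
  expect_equal(sys$d, c(stats$zs, zt) / stats$n)
  # high-correlation 2x2 with equi slack stays PD after ridge
  sig2 <- matrix(c(1, .9, .9, 1), 2)
  par2 <- knockoff_transform(sig2, s_method = "equi")
  st2 <- summary_stats(c(1, 2), yty = 4, n = 50)
  sys2 <- build_pseudo_system(st2, par2, sample_ghost_scores(st2, par2),
                              c_ridge = 0.01)
  expect_gt(min(eigen(sys2$C, symmetric = TRUE, only.values = TRUE)$values),
            0)
  # C is S-swap invariant for a random swap set
  k <- nrow(sys2$C)
  pp <- k / 2
  S <- sample(pp, 1)
  perm <- seq_len(k)
  perm[c(S, S + pp)] <- perm[c(S + pp, S)]
  expect_equal(sys2$C[perm, perm], sys2$C, tolerance = 1e-12)
})

test_that("swap equivariance of the solution holds exactly (Lemma-1 type)", {
  set.seed(311)
  for (rep in 1:8) {
    p <- 6
    sigma <- random_corr(p)
    params <- knockoff_transform(sigma, s_method = "equi")
    stats <- summary_stats(rnorm(p, sd = 3), yty = 30, n = 80)
    sys <- build_pseudo_system(stats, params,
                               sample_ghost_scores(stats, params))
    lambda <- 0.3 * max(abs(sys$d))
    S <- sample(p, sample(p, 1))
    perm <- seq_len(2 * p)
    perm[c(S, S + p)] <- perm[c(S + p, S)]
    b <- knocksum:::gram_lasso(sys$C, sys$d, lambda, tol = 1e-12)$beta
    b_sw <- knocksum:::gram_lasso(sys$C, sys$d[perm], lambda,
                                  tol = 1e-12)$beta
    expect_lt(max(abs(b_sw - b[perm])), 1e-8)
  }
})

test_that("identity system soft-thresholds the scores exactly", {
  set.seed(321)
  p <- 10
  stats <- summary_stats(rnorm(p, sd = 5), yty = 40, n = 60)
  params <- knockoff_transform(diag(p), s = rep(1, p))
  zt <- sample_ghost_scores(stats, params)
  sys <- build_pseudo_system(stats, params, zt, c_ridge = 0)
  lambda <- 0.04
  imp <- solve_pseudo_lasso(sys, lambda)
  d <- sys$d
  closed <- sign(d) * pmax(abs(d) - lambda, 0)
  expect_lt(max(abs(imp$beta - closed)), 1e-10)
  # KKT: full shrinkage at lambda >= ||d||_inf
  imp0 <- solve_pseudo_lasso(sys, max(abs(d)) * 1.001)
  expect_equal(imp0$beta, rep(0, 2 * p))
})

test_that("pseudo-lasso solution matches the glmnet oracle", {
  set.seed(331)
  for (rep in 1:10) {
    p <- 6
    sigma <- random_corr(p)
    params <- knockoff_transform(sigma, s_method = "equi")
    stats <- summary_stats(rnorm(p, sd = 4), yty = 50, n = 100)
    sys <- build_pseudo_system(stats, params,
                               sample_ghost_scores(stats, params))
    lambda <- runif(1, 0.05, 0.6) * max(abs(sys$d))
    mine <- knocksum:::gram_lasso(sys$C, sys$d, lambda, tol = 1e-12)$beta
    oracle <- glmnet_gram_oracle(sys$C, sys$d, lambda)
    expect_lt(max(abs(mine - oracle)), 1e-5)
  }
})

test_that("noise-scale estimator clips and recovers degenerate cases", {
  set.seed(341)
  p <- 4
  params <- knockoff_transform(diag(p), s = rep(1, p))
  # ||Y||^2 = 0 forces a zero estimate
  stats0 <- summary_stats(rep(0, p), yty = 0, n = 50)
  sys0 <- build_pseudo_system(stats0, params, rep(0, p))
  expect_equal(sigma_hat_summary(sys0), 0)
  # large scores with tiny yty force the inner expression negative
  stats_neg <- summary_stats(rep(100, p), yty = 1e-4, n = 50)
  sys_neg <- build_pseudo_system(stats_neg, params, rep(100, p))
  expect_equal(sigma_hat_summary(sys_neg), 0)
})

test_that("lasso-min rule scales correctly and matches brute force", {
  set.seed(351)
  p <- 1
  params <- knockoff_transform(diag(p), s = 1)
  stats <- summary_stats(2, yty = 10, n = 200)
  sys <- build_pseudo_system(stats, params, sample_ghost_scores(stats, params))
  # sigma_hat = 0 gives lambda = 0
  expect_equal(as.numeric(lambda_lasso_min(sys, sigma_hat = 0)), 0)
  # brute-force E||R'eps||_inf at C0 = I_2, n = 200:
  # = E||eps|| * E max(|g1|, |g2|)
  brute <- mean(sqrt(rchisq(1e5, 200))) *
    mean(apply(abs(matrix(rnorm(2e5), 2)), 2, max))
  ests <- replicate(30, knocksum:::estimate_e_inf(diag(2), 200, 200))
  expect_lt(abs(mean(ests) - brute),
            4 * sd(ests) / sqrt(30) + 0.002 * brute)
  # the assembled penalty is kappa * sigma / n * E-term
  lam <- lambda_lasso_min(sys, kappa = 0.6, e_inf = 100, sigma_hat = 2)
  expect_equal(as.numeric(lam), 0.6 * 2 / 200 * 100)
})

test_that("pseudo-sum split is exact at zero noise and scans the grid", {
  set.seed(361)
  p <- 5
  sigma <- random_corr(p)
  params <- knockoff_transform(sigma, s_method = "equi")
  stats <- summary_stats(rnorm(p, sd = 6), yty = 60, n = 100)
  sys <- build_pseudo_system(stats, params,
                             sample_ghost_scores(stats, params))
  # zero-noise branch: training and validation stats equal d identically,
  # so f(lambda) is the in-sample criterion evaluated on d
  lam0 <- lambda_pseudo_sum(sys, R = rep(0, 2 * p))
  grid <- attr(lam0, "grid")
  expect_length(grid, 100)
  expect_equal(grid[1], max(abs(sys$d)))
  expect_equal(grid[100], max(abs(sys$d)) / 1000)
  # log-linear spacing
  expect_equal(diff(log(grid)), rep(diff(log(grid))[1], 99),
               tolerance = 1e-10)
  # independent re-evaluation of f(lambda) from its definition
  f_vals <- attr(lam0, "f_values")
  check <- vapply(seq_along(grid), function(l) {
    b <- knocksum:::gram_lasso(sys$C, sys$d, grid[l], tol = 1e-10)$beta
    if (all(b == 0)) return(-Inf)
    sum(b * sys$d) / sqrt(drop(crossprod(b, sys$C0 %*% b)))
  }, numeric(1))
  finite <- is.finite(f_vals)
  expect_equal(f_vals[finite], check[finite], tolerance = 1e-4)
  expect_equal(which(!finite), which(!is.finite(check)))
})

test_that("full pseudo-lasso pipeline handles nulls and fixed penalties", {
  set.seed(371)
  p <- 30
  stats_null <- summary_stats(rep(0, p), yty = 100, n = 200)
  sel <- gk_pseudolasso(stats_null, diag(p), q = 0.2, lambda = "lasso-min")
  expect_s3_class(sel, "selection")
  sel_fix <- gk_pseudolasso(stats_null, diag(p), q = 0.2, lambda = 0.5)
  expect_equal(sel_fix$lambda, 0.5)
  expect_error(gk_pseudolasso(stats_null, diag(p), lambda = "nope"),
               "lambda must be")
})

test_that("multi-knockoff pseudo-lasso composes with the multi filter", {
  set.seed(381)
  p <- 20
  n <- 300
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p); beta[1:4] <- 6
  Y <- drop(X %*% beta) + sqrt(n) * rnorm(n)
  stats <- make_stats(X, Y, with_gram = FALSE)
  sel <- gk_pseudolasso(stats, diag(p), q = 0.25, lambda = "lasso-min",
                        M = 3)
  expect_s3_class(sel, "selection")
  expect_length(sel$kappa, p)
  expect_true(all(sel$selected %in% seq_len(p)))
})
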