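# Shared fixture builders; everything is generated in code.

# random correlation-scale PSD matrix
random_corr <- function(p, strength = 0.5) {
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) / p
  Dhalf <- diag(1 / sqrt(diag(S)), p)
  R <- Dhalf %*% S %*% Dhalf
  (1 - strength) * diag(p) + strength * (R + t(R)) / 2
}

ar1_sigma <- function(p, rho) rho^abs(outer(seq_len(p), seq_len(p), "-"))

# summary statistics (with Gram) from simulated individual-level data
make_stats <- function(X, Y, with_gram = TRUE) {
  summary_stats(zs = drop(crossprod(X, Y)), yty = sum(Y^2), n = nrow(X),
                gram_xx = if (with_gram) crossprod(X))
}

# independent lasso oracle through glmnet: solve
#   min 0.5 b'Cb - d'b + lambda ||b||_1
# by factoring C = A'A (Cholesky of the PD matrix) and y = A^{-T} d.
glmnet_gram_oracle <- function(C, d, lambda) {
  m <- length(d)
  A <- chol(C)
  y <- drop(solve(t(A), d))
  fit <- glmnet::glmnet(A, y, lambda = lambda / m, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
  drop(coef(fit))[-1]
}

# pseudo-data + knockoff params for a small simulated dataset
small_pseudo <- function(n = 40, p = 5, rho = 0, amp = 3) {
  sigma <- if (rho > 0) ar1_sigma(p, rho) else diag(p)
  X <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  beta <- numeric(p); beta[1:2] <- amp
  Y <- drop(X %*% beta) + rnorm(n)
  stats <- make_stats(X, Y)
  gram_full <- rbind(cbind(stats$gram_xx, stats$zs),
                     c(stats$zs, stats$yty))
  params <- knockoff_transform(sigma, s_method = "equi")
  list(pd = reconstruct_pseudo_data(gram_full, n), params = params,
       stats = stats, sigma = sigma, X = X, Y = Y)
}
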