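test_that("equicorrelated slack matches closed forms", {
  expect_equal(solve_s(diag(3), "equi"), rep(1, 3))
  expect_equal(solve_s(matrix(1), "equi"), 1)
  # 2x2 correlation, eigenvalues 1 +/- rho: s = 2 (1 - rho)
  expect_equal(solve_s(matrix(c(1, .8, .8, 1), 2), "equi"), c(0.4, 0.4),
               tolerance = 1e-8)
  # M = 2 scales the feasible cap to 3/2 lambda_min
  expect_equal(solve_s(matrix(c(1, .8, .8, 1), 2), "equi", M = 2),
               rep(1.5 * 0.2, 2), tolerance = 1e-8)
})

test_that("SDP slack is feasible, bounded and no worse than equi", {
  set.seed(11)
  for (rep in 1:5) {
    p <- sample(3:8, 1)
    sigma <- random_corr(p)
    for (M in c(1, 2)) {
      s <- solve_s(sigma, "sdp", M = M)
      expect_true(all(s >= 0) && all(s <= 1 + 1e-8))
      joint <- (M + 1) / M * sigma - diag(s, p)
      expect_gte(min(eigen(joint, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-6)
      expect_gte(sum(s), sum(solve_s(sigma, "equi", M = M)) - 1e-6)
    }
  }
  # identity covariance saturates the unit bound
  expect_equal(solve_s(diag(4), "sdp"), rep(1, 4), tolerance = 1e-5)
})

test_that("knockoff transform reproduces hand-computed parameters", {
  # identity covariance with s = 1: pure-noise knockoffs
  k <- knockoff_transform(diag(3), s = rep(1, 3))
  expect_equal(k$P, matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(k$V, diag(3), tolerance = 1e-12)
  # 2x2, rho = 0.5, s = (1,1): hand inversion
  k2 <- knockoff_transform(matrix(c(1, .5, .5, 1), 2), s = c(1, 1))
  expect_equal(k2$P, matrix(c(-1, 2, 2, -1) / 3, 2), tolerance = 1e-10)
  expect_equal(k2$V, matrix(2 / 3, 2, 2), tolerance = 1e-10)
  # M = 2 at Sigma = D = I: block-diagonal V with identity blocks
  k3 <- knockoff_transform(diag(2), s = c(1, 1), M = 2)
  expect_equal(k3$V, diag(4), tolerance = 1e-10)
  expect_equal(k3$P, matrix(0, 2, 4), tolerance = 1e-10)
})

test_that("joint knockoff covariance is PSD for accepted s", {
  set.seed(21)
  for (rep in 1:5) {
    sigma <- random_corr(6)
    s <- solve_s(sigma, sample(c("equi", "sdp"), 1))
    k <- knockoff_transform(sigma, s = s)
    G <- rbind(cbind(sigma, sigma - diag(s)),
               cbind(sigma - diag(s), sigma))
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_gte(min(eigen(k$V, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("sampled knockoffs have the stated joint covariance", {
  set.seed(31)
  p <- 3
  sigma <- ar1_sigma(p, 0.5)
  params <- knockoff_transform(sigma, s_method = "equi")
  # deterministic branch: E = 0 gives X P exactly
  X <- matrix(rnorm(10 * p), 10, p)
  expect_equal(sample_knockoff_matrix(X, params, E = matrix(0, 10, p)),
               X %*% params$P, tolerance = 1e-12)
  # LLN: empirical covariance of [X X~] approaches the joint target
  n <- 5000
  X <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  Xt <- sample_knockoff_matrix(X, params)
  emp <- crossprod(cbind(X, Xt)) / n
  target <- rbind(cbind(sigma, sigma - diag(params$s)),
                  cbind(sigma - diag(params$s), sigma))
  expect_lt(max(abs(emp - target)), 6 / sqrt(n))
  # identity covariance with s = 1: knockoffs are fresh noise
  params_id <- knockoff_transform(diag(p), s = rep(1, p))
  Xt_id <- sample_knockoff_matrix(X[, 1:p], params_id)
  expect_lt(max(abs(crossprod(X[, 1:p], Xt_id) / n)), 6 / sqrt(n))
})

test_that("knockoff threshold matches enumeration on worked examples", {
  sel <- knockoff_threshold(c(5, 4, -3, 2, 1, -1), q = 0.5)
  expect_equal(sel$threshold, 4)
  expect_equal(sel$selected, c(1L, 2L))
  sel2 <- knockoff_threshold(c(3, 2, 1), q = 0.34)
  expect_equal(sel2$threshold, 1)
  expect_equal(sel2$selected, 1:3)
  # no positive statistic can ever be selected
  sel3 <- knockoff_threshold(c(-2, -1, -0.5), q = 0.2)
  expect_equal(sel3$threshold, Inf)
  expect_length(sel3$selected, 0)
  expect_length(knockoff_threshold(rep(0, 5), q = 0.2)$selected, 0)
})

test_that("threshold agrees with a brute-force scan on random inputs", {
  set.seed(41)
  brute <- function(W, q, offset) {
    ts <- sort(unique(abs(W[W != 0])))
    ok <- ts[vapply(ts, function(t) {
      (offset + sum(W <= -t)) / max(sum(W >= t), 1) <= q
    }, logical(1))]
    if (length(ok)) which(W >= min(ok)) else integer(0)
  }
  for (rep in 1:25) {
    W <- round(rnorm(30), 1)  # ties on purpose
    q <- runif(1, 0.05, 0.5)
    offset <- sample(0:1, 1)
    expect_identical(knockoff_threshold(W, q, offset)$selected,
                     brute(W, q, offset))
  }
})

test_that("selection is monotone in q and obeys the size law", {
  set.seed(51)
  for (rep in 1:10) {
    W <- rnorm(40)
    qs <- sort(runif(4, 0.05, 0.6))
    sels <- lapply(qs, function(q) knockoff_threshold(W, q)$selected)
    for (i in seq_len(length(qs) - 1)) {
      expect_true(all(sels[[i]] %in% sels[[i + 1]]))
    }
    for (i in seq_along(qs)) {
      if (length(sels[[i]]) > 0) {
        expect_gte(length(sels[[i]]), ceiling(1 / qs[i]))
      }
    }
  }
})

test_that("multi-knockoff filter reduces to the standard filter at M = 1", {
  set.seed(61)
  for (rep in 1:10) {
    p <- 25
    scores <- matrix(abs(rnorm(2 * p)), p, 2)
    q <- runif(1, 0.1, 0.5)
    sel_multi <- multi_knockoff_filter(scores, q)
    W <- sign(scores[, 1] - scores[, 2]) * abs(scores[, 1] - scores[, 2])
    sel_std <- knockoff_threshold(W, q)
    expect_identical(sel_multi$selected, sel_std$selected)
  }
})

test_that("multi-knockoff filter matches exhaustive threshold enumeration", {
  set.seed(71)
  brute_multi <- function(scores, q) {
    M <- ncol(scores) - 1
    kappa <- max.col(scores, ties.method = "first") - 1L
    tau <- apply(scores, 1, function(r) max(r) - median(r[-which.max(r)]))
    cand <- sort(unique(tau[tau > 0]))
    for (t in cand) {
      num <- 1 / M + sum(kappa >= 1 & tau >= t) / M
      den <- max(sum(kappa == 0 & tau >= t), 1)
      if (num / den <= q) return(which(kappa == 0 & tau >= t))
    }
    integer(0)
  }
  for (rep in 1:20) {
    scores <- matrix(abs(rnorm(8 * 4)), 8, 4)  # p = 8, M = 3
    q <- runif(1, 0.1, 0.6)
    expect_identical(multi_knockoff_filter(scores, q)$selected,
                     brute_multi(scores, q))
  }
  # all originals dominated: nothing can be selected
  sc <- cbind(rep(0.1, 6), matrix(1, 6, 3))
  expect_length(multi_knockoff_filter(sc, 0.3)$selected, 0)
})

test_that("null scores are exchangeable with their knockoffs", {
  set.seed(81)
  p <- 4
  sigma <- ar1_sigma(p, 0.5)
  params <- knockoff_transform(sigma, s_method = "equi")
  reps <- 1000
  Z <- Zt <- matrix(NA_real_, reps, p)
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(20 * p), 20, p) %*% chol(sigma)
    Y <- rnorm(20)  # global null: Y independent of X
    Xt <- sample_knockoff_matrix(X, params)
    Z[r, ] <- crossprod(X, Y)
    Zt[r, ] <- crossprod(Xt, Y)
  }
  for (j in seq_len(p)) {
    expect_gt(suppressWarnings(ks.test(Z[, j], Zt[, j]))$p.value, 0.01)
  }
})
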