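#' Build Gaussian (multi-)knockoff parameters from a covariance matrix
#'
#' Given the feature covariance \eqn{\Sigma} and a slack vector `s`
#' (typically from [solve_s()]), computes the conditional-distribution
#' parameters of the Gaussian knockoff sampler: with \eqn{D =
#' \mathrm{diag}(s)},
#' \deqn{P = I - \Sigma^{-1} D, \qquad V = 2D - D \Sigma^{-1} D}
#' for a single knockoff copy. For `M > 1` copies, `P` is the `p x Mp`
#' horizontal stack of \eqn{I - \Sigma^{-1}D} and `V` is the `Mp x Mp`
#' block matrix with \eqn{2D - D\Sigma^{-1}D} on the diagonal blocks and
#' \eqn{D - D\Sigma^{-1}D} off the diagonal. `V` is repaired to PSD by the
#' minimal jitter, which is recorded, and a symmetric square root
#' `V_half` is precomputed for sampling.
#'
#' @param sigma Feature covariance matrix.
#' @param s Slack vector; defaults to [solve_s()] on `sigma`.
#' @param M Number of knockoff copies.
#' @param s_method Passed to [solve_s()] when `s` is missing.
#' @return Object of class `knockoff_params`: a list with `sigma`, `s`,
#'   `P` (`p x Mp`), `V` (`Mp x Mp`), `V_half`, `M`, `p`, and `jitter`.
#' @export
knockoff_transform <- function(sigma, s = NULL, M = 1,
                               s_method = c("auto", "sdp", "equi")) {
  sigma <- validate_sigma(sigma)
  p <- nrow(sigma)
  if (is.null(s)) s <- solve_s(sigma, match.arg(s_method), M = M)
  stopifnot(length(s) == p, all(s >= 0))
  D <- diag(s, p)
  # Sigma^{-1} D, with jitter escalation if Sigma is numerically singular
  sig_inv_D <- tryCatch(solve(sigma, D), error = function(e) NULL)
  if (is.null(sig_inv_D)) {
    rep_sig <- psd_jitter(sigma)
    sig_inv_D <- solve(rep_sig$mat + 1e-10 * diag(p), D)
  }
  P_block <- diag(p) - sig_inv_D
  DSD <- D %*% sig_inv_D              # D Sigma^{-1} D
  DSD <- (DSD + t(DSD)) / 2
  V_diag <- 2 * D - DSD
  if (M == 1) {
    V <- V_diag
    P <- P_block
  } else {
    V_off <- D - DSD
    V <- matrix(0, M * p, M * p)
    for (a in seq_len(M)) {
      for (b in seq_len(M)) {
        idx_a <- (a - 1) * p + seq_len(p)
        idx_b <- (b - 1) * p + seq_len(p)
        V[idx_a, idx_b] <- if (a == b) V_diag else V_off
      }
    }
    P <- do.call(cbind, rep(list(P_block), M))
  }
  rep_v <- psd_jitter(V)
  V <- rep_v$mat
  ev <- eigen(V, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  V_half <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  structure(
    list(sigma = sigma, s = s, P = P, V = V, V_half = V_half,
         M = M, p = p, jitter = rep_v$jitter),
    class = "knockoff_params")
}

#' @export
print.knockoff_params <- function(x, ...) {
  cat("Gaussian knockoff parameters: p =", x$p, ", M =", x$M,
      ", jitter =", format(x$jitter), "\n")
  cat("  s range: [", format(min(x$s)), ",", format(max(x$s)), "]\n")
  invisible(x)
}

#' Sample a knockoff data matrix
#'
#' Draws \eqn{\tilde X = X P + E V^{1/2}} with `E` an `n x Mp` matrix of
#' i.i.d. standard normal entries, so that `[X, X~]` has the joint
#' knockoff covariance. Uses the current RNG state; seed it for
#' reproducibility.
#'
#' @param X Data matrix (`n x p`), columns conforming to `params$sigma`.
#' @param params A `knockoff_params` object.
#' @param E Optional noise matrix (for deterministic checks).
#' @return `n x Mp` knockoff matrix.
#' @export
sample_knockoff_matrix <- function(X, params, E = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != params$p) {
    stop("X has ", ncol(X), " columns but params expect ", params$p)
  }
  mp <- params$M * params$p
  if (is.null(E)) {
    E <- matrix(rnorm(nrow(X) * mp), nrow(X), mp)
  }
  X %*% params$P + E %*% params$V_half
}

#' Knockoff selection filter
#'
#' Computes the data-dependent threshold
#' \deqn{T = \min\{t \in \mathcal{W} : \frac{\mathrm{offset} + \#\{j : W_j
#'   \le -t\}}{\#\{j : W_j \ge t\} \vee 1} \le q\}}
#' where \eqn{\mathcal{W}} is the set of distinct nonzero \eqn{|W_j|},
#' and selects \eqn{\{j : W_j \ge T\}}. `offset = 1` gives the knockoff+
#' procedure with exact FDR control; `offset = 0` the modified
#' (mFDR-controlling) variant. When no threshold qualifies, `T = Inf` and
#' the selection is empty.
#'
#' @param W Numeric vector of importance statistics.
#' @param q Target FDR level in (0, 1).
#' @param offset 0 or 1 (default 1).
#' @return Object of class `selection`: list with `threshold`, `selected`
#'   (integer indices), `q`, `offset`, and `W`.
#' @export
knockoff_threshold <- function(W, q, offset = 1) {
  stopifnot(q > 0, q < 1, offset %in% c(0, 1))
  if (any(!is.finite(W))) stop("W must be finite")
  ts <- sort(unique(abs(W[W != 0])))
  threshold <- Inf
  for (t in ts) {
    ratio <- (offset + sum(W <= -t)) / max(sum(W >= t), 1)
    if (ratio <= q) {
      threshold <- t
      break
    }
  }
  selected <- if (is.finite(threshold)) which(W >= threshold) else integer(0)
  structure(
    list(threshold = threshold, selected = selected, q = q,
         offset = offset, W = W),
    class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("Knockoff selection at q =", x$q, ": ", length(x$selected),
      "of", length(x$W), "variables, threshold =",
      if (is.finite(x$threshold)) format(x$threshold) else "Inf", "\n")
  invisible(x)
}

#' Multi-knockoff selection filter
#'
#' Generalizes the knockoff filter to `M` simultaneous knockoff copies
#' per feature. For each feature `j` with per-copy scores
#' \eqn{T_j^{(0)}, \ldots, T_j^{(M)}} (original first), the winner index
#' \eqn{\kappa_j} is the argmax and the gap \eqn{\tau_j} is the top score
#' minus the median of the remaining `M` scores. The threshold is
#' \deqn{T = \min\{t : \frac{1/M + (1/M)\,\#\{j: \kappa_j \ge 1, \tau_j
#'   \ge t\}}{\#\{j: \kappa_j = 0, \tau_j \ge t\} \vee 1} \le q\}}
#' and the selection is \eqn{\{j : \kappa_j = 0, \tau_j \ge T\}}. At
#' `M = 1` this reduces exactly to [knockoff_threshold()] with
#' `offset = 1` applied to the signed gaps.
#'
#' @param scores `p x (M+1)` matrix of nonnegative per-copy importance
#'   scores, original variable in column 1.
#' @param q Target FDR level.
#' @return A `selection` object; `W` holds the signed gap statistics
#'   (positive when the original wins), plus fields `kappa` and `tau`.
#' @export
multi_knockoff_filter <- function(scores, q) {
  scores <- as.matrix(scores)
  M <- ncol(scores) - 1
  if (M < 1) stop("scores must have at least 2 columns (original + M >= 1)")
  stopifnot(q > 0, q < 1)
  kappa <- max.col(scores, ties.method = "first") - 1L
  tau <- apply(scores, 1, function(r) {
    top <- which.max(r)
    max(r) - stats::median(r[-top])
  })
  cand <- sort(unique(tau[tau > 0]))
  threshold <- Inf
  for (t in cand) {
    num <- 1 / M + (1 / M) * sum(kappa >= 1 & tau >= t)
    den <- max(sum(kappa == 0 & tau >= t), 1)
    if (num / den <= q) {
      threshold <- t
      break
    }
  }
  selected <- if (is.finite(threshold)) {
    which(kappa == 0 & tau >= threshold)
  } else {
    integer(0)
  }
  out <- structure(
    list(threshold = threshold, selected = selected, q = q,
         offset = 1 / M, W = ifelse(kappa == 0, tau, -tau)),
    class = "selection")
  out$kappa <- kappa
  out$tau <- tau
  out
}
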