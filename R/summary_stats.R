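#' Bundle study summary statistics
#'
#' The observable quantities a study releases in place of individual-level
#' data: the score vector \eqn{z_s = X^\top Y}, the squared response norm
#' \eqn{\|Y\|_2^2}, the sample size `n`, and optionally the empirical Gram
#' matrix \eqn{X^\top X}.
#'
#' @param zs Numeric p-vector, \eqn{X^\top Y}.
#' @param yty Scalar \eqn{\|Y\|_2^2}, nonnegative.
#' @param n Sample size.
#' @param gram_xx Optional `p x p` matrix \eqn{X^\top X}.
#' @param ids Optional variable labels (default `V1..Vp`).
#' @return Object of class `summary_stats`.
#' @export
summary_stats <- function(zs, yty, n, gram_xx = NULL, ids = NULL) {
  zs <- as.numeric(zs)
  p <- length(zs)
  if (!is.numeric(yty) || length(yty) != 1 || yty < 0) {
    stop("yty must be a single nonnegative number")
  }
  if (!is.numeric(n) || length(n) != 1 || n <= 0) stop("n must be positive")
  if (!is.null(gram_xx)) {
    gram_xx <- as.matrix(gram_xx)
    if (nrow(gram_xx) != p || ncol(gram_xx) != p) {
      stop("gram_xx must be ", p, " x ", p)
    }
    asym <- max(abs(gram_xx - t(gram_xx)))
    if (asym > 1e-6 * max(1, max(abs(gram_xx)))) {
      stop("gram_xx is asymmetric beyond tolerance")
    }
    gram_xx <- (gram_xx + t(gram_xx)) / 2
  }
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  stopifnot(length(ids) == p)
  structure(list(zs = zs, yty = yty, n = n, gram_xx = gram_xx,
                 ids = as.character(ids), p = p),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("Summary statistics: p =", x$p, ", n =", x$n,
      ", ||Y||^2 =", format(x$yty),
      if (is.null(x$gram_xx)) "(no X'X)" else "(with X'X)", "\n")
  invisible(x)
}

#' Convert marginal Z-scores to score-scale summary statistics
#'
#' GWAS tools usually publish per-variant marginal Z-scores and a sample
#' size rather than \eqn{X^\top Y} and \eqn{\|Y\|_2^2}. Assuming
#' standardized features and a unit-variance response, \eqn{X_j^\top Y
#' \approx \sqrt{n}\, Z_j} and \eqn{\|Y\|_2^2 \approx n}. This adapter
#' applies that conversion; it is an approximation and is flagged as such
#' in the returned object.
#'
#' @param z Numeric vector of marginal Z-scores.
#' @param n Sample size.
#' @param ids Optional variable labels.
#' @return `summary_stats` object with attribute `"converted_from_z"`.
#' @export
zscores_to_summary <- function(z, n, ids = NULL) {
  out <- summary_stats(zs = sqrt(n) * as.numeric(z), yty = n, n = n,
                       ids = ids)
  attr(out, "converted_from_z") <- TRUE
  out
}

#' Sample knockoff score vectors from summary statistics
#'
#' Draws the "ghost" knockoff scores
#' \deqn{\tilde z_s = P^\top z_s + \|Y\|_2\, Z, \qquad Z \sim N(0, V),}
#' which, conditional on the data, have the same distribution as
#' \eqn{\tilde X^\top Y} computed from an actual knockoff matrix. No
#' individual-level data is needed.
#'
#' @param stats A `summary_stats` object.
#' @param params A `knockoff_params` object of matching dimension.
#' @param Z Optional pre-drawn `N(0, V)` vector (for deterministic
#'   checks); `Z = 0` gives the conditional mean \eqn{P^\top z_s}.
#' @return Numeric `Mp`-vector of knockoff scores.
#' @export
sample_ghost_scores <- function(stats, params, Z = NULL) {
  stopifnot(inherits(stats, "summary_stats"),
            inherits(params, "knockoff_params"))
  if (stats$p != params$p) {
    stop("summary statistics have p = ", stats$p,
         " but knockoff parameters have p = ", params$p)
  }
  mp <- params$M * params$p
  if (is.null(Z)) {
    Z <- drop(params$V_half %*% rnorm(mp))
  } else {
    stopifnot(length(Z) == mp)
  }
  drop(crossprod(params$P, stats$zs)) + sqrt(stats$yty) * Z
}

#' Marginal correlation difference importance statistic
#'
#' \eqn{W_j = |z_{s,j}| - |\tilde z_{s,j}|}: the flip-sign statistic of
#' the original GhostKnockoffs procedure (single knockoff copy).
#'
#' @param stats A `summary_stats` object.
#' @param z_tilde Knockoff scores from [sample_ghost_scores()] (`M = 1`).
#' @return Numeric p-vector `W`.
#' @export
marginal_diff_stat <- function(stats, z_tilde) {
  if (length(z_tilde) != stats$p) {
    stop("z_tilde has length ", length(z_tilde), ", expected ", stats$p,
         " (marginal statistic requires M = 1)")
  }
  abs(stats$zs) - abs(z_tilde)
}

#' GhostKnockoffs with the marginal correlation difference statistic
#'
#' End-to-end summary-statistic knockoff selection using only
#' \eqn{X^\top Y}, \eqn{\|Y\|_2^2} and \eqn{\Sigma}: builds the knockoff
#' parameters, samples ghost scores, forms \eqn{W = |z_s| - |\tilde z_s|}
#' and applies the knockoff filter at level `q`. With `M > 1` the
#' per-copy scores \eqn{|z_s|, |\tilde z^{(1)}|, \ldots, |\tilde z^{(M)}|}
#' enter the multi-knockoff filter instead.
#'
#' @param stats A `summary_stats` object.
#' @param sigma Feature covariance matrix.
#' @param q Target FDR level.
#' @param M Number of knockoff copies.
#' @param params Optional precomputed `knockoff_params` (reused across
#'   replications for speed).
#' @param offset Knockoff filter offset (default 1, knockoff+).
#' @return A `selection` object with the statistic vector attached.
#' @export
gk_marginal <- function(stats, sigma, q = 0.2, M = 1, params = NULL,
                        offset = 1) {
  if (is.null(params)) params <- knockoff_transform(sigma, M = M)
  z_tilde <- sample_ghost_scores(stats, params)
  if (M == 1) {
    W <- marginal_diff_stat(stats, z_tilde)
    sel <- knockoff_threshold(W, q, offset)
  } else {
    scores <- cbind(abs(stats$zs),
                    matrix(abs(z_tilde), stats$p, M))
    sel <- multi_knockoff_filter(scores, q)
  }
  sel$method <- "gk-marginal"
  sel$ids <- stats$ids
  sel
}
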