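#' Validate a covariance / LD matrix
#'
#' Checks symmetry and (near) positive semi-definiteness of a feature
#' covariance matrix, symmetrizing tiny storage asymmetries. LD matrices
#' from reference panels are expected on the correlation scale
#' (unit diagonal), but any PSD covariance is accepted.
#'
#' @param sigma Square numeric matrix.
#' @param tol Tolerance for symmetry and for the minimum eigenvalue.
#' @return The symmetrized matrix, with attribute `"min_eig"`.
#' @export
validate_sigma <- function(sigma, tol = 1e-8) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma)) {
    stop("sigma must be square, got ", nrow(sigma), " x ", ncol(sigma))
  }
  asym <- max(abs(sigma - t(sigma)))
  if (asym > 1e-6) {
    stop("sigma is asymmetric beyond tolerance (max |A - A'| = ",
         format(asym), ")")
  }
  sigma <- (sigma + t(sigma)) / 2
  min_eig <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig < -tol) {
    stop("sigma is not positive semi-definite (min eigenvalue = ",
         format(min_eig), ")")
  }
  attr(sigma, "min_eig") <- min_eig
  sigma
}

#' Repair a symmetric matrix to positive semi-definiteness
#'
#' Adds the smallest jitter `c * I` from an escalating ladder
#' (0, 1e-10, 1e-8, ...) such that the minimum eigenvalue is at least
#' `-1e-10`, and records the constant used.
#'
#' @param mat Symmetric matrix.
#' @param max_jitter Largest jitter tried before giving up.
#' @return List with elements `mat` and `jitter`.
#' @export
psd_jitter <- function(mat, max_jitter = 1e-2) {
  ladder <- c(0, 10^seq(-10, log10(max_jitter), by = 2))
  for (c_try in ladder) {
    cand <- mat
    if (c_try > 0) diag(cand) <- diag(cand) + c_try
    min_eig <- min(eigen(cand, symmetric = TRUE, only.values = TRUE)$values)
    if (min_eig >= -1e-10) {
      return(list(mat = cand, jitter = c_try, min_eig = min_eig))
    }
  }
  stop("matrix could not be repaired to PSD with jitter up to ",
       format(max_jitter))
}

#' Solve for the knockoff slack vector s
#'
#' Computes the free parameter vector \eqn{s} of the Gaussian knockoff
#' construction, subject to \eqn{\mathrm{diag}(s) \preceq \frac{M+1}{M}\Sigma}
#' (which guarantees the joint covariance of the original features and all
#' `M` knockoff copies is PSD) and \eqn{0 \le s_j \le \Sigma_{jj}}.
#'
#' Two constructions are available:
#' \describe{
#'   \item{`"equi"`}{equicorrelated, \eqn{s = \min(\frac{M+1}{M}
#'     \lambda_{\min}(\Sigma),\ \min_j \Sigma_{jj}) \cdot 1}.}
#'   \item{`"sdp"`}{maximize \eqn{\sum_j s_j} under the constraints above,
#'     by exact cyclic coordinate ascent (each coordinate maximization has
#'     the closed form \eqn{s_j \le 1/(B^{-1})_{jj}}).}
#' }
#' The default picks `"sdp"` for `p <= 500` and `"equi"` for larger
#' problems. If the SDP ascent fails numerically it falls back to `"equi"`
#' with a warning.
#'
#' @param sigma Covariance matrix (validated by [validate_sigma()]).
#' @param method `"sdp"`, `"equi"`, or `"auto"` (default).
#' @param M Number of knockoff copies (default 1).
#' @param tol Convergence tolerance for the SDP ascent.
#' @return Numeric vector `s` of length `p`.
#' @export
solve_s <- function(sigma, method = c("auto", "sdp", "equi"), M = 1,
                    tol = 1e-5) {
  method <- match.arg(method)
  sigma <- validate_sigma(sigma)
  p <- nrow(sigma)
  if (M < 1) stop("M must be at least 1")
  if (method == "auto") method <- if (p <= 500) "sdp" else "equi"
  scale_fac <- (M + 1) / M
  ub <- min(diag(sigma))
  if (method == "equi") {
    lam_min <- max(attr(sigma, "min_eig"), 0)
    s <- rep(min(scale_fac * lam_min, ub), p)
    return(s)
  }
  # coordinate-ascent maximization of sum(s) s.t. diag(s) <= scale_fac*Sigma
  target <- scale_fac * sigma
  rep0 <- psd_jitter(target)
  s <- tryCatch(
    drop(solve_s_sdp_cd(rep0$mat, diag(sigma), tol, 100L)),
    error = function(e) {
      warning("SDP coordinate ascent failed (", conditionMessage(e),
              "); falling back to equicorrelated construction")
      NULL
    })
  if (is.null(s)) return(solve_s(sigma, "equi", M = M))
  s <- pmin(pmax(s, 0), diag(sigma))
  # the coordinate ascent can stall at a corner of the feasible set; the
  # equicorrelated point is always feasible, so keep whichever dominates
  s_equi <- solve_s(sigma, "equi", M = M)
  if (sum(s_equi) > sum(s)) s_equi else s
}
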