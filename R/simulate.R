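#' Define a simulation scenario
#'
#' Bundles the design parameters of the synthetic-data generator:
#' Gaussian features that are independent or AR(1)-correlated
#' (\eqn{\Sigma_{s,t} = \rho^{|s-t|}}), or genotype-like discrete
#' features (standardized Binomial(2, maf) columns with maf drawn
#' uniformly from `maf_range`); a sparse linear response \eqn{Y = X\beta
#' + \sqrt{n}\,\epsilon} with `k_nonzero` coefficients of size
#' `amplitude` and random signs (so `amplitude` reads as an expected
#' marginal Z-score), or a mixed-effect logit response with latent
#' Gaussian noise and prevalence set through the intercept.
#'
#' @param n,p Sample size and feature count.
#' @param design `"independent"`, `"ar1"`, or `"genotype"`.
#' @param rho AR(1) autocorrelation in `[0, 1)`.
#' @param maf_range Minor-allele-frequency range for genotype designs.
#' @param k_nonzero Number of true signals (default 30).
#' @param amplitude Signal size `A` (default 4).
#' @param response `"linear"` or `"logit"`.
#' @param prevalence Expected case fraction for the logit response
#'   (default 0.1, i.e. intercept `-log(9)`).
#' @param logit_latent_sd Standard deviation of the latent logit noise
#'   (default 1).
#' @param logit_maf_effects For genotype designs with a logit response,
#'   use MAF-standardized effect sizes
#'   \eqn{\beta_j = 1/(20\sqrt{m_j(1-m_j)})} on the raw allele-count
#'   scale instead of `amplitude`.
#' @param q Target FDR level (default 0.2).
#' @param sigma_source `"true"` (methods receive the generating
#'   covariance) or `"reference"` (a shrinkage estimate from an
#'   independent panel of the same size, re-drawn each replication).
#' @param s_method Passed to [solve_s()].
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n, p, design = c("independent", "ar1", "genotype"),
                         rho = 0, maf_range = c(0.05, 0.5),
                         k_nonzero = 30, amplitude = 4,
                         response = c("linear", "logit"),
                         prevalence = 0.1, logit_latent_sd = 1,
                         logit_maf_effects = FALSE, q = 0.2,
                         sigma_source = c("true", "reference"),
                         s_method = "auto") {
  design <- match.arg(design)
  response <- match.arg(response)
  sigma_source <- match.arg(sigma_source)
  stopifnot(k_nonzero <= p, rho >= 0, rho < 1, amplitude >= 0)
  structure(list(n = n, p = p, design = design, rho = rho,
                 maf_range = maf_range, k_nonzero = k_nonzero,
                 amplitude = amplitude, response = response,
                 prevalence = prevalence,
                 logit_latent_sd = logit_latent_sd,
                 logit_maf_effects = logit_maf_effects, q = q,
                 sigma_source = sigma_source, s_method = s_method),
            class = "sim_scenario")
}

# True feature covariance of a scenario (identity for the standardized
# genotype design).
scenario_sigma <- function(scenario) {
  p <- scenario$p
  switch(scenario$design,
    independent = diag(p),
    ar1 = scenario$rho^abs(outer(seq_len(p), seq_len(p), "-")),
    genotype = diag(p))
}

#' Draw a design matrix for a scenario
#'
#' @param scenario A `sim_scenario`.
#' @return List with `X` (`n x p`), `sigma` (the generating covariance),
#'   and for genotype designs `maf` (per-column minor allele frequency).
#' @export
generate_design <- function(scenario) {
  n <- scenario$n
  p <- scenario$p
  sigma <- scenario_sigma(scenario)
  if (scenario$design == "genotype") {
    maf <- runif(p, scenario$maf_range[1], scenario$maf_range[2])
    G <- matrix(rbinom(n * p, 2, rep(maf, each = n)), n, p)
    X <- sweep(G, 2, 2 * maf) %*% diag(1 / sqrt(2 * maf * (1 - maf)), p)
    return(list(X = X, sigma = sigma, maf = maf))
  }
  Z <- matrix(rnorm(n * p), n, p)
  X <- if (scenario$design == "ar1" && scenario$rho > 0) {
    Z %*% chol(sigma)
  } else {
    Z
  }
  list(X = X, sigma = sigma)
}

#' Draw a response and its true support
#'
#' Linear: \eqn{Y = X\beta + \sqrt{n}\,\epsilon} with
#' \eqn{\epsilon_i \sim N(0,1)} i.i.d. Logit:
#' \eqn{Y_i \sim \mathrm{Bernoulli}(\mu_i)} with
#' \eqn{\mathrm{logit}(\mu_i) = \beta_0 + x_i^\top\beta + \epsilon_i^B}.
#' The support is `k_nonzero` uniform-random coordinates with
#' equiprobable signs.
#'
#' @param X Design matrix.
#' @param scenario A `sim_scenario`.
#' @param maf Optional per-column MAF (for `logit_maf_effects`).
#' @return List with `Y`, `support` (indices), `beta`.
#' @export
generate_response <- function(X, scenario, maf = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  support <- sort(sample.int(p, scenario$k_nonzero))
  beta <- numeric(p)
  if (scenario$response == "logit" && scenario$logit_maf_effects &&
      !is.null(maf)) {
    # raw-scale beta_j = 1/(20 sqrt(m(1-m))) on allele counts equals
    # sqrt(2)/20 on the standardized columns
    beta[support] <- sqrt(2) / 20
  } else {
    beta[support] <- scenario$amplitude *
      sample(c(-1, 1), scenario$k_nonzero, replace = TRUE)
  }
  eta <- drop(X %*% beta)
  if (scenario$response == "linear") {
    Y <- eta + sqrt(n) * rnorm(n)
  } else {
    b0 <- stats::qlogis(scenario$prevalence)
    latent <- b0 + eta + scenario$logit_latent_sd * rnorm(n)
    Y <- rbinom(n, 1, stats::plogis(latent))
  }
  list(Y = Y, support = support, beta = beta)
}

# Correlation-scale shrinkage covariance estimate from an independent
# reference panel (target: identity), in the style of the
# Schafer-Strimmer estimator.
shrinkage_correlation <- function(X) {
  n <- nrow(X)
  Xs <- scale(X)
  R <- crossprod(Xs) / (n - 1)
  r2_off <- R[upper.tri(R)]^2
  # variance of the empirical correlations under independence ~ 1/n
  gamma <- min(1, max(0, sum(1 / n) * length(r2_off) / sum(r2_off)))
  S <- (1 - gamma) * R
  diag(S) <- 1
  S
}

#' Individual-level knockoff reference (cross-validated lasso)
#'
#' The benchmark unavailable to summary-statistic methods: sample a
#' knockoff matrix, fit a cross-validated lasso on `[X, X~]` (via
#' `glmnet`), take \eqn{W_j = |\hat\beta_j| - |\hat\beta_{j+p}|} at the
#' CV-minimizing penalty, and filter at level `q`.
#'
#' @param X,Y Individual-level data.
#' @param params A `knockoff_params` object (`M = 1`).
#' @param q Target FDR level.
#' @param nfolds Cross-validation folds (default 5).
#' @return A `selection` object.
#' @export
kf_lassocv_reference <- function(X, Y, params, q = 0.2, nfolds = 5) {
  x_tilde <- sample_knockoff_matrix(X, params)
  A <- cbind(X, x_tilde)
  cv <- glmnet::cv.glmnet(A, Y, intercept = FALSE, standardize = FALSE,
                          nfolds = nfolds)
  beta <- drop(coef(cv, s = "lambda.min"))[-1]
  p <- ncol(X)
  W <- abs(beta[seq_len(p)]) - abs(beta[p + seq_len(p)])
  sel <- knockoff_threshold(W, q, offset = 1)
  sel$method <- "kf-lassocv"
  sel
}

#' Run replicated simulations and measure FDR and power
#'
#' For each replication: draw a design and response from the scenario,
#' form the summary statistics, run every requested method on the same
#' data, and record the false discovery proportion
#' `FDP = |S intersect H0| / max(|S|, 1)` and power
#' `|S intersect support| / k_nonzero`. Per-replication failures are
#' logged and excluded, with the count reported.
#'
#' @param scenario A `sim_scenario`.
#' @param methods Character vector from `"gk-marginal"`,
#'   `"gk-sqrtlasso"`, `"gk-lassomax"`, `"gk-pseudolasso-lasso-min"`,
#'   `"gk-pseudolasso-pseudo-sum"`, `"kf-lassocv"`.
#' @param reps Number of replications.
#' @param seed Master seed; per-replication seeds are derived from it.
#' @return Object of class `sim_result`: list with `summary` (one row
#'   per method: mean power, mean FDP, Monte Carlo standard errors),
#'   `per_rep` (per replication and method), `failures`, `scenario`.
#' @export
run_replications <- function(scenario, methods, reps = 100, seed = 1) {
  known <- c("gk-marginal", "gk-sqrtlasso", "gk-lassomax",
             "gk-pseudolasso-lasso-min", "gk-pseudolasso-pseudo-sum",
             "kf-lassocv")
  if (length(methods) == 0) {
    return(structure(list(summary = data.frame(), per_rep = data.frame(),
                          failures = 0L, scenario = scenario),
                     class = "sim_result"))
  }
  stopifnot(all(methods %in% known))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, reps)
  fixed_sigma <- scenario$sigma_source == "true"
  params <- matrices <- e_inf <- NULL
  if (fixed_sigma) {
    sigma <- scenario_sigma(scenario)
    params <- knockoff_transform(sigma, M = 1,
                                 s_method = scenario$s_method)
    if (any(grepl("pseudolasso", methods))) {
      matrices <- pseudo_system_matrices(params)
      if ("gk-pseudolasso-lasso-min" %in% methods) {
        e_inf <- estimate_e_inf(matrices$C0_half, scenario$n, 200)
      }
    }
  }
  rows <- list()
  failures <- 0L
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    des <- generate_design(scenario)
    resp <- generate_response(des$X, scenario, maf = des$maf)
    if (!fixed_sigma) {
      panel <- generate_design(scenario)
      sigma_hat <- shrinkage_correlation(panel$X)
      params <- knockoff_transform(sigma_hat, M = 1,
                                   s_method = scenario$s_method)
      matrices <- if (any(grepl("pseudolasso", methods))) {
        pseudo_system_matrices(params)
      }
      e_inf <- if ("gk-pseudolasso-lasso-min" %in% methods) {
        estimate_e_inf(matrices$C0_half, scenario$n, 200)
      }
    }
    sigma_used <- params$sigma
    stats <- summary_stats(zs = drop(crossprod(des$X, resp$Y)),
                           yty = sum(resp$Y^2), n = scenario$n,
                           gram_xx = if (any(methods %in%
                             c("gk-sqrtlasso", "gk-lassomax"))) {
                             crossprod(des$X)
                           })
    for (m in methods) {
      sel <- tryCatch(
        switch(m,
          "gk-marginal" = gk_marginal(stats, sigma_used, q = scenario$q,
                                      params = params),
          "gk-sqrtlasso" = gk_knowncov(stats, sigma_used, "sqrtlasso",
                                       q = scenario$q, params = params),
          "gk-lassomax" = gk_knowncov(stats, sigma_used, "lassomax",
                                      q = scenario$q, params = params),
          "gk-pseudolasso-lasso-min" =
            gk_pseudolasso(stats, sigma_used, q = scenario$q,
                           lambda = "lasso-min", params = params,
                           matrices = matrices, e_inf = e_inf),
          "gk-pseudolasso-pseudo-sum" =
            gk_pseudolasso(stats, sigma_used, q = scenario$q,
                           lambda = "pseudo-sum", params = params,
                           matrices = matrices),
          "kf-lassocv" = kf_lassocv_reference(des$X, resp$Y, params,
                                              q = scenario$q)),
        error = function(e) e)
      if (inherits(sel, "error")) {
        failures <- failures + 1L
        rows[[length(rows) + 1]] <- data.frame(
          rep = r, method = m, n_selected = NA_integer_,
          true_positives = NA_integer_, fdp = NA_real_,
          power = NA_real_, error = conditionMessage(sel))
        next
      }
      S <- sel$selected
      tp <- sum(S %in% resp$support)
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, method = m, n_selected = length(S),
        true_positives = tp,
        fdp = (length(S) - tp) / max(length(S), 1),
        power = tp / scenario$k_nonzero, error = NA_character_)
    }
  }
  per_rep <- do.call(rbind, rows)
  ok <- per_rep[is.na(per_rep$error), ]
  summary_df <- do.call(rbind, lapply(split(ok, ok$method), function(d) {
    data.frame(method = d$method[1],
               power = mean(d$power), fdr = mean(d$fdp),
               power_se = stats::sd(d$power) / sqrt(nrow(d)),
               fdr_se = stats::sd(d$fdp) / sqrt(nrow(d)),
               reps = nrow(d))
  }))
  rownames(summary_df) <- NULL
  structure(list(summary = summary_df, per_rep = per_rep,
                 failures = failures, scenario = scenario, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$scenario
  cat("Simulation:", s$design, "design, n =", s$n, ", p =", s$p,
      ", k =", s$k_nonzero, ", A =", s$amplitude, ", q =", s$q, "\n")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  if (x$failures > 0) cat("(", x$failures, "replication failures )\n")
  invisible(x)
}
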