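#' Per-SNP generalized least squares summary in the rotated coordinates
#'
#' With the frozen spectral context, each SNP `s` gives
#' `betahat_s = (xtilde' D^{-1} xtilde)^{-1} xtilde' D^{-1} ytilde` with
#' sampling variance `sigma2_s = (xtilde' D^{-1} xtilde)^{-1}`, where
#' `xtilde = P' x_s`.
#'
#' Because the adjusted observations have the *baseline* GLS fit of the
#' control covariates removed but the SNP column is regressed on alone,
#' the SNP column is mean-centered first (default): the centered column is
#' orthogonal to the intercept, so the single-column GLS matches the
#' intercept-adjusted effect instead of being attenuated by the allele
#' mean.
#'
#' @param ctx A [build_p3d()] context.
#' @param x_s Genotype column (length n).
#' @param center Mean-center `x_s` before rotating (default `TRUE`).
#' @return List with `beta_hat`, `sigma2`.
#' @export
snp_summary <- function(ctx, x_s, center = TRUE) {
  stopifnot(inherits(ctx, "p3d_context"), length(x_s) == ctx$n)
  if (stats::var(x_s) == 0) stop("monomorphic SNP")
  if (center) x_s <- x_s - mean(x_s)
  xt <- as.vector(crossprod(ctx$P, x_s))
  denom <- sum(xt^2 / ctx$d)
  list(beta_hat = sum(xt * ctx$y_tilde / ctx$d) / denom, sigma2 = 1 / denom)
}

# vectorized GLS summaries for all (centered) SNP columns at once;
# centering is applied in the rotated space: P'(x - xbar 1) = P'x - xbar P'1
snp_summaries <- function(ctx, X_s) {
  Xt <- crossprod(ctx$P, X_s)
  ones_t <- as.vector(crossprod(ctx$P, rep(1, ctx$n)))
  Xt <- Xt - outer(ones_t, colMeans(X_s))
  denom <- colSums(Xt^2 / ctx$d)
  if (any(denom < .Machine$double.eps)) {
    stop("monomorphic SNP at column ", which(denom < .Machine$double.eps)[1])
  }
  beta_hat <- colSums(Xt * (ctx$y_tilde / ctx$d)) / denom
  data.frame(beta_hat = beta_hat, sigma2 = 1 / denom)
}

#' Hyperprior on the pMOM scale and the null probability
#'
#' The screening prior on a SNP effect is the Dirac/pMOM mixture
#' `p(beta_s | tau, pi0) = pi0 dirac0 + (1 - pi0) (beta_s^2 / (n tau sigma_s^2))
#' N(beta_s | 0, n tau sigma_s^2)`. The null probability `pi0` always gets a
#' uniform prior on (0, 1); the scale `tau` gets one of three schemes:
#' an (improper) uniform prior on the positive half-line, an inverse-gamma
#' prior, or a fixed value. The default inverse gamma
#' `IG(0.55/0.022 + 1, 0.55)` has prior mean 0.022 (the scale recommended
#' for GWAS effect sizes) and keeps `tau` above 0.01 with probability 0.999,
#' avoiding the numerically unstable neighbourhood of zero.
#'
#' @param scheme `"uniform"`, `"invgamma"`, or `"fixed"`.
#' @param shape,rate Inverse-gamma parameters (invgamma scheme); shape must
#'   exceed 1 so the prior mean exists.
#' @param value Fixed value of `tau` (fixed scheme); default 0.022.
#' @return An object of class `hyper_prior`.
#' @export
hyper_prior <- function(scheme = c("uniform", "invgamma", "fixed"),
                        shape = 0.55 / 0.022 + 1, rate = 0.55,
                        value = 0.022) {
  scheme <- match.arg(scheme)
  if (scheme == "invgamma") stopifnot(shape > 1, rate > 0)
  if (scheme == "fixed") stopifnot(value > 0)
  structure(list(scheme = scheme, shape = shape, rate = rate, value = value),
            class = "hyper_prior")
}

# log inverse-gamma density
dinvgamma_log <- function(x, shape, rate) {
  ifelse(x > 0,
         shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
         -Inf)
}

#' Predictive density of a SNP effect estimate under the Dirac/pMOM mixture
#'
#' Marginalizes `betahat_s ~ N(beta_s, sigma2)` over the mixture prior on
#' `beta_s`, giving the closed form
#' `pi0 N(betahat | 0, sigma2) + (1 - pi0) (2 pi sigma2)^{-1/2}
#'  (n tau + 1)^{-3/2} exp(-betahat^2 / (2 sigma2 (n tau + 1)))
#'  (1 + n tau betahat^2 / ((n tau + 1) sigma2))`.
#' Vectorized over `beta_hat` and `sigma2`.
#'
#' @param beta_hat GLS effect estimate(s).
#' @param sigma2 Sampling variance(s), positive.
#' @param tau pMOM scale, positive.
#' @param pi0 Prior null probability in `[0, 1]`.
#' @param n Sample size.
#' @param log Return the log density?
#' @return Predictive density value(s).
#' @export
mixture_predictive <- function(beta_hat, sigma2, tau, pi0, n, log = FALSE) {
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (tau <= 0) stop("tau must be positive")
  stopifnot(pi0 >= 0, pi0 <= 1)
  nt1 <- n * tau + 1
  l_null <- stats::dnorm(beta_hat, 0, sqrt(sigma2), log = TRUE)
  l_alt <- -0.5 * log(2 * pi * sigma2) - 1.5 * log(nt1) -
    beta_hat^2 / (2 * sigma2 * nt1) +
    log1p(n * tau * beta_hat^2 / (nt1 * sigma2))
  lp <- if (pi0 == 1) {
    l_null
  } else if (pi0 == 0) {
    l_alt
  } else {
    a <- log(pi0) + l_null
    b <- log(1 - pi0) + l_alt
    m <- pmax(a, b)
    m + log(exp(a - m) + exp(b - m))
  }
  if (log) lp else exp(lp)
}

#' Log posterior of the screening hyperparameters
#'
#' Sum of the log predictive densities of all SNP summaries plus the log
#' prior densities of `tau` (per the hyperprior scheme; the uniform scheme
#' contributes 0 on its support) and of `pi0` (uniform on (0, 1),
#' contributing 0). Returns `-Inf` outside the support.
#'
#' @param beta_hat,sigma2 Vectors of per-SNP GLS summaries.
#' @param tau,pi0 Hyperparameter values.
#' @param hyperprior A [hyper_prior] object.
#' @param n Sample size.
#' @return Scalar log posterior (unnormalized).
#' @export
log_posterior_hyper <- function(beta_hat, sigma2, tau, pi0, hyperprior, n) {
  if (tau <= 0 || pi0 <= 0 || pi0 >= 1) return(-Inf)
  ll <- sum(mixture_predictive(beta_hat, sigma2, tau, pi0, n, log = TRUE))
  lp_tau <- switch(hyperprior$scheme,
    uniform = 0,
    invgamma = dinvgamma_log(tau, hyperprior$shape, hyperprior$rate),
    fixed = 0)
  ll + lp_tau
}

#' Empirical-Bayes estimates of the screening hyperparameters
#'
#' Maximizes the log posterior of `(tau, pi0)` over `(0, Inf) x (0, 1)`
#' (over `pi0` alone when `tau` is fixed) by bounded quasi-Newton search on
#' the transformed coordinates `(log tau, logit pi0)`, initialized at
#' `tau = 0.022` and `pi0 = 1 - 10/p` clipped to `[0.5, 1 - 1e-6]`.
#'
#' @inheritParams log_posterior_hyper
#' @return List with `tau_hat`, `pi0_hat`, and the achieved `log_post`.
#' @export
estimate_hyperparameters <- function(beta_hat, sigma2, hyperprior, n) {
  p <- length(beta_hat)
  stopifnot(p >= 1, all(is.finite(beta_hat)), all(is.finite(sigma2)))
  pi0_init <- min(max(1 - 10 / p, 0.5), 1 - 1e-6)
  # pi0 is kept in [0.5, 1 - 1e-6]: a genome-wide scan always has a null
  # majority, and the bound blocks a degenerate pi0 -> 0 collapse (the
  # pMOM component dominates the null density pointwise whenever the
  # summaries are slightly overdispersed)
  lo_pi <- stats::qlogis(0.5)
  hi_pi <- stats::qlogis(1 - 1e-6)

  if (hyperprior$scheme == "fixed") {
    tau <- hyperprior$value
    opt <- stats::optim(stats::qlogis(pi0_init),
      fn = function(z) {
        -log_posterior_hyper(beta_hat, sigma2, tau, stats::plogis(z),
                             hyperprior, n)
      },
      method = "L-BFGS-B", lower = lo_pi, upper = hi_pi,
      control = list(maxit = 200))
    if (opt$convergence != 0) {
      stop("hyperparameter optimizer did not converge: ", opt$message)
    }
    pi0_hat <- stats::plogis(opt$par)
    tau_hat <- tau
  } else {
    par0 <- c(log(0.022), stats::qlogis(pi0_init))
    opt <- stats::optim(par0,
      fn = function(par) {
        -log_posterior_hyper(beta_hat, sigma2, exp(par[1]),
                             stats::plogis(par[2]), hyperprior, n)
      },
      method = "L-BFGS-B",
      lower = c(log(1e-6), lo_pi), upper = c(log(100), hi_pi),
      control = list(maxit = 500))
    if (opt$convergence != 0) {
      stop("hyperparameter optimizer did not converge: ", opt$message)
    }
    tau_hat <- exp(opt$par[1])
    pi0_hat <- stats::plogis(opt$par[2])
  }
  if (pi0_hat > 1 - 1e-6) {
    warning("pi0 estimate collapsed to the boundary; clipped to 1 - 1e-6")
    pi0_hat <- 1 - 1e-6
  }
  list(tau_hat = tau_hat, pi0_hat = pi0_hat, log_post = -opt$value)
}

#' Posterior probability that a SNP effect is nonzero
#'
#' `P(beta_s != 0 | betahat_s, tauhat, pi0hat) =
#'  1 - pi0hat N(betahat | 0, sigma2) / p(betahat | tauhat, pi0hat)`.
#' Because the pMOM component vanishes at the origin, the inclusion
#' probability at `betahat = 0` is strictly below `1 - pi0hat`, and it is
#' non-decreasing in `|betahat|` for fixed `sigma2`.
#'
#' @inheritParams mixture_predictive
#' @return Inclusion probability/ies in `[0, 1]`.
#' @export
posterior_inclusion <- function(beta_hat, sigma2, tau, pi0, n) {
  if (pi0 == 1) return(rep(0, length(beta_hat)))
  l_null <- log(pi0) + stats::dnorm(beta_hat, 0, sqrt(sigma2), log = TRUE)
  l_mix <- mixture_predictive(beta_hat, sigma2, tau, pi0, n, log = TRUE)
  pmin(pmax(1 - exp(l_null - l_mix), 0), 1)
}

#' Bayesian false discovery rate selection
#'
#' Direct posterior-probability FDR control: with null probabilities
#' `q_s = 1 - incl_prob_s` sorted ascending, selects the largest `m` such
#' that the running mean `(1/m) sum_{i<=m} q_(i)` is at most `alpha`; ties
#' in `q_s` are broken by original SNP index for determinism.
#'
#' @param incl_prob Vector of posterior inclusion probabilities.
#' @param alpha Nominal Bayesian FDR level in (0, 1).
#' @return Integer vector of selected SNP indices (possibly empty).
#' @export
bayesian_fdr_select <- function(incl_prob, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(incl_prob) == 0) return(integer())
  stopifnot(all(incl_prob >= 0 & incl_prob <= 1))
  q <- 1 - incl_prob
  ord <- order(q, seq_along(q))
  ok <- cumsum(q[ord]) / seq_along(q) <= alpha
  if (!any(ok)) return(integer())
  sort(ord[seq_len(max(which(ok)))])
}

#' Screening step: Bayesian single-marker scan with FDR control
#'
#' Orchestrates the screening stage: fits the no-SNP baseline GLMM by PQL,
#' freezes the spectral (P3D) context, computes per-SNP GLS summaries,
#' estimates `(tau, pi0)` by empirical Bayes, converts each summary to a
#' posterior inclusion probability, and applies Bayesian FDR control at
#' level `alpha` to produce the candidate set.
#'
#' @param data A [gwas_data] object.
#' @param family A [glmm_family] object.
#' @param hyperprior A [hyper_prior]; default the uniform-`tau` scheme.
#' @param alpha Nominal Bayesian FDR (default 0.05).
#' @param max_iter,tol Passed to [pql_fit()].
#' @return An object of class `screening_result`: a per-SNP `table`
#'   (`snp_id`, `chrom`, `pos`, `beta_hat`, `sigma2`, `incl_prob`,
#'   `candidate`), `tau_hat`, `pi0_hat`, `candidates` (SNP indices),
#'   `alpha`, `n`, and the baseline `fit` and `ctx` for reuse.
#' @examples
#' sim <- simulate_gwas("binary", beta = 1, n = 120, p = 300, seed = 1)
#' scr <- screen_snps(sim$data, glmm_family("bernoulli"))
#' scr$candidates
#' @export
screen_snps <- function(data, family, hyperprior = hyper_prior("uniform"),
                        alpha = 0.05, max_iter = 50, tol = 1e-4) {
  fit <- pql_fit(data, family, snp_columns = integer(),
                 max_iter = max_iter, tol = tol)
  ctx <- build_p3d(fit, data)
  screen_with_context(data, ctx, hyperprior, alpha)
}

# screening given a prebuilt baseline context (shared with sma_scan)
screen_with_context <- function(data, ctx, hyperprior, alpha) {
  sm <- snp_summaries(ctx, data$X_s)
  hp <- estimate_hyperparameters(sm$beta_hat, sm$sigma2, hyperprior, data$n)
  incl <- posterior_inclusion(sm$beta_hat, sm$sigma2, hp$tau_hat, hp$pi0_hat,
                              data$n)
  cand <- bayesian_fdr_select(incl, alpha)
  tab <- data.frame(snp_id = data$snp_map$snp_id,
                    chrom = data$snp_map$chrom,
                    pos = data$snp_map$pos,
                    beta_hat = sm$beta_hat,
                    sigma2 = sm$sigma2,
                    incl_prob = incl,
                    candidate = seq_len(data$p) %in% cand,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, tau_hat = hp$tau_hat, pi0_hat = hp$pi0_hat,
                 candidates = cand, alpha = alpha, n = data$n,
                 hyperprior = hyperprior, fit = ctx$fit, ctx = ctx),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> p = ", nrow(x$table),
      ", tau_hat = ", format(x$tau_hat, digits = 4),
      ", pi0_hat = ", format(x$pi0_hat, digits = 6),
      ", ", length(x$candidates), " candidate(s) at FDR ", x$alpha, "\n",
      sep = "")
  invisible(x)
}
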