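# shared fixture builders and independent oracles used across test files

# small simulated data set with kinship from its own genotypes
make_sim_data <- function(n, p, family = "poisson", seed = 1,
                          causal = causal_spec(p, list(), intercept = 0.5),
                          kappa1 = 0.2, kappa2 = 0.1, replicates = 1) {
  g <- simulate_genotypes(n, p, seed = seed)
  K <- grm(g$genotypes)
  if (family == "poisson") {
    y <- simulate_count_phenotype(g$genotypes, K, causal, kappa1, kappa2,
                                  replicates, seed = seed + 1)
    dat <- gwas_data(g$genotypes, g$map, y, kinship = K,
                     replicates = rep(replicates, n))
  } else {
    y <- simulate_binary_phenotype(g$genotypes, K, causal, kappa1,
                                   seed = seed + 1)
    dat <- gwas_data(g$genotypes, g$map, y, kinship = K)
  }
  dat
}

# independent dense REML oracle for the Gaussian working LMM
# y ~ N(X b, k1 Sigma + k2 I + W) with W = diag(w_inv); explicit inverses,
# different optimizer trajectory than the package internals
oracle_reml <- function(y, X, Sigma, w_inv, k2_fixed = NULL) {
  nll <- function(par) {
    k1 <- exp(par[1])
    k2 <- if (is.null(k2_fixed)) exp(par[2]) else k2_fixed
    H <- k1 * Sigma + diag(k2 + w_inv)
    Hi <- solve(H)
    XtHiX <- t(X) %*% Hi %*% X
    b <- solve(XtHiX, t(X) %*% Hi %*% y)
    r <- y - X %*% b
    c(determinant(H)$modulus + determinant(XtHiX)$modulus +
        t(r) %*% Hi %*% r)
  }
  npar <- if (is.null(k2_fixed)) 2 else 1
  o <- stats::optim(rep(log(0.5), npar), nll, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 2000))
  k1 <- exp(o$par[1])
  k2 <- if (is.null(k2_fixed)) exp(o$par[2]) else k2_fixed
  H <- k1 * Sigma + diag(k2 + w_inv)
  Hi <- solve(H)
  b <- solve(t(X) %*% Hi %*% X, t(X) %*% Hi %*% y)
  list(kappa = c(k1, k2), beta = as.vector(b))
}

# brute-force Bayesian FDR selection: try every cutoff m explicitly
oracle_fdr_select <- function(incl_prob, alpha) {
  q <- 1 - incl_prob
  ord <- order(q, seq_along(q))
  best <- 0L
  for (m in seq_along(q)) {
    if (mean(q[ord[seq_len(m)]]) <= alpha) best <- m
  }
  sort(ord[seq_len(best)])
}

# brute-force buffered matcher: loops over every (causal, detected) pair
oracle_match <- function(detected, causal, buffer_bp = 5000) {
  tp <- 0L
  for (i in seq_len(nrow(causal))) {
    hit <- FALSE
    for (j in seq_len(nrow(detected))) {
      if (causal$chrom[i] == detected$chrom[j] &&
          abs(causal$pos[i] - detected$pos[j]) <= buffer_bp) hit <- TRUE
    }
    if (hit) tp <- tp + 1L
  }
  fp <- 0L
  for (j in seq_len(nrow(detected))) {
    covered <- FALSE
    for (i in seq_len(nrow(causal))) {
      if (causal$chrom[i] == detected$chrom[j] &&
          abs(causal$pos[i] - detected$pos[j]) <= buffer_bp) covered <- TRUE
    }
    if (!covered) fp <- fp + 1L
  }
  list(tp = tp, fp = fp)
}

# draw from the Dirac/pMOM predictive model of the effect estimates:
# beta ~ pi0 d0 + (1-pi0) pMOM(n tau sigma2); betahat ~ N(beta, sigma2).
# |beta| under the pMOM with scale v is sqrt(v * chisq_3).
sample_predictive <- function(p, sigma2, tau, pi0, n) {
  nullmask <- stats::runif(p) < pi0
  v <- n * tau * sigma2
  beta <- ifelse(nullmask, 0,
                 sample(c(-1, 1), p, replace = TRUE) *
                   sqrt(v * stats::rchisq(p, df = 3)))
  stats::rnorm(p, beta, sqrt(sigma2))
}

# numerical quadrature of the mixture predictive's defining integral
quad_predictive <- function(beta_hat, sigma2, tau, pi0, n) {
  v <- n * tau * sigma2
  f <- function(b) {
    (b^2 / v) * stats::dnorm(b, 0, sqrt(v)) *
      stats::dnorm(beta_hat, b, sqrt(sigma2))
  }
  nonnull <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
  pi0 * stats::dnorm(beta_hat, 0, sqrt(sigma2)) + (1 - pi0) * nonnull
}
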