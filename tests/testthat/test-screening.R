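# minimal hand-built spectral context (identity rotation)
identity_ctx <- function(y_tilde, d = rep(1, length(y_tilde))) {
  n <- length(y_tilde)
  structure(list(P = diag(n), d = d, y_tilde = y_tilde, n = n,
                 rotate = identity), class = "p3d_context")
}

test_that("per-SNP GLS summary solves the diagonal normal equations", {
  set.seed(3)
  x <- rnorm(12)
  x <- x / sqrt(sum(x^2))
  ctx <- identity_ctx(2 * x)
  s <- snp_summary(ctx, x, center = FALSE)
  expect_equal(s$beta_hat, 2, tolerance = 1e-12)
  expect_equal(s$sigma2, 1, tolerance = 1e-12)
  # orthogonal response gives a zero estimate
  y_perp <- rnorm(12)
  y_perp <- y_perp - sum(y_perp * x) * x
  ctx2 <- identity_ctx(y_perp)
  expect_equal(snp_summary(ctx2, x, center = FALSE)$beta_hat, 0,
               tolerance = 1e-10)
  expect_error(snp_summary(ctx, rep(1, 12)), "monomorphic")
})

test_that("mixture predictive density matches its defining integral", {
  # worked instance
  expect_equal(mixture_predictive(0.3, 0.01, 0.022, 0.9, 1000),
               quad_predictive(0.3, 0.01, 0.022, 0.9, 1000),
               tolerance = 1e-8)
  # pure-null mixture is the Gaussian sampling density
  expect_equal(mixture_predictive(0.4, 0.02, 0.05, 1, 500),
               dnorm(0.4, 0, sqrt(0.02)))
  # symmetry in the estimate
  expect_equal(mixture_predictive(0.7, 0.1, 0.02, 0.8, 100),
               mixture_predictive(-0.7, 0.1, 0.02, 0.8, 100))
  # closed form vs quadrature across random parameter draws
  set.seed(101)
  for (i in 1:200) {
    bh <- rnorm(1, 0, 0.5)
    s2 <- runif(1, 0.001, 0.3)
    tau <- runif(1, 0.005, 0.3)
    pi0 <- runif(1, 0.05, 0.99)
    n <- sample(50:5000, 1)
    expect_equal(mixture_predictive(bh, s2, tau, pi0, n),
                 quad_predictive(bh, s2, tau, pi0, n),
                 tolerance = 1e-6)
  }
  expect_error(mixture_predictive(0.1, -1, 0.02, 0.5, 100), "sigma2")
  expect_error(mixture_predictive(0.1, 0.1, 0, 0.5, 100), "tau")
})

test_that("mixture predictive integrates to one over the estimate", {
  for (par in list(c(0.02, 0.022, 0.9, 200), c(0.1, 0.1, 0.5, 50))) {
    val <- integrate(function(b) {
      mixture_predictive(b, par[1], par[2], par[3], par[4])
    }, -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(val, 1, tolerance = 1e-4)
  }
})

test_that("hyperparameter log posterior adds log prior terms correctly", {
  hp_u <- hyper_prior("uniform")
  hp_ig <- hyper_prior("invgamma")
  # single summary, pi0 = 1 - eps: essentially the null normal density
  lp <- log_posterior_hyper(0.1, 0.04, 0.022, 1 - 1e-12, hp_u, 100)
  expect_equal(lp, dnorm(0.1, 0, 0.2, log = TRUE), tolerance = 1e-9)
  # additivity over SNPs (flat priors contribute zero)
  l12 <- log_posterior_hyper(c(0.1, -0.3), c(0.04, 0.02), 0.03, 0.9, hp_u, 100)
  l1 <- log_posterior_hyper(0.1, 0.04, 0.03, 0.9, hp_u, 100)
  l2 <- log_posterior_hyper(-0.3, 0.02, 0.03, 0.9, hp_u, 100)
  expect_equal(l12, l1 + l2, tolerance = 1e-10)
  # inverse-gamma log prior against a transformed dgamma reference
  a <- 0.55 / 0.022 + 1
  ref <- dgamma(1 / 0.022, shape = a, rate = 0.55, log = TRUE) - 2 * log(0.022)
  expect_equal(log_posterior_hyper(0.1, 0.04, 0.022, 0.9, hp_ig, 100) -
                 log_posterior_hyper(0.1, 0.04, 0.022, 0.9, hp_u, 100),
               ref, tolerance = 1e-10)
  # support contract
  expect_identical(log_posterior_hyper(0.1, 0.04, -1, 0.9, hp_u, 100), -Inf)
  expect_identical(log_posterior_hyper(0.1, 0.04, 0.02, 1, hp_u, 100), -Inf)
})

test_that("fixed-tau scheme returns tau unchanged", {
  set.seed(5)
  bh <- rnorm(500, 0, 0.1)
  s2 <- rep(0.01, 500)
  est <- estimate_hyperparameters(bh, s2, hyper_prior("fixed", value = 0.022),
                                  n = 300)
  expect_identical(est$tau_hat, 0.022)
  expect_true(est$pi0_hat > 0 && est$pi0_hat < 1)
})

test_that("hyperparameters are recovered from data drawn under the mixture", {
  reps <- 20
  p <- 20000
  est <- t(vapply(seq_len(reps), function(i) {
    set.seed(300 + i)
    s2 <- runif(p, 0.005, 0.02)
    bh <- sample_predictive(p, s2, tau = 0.05, pi0 = 0.99, n = 500)
    out <- estimate_hyperparameters(bh, s2, hyper_prior("uniform"), n = 500)
    c(out$tau_hat, out$pi0_hat)
  }, numeric(2)))
  se <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 0.05), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - 0.99), 3 * se[2])
})

test_that("optimum is stable across a grid of restarts", {
  set.seed(17)
  s2 <- runif(2000, 0.005, 0.02)
  bh <- sample_predictive(2000, s2, tau = 0.08, pi0 = 0.97, n = 400)
  base <- estimate_hyperparameters(bh, s2, hyper_prior("uniform"), n = 400)
  hp <- hyper_prior("uniform")
  grid <- expand.grid(tau = c(0.005, 0.05, 0.5), pi0 = c(0.6, 0.9, 0.99))
  for (i in seq_len(nrow(grid))) {
    o <- optim(c(log(grid$tau[i]), qlogis(grid$pi0[i])),
               function(par) {
                 -log_posterior_hyper(bh, s2, exp(par[1]), plogis(par[2]),
                                      hp, 400)
               },
               method = "L-BFGS-B",
               lower = c(log(1e-6), qlogis(0.5)),
               upper = c(log(100), qlogis(1 - 1e-6)))
    expect_equal(exp(o$par[1]), base$tau_hat, tolerance = 1e-3)
    expect_equal(plogis(o$par[2]), base$pi0_hat, tolerance = 1e-4)
  }
})

test_that("posterior inclusion behaves as the nonlocal prior dictates", {
  # pi0 = 1 forces exclusion
  expect_equal(posterior_inclusion(c(-1, 0, 2), rep(0.1, 3), 0.022, 1, 100),
               rep(0, 3))
  # at betahat = 0 the pMOM component vanishes: inclusion < 1 - pi0
  incl0 <- posterior_inclusion(0, 0.01, 0.022, 0.9, 500)
  expect_lt(incl0, 1 - 0.9)
  # monotone non-decreasing in |betahat| at fixed sigma2
  grid <- seq(0, 2, by = 0.02)
  incl <- posterior_inclusion(grid, 0.01, 0.022, 0.9, 500)
  expect_true(all(diff(incl) >= -1e-12))
})

test_that("Bayesian FDR selection matches brute force and its invariants", {
  # worked example: mean null prob 0.02 <= 0.05, adding third gives 0.1467
  expect_identical(bayesian_fdr_select(c(0.99, 0.97, 0.60), 0.05), c(1L, 2L))
  expect_identical(bayesian_fdr_select(rep(1, 5), 0.05), 1:5)
  expect_identical(bayesian_fdr_select(c(0.5, 0.6), 0.05), integer())
  expect_identical(bayesian_fdr_select(numeric(), 0.05), integer())
  set.seed(9)
  for (i in 1:50) {
    incl <- runif(sample(1:30, 1))
    alpha <- runif(1, 0.01, 0.3)
    expect_identical(bayesian_fdr_select(incl, alpha),
                     oracle_fdr_select(incl, alpha))
    # order invariance
    perm <- sample(length(incl))
    expect_identical(sort(perm[bayesian_fdr_select(incl[perm], alpha)]),
                     as.integer(bayesian_fdr_select(incl, alpha)))
    # monotone in alpha
    expect_true(all(bayesian_fdr_select(incl, alpha) %in%
                      bayesian_fdr_select(incl, min(alpha * 2, 0.9))))
  }
})

test_that("screening flags a huge-effect SNP and respects SNP order", {
  hits <- vapply(1:20, function(i) {
    g <- simulate_genotypes(200, 100, seed = 4000 + i)
    K <- grm(g$genotypes)
    cs <- causal_spec(100, list(c(1, 2)), intercept = -0.5)
    y <- simulate_binary_phenotype(g$genotypes, K, cs, kappa1 = 0.15,
                                   seed = 5000 + i)
    dat <- gwas_data(g$genotypes, g$map, y, kinship = K)
    scr <- screen_snps(dat, glmm_family("bernoulli"))
    cs$indices %in% scr$candidates
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # permuting SNP columns permutes the candidate set identically
  g <- simulate_genotypes(150, 80, seed = 77)
  K <- grm(g$genotypes)
  cs <- causal_spec(80, list(c(2, 1.5)), intercept = 1)
  y <- simulate_count_phenotype(g$genotypes, K, cs, kappa1 = 0.5,
                                kappa2 = 0.2, replicates = 4, seed = 78)
  dat <- gwas_data(g$genotypes, g$map, y, kinship = K,
                   replicates = rep(4, 150))
  scr1 <- screen_snps(dat, glmm_family("poisson"))
  set.seed(2)
  perm <- sample(80)
  dat2 <- gwas_data(dat$X_s[, perm], dat$snp_map[perm, ], dat$y,
                    kinship = K, replicates = dat$replicates)
  scr2 <- screen_snps(dat2, glmm_family("poisson"))
  expect_identical(sort(match(scr1$candidates, perm)), sort(scr2$candidates))
})
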