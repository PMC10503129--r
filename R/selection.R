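#' Exchangeable-Bernoulli log prior of a model
#'
#' Each of the `k` candidate SNPs enters a model independently with
#' probability `1 - pi0hat`, so a model with `p_m` SNPs has log prior
#' `(k - p_m) log(pi0hat) + p_m log(1 - pi0hat)`; reusing the screening
#' estimate of `pi0` keeps the selection step's false-discovery control as
#' strict as the screening step's.
#'
#' @param p_m Number of SNPs in the model.
#' @param k Number of candidates.
#' @param pi0_hat Null probability estimate in (0, 1).
#' @return Scalar log prior probability.
#' @export
model_log_prior <- function(p_m, k, pi0_hat) {
  stopifnot(p_m >= 0, p_m <= k)
  if (pi0_hat <= 0 || pi0_hat >= 1) stop("pi0_hat must lie in (0, 1)")
  (k - p_m) * log(pi0_hat) + p_m * log1p(-pi0_hat)
}

#' Monte-Carlo moments of the product of squared coefficients
#'
#' Approximates the two expectations appearing in the pMOM marginal
#' likelihood: `E2 = E prod(beta_i^2)` under `N(beta_tilde, C_m^{-1})` and
#' `E1 = E prod(beta_i^2)` under `N(0, (1 + tau n) C_m^{-1})`. Both use the
#' same draws (common random numbers): samples `beta^(j)` from
#' `N(beta_tilde, C_m^{-1})` give E2 directly, and the rescaled residuals
#' `(1 + tau n)^{1/2} (beta^(j) - beta_tilde)` give E1, so the ratio
#' `E2/E1` is stable and model rankings are reproducible.
#'
#' @param beta_tilde Posterior-mode coefficient vector (length `p_m`).
#' @param C_m Positive definite `p_m x p_m` precision-like matrix.
#' @param tau_hat pMOM scale estimate.
#' @param n Sample size.
#' @param mc_samples Number of Monte-Carlo draws (default 2000).
#' @param seed Optional integer seed for the draws.
#' @return List with `E1`, `E2`.
#' @export
mom_moments <- function(beta_tilde, C_m, tau_hat, n, mc_samples = 2000,
                        seed = NULL) {
  p_m <- length(beta_tilde)
  stopifnot(p_m >= 1, mc_samples >= 1)
  R <- tryCatch(chol(C_m), error = function(e) {
    stop("C_m is not positive definite (collinear candidates?)")
  })
  with_seed(seed, {
    Z <- matrix(stats::rnorm(mc_samples * p_m), nrow = p_m)
    # beta^(j) = beta_tilde + R^{-1} z_j  since C_m = R'R
    Dev <- backsolve(R, Z)
    B <- Dev + beta_tilde
    e2 <- rep(1, mc_samples)
    e1 <- rep(1, mc_samples)
    for (i in seq_len(p_m)) {
      e2 <- e2 * B[i, ]^2
      e1 <- e1 * Dev[i, ]^2
    }
    list(E1 = (1 + tau_hat * n)^p_m * mean(e1), E2 = mean(e2))
  })
}

# score one model (set of rotated candidate columns) under the pMOM prior
score_model <- function(Xt_cand, d, y_tilde, cols, tau_hat, n, mc_samples,
                        seed) {
  yDy <- sum(y_tilde^2 / d)
  logdetD <- sum(log(d))
  p_m <- length(cols)
  if (p_m == 0) {
    return(list(log_marginal = -(n / 2) * log(2 * pi) - logdetD / 2 - yDy / 2,
                R_m = yDy, beta_tilde = numeric(), E1 = 1, E2 = 1))
  }
  Xm <- Xt_cand[, cols, drop = FALSE]
  XD <- Xm / d
  A <- crossprod(Xm, XD)          # Xm' D^{-1} Xm
  C_m <- A * (1 + 1 / (tau_hat * n))
  Xty <- crossprod(XD, y_tilde)   # Xm' D^{-1} ytilde
  cC <- tryCatch(chol(C_m), error = function(e) NULL)
  if (is.null(cC) || any(diag(cC) < sqrt(.Machine$double.eps) * max(diag(cC)))) {
    stop("collinear candidates: X'D^{-1}X is numerically rank deficient")
  }
  beta_tilde <- as.vector(backsolve(cC, backsolve(cC, Xty, transpose = TRUE)))
  R_m <- yDy - sum(Xty * beta_tilde)
  mm <- mom_moments(beta_tilde, C_m, tau_hat, n, mc_samples, seed)
  lm <- -(n / 2) * log(2 * pi) - logdetD / 2 -
    (p_m / 2) * log1p(tau_hat * n) - R_m / 2 + log(mm$E2) - log(mm$E1)
  list(log_marginal = lm, R_m = R_m, beta_tilde = beta_tilde,
       E1 = mm$E1, E2 = mm$E2)
}

#' Marginal likelihood of the adjusted observations under one model
#'
#' Evaluates the log marginal density of the rotated adjusted observations
#' given a model containing the specified candidate columns, under the
#' multivariate pMOM prior with covariance kernel
#' `tau n (Xtilde' D^{-1} Xtilde)^{-1}`:
#' `log m = -(n/2) log(2 pi) - (1/2) log|D| - (p_m/2) log(1 + tau n)
#'          - R_m / 2 + log E2 - log E1`,
#' where `C_m = Xtilde' D^{-1} Xtilde (1 + (tau n)^{-1})`,
#' `beta_tilde = C_m^{-1} Xtilde' D^{-1} ytilde`, and
#' `R_m = ytilde' D^{-1} ytilde - ytilde' D^{-1} Xtilde beta_tilde`.
#' The pMOM normalizing constant never appears explicitly: it cancels into
#' the `E1` factor. The empty model returns the exact Gaussian null
#' log-density with `E2/E1 = 1`.
#'
#' @param ctx A [build_p3d()] context (selection-step baseline).
#' @param X_m Matrix of candidate SNP columns on the original (unrotated)
#'   scale, or `NULL` for the null model.
#' @param tau_hat,n pMOM scale and sample size.
#' @param mc_samples Monte-Carlo draws for `E1`, `E2`.
#' @param seed Optional seed for the draws.
#' @return Scalar log marginal likelihood.
#' @export
model_log_marginal <- function(ctx, X_m, tau_hat, n = ctx$n,
                               mc_samples = 2000, seed = NULL) {
  stopifnot(inherits(ctx, "p3d_context"))
  if (is.null(X_m) || NCOL(X_m) == 0) {
    sc <- score_model(NULL, ctx$d, ctx$y_tilde, integer(), tau_hat, n,
                      mc_samples, seed)
    return(sc$log_marginal)
  }
  X_m <- as.matrix(X_m)
  Xt <- crossprod(ctx$P, sweep(X_m, 2, colMeans(X_m), "-"))
  sc <- score_model(Xt, ctx$d, ctx$y_tilde, seq_len(ncol(Xt)), tau_hat, n,
                    mc_samples, seed)
  sc$log_marginal
}

# indicator -> canonical per-model seed (order-independent: cols are sorted)
model_seed <- function(seed, cols) {
  if (is.null(seed)) return(NULL)
  do.call(mix_seed, c(list(seed), as.list(sort(cols))))
}

# score a list of indicator vectors; returns a data.frame of model scores
score_model_family <- function(ctx, candidates, indicators, tau_hat, pi0_hat,
                               mc_samples, seed) {
  k <- length(candidates)
  Xt_cand <- crossprod(ctx$P, ctx$fit_Xs_cand)
  n <- ctx$n
  res <- lapply(indicators, function(ind) {
    cols <- which(as.logical(ind))
    sc <- score_model(Xt_cand, ctx$d, ctx$y_tilde, cols, tau_hat, n,
                      mc_samples, model_seed(seed, cols))
    data.frame(indicator = paste(as.integer(ind), collapse = ""),
               p_m = length(cols),
               log_prior = model_log_prior(length(cols), k, pi0_hat),
               log_marginal = sc$log_marginal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Enumerate and score all models over the screened candidates
#'
#' Scores every subset of the `k` candidate SNPs (posterior proportional to
#' exchangeable-Bernoulli prior times pMOM marginal likelihood), normalizes
#' over the enumerated family and returns models in decreasing posterior
#' order. Refuses `k >= 16` (65536+ models); use [ga_search()] there.
#'
#' @param ctx Selection-step [build_p3d()] context.
#' @param X_cand Matrix of the `k` candidate genotype columns.
#' @param tau_hat,pi0_hat Hyperparameter estimates from screening.
#' @param mc_samples Monte-Carlo draws per model (default 2000).
#' @param seed Master seed; each model draws from its own substream derived
#'   from the seed and the model indicator, so results do not depend on
#'   enumeration order.
#' @return Data frame of model scores (`indicator`, `p_m`, `log_prior`,
#'   `log_marginal`, `post_prob`) sorted by decreasing `post_prob`.
#' @export
enumerate_models <- function(ctx, X_cand, tau_hat, pi0_hat,
                             mc_samples = 2000, seed = NULL) {
  k <- ncol(X_cand)
  if (k >= 16) {
    stop("k = ", k, " candidates: exhaustive enumeration refused for ",
         "k >= 16; use ga_search()")
  }
  ctx$fit_Xs_cand <- center_cols(as.matrix(X_cand))
  indicators <- lapply(0:(2^k - 1), function(m) {
    as.integer(intToBits(m)[seq_len(k)])
  })
  tab <- score_model_family(ctx, seq_len(k), indicators, tau_hat, pi0_hat,
                            mc_samples, seed)
  lp <- tab$log_prior + tab$log_marginal
  w <- exp(lp - max(lp))
  tab$post_prob <- w / sum(w)
  tab[order(-tab$post_prob, tab$indicator), , drop = FALSE]
}

#' Genetic-algorithm search over the model space
#'
#' Binary-encoded genetic algorithm maximizing
#' `log prior + log marginal` over inclusion vectors of the `k` candidates:
#' rank-based selection, one-point crossover (rate 0.8), per-bit mutation
#' (rate 0.1), elitism of 2, population 50, up to 200 generations with early
#' stop after 50 stagnant generations. Fitness values are cached per
#' indicator under common random numbers, so every individual is scored
#' exactly once and the search is deterministic given the seed. The null
#' model, the full model, and all single-SNP models are always evaluated,
#' and the best model found anywhere is returned.
#'
#' @inheritParams enumerate_models
#' @param ga_config Optional list overriding `pop_size`, `generations`,
#'   `p_crossover`, `p_mutation`, `elitism`, `stagnation`.
#' @return One-row data frame with the best model's `indicator`, `p_m`,
#'   `log_prior`, `log_marginal`, plus `n_evaluated`.
#' @export
ga_search <- function(ctx, X_cand, tau_hat, pi0_hat, mc_samples = 2000,
                      seed = NULL, ga_config = list()) {
  k <- ncol(X_cand)
  stopifnot(k >= 2)
  cfg <- utils::modifyList(list(pop_size = 50, generations = 200,
                                p_crossover = 0.8, p_mutation = 0.1,
                                elitism = 2, stagnation = 50), ga_config)
  ctx$fit_Xs_cand <- center_cols(as.matrix(X_cand))
  Xt_cand <- crossprod(ctx$P, ctx$fit_Xs_cand)
  n <- ctx$n
  cache <- new.env(parent = emptyenv())
  fitness <- function(ind) {
    key <- paste(ind, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cols <- which(as.logical(ind))
    sc <- score_model(Xt_cand, ctx$d, ctx$y_tilde, cols, tau_hat, n,
                      mc_samples, model_seed(seed, cols))
    val <- model_log_prior(length(cols), k, pi0_hat) + sc$log_marginal
    cache[[key]] <- val
    val
  }

  with_seed(if (is.null(seed)) NULL else mix_seed(seed, 797), {
    # mandatory evaluations: null, full, singles
    must <- c(list(rep(0L, k), rep(1L, k)),
              lapply(seq_len(k), function(j) {
                v <- rep(0L, k); v[j] <- 1L; v
              }))
    pop <- lapply(seq_len(cfg$pop_size), function(i) {
      if (i <= length(must)) must[[i]] else
        as.integer(stats::runif(k) < 0.5)
    })
    fit <- vapply(pop, fitness, numeric(1))
    best <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    stagnant <- 0L
    for (g in seq_len(cfg$generations)) {
      ord <- order(fit, decreasing = TRUE)
      # rank-based selection probabilities
      pr <- (cfg$pop_size - rank(-fit, ties.method = "first") + 1)
      pr <- pr / sum(pr)
      newpop <- pop[ord[seq_len(cfg$elitism)]]
      while (length(newpop) < cfg$pop_size) {
        pa <- pop[[sample.int(cfg$pop_size, 1, prob = pr)]]
        pb <- pop[[sample.int(cfg$pop_size, 1, prob = pr)]]
        if (stats::runif(1) < cfg$p_crossover && k >= 2) {
          cut <- sample.int(k - 1, 1)
          child <- c(pa[seq_len(cut)], pb[(cut + 1):k])
        } else {
          child <- pa
        }
        flip <- stats::runif(k) < cfg$p_mutation
        child[flip] <- 1L - child[flip]
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1))
      if (max(fit) > best_fit + 1e-12) {
        best_fit <- max(fit)
        best <- pop[[which.max(fit)]]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= cfg$stagnation) break
      }
    }
  })
  cols <- which(as.logical(best))
  data.frame(indicator = paste(best, collapse = ""),
             p_m = length(cols),
             log_prior = model_log_prior(length(cols), k, pi0_hat),
             log_marginal = best_fit - model_log_prior(length(cols), k, pi0_hat),
             n_evaluated = length(ls(cache)),
             stringsAsFactors = FALSE)
}

#' Model-selection step over the screened candidates
#'
#' Second stage of the two-step procedure: refits the pseudo-likelihood
#' baseline with all `k` screened candidates as fixed effects (the full
#' model is the selection-step baseline), rebuilds the frozen spectral
#' context from that fit, and searches the `2^k` model space — exhaustively
#' for `k < 16`, by genetic algorithm otherwise. Hyperparameters
#' `(tau_hat, pi0_hat)` are reused from the screening step.
#'
#' @param data A [gwas_data] object.
#' @param family A [glmm_family] object.
#' @param screening A [screen_snps()] result.
#' @param mc_samples Monte-Carlo draws per model (default 2000).
#' @param seed Optional master seed for the model-scoring substreams.
#' @param max_enumerate_k Largest `k` enumerated exhaustively (default 15).
#' @param ga_config Passed to [ga_search()] when used.
#' @return An object of class `selection_result`: `selected` (original SNP
#'   indices of the highest-posterior model), `model_table` (scored models;
#'   all of them when enumerated), `best` (one-row score of the best
#'   model), `candidates`, `tau_hat`, `pi0_hat`, `fit` (selection
#'   baseline). With zero candidates returns an empty selection.
#' @export
select_model <- function(data, family, screening, mc_samples = 2000,
                         seed = NULL, max_enumerate_k = 15,
                         ga_config = list()) {
  stopifnot(inherits(screening, "screening_result"))
  cand <- screening$candidates
  k <- length(cand)
  if (k == 0) {
    return(structure(list(selected = integer(), model_table = NULL,
                          best = NULL, candidates = integer(),
                          tau_hat = screening$tau_hat,
                          pi0_hat = screening$pi0_hat, fit = NULL),
                     class = "selection_result"))
  }
  fit <- tryCatch(
    pql_fit(data, family, snp_columns = cand),
    error = function(e) {
      stop("PQL failed on the full candidate model (", conditionMessage(e),
           "); consider pruning collinear candidates")
    })
  ctx <- build_p3d(fit, data)
  X_cand <- data$X_s[, cand, drop = FALSE]
  if (k <= max_enumerate_k) {
    tab <- enumerate_models(ctx, X_cand, screening$tau_hat,
                            screening$pi0_hat, mc_samples, seed)
    best <- tab[1, , drop = FALSE]
  } else {
    best <- ga_search(ctx, X_cand, screening$tau_hat, screening$pi0_hat,
                      mc_samples, seed, ga_config)
    tab <- best
  }
  sel <- cand[which(strsplit(best$indicator, "")[[1]] == "1")]
  structure(list(selected = sel, model_table = tab, best = best,
                 candidates = cand, tau_hat = screening$tau_hat,
                 pi0_hat = screening$pi0_hat, fit = fit),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$candidates), " candidate(s), ",
      length(x$selected), " selected",
      if (length(x$selected)) paste0(": ", paste(x$selected, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Two-stage Bayesian SNP selection
#'
#' Runs the full two-stage pipeline: screening with Bayesian FDR control,
#' then model selection over the screened candidates.
#'
#' @inheritParams screen_snps
#' @inheritParams select_model
#' @return List with components `screening` and `selection`.
#' @examples
#' sim <- simulate_gwas("binary", beta = 1.5, n = 150, p = 300, seed = 7)
#' res <- gwas_select(sim$data, glmm_family("bernoulli"), seed = 7)
#' res$selection$selected
#' @export
gwas_select <- function(data, family, hyperprior = hyper_prior("uniform"),
                        alpha = 0.05, mc_samples = 2000, seed = NULL,
                        max_enumerate_k = 15, ga_config = list()) {
  scr <- screen_snps(data, family, hyperprior, alpha)
  sel <- select_model(data, family, scr, mc_samples = mc_samples,
                      seed = seed, max_enumerate_k = max_enumerate_k,
                      ga_config = ga_config)
  list(screening = scr, selection = sel)
}

# mean-center matrix columns (SNP columns enter per-model GLS intercept-free)
center_cols <- function(X) sweep(X, 2, colMeans(X), "-")
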