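#' Penalized quasi-likelihood fit of the GWAS GLMM
#'
#' Fits the generalized linear mixed model
#' `g(E(y | a1, a2)) = offset + X beta + a1 + a2` with
#' `a1 ~ N(0, kappa1 Sigma)` (kinship) and `a2 ~ N(0, kappa2 I)`
#' (overdispersion) by iterating the pseudo-likelihood (PQL) scheme: at each
#' step the model is linearized around the current fit, giving adjusted
#' observations `y* = Vhat^{-1}(y - muhat) + X betahat + a1hat + a2hat`
#' that follow the working linear mixed model
#' `y* = X beta + a1 + a2 + Vhat^{-1} eps` with `Var(Vhat^{-1} eps) ~= Vhat^{-1}`.
#' Variance components of the working model are estimated by REML (bounded
#' quasi-Newton on the log scale), fixed effects by generalized least
#' squares, and random effects by their BLUPs; the loop repeats until the
#' maximum absolute change in `(beta, kappa1, kappa2)` drops below `tol`.
#'
#' The fixed-effect design is the control-covariate block `X_c` plus any
#' genotype columns named in `snp_columns` (empty for the screening
#' baseline; the screened candidates for the selection baseline).
#'
#' @param data A [gwas_data] object.
#' @param family A [glmm_family] object matching the phenotype support.
#' @param snp_columns Integer indices of genotype columns included as fixed
#'   effects in the baseline model (default none).
#' @param max_iter Maximum PQL iterations (default 50).
#' @param tol Convergence tolerance on the maximum absolute parameter change
#'   (default 1e-4).
#' @param kappa_fixed Optional length-2 vector fixing `(kappa1, kappa2)`
#'   (e.g. `c(0, 0)` collapses the fit to iteratively reweighted least
#'   squares); `NULL` (default) estimates both by REML.
#' @return An object of class `pseudo_fit` with elements `beta_c_hat`,
#'   `beta_snp_hat`, `alpha1_hat`, `alpha2_hat`, `v_hat` (diagonal of Vhat),
#'   `kappas` (named `kappa1`, `kappa2`), `y_star`, `n_iter`, `converged`,
#'   plus the design pieces needed downstream.
#' @seealso [build_p3d()] for the frozen spectral context used by the
#'   screening and selection steps.
#' @export
pql_fit <- function(data, family, snp_columns = integer(), max_iter = 50,
                    tol = 1e-4, kappa_fixed = NULL) {
  stopifnot(inherits(data, "gwas_data"), inherits(family, "glmm_family"))
  y <- data$y
  n <- data$n
  if (!family$support_check(y)) {
    stop("phenotype is outside the support of the '", family$family_name,
         "' family")
  }
  snp_columns <- as.integer(snp_columns)
  if (length(snp_columns) && (min(snp_columns) < 1 || max(snp_columns) > data$p)) {
    stop("snp_columns out of range 1..", data$p)
  }
  X <- data$X_c
  q <- ncol(X)
  if (length(snp_columns)) {
    # SNP columns are mean-centered so downstream per-model GLS (which
    # regresses on SNPs with the control fit frozen) sees intercept-free
    # columns; with an intercept present this leaves the slopes unchanged
    snps <- data$X_s[, snp_columns, drop = FALSE]
    X <- cbind(X, sweep(snps, 2, colMeans(snps), "-"))
  }

  offset <- family$offset
  if (is.null(offset)) {
    offset <- if (family$family_name == "poisson" && !is.null(data$replicates)) {
      log(data$replicates)
    } else {
      rep(0, n)
    }
  }
  stopifnot(length(offset) == n)

  # initial linear predictor from a crude mean estimate
  mu <- family$init_mu(y)
  if (family$family_name == "bernoulli") mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  if (family$family_name == "poisson") mu <- pmax(mu, 1e-3)
  eta <- family$linkfun(mu)

  beta <- rep(0, ncol(X))
  kappa <- NULL
  alpha <- rep(0, n)
  converged <- FALSE
  n_iter <- 0L

  for (it in seq_len(max_iter)) {
    n_iter <- it
    mu <- family$mean_fn(eta)
    v <- pmax(family$variance_fn(eta), 1e-6)
    y_star <- (y - mu) / v + (eta - offset)
    if (any(!is.finite(y_star))) {
      stop("non-finite adjusted observations at iteration ", it,
           " (likely separation or extreme fitted values); ",
           "range(eta) = [", format(min(eta)), ", ", format(max(eta)), "]")
    }
    w_inv <- 1 / v

    if (is.null(kappa)) {
      kappa <- if (is.null(kappa_fixed)) {
        rep(0.1 * stats::var(y_star), 2)
      } else {
        as.numeric(kappa_fixed)
      }
    }
    if (is.null(kappa_fixed)) {
      kappa <- reml_kappa(y_star, X, data$Sigma, w_inv, init = kappa)
    }

    sol <- working_lmm_solve(y_star, X, data$Sigma, w_inv, kappa)
    d_beta <- max(abs(sol$beta - beta))
    d_kappa <- if (is.null(kappa_fixed)) {
      if (it == 1L) Inf else max(abs(kappa - kappa_prev))
    } else 0
    kappa_prev <- kappa
    beta <- sol$beta
    eta <- offset + as.vector(X %*% beta) + sol$alpha1 + sol$alpha2

    if (it > 1L && max(d_beta, d_kappa) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("PQL did not converge in ", max_iter, " iterations ",
            "(last max parameter change ", format(max(d_beta, d_kappa)), ")")
  }

  structure(list(
    beta_c_hat = beta[seq_len(q)],
    beta_snp_hat = if (length(snp_columns)) beta[-seq_len(q)] else numeric(),
    alpha1_hat = sol$alpha1,
    alpha2_hat = sol$alpha2,
    v_hat = v,
    kappas = c(kappa1 = kappa[1], kappa2 = kappa[2]),
    y_star = y_star,
    n_iter = n_iter,
    converged = converged,
    snp_columns = snp_columns,
    X_c = data$X_c,
    family_name = family$family_name,
    offset = offset
  ), class = "pseudo_fit")
}

#' @export
print.pseudo_fit <- function(x, ...) {
  cat("<pseudo_fit> ", x$family_name, " PQL, ", x$n_iter, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n",
      "  kappa1 = ", format(x$kappas[1], digits = 4),
      ", kappa2 = ", format(x$kappas[2], digits = 4),
      ", baseline SNPs: ", length(x$snp_columns), "\n", sep = "")
  invisible(x)
}

# REML profile log-likelihood of the working LMM
# y* ~ N(X beta, H), H = k1 Sigma + k2 I + diag(w_inv).
# Returns -2 * restricted log-likelihood up to a constant.
reml_neg2ll <- function(kappa, y_star, X, Sigma, w_inv) {
  H <- kappa[1] * Sigma
  diag(H) <- diag(H) + kappa[2] + w_inv
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  # half-weighted quantities: R' u = b  =>  u = backsolve(R, b, transpose)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y_star, transpose = TRUE)
  XtHiX <- crossprod(Xw)
  XtHiy <- crossprod(Xw, yw)
  cX <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(cX)) return(1e10)
  beta <- backsolve(cX, backsolve(cX, XtHiy, transpose = TRUE))
  quad <- sum(yw^2) - 2 * sum(XtHiy * beta) + sum((cX %*% beta)^2)
  logdetH <- 2 * sum(log(diag(R)))
  logdetX <- 2 * sum(log(diag(cX)))
  logdetH + logdetX + quad
}

# maximize REML over (kappa1, kappa2) >= 0 on the log scale
reml_kappa <- function(y_star, X, Sigma, w_inv, init) {
  lower <- log(1e-8)
  upper <- log(1e4)
  par0 <- pmin(pmax(log(pmax(init, 1e-6)), lower + 1), upper - 1)
  opt <- stats::optim(par0,
                      fn = function(lk) reml_neg2ll(exp(lk), y_star, X, Sigma, w_inv),
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 100, factr = 1e9))
  kappa <- exp(opt$par)
  # boundary: treat estimates at the lower bound as exact zeros
  kappa[kappa <= 2e-8] <- 0
  kappa
}

# GLS fixed effects + BLUP random effects for the working LMM at fixed kappa
working_lmm_solve <- function(y_star, X, Sigma, w_inv, kappa) {
  H <- kappa[1] * Sigma
  diag(H) <- diag(H) + kappa[2] + w_inv
  R <- chol(H)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y_star, transpose = TRUE)
  XtHiX <- crossprod(Xw)
  beta <- solve(XtHiX, crossprod(Xw, yw))
  r <- y_star - as.vector(X %*% beta)
  Hi_r <- backsolve(R, backsolve(R, r, transpose = TRUE))
  alpha1 <- if (kappa[1] > 0) kappa[1] * as.vector(Sigma %*% Hi_r) else rep(0, length(r))
  alpha2 <- if (kappa[2] > 0) kappa[2] * Hi_r else rep(0, length(r))
  list(beta = as.vector(beta), alpha1 = alpha1, alpha2 = alpha2)
}
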