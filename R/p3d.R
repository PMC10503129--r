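#' Frozen spectral context for P3D association scans
#'
#' Implements the population-parameters-previously-determined (P3D)
#' approximation: the converged pseudo-likelihood baseline fit supplies
#' variance components, per-sample variances and adjusted observations,
#' which are frozen into the covariance
#' `H = kappa1hat Sigma + kappa2hat I + Vhat^{-1}` of the adjusted
#' observations. Its spectral decomposition `H = P D P'` is computed once;
#' all models in a step are then fitted in the rotated coordinates
#' `ytilde = P' (y* - X_c beta_c_hat)`, `xtilde = P' x`, where the working
#' covariance is the diagonal `D`, making per-SNP generalized least squares
#' an O(n) operation.
#'
#' @param fit A converged [pql_fit()] result (the step's baseline model).
#' @param data The [gwas_data] object the baseline was fitted to.
#' @return An object of class `p3d_context` with elements `P` (orthonormal
#'   eigenvectors), `d` (eigenvalues of `H`), `y_tilde`, `n`, `kappas`,
#'   `rotate` (function `x -> P' x`), and the baseline `fit`.
#' @export
build_p3d <- function(fit, data) {
  stopifnot(inherits(fit, "pseudo_fit"), inherits(data, "gwas_data"))
  if (any(fit$v_hat <= 0)) stop("baseline fit has non-positive variances")
  H <- fit$kappas[1] * data$Sigma
  diag(H) <- diag(H) + fit$kappas[2] + 1 / fit$v_hat
  eg <- eigen(H, symmetric = TRUE)
  if (any(eg$values <= 0)) {
    stop("H has a non-positive eigenvalue (",
         format(min(eg$values)), "); baseline fit is degenerate")
  }
  P <- eg$vectors
  resid_c <- fit$y_star - as.vector(fit$X_c %*% fit$beta_c_hat)
  y_tilde <- as.vector(crossprod(P, resid_c))
  structure(list(
    P = P,
    d = eg$values,
    y_tilde = y_tilde,
    n = length(y_tilde),
    kappas = fit$kappas,
    rotate = function(x) crossprod(P, x),
    fit = fit
  ), class = "p3d_context")
}

#' @export
print.p3d_context <- function(x, ...) {
  cat("<p3d_context> n = ", x$n,
      ", eigenvalues in [", format(min(x$d), digits = 4), ", ",
      format(max(x$d), digits = 4), "]\n", sep = "")
  invisible(x)
}
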