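#' Exponential-family response model with canonical link
#'
#' Defines the conditional distribution of the phenotype given the random
#' effects: `f(y | eta) = exp(T(y) eta - B(eta) + C(y))` with mean
#' `mu = B'(eta)` and variance `v = B''(eta)`. Only canonical links are used,
#' so `dmu/deta = v`. Supported phenotypes are binary (Bernoulli, logit
#' link), counts (Poisson, log link), and a Gaussian identity-link family
#' with unit variance that exists so the pseudo-likelihood fitter collapses
#' to an ordinary linear mixed model.
#'
#' An additive per-sample `offset` on the linear-predictor scale carries the
#' log of replicate totals when a count phenotype is a sum over replicates;
#' when `offset` is `NULL`, [pql_fit()] derives `log(replicates)` from the
#' data if replicate counts are present.
#'
#' @param family_name One of `"bernoulli"`, `"poisson"`, `"gaussian"`.
#' @param offset Optional numeric vector of per-sample offsets.
#' @return An object of class `glmm_family` with elements `family_name`,
#'   `link`, `mean_fn`, `variance_fn`, `sufficient_stat`, `linkinv`,
#'   `linkfun`, `offset`, and helpers used by the fitter.
#' @examples
#' fam <- glmm_family("bernoulli")
#' fam$mean_fn(0)        # 0.5
#' fam$variance_fn(0)    # 0.25
#' @export
glmm_family <- function(family_name = c("bernoulli", "poisson", "gaussian"),
                        offset = NULL) {
  family_name <- match.arg(family_name)
  fam <- switch(family_name,
    bernoulli = list(
      link = "logit",
      mean_fn = stats::plogis,
      variance_fn = function(eta) {
        p <- stats::plogis(eta)
        p * (1 - p)
      },
      sufficient_stat = identity,
      linkfun = stats::qlogis,
      support_check = function(y) all(y %in% c(0, 1)),
      init_mu = function(y) (y + 0.5) / 2
    ),
    poisson = list(
      link = "log",
      mean_fn = exp,
      variance_fn = exp,
      sufficient_stat = identity,
      linkfun = log,
      support_check = function(y) all(is.finite(y) & y >= 0 & y == round(y)),
      init_mu = function(y) y + 0.1
    ),
    gaussian = list(
      link = "identity",
      mean_fn = identity,
      variance_fn = function(eta) rep(1, length(eta)),
      sufficient_stat = identity,
      linkfun = identity,
      support_check = function(y) all(is.finite(y)),
      init_mu = identity
    )
  )
  if (!is.null(offset)) stopifnot(is.numeric(offset), all(is.finite(offset)))
  structure(c(list(family_name = family_name, offset = offset), fam),
            class = "glmm_family")
}

#' @export
print.glmm_family <- function(x, ...) {
  cat("<glmm_family> ", x$family_name, " (", x$link, " link)",
      if (!is.null(x$offset)) sprintf(", offset of length %d", length(x$offset)),
      "\n", sep = "")
  invisible(x)
}
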