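#' Simulate structured genotypes
#'
#' Balding-Nichols-style generator: each SNP draws an ancestral minor
#' allele frequency uniformly on `maf_range`; each subpopulation perturbs
#' it through a beta model with divergence `fst`
#' (`Beta(q(1-F)/F, (1-q)(1-F)/F)`, collapsing to the ancestral frequency
#' at `fst = 0`); genotypes are binomial(2, subpopulation frequency) allele
#' counts. Samples are assigned to subpopulations round-robin. SNPs whose
#' realized MAF falls below 0.01 are redrawn. Positions sit on one
#' synthetic chromosome at 1 kb spacing, so a 5000 bp buffer spans +/- 5
#' SNPs.
#'
#' @param n Number of samples.
#' @param p Number of SNPs.
#' @param maf_range Ancestral MAF range, default `c(0.05, 0.5)`.
#' @param n_subpops Number of subpopulations (default 3).
#' @param fst Divergence parameter in `[0, 1)` (default 0.01).
#' @param seed Optional integer seed.
#' @return List with `genotypes` (n x p matrix) and `map` (data frame
#'   `snp_id`, `chrom`, `pos`).
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.05, 0.5),
                               n_subpops = 3, fst = 0.01, seed = NULL) {
  stopifnot(n > 0, p > 0, maf_range[1] > 0, maf_range[2] <= 0.5, fst >= 0,
            fst < 1)
  subpop <- rep_len(seq_len(n_subpops), n)
  with_seed(seed, {
    G <- matrix(0L, n, p)
    todo <- seq_len(p)
    for (round in 1:100) {
      m <- length(todo)
      if (m == 0) break
      q <- stats::runif(m, maf_range[1], maf_range[2])
      # subpop frequencies: n_subpops x m
      Fq <- if (fst == 0) {
        matrix(q, n_subpops, m, byrow = TRUE)
      } else {
        matrix(stats::rbeta(n_subpops * m,
                            rep(q * (1 - fst) / fst, each = n_subpops),
                            rep((1 - q) * (1 - fst) / fst, each = n_subpops)),
               n_subpops, m)
      }
      Fq <- pmin(pmax(Fq, 1e-6), 1 - 1e-6)
      draw <- matrix(stats::rbinom(n * m, 2L, Fq[subpop, , drop = FALSE]),
                     n, m)
      G[, todo] <- draw
      af <- colMeans(draw) / 2
      ok <- pmin(af, 1 - af) >= 0.01
      todo <- todo[!ok]
    }
    if (length(todo)) {
      stop("could not realize MAF >= 0.01 for ", length(todo),
           " SNP(s); widen maf_range or increase n")
    }
    map <- data.frame(snp_id = sprintf("snp_%05d", seq_len(p)),
                      chrom = 1L,
                      pos = seq_len(p) * 1000L - 999L,
                      stringsAsFactors = FALSE)
    colnames(G) <- map$snp_id
    list(genotypes = G, map = map)
  })
}

#' Causal architecture of a simulated scenario
#'
#' Places `n_causal` causal SNPs evenly spaced over the SNP indices and
#' assigns them coefficients by effect group, e.g. the binary design's 20
#' causal SNPs (10 at a varying `beta`, 5 at 0.2, 5 at -0.2) or the count
#' design's 10 (5 at `beta`, 5 at 0.2).
#'
#' @param p Total number of SNPs.
#' @param effect_groups List of `c(count, coefficient)` pairs; counts must
#'   sum to the number of causal SNPs.
#' @param intercept Intercept `beta0` of the linear predictor.
#' @return An object of class `causal_spec` with `indices`, `effects`,
#'   `intercept`, `n_causal`.
#' @export
causal_spec <- function(p, effect_groups, intercept) {
  counts <- vapply(effect_groups, `[`, numeric(1), 1)
  coefs <- vapply(effect_groups, `[`, numeric(1), 2)
  stopifnot(all(counts == round(counts)), all(is.finite(coefs)),
            is.finite(intercept))
  n_causal <- sum(counts)
  stopifnot(n_causal <= p)
  idx <- if (n_causal > 0) {
    round(seq(1, p, length.out = n_causal + 2))[seq_len(n_causal) + 1]
  } else {
    integer()
  }
  structure(list(indices = as.integer(idx),
                 effects = rep(coefs, counts),
                 intercept = intercept,
                 n_causal = as.integer(n_causal)),
            class = "causal_spec")
}

# draw alpha ~ N(0, kappa * Sigma)
draw_kinship_effect <- function(Sigma, kappa) {
  n <- nrow(Sigma)
  if (kappa == 0) return(rep(0, n))
  R <- chol(Sigma + diag(1e-8, n))
  sqrt(kappa) * as.vector(crossprod(R, stats::rnorm(n)))
}

#' Simulate a binary phenotype from the Bernoulli GLMM
#'
#' Linear predictor `eta = beta0 + sum_j effect_j x_ij + alpha_i` with
#' kinship effect `alpha ~ N(0, kappa1 Sigma)`; `y ~ Bernoulli(logit^{-1}(eta))`.
#'
#' @param genotypes n x p allele-count matrix.
#' @param Sigma Kinship matrix.
#' @param causal A [causal_spec].
#' @param kappa1 Kinship variance component.
#' @param seed Optional integer seed.
#' @return Integer 0/1 phenotype vector.
#' @export
simulate_binary_phenotype <- function(genotypes, Sigma, causal, kappa1,
                                      seed = NULL) {
  stopifnot(inherits(causal, "causal_spec"),
            all(causal$indices <= ncol(genotypes)))
  with_seed(seed, {
    eta <- causal$intercept + rep(0, nrow(genotypes))
    if (causal$n_causal > 0) {
      eta <- eta + as.vector(genotypes[, causal$indices, drop = FALSE] %*%
                               causal$effects)
    }
    eta <- eta + draw_kinship_effect(Sigma, kappa1)
    stats::rbinom(length(eta), 1L, stats::plogis(eta))
  })
}

#' Simulate a count phenotype from the Poisson GLMM
#'
#' Linear predictor `eta = log(r_i) + beta0 + sum_j effect_j x_ij +
#' alpha_1i + alpha_2i` with kinship effect `alpha1 ~ N(0, kappa1 Sigma)`,
#' overdispersion effect `alpha2 ~ N(0, kappa2 I)`, and per-sample
#' replicate totals `r_i` entering as a log offset;
#' `y ~ Poisson(exp(eta))`.
#'
#' @inheritParams simulate_binary_phenotype
#' @param kappa2 Overdispersion variance component.
#' @param replicates Per-sample replicate totals (scalar recycled).
#' @return Integer count phenotype vector.
#' @export
simulate_count_phenotype <- function(genotypes, Sigma, causal, kappa1,
                                     kappa2, replicates = 1, seed = NULL) {
  stopifnot(inherits(causal, "causal_spec"), all(replicates >= 1))
  n <- nrow(genotypes)
  r <- rep_len(replicates, n)
  with_seed(seed, {
    eta <- log(r) + causal$intercept
    if (causal$n_causal > 0) {
      eta <- eta + as.vector(genotypes[, causal$indices, drop = FALSE] %*%
                               causal$effects)
    }
    eta <- eta + draw_kinship_effect(Sigma, kappa1) +
      stats::rnorm(n, 0, sqrt(kappa2))
    lambda <- exp(eta)
    if (any(lambda > 1e8)) {
      stop("exp(eta) overflow (max lambda ", format(max(lambda)),
           "); reduce kappa1/kappa2 or the effect sizes")
    }
    stats::rpois(n, lambda)
  })
}

#' Build a complete simulated GWAS data set
#'
#' Scenario builders reproducing the simulation designs used throughout:
#' \describe{
#'   \item{`"binary"`}{Bernoulli-logit phenotype, 20 evenly spaced causal
#'     SNPs (10 at `beta`, 5 at 0.2, 5 at -0.2), intercept -0.5, kinship
#'     variance 0.15.}
#'   \item{`"count"`}{Poisson-log phenotype with a log-replicate offset
#'     (12 replicates), 10 evenly spaced causal SNPs (5 at `beta`, 5 at
#'     0.2), intercept 1, kinship variance 1, overdispersion variance 0.3.}
#'   \item{`"null-binary"`, `"null-count"`}{Same models with no causal
#'     SNPs.}
#' }
#' Genotypes come from [simulate_genotypes()] and the kinship matrix is the
#' genomic relationship matrix of those genotypes.
#'
#' @param scenario One of `"binary"`, `"count"`, `"null-binary"`,
#'   `"null-count"`.
#' @param beta Varying causal coefficient (required for the non-null
#'   scenarios).
#' @param n,p Samples and SNPs.
#' @param seed Integer seed (drives genotypes and phenotype).
#' @param ... Passed to [simulate_genotypes()] (e.g. `n_subpops`, `fst`).
#' @return List with `data` (a [gwas_data]), `causal` (a [causal_spec]),
#'   and `truth` (data frame of causal `chrom`/`pos`, empty under the
#'   null).
#' @export
simulate_gwas <- function(scenario = c("binary", "count", "null-binary",
                                       "null-count"),
                          beta = NULL, n, p, seed = NULL, ...) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("binary", "count") && is.null(beta)) {
    stop("scenario '", scenario, "' needs a varying coefficient `beta`")
  }
  g <- simulate_genotypes(n, p, seed = if (is.null(seed)) NULL
                          else mix_seed(seed, 1), ...)
  Sigma <- grm(g$genotypes)
  pheno_seed <- if (is.null(seed)) NULL else mix_seed(seed, 2)
  if (scenario %in% c("binary", "null-binary")) {
    groups <- if (scenario == "binary") {
      list(c(10, beta), c(5, 0.2), c(5, -0.2))
    } else {
      list()
    }
    cs <- causal_spec(p, groups, intercept = -0.5)
    y <- simulate_binary_phenotype(g$genotypes, Sigma, cs, kappa1 = 0.15,
                                   seed = pheno_seed)
    dat <- gwas_data(g$genotypes, g$map, y, kinship = Sigma)
  } else {
    groups <- if (scenario == "count") list(c(5, beta), c(5, 0.2)) else list()
    cs <- causal_spec(p, groups, intercept = 1)
    y <- simulate_count_phenotype(g$genotypes, Sigma, cs, kappa1 = 1,
                                  kappa2 = 0.3, replicates = 12,
                                  seed = pheno_seed)
    dat <- gwas_data(g$genotypes, g$map, y, kinship = Sigma,
                     replicates = rep(12, n))
  }
  truth <- g$map[cs$indices, c("chrom", "pos"), drop = FALSE]
  rownames(truth) <- NULL
  list(data = dat, causal = cs, truth = truth)
}
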