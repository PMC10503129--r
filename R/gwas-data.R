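#' Assemble a GWAS data set
#'
#' Bundles the genotype matrix, SNP map, phenotype, control covariates,
#' kinship matrix and optional replicate counts into one validated object.
#' Missing genotypes are mean-imputed per SNP; SNPs whose minor allele
#' frequency (computed after imputation) falls below `maf_min` are dropped
#' together with their map rows. If no kinship matrix is supplied, a
#' genomic relationship matrix is computed from the (filtered) genotypes
#' with [grm()].
#'
#' @param genotypes Numeric matrix, samples x SNPs, allele counts in
#'   `{0, 1, 2}` with `NA` allowed.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   one row per SNP column. Defaults to column names (or `snp_<j>`) on one
#'   synthetic chromosome at 1 kb spacing.
#' @param phenotype Numeric vector, length `nrow(genotypes)`.
#' @param covariates Optional numeric matrix of control covariates; an
#'   intercept column of ones is prepended automatically.
#' @param kinship Optional n x n positive semi-definite kinship matrix.
#' @param replicates Optional positive integer vector of per-sample
#'   replicate totals (Poisson offset is `log(replicates)`).
#' @param maf_min Minimum minor allele frequency; default 0.01.
#' @return An object of class `gwas_data` with elements `y`, `X_s`,
#'   `snp_map`, `X_c`, `Sigma`, `replicates`, `n`, `p`, `n_imputed`.
#' @export
gwas_data <- function(genotypes, map = NULL, phenotype, covariates = NULL,
                      kinship = NULL, replicates = NULL, maf_min = 0.01) {
  X_s <- as.matrix(genotypes)
  storage.mode(X_s) <- "double"
  n <- nrow(X_s)
  p <- ncol(X_s)
  y <- as.numeric(phenotype)
  if (length(y) != n) {
    stop("phenotype length (", length(y), ") != number of samples (", n, ")")
  }
  bad <- !(X_s %in% c(0, 1, 2) | is.na(X_s))
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1], dim(X_s))
    stop("genotype value not in {0,1,2,NA} at row ", idx[1], ", column ", idx[2])
  }

  if (is.null(map)) {
    ids <- colnames(X_s)
    if (is.null(ids)) ids <- sprintf("snp_%d", seq_len(p))
    map <- data.frame(snp_id = ids, chrom = 1L,
                      pos = seq_len(p) * 1000L - 999L,
                      stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)), nrow(map) == p)
  if (anyDuplicated(map$snp_id)) {
    stop("duplicated SNP id: ", map$snp_id[duplicated(map$snp_id)][1])
  }

  # mean imputation per SNP, then MAF filter on the imputed matrix
  n_imputed <- 0L
  if (anyNA(X_s)) {
    na_cols <- which(colSums(is.na(X_s)) > 0)
    n_imputed <- sum(is.na(X_s))
    for (j in na_cols) {
      m <- mean(X_s[, j], na.rm = TRUE)
      X_s[is.na(X_s[, j]), j] <- m
    }
  }
  af <- colMeans(X_s) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_min
  if (!all(keep)) {
    X_s <- X_s[, keep, drop = FALSE]
    map <- map[keep, , drop = FALSE]
    rownames(map) <- NULL
    p <- ncol(X_s)
  }
  if (p == 0L) stop("no SNPs left after MAF filter")

  X_c <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    X_c <- cbind(X_c, as.matrix(covariates))
  }
  if (qr(X_c)$rank < ncol(X_c)) stop("control covariates are rank deficient")

  if (is.null(kinship)) {
    Sigma <- grm(X_s)
  } else {
    Sigma <- as.matrix(kinship)
    if (nrow(Sigma) != n || ncol(Sigma) != n) stop("kinship matrix must be n x n")
    if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma)))) {
      stop("kinship matrix is not symmetric")
    }
    Sigma <- (Sigma + t(Sigma)) / 2
    ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8) {
      stop("kinship matrix is not positive semi-definite (min eigenvalue ",
           format(ev_min), ")")
    }
  }

  if (!is.null(replicates)) {
    replicates <- as.numeric(replicates)
    stopifnot(length(replicates) == n, all(replicates >= 1))
  }

  structure(list(y = y, X_s = X_s, snp_map = map, X_c = X_c, Sigma = Sigma,
                 replicates = replicates, n = n, p = p, n_imputed = n_imputed),
            class = "gwas_data")
}

#' @export
print.gwas_data <- function(x, ...) {
  cat("<gwas_data> ", x$n, " samples x ", x$p, " SNPs; ",
      ncol(x$X_c) - 1L, " control covariate(s)",
      if (!is.null(x$replicates)) "; replicate counts present",
      if (x$n_imputed > 0) sprintf("; %d genotypes mean-imputed", x$n_imputed),
      "\n", sep = "")
  invisible(x)
}

#' Genomic relationship matrix
#'
#' Centered, allele-frequency-standardized realized relationship matrix
#' `Z Z' / p` where `Z[, j] = (g_j - 2 q_j) / sqrt(2 q_j (1 - q_j))`, used
#' as the kinship matrix when none is supplied. The result is symmetrized
#' and jittered by `1e-8 * I` so it is numerically positive semi-definite.
#'
#' @param genotypes Samples x SNPs allele-count matrix (no missing values).
#' @return An n x n kinship matrix.
#' @export
grm <- function(genotypes) {
  G <- as.matrix(genotypes)
  q <- colMeans(G) / 2
  v <- 2 * q * (1 - q)
  realized_var <- colMeans(G^2) - (2 * q)^2
  if (any(v <= 0 | realized_var <= 0)) {
    stop("zero-variance SNP at column ",
         which(v <= 0 | realized_var <= 0)[1],
         "; filter monomorphic SNPs first")
  }
  Z <- sweep(G, 2, 2 * q, "-")
  Z <- sweep(Z, 2, sqrt(v), "/")
  K <- tcrossprod(Z) / ncol(G)
  K <- (K + t(K)) / 2
  diag(K) <- diag(K) + 1e-8
  K
}
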