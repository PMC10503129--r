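#' Single-marker analysis with Bonferroni correction
#'
#' Frequentist baseline scan: per-SNP Wald tests on the same
#' pseudo-likelihood working model used by the screening step. The no-SNP
#' baseline GLMM is fitted by PQL, the spectral P3D context is frozen, and
#' each SNP's GLS estimate and standard error give a z statistic
#' `z = betahat_s / se_s` referred to the standard normal; SNPs with
#' `p < alpha / p_total` are selected (Bonferroni at family level `alpha`).
#'
#' @param data A [gwas_data] object.
#' @param family A [glmm_family] object.
#' @param alpha Family-wise level for the Bonferroni rule (default 0.05).
#' @param ctx Optional prebuilt [build_p3d()] context (reuses a screening
#'   baseline so both methods share identical summaries).
#' @return An object of class `sma_result`: a per-SNP `table` (`snp_id`,
#'   `chrom`, `pos`, `beta_hat`, `se`, `z`, `p`, `bonferroni_selected`) and
#'   `selected` (SNP indices).
#' @examples
#' sim <- simulate_gwas("null-binary", n = 100, p = 200, seed = 3)
#' sma_scan(sim$data, glmm_family("bernoulli"))$selected
#' @export
sma_scan <- function(data, family, alpha = 0.05, ctx = NULL) {
  if (is.null(ctx)) {
    fit <- pql_fit(data, family, snp_columns = integer())
    ctx <- build_p3d(fit, data)
  }
  sm <- snp_summaries(ctx, data$X_s)
  se <- sqrt(sm$sigma2)
  z <- sm$beta_hat / se
  pval <- 2 * stats::pnorm(-abs(z))
  sel <- which(pval < alpha / data$p)
  tab <- data.frame(snp_id = data$snp_map$snp_id,
                    chrom = data$snp_map$chrom,
                    pos = data$snp_map$pos,
                    beta_hat = sm$beta_hat,
                    se = se, z = z, p = pval,
                    bonferroni_selected = seq_len(data$p) %in% sel,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, selected = sel, alpha = alpha),
            class = "sma_result")
}

#' @export
print.sma_result <- function(x, ...) {
  cat("<sma_result> ", nrow(x$table), " SNPs tested, ",
      length(x$selected), " selected at Bonferroni ", x$alpha, "\n", sep = "")
  invisible(x)
}
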