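#' Read a genotype matrix from disk
#'
#' Two dialects are supported. `"csv-matrix"`: a CSV with a header row of
#' SNP ids, sample ids in the first column, and cells in `{0, 1, 2, NA}`.
#' `"plink-raw"`: the whitespace-delimited dialect written by
#' `plink --recode A` (six meta columns `FID IID PAT MAT SEX PHENOTYPE`
#' followed by one column per SNP, names carrying an `_A`-style counted
#' allele suffix, which is stripped).
#'
#' @param path File path.
#' @param format `"csv-matrix"` or `"plink-raw"`.
#' @return List with `genotypes` (numeric matrix with SNP ids as column
#'   names, sample ids as row names) and `sample_ids`.
#' @export
read_genotypes <- function(path, format = c("csv-matrix", "plink-raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty genotype file: ", path)
  if (format == "csv-matrix") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0 || ncol(df) < 2) stop("empty genotype file: ", path)
    sample_ids <- as.character(df[[1]])
    G <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(G) <- "double"
    colnames(G) <- names(df)[-1] # data-frame subsetting mangles duplicates
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df))) {
      stop("plink-raw file lacks the 6 meta columns ",
           paste(meta, collapse = " "))
    }
    sample_ids <- as.character(df$IID)
    G <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
    storage.mode(G) <- "double"
    colnames(G) <- sub("_[ACGT0-9]+$", "", colnames(G))
  }
  if (anyDuplicated(colnames(G))) {
    stop("duplicated SNP id: ", colnames(G)[duplicated(colnames(G))][1])
  }
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1], dim(G))
    stop("genotype value not in {0,1,2,NA} at row ", idx[1],
         ", column ", idx[2], " (", colnames(G)[idx[2]], ")")
  }
  rownames(G) <- sample_ids
  list(genotypes = G, sample_ids = sample_ids)
}

#' Write a genotype matrix as csv-matrix
#'
#' Inverse of [read_genotypes()] for the `"csv-matrix"` dialect.
#'
#' @param genotypes Matrix with SNP ids as column names.
#' @param path Output path.
#' @param sample_ids Sample identifiers (defaults to row names or `s<i>`).
#' @export
write_genotypes <- function(genotypes, path, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- rownames(genotypes)
    if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(nrow(genotypes)))
  }
  df <- data.frame(sample_id = sample_ids, genotypes, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read or write a SNP map, phenotype, or kinship file
#'
#' Plain-text table helpers: the SNP map is a TSV with columns `snp_id`,
#' `chrom`, `pos`; the phenotype a TSV with `sample_id`, `y` and optional
#' `replicates`; the kinship matrix a square CSV.
#'
#' @param path File path.
#' @return The parsed object.
#' @name gwas_io
#' @export
read_snp_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(m)))
  m
}

#' @rdname gwas_io
#' @param map Data frame as returned by [read_snp_map()].
#' @export
write_snp_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname gwas_io
#' @export
read_phenotype <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname gwas_io
#' @param phenotype Data frame with `sample_id`, `y`, optional `replicates`.
#' @export
write_phenotype <- function(phenotype, path) {
  utils::write.table(phenotype, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' @rdname gwas_io
#' @export
read_kinship <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' @rdname gwas_io
#' @param kinship Square numeric matrix.
#' @export
write_kinship <- function(kinship, path) {
  utils::write.table(kinship, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

#' Write a results table as TSV
#'
#' Serializes the per-SNP table of a screening, SMA, or selection result.
#' A header comment records the hyperparameter scheme so runs are
#' self-describing.
#'
#' @param result A `screening_result`, `sma_result`, or `selection_result`.
#' @param path Output path.
#' @export
write_results <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(result, "screening_result")) {
    writeLines(sprintf(
      "# screening: tau_scheme=%s tau_hat=%.6g pi0_hat=%.8g fdr_alpha=%g",
      result$hyperprior$scheme, result$tau_hat, result$pi0_hat, result$alpha),
      con)
    tab <- result$table
  } else if (inherits(result, "sma_result")) {
    writeLines(sprintf("# sma: bonferroni family alpha=%g", result$alpha), con)
    tab <- result$table
  } else if (inherits(result, "selection_result")) {
    writeLines(sprintf("# selection: tau_hat=%.6g pi0_hat=%.8g k=%d",
                       result$tau_hat, result$pi0_hat,
                       length(result$candidates)), con)
    tab <- result$model_table
    if (is.null(tab)) tab <- data.frame(indicator = character(0))
    if (nrow(tab) && !is.null(result$best)) {
      tab$best <- tab$indicator == result$best$indicator[1]
    }
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
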