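#' Buffered matching of detections against causal SNPs
#'
#' Causal-centric matching rule: a causal SNP with one or more detected
#' SNPs on the same chromosome within `buffer_bp` base pairs contributes
#' exactly one true positive (several detections near the same causal SNP
#' still count once); each detected SNP not within the buffer of any causal
#' SNP contributes one false positive. A detected SNP inside the buffers of
#' two causal SNPs credits both.
#'
#' @param detected Data frame of detections with columns `chrom`, `pos`
#'   (1-based bp).
#' @param causal Data frame of causal SNPs with columns `chrom`, `pos`.
#' @param buffer_bp Buffer width in base pairs (default 5000).
#' @return List with integer `tp`, `fp`.
#' @export
match_detections <- function(detected, causal, buffer_bp = 5000) {
  detected <- as.data.frame(detected)
  causal <- as.data.frame(causal)
  near <- function(chrom, pos) {
    hit <- detected$chrom == chrom & abs(detected$pos - pos) <= buffer_bp
    any(hit)
  }
  tp <- if (nrow(causal)) {
    sum(mapply(near, causal$chrom, causal$pos))
  } else 0L
  fp <- if (nrow(detected)) {
    covered <- vapply(seq_len(nrow(detected)), function(i) {
      nrow(causal) > 0 &&
        any(causal$chrom == detected$chrom[i] &
              abs(causal$pos - detected$pos[i]) <= buffer_bp)
    }, logical(1))
    sum(!covered)
  } else 0L
  list(tp = as.integer(tp), fp = as.integer(fp))
}

#' Detection metrics: TP, FP, FDR and F1
#'
#' `fdr = FP / (TP + FP)` with the `0/0` case defined as 0 (no discoveries
#' means no false discovery), and `f1 = 2 TP / (2 TP + FP + FN)` with
#' `FN = n_causal - TP` (unmatched causal SNPs), also 0 in the `0/0` case.
#'
#' @param tp,fp Non-negative counts from [match_detections()].
#' @param n_causal Number of causal SNPs in the truth.
#' @return List with `tp`, `fp`, `fdr`, `f1`.
#' @export
detection_metrics <- function(tp, fp, n_causal) {
  stopifnot(tp >= 0, fp >= 0, n_causal >= 0)
  if (tp > n_causal) stop("tp (", tp, ") exceeds n_causal (", n_causal, ")")
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  fn <- n_causal - tp
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(tp = tp, fp = fp, fdr = fdr, f1 = f1)
}
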