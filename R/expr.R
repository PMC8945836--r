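# Simplified differential-expression stage (median-of-ratios normalization +
# Welch test on log counts, BH adjustment, the FDR<0.05 & |log2FC|>=1 DEG
# rule) and 2^-ddCt relative expression from qPCR Ct tables.

#' Median-of-ratios size factors
#'
#' Per gene, the geometric mean across samples is taken over genes with no
#' zero count; each sample's factor is the median over those genes of
#' count / geometric mean.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort_("counts must be non-negative")
  use <- rowSums(counts == 0) == 0
  if (!any(use)) abort_("no gene has nonzero counts in every sample")
  lg <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, median)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values (monotone, capped at 1), in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    abort_("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(pvalues[o] * m / (m:1)))[ro]
}

#' Welch differential-expression test on normalized log counts
#'
#' Counts are scaled by [size_factors()], log2(x + 1)-transformed, and each
#' gene is tested with a Welch two-sample t-test (MUT vs WT). log2 fold change
#' is computed from normalized group means with a +1 pseudocount. Genes that
#' are constant across all samples get p = 1 by convention. A gene is a DEG
#' when BH-adjusted FDR < 0.05 and |log2FC| >= 1.
#'
#' @param counts Genes x samples matrix (rownames = gene ids).
#' @param groups Character vector over `{"WT","MUT"}`, one per sample, at
#'   least two replicates each.
#' @param fdr_cut,lfc_cut DEG thresholds (defaults 0.05 and 1).
#' @return data.frame `gene`, `log2fc`, `pvalue`, `fdr`, `is_deg`,
#'   `direction` (up/down/none, MUT relative to WT).
#' @export
de_test <- function(counts, groups, fdr_cut = 0.05, lfc_cut = 1) {
  counts <- as.matrix(counts)
  stopifnot(length(groups) == ncol(counts))
  if (!all(groups %in% c("WT", "MUT"))) abort_("groups must be WT or MUT")
  if (min(table(factor(groups, c("WT", "MUT")))) < 2L)
    abort_("need >= 2 replicates per group")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  lx <- log2(norm + 1)
  a <- groups == "MUT"; b <- groups == "WT"
  na <- sum(a); nb <- sum(b)
  ma <- rowMeans(lx[, a, drop = FALSE]); mb <- rowMeans(lx[, b, drop = FALSE])
  va <- apply(lx[, a, drop = FALSE], 1, stats::var)
  vb <- apply(lx[, b, drop = FALSE], 1, stats::var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  constant <- apply(counts, 1, function(x) length(unique(x)) == 1L)
  p[constant | !is.finite(p)] <- 1
  log2fc <- log2(rowMeans(norm[, a, drop = FALSE]) + 1) -
            log2(rowMeans(norm[, b, drop = FALSE]) + 1)
  fdr <- bh_fdr(p)
  is_deg <- fdr < fdr_cut & abs(log2fc) >= lfc_cut
  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             log2fc = log2fc, pvalue = p, fdr = fdr, is_deg = is_deg,
             direction = ifelse(!is_deg, "none",
                                ifelse(log2fc > 0, "up", "down")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize DEG counts and percentages
#'
#' @param results A [de_test()] result.
#' @return List `n_up`, `n_down`, `pct_up`, `pct_down`; percentages of the DEG
#'   total rounded to 2 decimals, `NULL` when there are no DEGs.
#' @export
deg_summary <- function(results) {
  n_up <- sum(results$is_deg & results$direction == "up")
  n_down <- sum(results$is_deg & results$direction == "down")
  tot <- n_up + n_down
  if (tot == 0L)
    return(list(n_up = 0L, n_down = 0L, pct_up = NULL, pct_down = NULL))
  list(n_up = n_up, n_down = n_down,
       pct_up = round(100 * n_up / tot, 2),
       pct_down = round(100 * n_down / tot, 2))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per condition, delta-Ct is the mean target Ct minus the mean reference-gene
#' Ct; delta-delta-Ct subtracts the calibrator condition, and the fold change
#' is 2^-ddCt.
#'
#' @param test,calibrator data.frames with numeric columns `ct_target` and
#'   `ct_reference` (one row per technical/biological replicate).
#' @return Positive fold change (test relative to calibrator).
#' @examples
#' ddct(data.frame(ct_target = 20, ct_reference = 18),
#'      data.frame(ct_target = 22, ct_reference = 18))  # 4
#' @export
ddct <- function(test, calibrator) {
  need <- c("ct_target", "ct_reference")
  for (d in list(test, calibrator))
    if (!all(need %in% names(d)) || nrow(d) < 1L)
      abort_("need ct_target and ct_reference rows for both conditions")
  dct <- function(d) mean(d$ct_target) - mean(d$ct_reference)
  2^-(dct(test) - dct(calibrator))
}
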