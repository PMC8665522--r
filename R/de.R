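# Differential-expression screening at the p < 0.05, |log2FC| > 1
# thresholds, with MA/volcano summary tables and hierarchical clustering
# of the DE panel.

#' Per-gene differential-expression test
#'
#' For each gene, the fold change is computed on the FPKM scale as
#' `log2((mean_tumor + 1) / (mean_control + 1))` (pseudocount 1 keeps the
#' statistic finite for silent genes) and the p-value from Welch's
#' two-sample t-test on `log2(FPKM + 1)`. Genes with zero variance in
#' both groups are handled deterministically: equal means give p = 1,
#' unequal means give p = 0 and are flagged `degenerate`. A
#' Benjamini-Hochberg adjusted p-value is reported alongside but the
#' default status call in [classifyDE()] uses the raw p-value.
#'
#' @param object an [ExpressionMatrix-class] with unit `"fpkm"`.
#' @return data.frame with columns `gene_id`, `biotype`, `mean_control`,
#'   `mean_tumor`, `base_mean` (mean FPKM over all samples, the MA-plot
#'   x-axis), `log2fc`, `p_value`, `adj_p`, `degenerate`.
#' @export
testDifferential <- function(object) {
  stopifnot(is(object, "ExpressionMatrix"))
  if (exprUnit(object) != "fpkm")
    stop("testDifferential expects FPKM values")
  if (nrow(object) == 0) stop("empty expression matrix")
  cond <- SummarizedExperiment::colData(object)$condition
  if (sum(cond == "tumor") < 2 || sum(cond == "control") < 2)
    stop("each group needs at least 2 samples")
  fpkm <- exprValues(object)
  lg <- log2p1(fpkm)
  res <- welchRows(lg[, cond == "tumor", drop = FALSE],
                   lg[, cond == "control", drop = FALSE])
  mean_t <- rowMeans(fpkm[, cond == "tumor", drop = FALSE])
  mean_c <- rowMeans(fpkm[, cond == "control", drop = FALSE])
  data.frame(
    gene_id = rownames(fpkm),
    biotype = unname(geneBiotypes(object)),
    mean_control = mean_c,
    mean_tumor = mean_t,
    base_mean = rowMeans(fpkm),
    log2fc = log2((mean_t + 1) / (mean_c + 1)),
    p_value = res$p,
    adj_p = stats::p.adjust(res$p, "BH"),
    degenerate = res$degenerate,
    stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized Welch t-test across rows; x = group 1, y = group 2.
welchRows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowVars(x); v2 <- rowVars(y)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  degenerate <- zero & (m1 != m2)
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  list(t = tt, df = df, p = p, degenerate = degenerate)
}

#' Call differential-expression status
#'
#' Applies the screening rule: `up` iff `p < alpha` and
#' `log2fc > lfcMin`; `down` iff `p < alpha` and `log2fc < -lfcMin`;
#' otherwise `ns`. Inequalities are strict, so a gene sitting exactly at
#' `log2fc = lfcMin` is not significant.
#'
#' @param results output of [testDifferential()].
#' @param alpha raw p-value threshold (default 0.05).
#' @param lfcMin minimum |log2 fold change| (default 1).
#' @param useAdjusted call status on `adj_p` instead of the raw
#'   `p_value`.
#' @return `results` with a `status` column in \{up, down, ns\}.
#' @export
classifyDE <- function(results, alpha = 0.05, lfcMin = 1,
                       useAdjusted = FALSE) {
  p <- if (useAdjusted) results$adj_p else results$p_value
  status <- rep("ns", nrow(results))
  status[p < alpha & results$log2fc > lfcMin] <- "up"
  status[p < alpha & results$log2fc < -lfcMin] <- "down"
  results$status <- status
  results
}

#' MA/volcano summary tables and DE-panel clustering
#'
#' Produces the plot-ready tables behind the standard DE overview
#' figures and a hierarchical clustering of samples on the DE panel:
#' z-scored `log2(FPKM + 1)` of the DE genes, Euclidean distance,
#' average linkage, with a 2-cut sample partition.
#'
#' @param results a classified DE table (from [classifyDE()]).
#' @param object the [ExpressionMatrix-class] (unit `"fpkm"`) the tests
#'   were run on.
#' @return list with `ma` (`gene_id`, `base_mean`, `log2fc`, `status`),
#'   `volcano` (`gene_id`, `log2fc`, `neg_log10_p`, `status`) and
#'   `clustering` (`hclust` object, `merge` order and 2-cut `partition`
#'   named by sample), or `NULL` clustering with a warning when no gene
#'   is DE.
#' @export
summarizePlots <- function(results, object) {
  stopifnot(is(object, "ExpressionMatrix"), "status" %in% names(results))
  ma <- data.frame(gene_id = results$gene_id,
                   base_mean = results$base_mean,
                   log2fc = results$log2fc, status = results$status,
                   stringsAsFactors = FALSE)
  volcano <- data.frame(gene_id = results$gene_id,
                        log2fc = results$log2fc,
                        neg_log10_p = -log10(results$p_value),
                        status = results$status,
                        stringsAsFactors = FALSE)
  de_ids <- results$gene_id[results$status != "ns"]
  clustering <- NULL
  if (length(de_ids) == 0) {
    warning("no DE genes; clustering skipped")
  } else {
    z <- zscoreGenes(log2p1(exprValues(object)[de_ids, , drop = FALSE]))
    hc <- stats::hclust(stats::dist(t(z)), method = "average")
    clustering <- list(hclust = hc, merge = hc$merge,
                       partition = stats::cutree(hc, k = 2))
  }
  list(ma = ma, volcano = volcano, clustering = clustering)
}

# z-score each gene (row) across samples; constant rows are dropped.
zscoreGenes <- function(m) {
  sds <- sqrt(rowVars(m))
  keep <- is.finite(sds) & sds > 0
  m <- m[keep, , drop = FALSE]
  (m - rowMeans(m)) / sds[keep]
}

#' Write a DE result table as TSV
#' @param results DE table.
#' @param path TSV path.
#' @export
writeDEResults <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
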