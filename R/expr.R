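# FPKM normalization, expression filtering and TSV I/O.

#' FPKM normalization of a count matrix
#'
#' Converts raw fragment counts to fragments per kilobase of transcript
#' per million mapped fragments:
#' \deqn{FPKM_{gs} = \frac{10^9 \, c_{gs}}{N_s \, L_g}}
#' where \eqn{c_{gs}} is the count of gene g in sample s, \eqn{L_g} the
#' transcript length in bp and \eqn{N_s} the per-sample library size,
#' taken as the column sum of the supplied matrix (the standard surrogate
#' for "mapped fragments" when alignments are not at hand).
#'
#' @param object an [ExpressionMatrix-class] with unit `"counts"`.
#' @return an [ExpressionMatrix-class] with unit `"fpkm"`; metadata are
#'   carried over unchanged.
#' @examples
#' m <- matrix(c(100, 900), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' em <- ExpressionMatrix(m, c(2000, 1000), c("mRNA", "mRNA"),
#'                        data.frame(sample_id = "s1", condition = "tumor"))
#' exprValues(computeFPKM(em))
#' @export
computeFPKM <- function(object) {
  stopifnot(is(object, "ExpressionMatrix"))
  if (exprUnit(object) != "counts")
    stop("computeFPKM expects a counts matrix, got unit '",
         exprUnit(object), "'")
  counts <- exprValues(object)
  len <- geneLengths(object)
  if (anyNA(len)) stop("missing gene lengths")
  total <- colSums(counts)
  if (ncol(counts) && any(total == 0))
    stop("zero column sum for sample(s): ",
         paste(colnames(counts)[total == 0], collapse = ", "))
  fpkm <- sweep(counts, 2, total, "/")
  fpkm <- fpkm / len * 1e9
  out <- object
  SummarizedExperiment::assays(out) <- stats::setNames(list(fpkm), "fpkm")
  out@unit <- "fpkm"
  validObject(out)
  out
}

#' Filter genes by minimum expression
#'
#' Keeps genes whose FPKM is at least `minFpkm` in at least `minSamples`
#' samples; gene order is preserved. With `minFpkm = 0` this is the
#' identity.
#'
#' @param object an [ExpressionMatrix-class] with unit `"fpkm"`.
#' @param minFpkm expression threshold (FPKM).
#' @param minSamples number of samples that must reach the threshold.
#' @return the filtered [ExpressionMatrix-class].
#' @export
filterExpressed <- function(object, minFpkm = 0.5, minSamples = 2) {
  stopifnot(is(object, "ExpressionMatrix"))
  if (exprUnit(object) != "fpkm")
    stop("filterExpressed expects FPKM values")
  if (minSamples > ncol(object))
    stop("minSamples exceeds the number of samples")
  keep <- rowSums(exprValues(object) >= minFpkm) >= minSamples
  object[keep, ]
}

#' Read / write expression matrices as TSV
#'
#' `writeExpression` writes two tab-separated files: the value matrix
#' (columns `gene_id`, `length_bp`, `biotype`, then one column per
#' sample; a `# unit: <tag>` comment line records the unit) and the
#' sample sheet (`sample_id`, `condition`, optional `pair_id`).
#' `readExpression` reverses this losslessly.
#'
#' @param object an [ExpressionMatrix-class].
#' @param path path of the value matrix TSV.
#' @param samplePath path of the sample sheet TSV; by default derived
#'   from `path` by appending `_samples` before the extension.
#' @return `readExpression` returns an [ExpressionMatrix-class];
#'   `writeExpression` returns `path` invisibly.
#' @export
writeExpression <- function(object, path, samplePath = NULL) {
  stopifnot(is(object, "ExpressionMatrix"))
  samplePath <- samplePath %||% defaultSamplePath(path)
  v <- exprValues(object)
  df <- data.frame(gene_id = rownames(v) %||% character(0),
                   length_bp = unname(geneLengths(object)),
                   biotype = unname(geneBiotypes(object)),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(v, optional = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", exprUnit(object)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sampleSheet(object), samplePath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path, samplePath = NULL) {
  samplePath <- samplePath %||% defaultSamplePath(path)
  first <- readLines(path, n = 1L)
  unit <- sub("^#\\s*unit:\\s*", "", first)
  if (identical(unit, first))
    stop("missing '# unit:' header line in ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- c("gene_id", "length_bp", "biotype")
  if (!all(meta_cols %in% colnames(df)))
    stop("expression TSV must start with gene_id, length_bp, biotype")
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene rows in ", path)
  sample_cols <- setdiff(colnames(df), meta_cols)
  v <- as.matrix(df[, sample_cols, drop = FALSE])
  if (length(v) && !is.numeric(v)) stop("non-numeric expression values")
  rownames(v) <- df$gene_id
  ss <- utils::read.delim(samplePath, stringsAsFactors = FALSE,
                          colClasses = "character")
  ExpressionMatrix(v, df$length_bp, df$biotype, ss, unit = unit)
}

defaultSamplePath <- function(path) {
  ext <- tools::file_ext(path)
  if (nzchar(ext))
    sub(paste0("\\.", ext, "$"), paste0("_samples.", ext), path)
  else paste0(path, "_samples")
}

#' log2(FPKM + 1) transform
#'
#' The variance-stabilizing transform used by the downstream testing,
#' correlation and clustering steps. The pseudocount of 1 keeps zeros at
#' zero.
#'
#' @param object an [ExpressionMatrix-class] with unit `"fpkm"`.
#' @return an [ExpressionMatrix-class] with unit `"log2fpkm"`.
#' @export
logTransform <- function(object) {
  stopifnot(is(object, "ExpressionMatrix"))
  if (exprUnit(object) != "fpkm")
    stop("logTransform expects FPKM values")
  out <- object
  SummarizedExperiment::assays(out) <-
    stats::setNames(list(log2p1(exprValues(object))), "log2fpkm")
  out@unit <- "log2fpkm"
  validObject(out)
  out
}
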