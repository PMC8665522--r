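#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

VALID_UNITS <- c("counts", "fpkm", "log2fpkm")
VALID_BIOTYPES <- c("mRNA", "lncRNA")
VALID_CONDITIONS <- c("tumor", "control")
NODE_TYPES <- c("lncRNA", "mRNA", "miRNA")
EDGE_KINDS <- c("correlation", "targeting")

#' ExpressionMatrix: genes-by-samples expression values with metadata
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment]
#' that stores a gene-level expression matrix (raw counts, FPKM, or
#' log2(FPKM+1)) together with the per-gene metadata (transcript length in
#' bp, biotype mRNA/lncRNA) and per-sample metadata (condition
#' tumor/control, optional pair id) the downstream analyses need.
#'
#' The single assay is named after the unit tag. Validity enforces: unique
#' gene and sample ids, positive integer lengths, biotype in
#' \{mRNA, lncRNA\}, condition in \{tumor, control\} for every sample, and
#' finite non-negative values for counts/FPKM.
#'
#' @slot unit one of `"counts"`, `"fpkm"`, `"log2fpkm"`.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(unit = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character(0)
  if (length(object@unit) != 1L || !object@unit %in% VALID_UNITS)
    msg <- c(msg, sprintf("unit must be one of %s",
                          paste(VALID_UNITS, collapse = ", ")))
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return(c(msg, "an assay is required"))
  v <- SummarizedExperiment::assay(object, 1L)
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample ids")
  if (length(v) && any(!is.finite(v))) msg <- c(msg, "non-finite values")
  if (length(v) && length(object@unit) == 1L &&
      object@unit %in% c("counts", "fpkm") && any(v < 0))
    msg <- c(msg, "counts/fpkm values must be >= 0")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("length_bp", "biotype") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain length_bp and biotype")
  } else if (nrow(rd)) {
    if (any(!is.finite(rd$length_bp)) || any(rd$length_bp <= 0))
      msg <- c(msg, "length_bp must be positive")
    if (!all(rd$biotype %in% VALID_BIOTYPES))
      msg <- c(msg, "biotype must be mRNA or lncRNA")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain condition")
  } else if (nrow(cd)) {
    if (any(is.na(cd$condition)) || !all(cd$condition %in% VALID_CONDITIONS))
      msg <- c(msg, "every sample needs condition tumor or control")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param lengthBp positive integer vector of transcript lengths (bp),
#'   one per gene.
#' @param biotype character vector, `"mRNA"` or `"lncRNA"`, one per gene.
#' @param sampleSheet data.frame with columns `sample_id`, `condition`
#'   (`"tumor"`/`"control"`) and optionally `pair_id`; rows are matched to
#'   the columns of `values` by `sample_id`.
#' @param unit unit tag of `values`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ss <- data.frame(sample_id = paste0("s", 1:4),
#'                  condition = rep(c("tumor", "control"), each = 2))
#' em <- ExpressionMatrix(m, c(1000, 2000, 1500),
#'                        c("mRNA", "mRNA", "lncRNA"), ss)
#' @export
ExpressionMatrix <- function(values, lengthBp, biotype, sampleSheet,
                             unit = c("counts", "fpkm", "log2fpkm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("values must have gene ids as rownames")
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("values must have sample ids as colnames")
  if (!"sample_id" %in% colnames(sampleSheet) ||
      !"condition" %in% colnames(sampleSheet))
    stop("sampleSheet needs columns sample_id and condition")
  idx <- match(colnames(values), sampleSheet$sample_id)
  if (anyNA(idx))
    stop("sampleSheet is missing samples: ",
         paste(colnames(values)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(
    condition = as.character(sampleSheet$condition)[idx],
    row.names = colnames(values))
  if ("pair_id" %in% colnames(sampleSheet))
    cd$pair_id <- as.character(sampleSheet$pair_id)[idx]
  rd <- S4Vectors::DataFrame(length_bp = as.numeric(lengthBp),
                             biotype = as.character(biotype),
                             row.names = rownames(values))
  assays <- stats::setNames(list(values), unit)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = cd)
  new("ExpressionMatrix", se, unit = unit)
}

#' @describeIn ExpressionMatrix unit tag accessor
#' @param object,x an `ExpressionMatrix`
#' @export
exprUnit <- function(object) object@unit

#' @describeIn ExpressionMatrix the value matrix (first assay)
#' @export
exprValues <- function(object) SummarizedExperiment::assay(object, 1L)

#' @describeIn ExpressionMatrix per-gene transcript lengths (bp)
#' @export
geneLengths <- function(object) {
  stats::setNames(SummarizedExperiment::rowData(object)$length_bp,
                  rownames(object))
}

#' @describeIn ExpressionMatrix per-gene biotypes
#' @export
geneBiotypes <- function(object) {
  stats::setNames(SummarizedExperiment::rowData(object)$biotype,
                  rownames(object))
}

#' @describeIn ExpressionMatrix sample sheet as a plain data.frame
#' @export
sampleSheet <- function(object) {
  cd <- SummarizedExperiment::colData(object)
  out <- data.frame(sample_id = rownames(cd),
                    condition = cd$condition,
                    stringsAsFactors = FALSE)
  if ("pair_id" %in% colnames(cd)) out$pair_id <- cd$pair_id
  out
}

setMethod("show", "ExpressionMatrix", function(object) {
  bt <- table(factor(geneBiotypes(object), levels = VALID_BIOTYPES))
  cnd <- table(factor(SummarizedExperiment::colData(object)$condition,
                      levels = VALID_CONDITIONS))
  cat(sprintf("ExpressionMatrix [%s]: %d genes (%d mRNA, %d lncRNA) x %d samples (%d tumor, %d control)\n",
              object@unit, nrow(object), bt[["mRNA"]], bt[["lncRNA"]],
              ncol(object), cnd[["tumor"]], cnd[["control"]]))
})

#' CeRNANetwork: typed lncRNA-mRNA-miRNA interaction graph
#'
#' An undirected simple graph with typed nodes (lncRNA, mRNA, miRNA) and
#' typed edges: `correlation` edges connect an lncRNA to an mRNA
#' (co-expression support) and `targeting` edges connect a miRNA to the
#' lncRNA or mRNA it is predicted to bind. Validity enforces the type
#' constraints, forbids self-loops and duplicate edges.
#'
#' @slot nodes data.frame with columns `id`, `type`.
#' @slot edges data.frame with columns `from`, `to`, `kind`.
#' @export
setClass("CeRNANetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("CeRNANetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  msg <- character(0)
  if (!all(c("id", "type") %in% colnames(nd)))
    return("nodes needs columns id, type")
  if (!all(c("from", "to", "kind") %in% colnames(ed)))
    return("edges needs columns from, to, kind")
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicate node ids")
  if (nrow(nd) && !all(nd$type %in% NODE_TYPES))
    msg <- c(msg, "node type must be lncRNA, mRNA or miRNA")
  if (nrow(ed)) {
    if (!all(ed$kind %in% EDGE_KINDS))
      msg <- c(msg, "edge kind must be correlation or targeting")
    if (!all(c(ed$from, ed$to) %in% nd$id))
      msg <- c(msg, "edge endpoint not in node table")
    if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    ty <- stats::setNames(nd$type, nd$id)
    corr <- ed$kind == "correlation"
    if (any(corr)) {
      pairs <- cbind(ty[ed$from[corr]], ty[ed$to[corr]])
      ok <- (pairs[, 1] == "lncRNA" & pairs[, 2] == "mRNA") |
            (pairs[, 1] == "mRNA" & pairs[, 2] == "lncRNA")
      if (!all(ok)) msg <- c(msg, "correlation edges must join lncRNA-mRNA")
    }
    tgt <- ed$kind == "targeting"
    if (any(tgt)) {
      pairs <- cbind(ty[ed$from[tgt]], ty[ed$to[tgt]])
      ok <- xor(pairs[, 1] == "miRNA", pairs[, 2] == "miRNA") &
            (pairs[, 1] %in% c("lncRNA", "mRNA") |
             pairs[, 2] %in% c("lncRNA", "mRNA"))
      if (!all(ok)) msg <- c(msg, "targeting edges must join miRNA to lncRNA/mRNA")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CeRNANetwork
#'
#' @param nodes data.frame with columns `id`, `type`
#'   (lncRNA/mRNA/miRNA).
#' @param edges data.frame with columns `from`, `to`, `kind`
#'   (correlation/targeting).
#' @return a [CeRNANetwork-class] object.
#' @export
CeRNANetwork <- function(nodes = data.frame(id = character(0),
                                            type = character(0)),
                         edges = data.frame(from = character(0),
                                            to = character(0),
                                            kind = character(0))) {
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      kind = as.character(edges$kind),
                      stringsAsFactors = FALSE)
  new("CeRNANetwork", nodes = nodes, edges = edges)
}

#' @describeIn CeRNANetwork node table accessor
#' @param object,x a `CeRNANetwork`
#' @export
networkNodes <- function(object) object@nodes

#' @describeIn CeRNANetwork edge table accessor
#' @export
networkEdges <- function(object) object@edges

#' Convert a CeRNANetwork to an igraph graph
#'
#' Nodes keep their `type` attribute, edges their `kind`.
#' @param object a [CeRNANetwork-class]
#' @return an undirected [igraph::igraph] graph.
#' @export
asIgraph <- function(object) {
  stopifnot(is(object, "CeRNANetwork"))
  igraph::graph_from_data_frame(object@edges, directed = FALSE,
                                vertices = object@nodes)
}

setMethod("show", "CeRNANetwork", function(object) {
  nt <- table(factor(object@nodes$type, levels = NODE_TYPES))
  ek <- table(factor(object@edges$kind, levels = EDGE_KINDS))
  cat(sprintf("CeRNANetwork: %d nodes (%d lncRNA, %d mRNA, %d miRNA), %d edges (%d correlation, %d targeting)\n",
              nrow(object@nodes), nt[["lncRNA"]], nt[["mRNA"]], nt[["miRNA"]],
              nrow(object@edges), ek[["correlation"]], ek[["targeting"]]))
})
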