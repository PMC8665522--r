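# lncRNA-mRNA co-expression network: all-pairs Pearson correlation,
# significance filtering, miRNA-target cross-reference and assembly of
# the mRNA-lncRNA-miRNA ceRNA graph.

#' All lncRNA-mRNA Pearson correlation edges
#'
#' Computes, for every (lncRNA, mRNA) pair, the Pearson correlation of
#' `log2(FPKM + 1)` across all samples (tumor and control pooled) and a
#' two-sided p-value from the t transform
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom.
#' Pairs where either gene is constant get `r = NA` and are excluded by
#' [filterCorrelation()].
#'
#' @param object an [ExpressionMatrix-class] with unit `"fpkm"`.
#' @param lncIds,mrnaIds gene ids present in `object`.
#' @return data.frame with `lncrna_id`, `mrna_id`, `r`, `p_value`,
#'   `n_samples`.
#' @export
correlationEdges <- function(object, lncIds, mrnaIds) {
  stopifnot(is(object, "ExpressionMatrix"))
  if (exprUnit(object) != "fpkm")
    stop("correlationEdges expects FPKM values")
  missing <- setdiff(c(lncIds, mrnaIds), rownames(object))
  if (length(missing))
    stop("ids not in matrix: ", paste(utils::head(missing), collapse = ", "))
  n <- ncol(object)
  if (n < 3) stop("need at least 3 samples")
  lg <- log2p1(exprValues(object))
  xl <- t(lg[lncIds, , drop = FALSE])
  xm <- t(lg[mrnaIds, , drop = FALSE])
  sd_l <- apply(xl, 2, stats::sd)
  sd_m <- apply(xm, 2, stats::sd)
  r <- suppressWarnings(stats::cor(xl, xm))
  r[sd_l == 0, ] <- NA
  r[, sd_m == 0] <- NA
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  out <- data.frame(
    lncrna_id = rep(lncIds, times = length(mrnaIds)),
    mrna_id = rep(mrnaIds, each = length(lncIds)),
    r = as.vector(r),
    p_value = as.vector(p),
    n_samples = n,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter correlation edges at the significance and strength thresholds
#'
#' Keeps edges with `p < alpha` and, under the default positive sign
#' mode, `r >= rMin` (inclusive, so an edge exactly at the correlation
#' threshold is kept); `signMode = "absolute"` keeps `|r| >= rMin`.
#' Positive correlation is the default because ceRNA regulation predicts
#' co-expression of the sponge lncRNA and its de-repressed mRNA.
#' Undefined correlations (constant genes) are dropped.
#'
#' @param edges output of [correlationEdges()].
#' @param alpha p-value threshold (default 0.05).
#' @param rMin correlation threshold in (0, 1\] (default 0.6).
#' @param signMode `"positive"` (default) or `"absolute"`.
#' @return the retained rows of `edges`.
#' @export
filterCorrelation <- function(edges, alpha = 0.05, rMin = 0.6,
                              signMode = c("positive", "absolute")) {
  signMode <- match.arg(signMode)
  if (!is.numeric(rMin) || rMin <= 0 || rMin > 1)
    stop("rMin must be in (0, 1]")
  ok <- !is.na(edges$r) & edges$p_value < alpha &
    (if (signMode == "positive") edges$r >= rMin else abs(edges$r) >= rMin)
  out <- edges[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference correlation edges against a miRNA-target table
#'
#' Implements the ceRNA requirement that a correlated lncRNA-mRNA pair
#' be supported by shared miRNAs: an edge is kept iff the set of miRNAs
#' targeting the lncRNA and the set targeting the mRNA intersect in at
#' least `minShared` ids. The shared ids are recorded on the edge.
#'
#' @param edges filtered correlation edges.
#' @param interactions data.frame with `mirna_id`, `target_id` (see
#'   [readInteractions()]).
#' @param minShared minimum number of shared miRNAs (default 1).
#' @param annotateOnly if `TRUE`, record shared miRNAs without dropping
#'   unsupported edges (annotation-only cross-reference).
#' @return `edges` with `shared_mirnas` (semicolon-joined ids) and
#'   `n_shared` columns.
#' @export
crossReference <- function(edges, interactions, minShared = 1,
                           annotateOnly = FALSE) {
  by_target <- split(interactions$mirna_id, interactions$target_id)
  shared <- lapply(seq_len(nrow(edges)), function(i) {
    intersect(by_target[[edges$lncrna_id[i]]] %||% character(0),
              by_target[[edges$mrna_id[i]]] %||% character(0))
  })
  edges$shared_mirnas <- vapply(shared, paste, character(1),
                                collapse = ";")
  edges$n_shared <- lengths(shared)
  if (!annotateOnly)
    edges <- edges[edges$n_shared >= minShared, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Assemble the mRNA-lncRNA-miRNA ceRNA network
#'
#' Nodes are the lncRNAs and mRNAs of the surviving cross-referenced
#' edges plus every miRNA recorded as shared on some edge. Edges are the
#' correlation edges plus targeting edges joining each shared miRNA to
#' both endpoints of its pair; the result is an undirected simple graph.
#'
#' @param edges cross-referenced edges (from [crossReference()]).
#' @return a [CeRNANetwork-class].
#' @export
buildCeRNA <- function(edges) {
  if (nrow(edges) == 0) return(CeRNANetwork())
  shared <- strsplit(edges$shared_mirnas, ";", fixed = TRUE)
  shared <- lapply(shared, function(s) s[nzchar(s)])
  nodes <- rbind(
    data.frame(id = unique(edges$lncrna_id), type = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = unique(edges$mrna_id), type = "mRNA",
               stringsAsFactors = FALSE),
    data.frame(id = unique(unlist(shared)) %||% character(0),
               type = "miRNA", stringsAsFactors = FALSE))
  corr <- data.frame(from = edges$lncrna_id, to = edges$mrna_id,
                     kind = "correlation", stringsAsFactors = FALSE)
  tgt <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
    s <- shared[[i]]
    if (!length(s)) return(NULL)
    data.frame(from = rep(s, 2L),
               to = rep(c(edges$lncrna_id[i], edges$mrna_id[i]),
                        each = length(s)),
               kind = "targeting", stringsAsFactors = FALSE)
  }))
  all_edges <- rbind(corr, tgt)
  key <- paste(pmin(all_edges$from, all_edges$to),
               pmax(all_edges$from, all_edges$to))
  all_edges <- all_edges[!duplicated(key), , drop = FALSE]
  CeRNANetwork(nodes, all_edges)
}

#' Export / import a CeRNANetwork
#'
#' `writeNetworkSIF` writes the Cytoscape-loadable SIF format
#' (`source <kind> target`). `writeNetworkTables` writes an edge-list
#' TSV plus a node-attribute TSV, which `readNetworkTables` reads back
#' into an identical network.
#'
#' @param network a [CeRNANetwork-class].
#' @param path SIF path.
#' @param edgePath,nodePath TSV paths.
#' @export
writeNetworkSIF <- function(network, path) {
  stopifnot(is(network, "CeRNANetwork"))
  ed <- networkEdges(network)
  writeLines(sprintf("%s\t%s\t%s", ed$from, ed$kind, ed$to), path)
  invisible(path)
}

#' @rdname writeNetworkSIF
#' @export
writeNetworkTables <- function(network, edgePath, nodePath) {
  stopifnot(is(network, "CeRNANetwork"))
  utils::write.table(networkEdges(network), edgePath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(networkNodes(network), nodePath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(edgePath)
}

#' @rdname writeNetworkSIF
#' @export
readNetworkTables <- function(edgePath, nodePath) {
  ed <- utils::read.delim(edgePath, stringsAsFactors = FALSE)
  nd <- utils::read.delim(nodePath, stringsAsFactors = FALSE)
  CeRNANetwork(nd, ed)
}
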