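# Centrality analysis and tie-aware TOP-k triple intersection (pivotal
# nodes).

#' Exact node centralities of a ceRNA network
#'
#' Degree (edge count), betweenness (sum over unordered pairs s != t of
#' the fraction of shortest s-t paths through the node, endpoints
#' excluded, unnormalized) and Wasserman-Faust closeness
#' `((reachable - 1) / (n - 1)) * (reachable - 1) / sum(dist)`, the
#' component-scaled form that stays comparable when the graph is
#' disconnected; isolated nodes have closeness 0. All values are exact
#' (full shortest-path computation, no sampling).
#'
#' @param network a [CeRNANetwork-class] or an [igraph::igraph] graph.
#' @param normalized also report betweenness divided by
#'   `(n - 1)(n - 2)/2`.
#' @return data.frame with `node`, `type` (NA for plain igraph input),
#'   `degree`, `betweenness`, `closeness`, ordered as in the node table.
#' @export
centralities <- function(network, normalized = FALSE) {
  if (is(network, "CeRNANetwork")) {
    g <- asIgraph(network)
    types <- stats::setNames(networkNodes(network)$type,
                             networkNodes(network)$id)
  } else if (igraph::is_igraph(network)) {
    g <- network
    types <- stats::setNames(rep(NA_character_, igraph::vcount(network)),
                             igraph::V(network)$name)
  } else stop("network must be a CeRNANetwork or igraph graph")
  n <- igraph::vcount(g)
  if (n == 0)
    return(data.frame(node = character(0), type = character(0),
                      degree = numeric(0), betweenness = numeric(0),
                      closeness = numeric(0)))
  deg <- igraph::degree(g, mode = "all", loops = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  d <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
  out <- data.frame(node = igraph::V(g)$name,
                    type = unname(types[igraph::V(g)$name]),
                    degree = unname(deg), betweenness = unname(btw),
                    closeness = clo, stringsAsFactors = FALSE)
  if (normalized)
    out$betweenness_normalized <-
      if (n > 2) out$betweenness / ((n - 1) * (n - 2) / 2) else 0
  rownames(out) <- NULL
  out
}

#' Tie-inclusive top-k node set for one centrality metric
#'
#' Returns every node whose value is at least the k-th largest value of
#' the metric, so boundary ties are kept (deterministic; the set may
#' exceed `k`).
#'
#' @param report output of [centralities()].
#' @param metric `"degree"`, `"betweenness"` or `"closeness"`.
#' @param k cutoff rank (default 100).
#' @return character vector of node ids.
#' @export
topK <- function(report, metric = c("degree", "betweenness", "closeness"),
                 k = 100) {
  metric <- match.arg(metric)
  if (k < 1) stop("k must be >= 1")
  v <- report[[metric]]
  if (length(v) == 0) return(character(0))
  thr <- sort(v, decreasing = TRUE)[min(k, length(v))]
  report$node[v >= thr]
}

#' Pivotal nodes: the triple top-k intersection
#'
#' Intersects the tie-inclusive top-k sets of degree, betweenness and
#' closeness; nodes in all three are the pivotal nodes. All seven Venn
#' region counts over the three sets are reported.
#'
#' @param report output of [centralities()].
#' @param k cutoff rank per metric (default 100).
#' @return a `PivotalSet` list: `top` (the three sets), `intersection`,
#'   `regions` (named counts `degree_only`, ..., `all_three`, summing to
#'   the union size), `by_type` (intersection members split by node
#'   type), and `k`.
#' @export
pivotalNodes <- function(report, k = 100) {
  tops <- lapply(c(degree = "degree", betweenness = "betweenness",
                   closeness = "closeness"),
                 function(m) topK(report, m, k))
  D <- tops$degree; B <- tops$betweenness; C <- tops$closeness
  inter <- intersect(intersect(D, B), C)
  inD <- function(x) x %in% D
  inB <- function(x) x %in% B
  inC <- function(x) x %in% C
  u <- union(union(D, B), C)
  regions <- c(
    degree_only = sum(inD(u) & !inB(u) & !inC(u)),
    betweenness_only = sum(!inD(u) & inB(u) & !inC(u)),
    closeness_only = sum(!inD(u) & !inB(u) & inC(u)),
    degree_betweenness = sum(inD(u) & inB(u) & !inC(u)),
    degree_closeness = sum(inD(u) & !inB(u) & inC(u)),
    betweenness_closeness = sum(!inD(u) & inB(u) & inC(u)),
    all_three = sum(inD(u) & inB(u) & inC(u)))
  types <- stats::setNames(report$type, report$node)
  by_type <- split(inter, factor(types[inter], levels = NODE_TYPES))
  structure(list(top = tops, intersection = inter, regions = regions,
                 by_type = by_type, k = k),
            class = "PivotalSet")
}

#' @export
print.PivotalSet <- function(x, ...) {
  cat(sprintf("PivotalSet (k = %d): %d pivotal nodes\n", x$k,
              length(x$intersection)))
  for (ty in names(x$by_type))
    if (length(x$by_type[[ty]]))
      cat(sprintf("  %s: %s\n", ty,
                  paste(x$by_type[[ty]], collapse = ", ")))
  invisible(x)
}

#' Write a centrality report / pivotal set to disk
#' @param report centrality data.frame.
#' @param pivotal a `PivotalSet`.
#' @param path output path (TSV for the report, JSON for the set).
#' @export
writeCentralities <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCentralities
#' @export
writePivotalSet <- function(pivotal, path) {
  jsonlite::write_json(
    list(k = pivotal$k, top = pivotal$top,
         intersection = pivotal$intersection,
         regions = as.list(pivotal$regions),
         by_type = pivotal$by_type),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
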