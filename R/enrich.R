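# Over-representation analysis of DE genes with the expression-trend
# z-score.

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: the chance of drawing at least `k`
#' members of a `K`-gene term when `n` DE genes are drawn from a
#' universe of `N` genes.
#'
#' @param k overlap between the DE list and the term.
#' @param K term size within the universe.
#' @param n DE genes within the universe.
#' @param N universe size.
#' @return the p-value; 1 when `k = 0`.
#' @examples
#' hypergeomP(5, 5, 10, 20)  # 3003/184756
#' @export
hypergeomP <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric margins")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene-set collection
#'
#' One-sided hypergeometric test per term, restricted to the universe
#' (by default all genes tested for DE, the standard guard against
#' detection bias). Only terms overlapping the DE list (`k >= 1`) are
#' reported. The expression-trend z-score summarizes the direction of
#' the DE members of a term as `(up - down) / sqrt(up + down)`.
#'
#' @param deTable classified DE table ([classifyDE()]) or a data.frame
#'   with `gene_id` and `status`.
#' @param collection a `GeneSetCollection` (see [readGMT()] /
#'   [simulateGeneSets()]).
#' @param universe character vector of universe gene ids; defaults to
#'   `deTable$gene_id`.
#' @return data.frame with `term_id`, `term_name`, `N`, `K`, `n`, `k`,
#'   `p_value`, `adj_p` (BH across reported terms), `enrichment_score`
#'   (`-log10 p`), `up`, `down`, `z_trend` (NA when no DE member),
#'   sorted by `p_value`.
#' @export
enrichCollection <- function(deTable, collection, universe = NULL) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            all(c("gene_id", "status") %in% colnames(deTable)))
  universe <- unique(universe %||% deTable$gene_id)
  if (length(universe) == 0) stop("empty universe")
  de <- deTable[deTable$status %in% c("up", "down"), , drop = FALSE]
  de <- de[de$gene_id %in% universe, , drop = FALSE]
  status <- stats::setNames(de$status, de$gene_id)
  N <- length(universe)
  n <- nrow(de)
  rows <- lapply(names(collection$sets), function(term) {
    members <- intersect(collection$sets[[term]], universe)
    K <- length(members)
    hits <- intersect(members, de$gene_id)
    k <- length(hits)
    if (k == 0 || K == 0) return(NULL)
    up <- sum(status[hits] == "up")
    down <- sum(status[hits] == "down")
    data.frame(term_id = term,
               term_name = unname(collection$descriptions[term]),
               N = N, K = K, n = n, k = k,
               p_value = hypergeomP(k, K, n, N),
               up = up, down = down,
               z_trend = if (up + down > 0)
                 (up - down) / sqrt(up + down) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), term_name = character(0),
                      N = integer(0), K = integer(0), n = integer(0),
                      k = integer(0), p_value = numeric(0),
                      adj_p = numeric(0), enrichment_score = numeric(0),
                      up = integer(0), down = integer(0),
                      z_trend = numeric(0)))
  out$adj_p <- stats::p.adjust(out$p_value, "BH")
  out$enrichment_score <- -log10(out$p_value)
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "term_name", "N", "K", "n", "k", "p_value",
               "adj_p", "enrichment_score", "up", "down", "z_trend")]
  rownames(out) <- NULL
  out
}

#' Read / write gene-set collections in GMT format
#'
#' Standard tab-separated GMT: one term per line, fields term id,
#' description, then member gene ids.
#'
#' @param path GMT file path.
#' @param collection a `GeneSetCollection`.
#' @return `readGMT` returns a `GeneSetCollection` (list with `sets`, a
#'   named list of gene-id vectors, and `descriptions`); `writeGMT`
#'   returns `path` invisibly.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  descriptions <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L), ids)
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @rdname readGMT
#' @export
writeGMT <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(term) {
    paste(c(term, collection$descriptions[[term]],
            collection$sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
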