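# Independent brute-force oracles used to validate the package's
# implementations, written against the definitions rather than the code
# paths they check.

# --- graph centralities from an adjacency matrix ----------------------

# BFS from source s on adjacency matrix A: shortest-path distances and
# path counts to every node.
bfs_counts <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(A[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Exact degree, betweenness (unordered pairs, endpoints excluded) and
# Wasserman-Faust closeness by explicit path counting.
brute_centralities <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  bfs <- lapply(seq_len(n), function(s) bfs_counts(A, s))
  dist <- do.call(rbind, lapply(bfs, `[[`, "dist"))
  sigma <- do.call(rbind, lapply(bfs, `[[`, "sigma"))
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v) next
        if (!is.finite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t])
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    dv <- dist[v, -v]
    reach <- dv[is.finite(dv)]
    r <- length(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
  list(degree = deg, betweenness = btw, closeness = clo)
}

random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(stats::runif(sum(up)) < p)
  A + t(A)
}

adjacency_to_igraph <- function(A) {
  rownames(A) <- colnames(A) <- paste0("v", seq_len(nrow(A)))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# --- hypergeometric upper tail by direct enumeration ------------------

enum_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- per-pair Pearson correlation via cor.test ------------------------

brute_correlation_edges <- function(lg, lnc_ids, mrna_ids,
                                    alpha = 0.05, r_min = 0.6) {
  kept <- list()
  for (l in lnc_ids) {
    for (m in mrna_ids) {
      x <- lg[l, ]; y <- lg[m, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- stats::cor.test(x, y)
      if (ct$p.value < alpha && unname(ct$estimate) >= r_min)
        kept[[length(kept) + 1]] <- c(l, m)
    }
  }
  if (!length(kept)) return(character(0))
  sort(vapply(kept, paste, character(1), collapse = "|"))
}

# --- shared fixtures --------------------------------------------------

toy_expression <- function(values, unit = "counts",
                           lengths = NULL, biotype = NULL) {
  n <- nrow(values)
  ExpressionMatrix(
    values,
    lengths %||% rep(1000, n),
    biotype %||% rep("mRNA", n),
    data.frame(sample_id = colnames(values),
               condition = rep(c("tumor", "control"),
                               length.out = ncol(values))),
    unit = unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
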