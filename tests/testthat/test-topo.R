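path_graph <- function() {
  CeRNANetwork(
    data.frame(id = c("A", "B", "C"),
               type = c("lncRNA", "mRNA", "lncRNA")),
    data.frame(from = c("A", "C"), to = c("B", "B"),
               kind = "correlation"))
}

star_graph <- function() {
  # hub miRNA targeting 4 genes
  CeRNANetwork(
    data.frame(id = c("h", "a", "b", "c", "d"),
               type = c("miRNA", "mRNA", "mRNA", "lncRNA", "lncRNA")),
    data.frame(from = "h", to = c("a", "b", "c", "d"),
               kind = "targeting"))
}

test_that("centralities on the path A-B-C match hand calculation", {
  ct <- centralities(path_graph())
  b <- ct[ct$node == "B", ]
  expect_equal(b$degree, 2)
  expect_equal(b$betweenness, 1)
  expect_equal(b$closeness, 1)
  a <- ct[ct$node == "A", ]
  expect_equal(a$degree, 1)
  expect_equal(a$betweenness, 0)
  expect_equal(a$closeness, (2 / 2) * (2 / 3))
})

test_that("centralities on the 4-leaf star match hand enumeration", {
  ct <- centralities(star_graph())
  h <- ct[ct$node == "h", ]
  expect_equal(h$degree, 4)
  expect_equal(h$betweenness, 6)   # all 6 leaf pairs route through h
  expect_equal(h$closeness, 1)
  leaf <- ct[ct$node == "a", ]
  expect_equal(leaf$closeness, 4 / 7)
  expect_equal(leaf$betweenness, 0)
})

test_that("disconnected graphs use within-component closeness", {
  net <- CeRNANetwork(
    data.frame(id = c("l1", "m1", "l2", "m2", "iso"),
               type = c("lncRNA", "mRNA", "lncRNA", "mRNA", "miRNA")),
    data.frame(from = c("l1", "l2"), to = c("m1", "m2"),
               kind = "correlation"))
  ct <- centralities(net)
  expect_true(all(ct$betweenness == 0))
  # two disjoint edges: reachable = 1, dist = 1 -> (1/4) * (1/1)
  expect_equal(ct$closeness[ct$node == "l1"], 1 / 4)
  expect_equal(ct$closeness[ct$node == "iso"], 0)
  # empty graph -> empty report
  expect_equal(nrow(centralities(CeRNANetwork())), 0)
})

test_that("centralities equal the brute-force oracle on random graphs", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    A <- random_adjacency(n, 0.4)
    g <- adjacency_to_igraph(A)
    got <- centralities(g)
    want <- brute_centralities(A)
    expect_equal(got$degree, unname(want$degree))
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    expect_true(max(abs(got$closeness - want$closeness)) < 1e-9)
  }
})

test_that("relabeling nodes permutes but does not change centralities", {
  set.seed(5)
  A <- random_adjacency(7, 0.5)
  g1 <- adjacency_to_igraph(A)
  perm <- sample(7)
  A2 <- A[perm, perm]
  g2 <- adjacency_to_igraph(A2)
  c1 <- centralities(g1); c2 <- centralities(g2)
  expect_equal(c2$betweenness, c1$betweenness[perm], tolerance = 1e-12)
  expect_equal(c2$closeness, c1$closeness[perm], tolerance = 1e-12)
  expect_equal(c2$degree, c1$degree[perm])
})

test_that("topK is tie-inclusive at the boundary", {
  rep_ <- data.frame(node = c("a", "b", "c", "d"),
                     type = "mRNA",
                     degree = c(5, 4, 4, 1),
                     betweenness = c(5, 4, 4, 1),
                     closeness = c(0.9, 0.5, 0.5, 0.1))
  expect_setequal(topK(rep_, "degree", 2), c("a", "b", "c"))
  expect_setequal(topK(rep_, "degree", 10), c("a", "b", "c", "d"))
  expect_equal(topK(rep_, "closeness", 1), "a")
  expect_error(topK(rep_, "degree", 0), "k must be")
  # star: hub is top-1 on every metric
  ct <- centralities(star_graph())
  for (m in c("degree", "betweenness", "closeness"))
    expect_equal(topK(ct, m, 1), "h")
})

test_that("pivotalNodes intersects the three top-k sets with Venn counts", {
  # barbell-ish graph: v3-v4 bridge has high betweenness but low degree
  nodes <- data.frame(id = paste0("v", 1:8), type = "mRNA")
  edges <- data.frame(
    from = c("v1", "v1", "v2", "v3", "v4", "v5", "v5", "v6"),
    to   = c("v2", "v3", "v3", "v4", "v5", "v6", "v7", "v7"),
    kind = "correlation")
  nodes$type <- rep(c("lncRNA", "mRNA"), 4)
  # use a plain igraph to avoid type restrictions
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$id)
  ct <- centralities(g)
  ps <- pivotalNodes(ct, k = 2)
  expect_true(all(ps$intersection %in% ct$node))
  expect_true(all(vapply(names(ps$top), function(m)
    all(ps$intersection %in% ps$top[[m]]), logical(1))))
  u <- unique(unlist(ps$top))
  expect_equal(sum(ps$regions), length(u))
  # a node top-1 in all three metrics is pivotal
  star <- centralities(star_graph())
  expect_equal(pivotalNodes(star, 1)$intersection, "h")
  expect_equal(unname(pivotalNodes(star, 1)$regions[["all_three"]]), 1)
})

test_that("a node can lead two metrics yet miss the third", {
  # bridge node: maximal betweenness, low degree
  nodes <- paste0("n", 1:7)
  edges <- data.frame(
    from = c("n1", "n1", "n2", "n4", "n5", "n5", "n6", "n3", "n4"),
    to   = c("n2", "n3", "n3", "n5", "n6", "n7", "n7", "n4", "n6"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  ct <- centralities(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  want <- brute_centralities(A)
  expect_equal(ct$betweenness, want$betweenness, tolerance = 1e-12)
  k <- 1
  ps <- pivotalNodes(ct, k)
  for (v in ps$intersection) {
    expect_true(v %in% topK(ct, "degree", k))
    expect_true(v %in% topK(ct, "betweenness", k))
    expect_true(v %in% topK(ct, "closeness", k))
  }
  # any node in exactly two top-k sets is excluded from the intersection
  two_not_three <- setdiff(
    intersect(topK(ct, "degree", k), topK(ct, "closeness", k)),
    topK(ct, "betweenness", k))
  expect_true(all(!two_not_three %in% ps$intersection))
})

test_that("planted hub lncRNA lands in the pivotal intersection", {
  hits <- vapply(1:5, function(s) {
    cfg <- simConfig(seed = s)
    sim <- simulateExpression(cfg)
    tab <- simulateInteractionTable(cfg, sim$truth)
    fpkm <- computeFPKM(sim$matrix)
    de <- classifyDE(testDifferential(fpkm))
    de_l <- de$gene_id[de$status != "ns" & de$biotype == "lncRNA"]
    de_m <- de$gene_id[de$status != "ns" & de$biotype == "mRNA"]
    net <- buildCeRNA(crossReference(
      filterCorrelation(correlationEdges(fpkm, de_l, de_m)), tab))
    piv <- pivotalNodes(centralities(net), k = 10)
    sim$truth$hub_lncrna_id %in% piv$intersection
  }, logical(1))
  expect_true(all(hits))
})
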