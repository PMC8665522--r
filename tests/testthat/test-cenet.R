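corr_fixture <- function(n_lnc = 5, n_mrna = 45, n_samp = 12,
                         seed = 101) {
  set.seed(seed)
  ids <- c(sprintf("L%02d", seq_len(n_lnc)),
           sprintf("M%02d", seq_len(n_mrna)))
  v <- matrix(rlnorm(length(ids) * n_samp, 4, 1.2), length(ids), n_samp,
              dimnames = list(ids, c(paste0("T", 1:(n_samp / 2)),
                                     paste0("N", 1:(n_samp / 2)))))
  ExpressionMatrix(
    v, rep(1000, length(ids)),
    rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna)),
    data.frame(sample_id = colnames(v),
               condition = rep(c("tumor", "control"), each = n_samp / 2)),
    unit = "fpkm")
}

test_that("perfect affine correlation gives r = 1, tiny p", {
  em <- corr_fixture(n_lnc = 1, n_mrna = 2)
  v <- exprValues(em)
  lg <- log2(v + 1)
  v["M01", ] <- 2^(3 * lg["L01", ] + 1) - 1  # exact positive affine in log space
  em2 <- ExpressionMatrix(v, geneLengths(em), geneBiotypes(em),
                          sampleSheet(em), unit = "fpkm")
  ed <- correlationEdges(em2, "L01", c("M01", "M02"))
  row <- ed[ed$mrna_id == "M01", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_lt(row$p_value, 1e-10)
})

test_that("t-transform p-values match the boundary cases r=0.6 at n=6 and n=12", {
  p_of <- function(r, n) {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(-abs(tt), n - 2)
  }
  expect_equal(p_of(0.6, 6), 0.208, tolerance = 5e-3)
  expect_equal(p_of(0.6, 12), 0.039, tolerance = 5e-3)
  expect_gt(p_of(0.6, 6), 0.05)   # dropped at n = 6
  expect_lt(p_of(0.6, 12), 0.05)  # kept at n = 12
  # and the implementation reproduces the transform on real data
  em <- corr_fixture()
  ed <- correlationEdges(em, sprintf("L%02d", 1:5), sprintf("M%02d", 1:5))
  ct <- cor.test(log2(exprValues(em)["L01", ] + 1),
                 log2(exprValues(em)["M03", ] + 1))
  row <- ed[ed$lncrna_id == "L01" & ed$mrna_id == "M03", ]
  expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(row$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("filterCorrelation applies thresholds with inclusive r boundary", {
  ed <- data.frame(lncrna_id = "l", mrna_id = paste0("m", 1:5),
                   r = c(0.95, 0.60, -0.95, 0.59, 0.7),
                   p_value = c(0.001, 0.039, 0.001, 0.01, 0.2),
                   n_samples = 12)
  kept <- filterCorrelation(ed)
  expect_setequal(kept$mrna_id, c("m1", "m2"))  # r>=0.6 inclusive, p<0.05
  kept_abs <- filterCorrelation(ed, signMode = "absolute")
  expect_setequal(kept_abs$mrna_id, c("m1", "m2", "m3"))
  expect_error(filterCorrelation(ed, rMin = 0), "rMin")
  # NA r (constant gene) is dropped
  ed$r[1] <- NA
  expect_false("m1" %in% filterCorrelation(ed)$mrna_id)
})

test_that("filtered edges equal a brute-force cor.test recomputation (50x12)", {
  em <- corr_fixture(n_lnc = 5, n_mrna = 45, seed = 300)
  # plant a few strong pairs so the kept set is nonempty
  v <- exprValues(em)
  lg <- log2(v + 1)
  for (i in 1:3)
    v[sprintf("M%02d", i), ] <-
      2^(lg[sprintf("L%02d", i), ] +
           rnorm(12, 0, 0.15)) - 1
  em <- ExpressionMatrix(pmax(v, 0), geneLengths(em), geneBiotypes(em),
                         sampleSheet(em), unit = "fpkm")
  lnc <- sprintf("L%02d", 1:5); mrna <- sprintf("M%02d", 1:45)
  kept <- filterCorrelation(correlationEdges(em, lnc, mrna))
  got <- sort(paste(kept$lncrna_id, kept$mrna_id, sep = "|"))
  want <- brute_correlation_edges(log2(exprValues(em) + 1), lnc, mrna)
  expect_identical(got, want)
  expect_gt(length(want), 0)
})

test_that("correlation edges are invariant to sample order and to affine maps", {
  em <- corr_fixture(seed = 12)
  lnc <- sprintf("L%02d", 1:5); mrna <- sprintf("M%02d", 1:10)
  e1 <- correlationEdges(em, lnc, mrna)
  perm <- sample(ncol(em))
  e2 <- correlationEdges(em[, perm], lnc, mrna)
  expect_equal(e1$r, e2$r, tolerance = 1e-12)
  expect_equal(e1$p_value, e2$p_value, tolerance = 1e-12)
})

test_that("cross-reference keeps edges with enough shared miRNAs", {
  edges <- data.frame(lncrna_id = c("l1", "l1"),
                      mrna_id = c("m1", "m2"),
                      r = 0.9, p_value = 0.001, n_samples = 12)
  tab <- data.frame(
    mirna_id = c("mi1", "mi2", "mi3", "mi1", "mi2", "mi3", "mi9"),
    target_id = c("l1", "l1", "l1", "m1", "m1", "m1", "m2"),
    target_biotype = c("lncRNA", "lncRNA", "lncRNA",
                       "mRNA", "mRNA", "mRNA", "mRNA"))
  out <- crossReference(edges, tab, minShared = 1)
  expect_equal(out$mrna_id, "m1")
  expect_equal(out$n_shared, 3)
  expect_setequal(strsplit(out$shared_mirnas, ";")[[1]],
                  c("mi1", "mi2", "mi3"))
  # annotate-only keeps the unsupported edge
  out2 <- crossReference(edges, tab, annotateOnly = TRUE)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$n_shared, c(3, 0))
  # empty table -> empty output
  empty <- tab[0, ]
  expect_equal(nrow(crossReference(edges, empty)), 0)
  # monotone in min_shared
  expect_gte(nrow(crossReference(edges, tab, 1)),
             nrow(crossReference(edges, tab, 4)))
})

test_that("buildCeRNA assembles the typed graph with correct counts", {
  edges <- data.frame(lncrna_id = "l1", mrna_id = "m1", r = 0.9,
                      p_value = 0.001, n_samples = 12,
                      shared_mirnas = "mi1;mi2", n_shared = 2)
  net <- buildCeRNA(edges)
  expect_equal(nrow(networkNodes(net)), 4)
  ek <- table(networkEdges(net)$kind)
  expect_equal(unname(ek[["correlation"]]), 1)
  expect_equal(unname(ek[["targeting"]]), 4)
  # no surviving edges -> empty network
  empty <- buildCeRNA(edges[0, ])
  expect_equal(nrow(networkNodes(empty)), 0)
  # export / import round trip
  ep <- tempfile(); np <- tempfile()
  writeNetworkTables(net, ep, np)
  back <- readNetworkTables(ep, np)
  expect_equal(networkNodes(back), networkNodes(net))
  expect_equal(networkEdges(back), networkEdges(net))
  sif <- tempfile(fileext = ".sif")
  writeNetworkSIF(net, sif)
  expect_equal(length(readLines(sif)), 5)
})

test_that("CeRNANetwork validity enforces edge typing", {
  nodes <- data.frame(id = c("l", "m", "mi"),
                      type = c("lncRNA", "mRNA", "miRNA"))
  bad_corr <- data.frame(from = "mi", to = "m", kind = "correlation")
  expect_error(CeRNANetwork(nodes, bad_corr), "lncRNA-mRNA")
  bad_loop <- data.frame(from = "l", to = "l", kind = "correlation")
  expect_error(CeRNANetwork(nodes, bad_loop), "self-loops")
  dup <- data.frame(from = c("l", "m"), to = c("m", "l"),
                    kind = "correlation")
  expect_error(CeRNANetwork(nodes, dup), "duplicate")
})

test_that("planted hub-module edges survive the full edge pipeline", {
  survived <- vapply(1:5, function(s) {
    cfg <- simConfig(n_mrna = 200, n_lncrna = 80, module_size = 5,
                     seed = s)
    sim <- simulateExpression(cfg)
    tab <- simulateInteractionTable(cfg, sim$truth)
    fpkm <- computeFPKM(sim$matrix)
    de <- classifyDE(testDifferential(fpkm))
    de_l <- de$gene_id[de$status != "ns" & de$biotype == "lncRNA"]
    de_m <- de$gene_id[de$status != "ns" & de$biotype == "mRNA"]
    kept <- filterCorrelation(correlationEdges(fpkm, de_l, de_m))
    xr <- crossReference(kept, tab)
    hub_edges <- xr[xr$lncrna_id == sim$truth$hub_lncrna_id, ]
    # most hub-module pairs survive; unsupported background pairs are rare
    mean(sim$truth$module_mrna_ids %in% hub_edges$mrna_id) >= 0.6 &&
      nrow(xr) < nrow(kept)
  }, logical(1))
  expect_gte(mean(survived), 0.8)
})
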