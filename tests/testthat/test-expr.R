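test_that("FPKM formula matches direct arithmetic", {
  # one gene with counts 100, length 2000 bp, in a column totalling 1e6
  v <- matrix(c(100, 999900), 2, 1,
              dimnames = list(c("g1", "g2"), "s1"))
  em <- toy_expression(v, lengths = c(2000, 1000))
  f <- exprValues(computeFPKM(em))
  expect_equal(unname(f["g1", "s1"]), 100 * 1e9 / (1e6 * 2000))
  expect_equal(unname(f["g1", "s1"]), 50)
})

test_that("zero counts give zero FPKM and doubling a column changes nothing", {
  set.seed(42)
  v <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  v[1, ] <- 0
  em <- toy_expression(v, lengths = sample(500:5000, 10))
  f1 <- exprValues(computeFPKM(em))
  expect_true(all(f1[1, ] == 0))
  v2 <- v; v2[, 2] <- v[, 2] * 2
  em2 <- toy_expression(v2, lengths = geneLengths(em))
  f2 <- exprValues(computeFPKM(em2))
  expect_equal(f2[, 2], f1[, 2])
})

test_that("FPKM columns satisfy the conservation identity", {
  set.seed(7)
  v <- matrix(rpois(60, 200), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  em <- toy_expression(v, lengths = sample(200:10000, 12))
  f <- computeFPKM(em)
  sums <- colSums(exprValues(f) * geneLengths(f))
  expect_equal(sums, setNames(rep(1e9, 5), colnames(v)),
               tolerance = 1e-6)
})

test_that("computeFPKM is permutation-equivariant and rejects bad input", {
  set.seed(8)
  v <- matrix(rpois(24, 100), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  em <- toy_expression(v, lengths = sample(300:3000, 6))
  f <- computeFPKM(em)
  pg <- sample(6); ps <- sample(4)
  fp <- computeFPKM(em[pg, ps])
  expect_equal(exprValues(fp), exprValues(f)[pg, ps])
  # empty sample
  v0 <- v; v0[, 1] <- 0
  expect_error(computeFPKM(toy_expression(v0)), "zero column sum")
  # wrong unit
  expect_error(computeFPKM(f), "counts")
})

test_that("filterExpressed keeps genes above threshold and preserves order", {
  v <- matrix(1, 10, 3, dimnames = list(paste0("g", 1:10),
                                        paste0("s", 1:3)))
  v[4, ] <- 0.01  # below threshold everywhere
  em <- toy_expression(v, unit = "fpkm")
  kept <- filterExpressed(em, minFpkm = 0.1, minSamples = 1)
  expect_equal(nrow(kept), 9)
  expect_equal(rownames(kept), rownames(v)[-4])
  # identity at zero threshold
  expect_equal(nrow(filterExpressed(em, 0, 1)), 10)
  # all-zero gene removed
  v[4, ] <- 0
  expect_false("g4" %in%
                 rownames(filterExpressed(toy_expression(v, unit = "fpkm"),
                                          0.1, 1)))
  expect_error(filterExpressed(em, 0.1, minSamples = 10), "minSamples")
})

test_that("expression TSV round trip is lossless, including unit and pairs", {
  set.seed(11)
  v <- matrix(rpois(24, 80), 6, 4,
              dimnames = list(paste0("g", 1:6),
                              c("T1", "T2", "N1", "N2")))
  ss <- data.frame(sample_id = colnames(v),
                   condition = c("tumor", "tumor", "control", "control"),
                   pair_id = c("P1", "P2", "P1", "P2"))
  em <- ExpressionMatrix(v, sample(200:10000, 6),
                         rep(c("mRNA", "lncRNA"), 3), ss)
  path <- tempfile(fileext = ".tsv")
  writeExpression(em, path)
  back <- readExpression(path)
  expect_equal(exprValues(back), exprValues(em))
  expect_equal(geneLengths(back), geneLengths(em))
  expect_equal(geneBiotypes(back), geneBiotypes(em))
  expect_equal(exprUnit(back), "counts")
  expect_equal(sampleSheet(back), sampleSheet(em))
})

test_that("expression reader rejects duplicate genes, handles empty matrices", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# unit: counts",
               "gene_id\tlength_bp\tbiotype\ts1",
               "g1\t1000\tmRNA\t5",
               "g1\t1000\tmRNA\t7"), path)
  sp <- sub("\\.tsv$", "_samples.tsv", path)
  writeLines(c("sample_id\tcondition", "s1\ttumor"), sp)
  expect_error(readExpression(path), "duplicated gene")

  # 0-gene matrix round trips
  v <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("s1", "s2")))
  em <- ExpressionMatrix(v, numeric(0), character(0),
                         data.frame(sample_id = c("s1", "s2"),
                                    condition = c("tumor", "control")))
  p2 <- tempfile(fileext = ".tsv")
  writeExpression(em, p2)
  back <- readExpression(p2)
  expect_equal(nrow(back), 0)
  expect_equal(colnames(back), c("s1", "s2"))
})

test_that("ExpressionMatrix validity catches malformed objects", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  ss <- data.frame(sample_id = c("s1", "s2"),
                   condition = c("tumor", "control"))
  expect_error(ExpressionMatrix(v, c(1000, -5), c("mRNA", "mRNA"), ss),
               "positive")
  expect_error(ExpressionMatrix(v, c(1000, 500), c("mRNA", "rRNA"), ss),
               "biotype")
  ss_bad <- data.frame(sample_id = c("s1", "s2"),
                       condition = c("tumor", "sick"))
  expect_error(ExpressionMatrix(v, c(1000, 500), c("mRNA", "mRNA"),
                                ss_bad), "condition")
})

test_that("logTransform maps zeros to zero and tags the unit", {
  v <- matrix(c(0, 3), 1, 2, dimnames = list("g", c("s1", "s2")))
  lt <- logTransform(toy_expression(v, unit = "fpkm"))
  expect_equal(exprUnit(lt), "log2fpkm")
  expect_equal(unname(exprValues(lt)[1, ]), c(0, 2))
})
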