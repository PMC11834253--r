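test_that("edge list reading applies the strict score filter and derives nodes from surviving edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.9", "B\tA\t0.9", "A\tA\t1.0", "B\tC\t0.4"), f)
  net <- read_edge_list(f, score_threshold = 0.5)
  expect_equal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(unlist(net$edges[1, ], use.names = FALSE), c("A", "B"))

  # no threshold: pass-through with dedup and node universe from edges
  writeLines(c("A\tB", "B\tC"), f)
  net2 <- read_edge_list(f)
  expect_equal(net2$nodes, c("A", "B", "C"))
  expect_equal(nrow(net2$edges), 2)

  # retention is strictly greater-than: a score equal to the cutoff is dropped
  writeLines("A\tB\t0.5", f)
  net3 <- read_edge_list(f, score_threshold = 0.5)
  expect_equal(length(net3$nodes), 0)
  expect_equal(nrow(net3$edges), 0)
})

test_that("edge list errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tB\t0.9", "oops"), f)
  expect_error(read_edge_list(f), "line 3")
  writeLines(c("A\tB\t0.9", "C\tD"), f)
  expect_error(read_edge_list(f, score_threshold = 0.5), "no score column")
  writeLines(c("A\tB\tx"), f)
  expect_error(read_edge_list(f, score_threshold = 0.5), "non-numeric")
})

test_that("feature table reading validates shape, duplicates and cell values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  full <- matrix(rnorm(3 * 64), 3, 64,
                 dimnames = list(c("A", "B", "C"), gefdriver:::full_feature_grid()))
  write_feature_table(full, f)
  x <- read_feature_table(f, strict = TRUE)
  expect_equal(dim(x), c(3, 64))
  expect_equal(x, full, tolerance = 1e-12)

  two <- full[, c("MF_BLCA", "MF_BRCA")]
  write_feature_table(two, f)
  expect_equal(dim(read_feature_table(f)), c(3, 2))
  expect_error(read_feature_table(f, strict = TRUE), "64-column")

  writeLines(c("gene\tMF_BLCA", "A\t1.0", "A\t2.0"), f)
  expect_error(read_feature_table(f), "duplicate gene row 'A'")
  writeLines(c("gene\tMF_BLCA\tMF_BRCA", "A\t1.0\tbad"), f)
  expect_error(read_feature_table(f), "gene A.*MF_BRCA")
})

test_that("subset_omics restricts to the requested blocks and keeps order", {
  full <- matrix(0, 2, 64, dimnames = list(c("A", "B"), gefdriver:::full_feature_grid()))
  expect_equal(ncol(subset_omics(full, "MF")), 16)
  expect_equal(ncol(subset_omics(full, c("MF", "METH"))), 32)
  expect_identical(subset_omics(full, c("MF", "METH", "GE", "CNA")), full)
  expect_true(all(startsWith(colnames(subset_omics(full, "GE")), "GE_")))
  expect_error(subset_omics(full, character()), "non-empty")
  expect_error(subset_omics(full, "XX"), "unknown omics")
})

test_that("dataset assembly aligns features and labels to the network", {
  net <- gene_network(cbind(c("A", "B"), c("B", "C")))
  x <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("MF_BLCA", "GE_BLCA")))
  ds <- assemble_dataset(net, x, label_catalog("A", "B"))
  expect_equal(as.character(ds$y), c("positive", "negative", "unlabeled"))
  expect_equal(rownames(ds$features), c("A", "B", "C"))

  # genes only in the table are dropped; network genes missing from the table
  # get zero rows with a warning
  net2 <- gene_network(cbind("A", "B"))
  x2 <- rbind(x, Z = c(9, 9))
  ds2 <- assemble_dataset(net2, x2, label_catalog("A", "B"))
  expect_equal(dim(ds2$features), c(2, 2))
  net3 <- gene_network(cbind(c("A", "B"), c("B", "D")))
  expect_warning(ds3 <- assemble_dataset(net3, x, label_catalog("A", "B")),
                 "zero-imputed")
  expect_equal(unname(ds3$features["D", ]), c(0, 0))

  expect_error(assemble_dataset(net2, x, label_catalog("Q", "R")),
               "untrainable")
})

test_that("labels cannot be both positive and negative", {
  expect_error(label_catalog(c("A", "B"), c("B", "C")), "both positive and negative")
})

test_that("write/read round-trips reproduce networks, tables, lists and rankings", {
  withr::local_seed(11)
  g <- random_graph(12, 0.3)
  f <- withr::local_tempfile()
  write_edge_list(g$net, f)
  # the edge-list format carries no isolated nodes, so compare against the
  # edge-derived network
  expect_equal(read_edge_list(f, name = g$net$name),
               gene_network(as.matrix(g$net$edges), name = g$net$name))

  x <- matrix(rnorm(8), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), c("MF_BLCA", "GE_BLCA")))
  write_feature_table(x, f)
  expect_equal(read_feature_table(f), x, tolerance = 1e-12)

  write_gene_list(c("TP53", "KRAS"), f)
  expect_equal(read_gene_list(f), c("TP53", "KRAS"))

  r <- rank_genes(c(a = 0.9, b = 0.4, c = 0.7), network = "net1")
  write_ranking(r, f)
  r2 <- read_ranking(f, network = "net1")
  expect_equal(r2$gene, r$gene)
  expect_equal(r2$probability, r$probability, tolerance = 1e-12)
})

test_that("dataset snapshots are exact and deterministic", {
  withr::local_seed(7)
  ds <- random_dataset()
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_dataset(ds, f1)
  back <- read_dataset(f1)
  expect_equal(back$network, ds$network)
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_equal(back$y, ds$y)
  write_dataset(ds, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("z-score utility centers and scales columns, constant columns to zero", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5))
  z <- zscore_columns(x)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(sd(z[, "a"]), 1)
  expect_true(all(z[, "b"] == 0))
})
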