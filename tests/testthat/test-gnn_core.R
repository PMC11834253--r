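test_that("normalized adjacency matches hand-computed values", {
  # single node, no edges: just the self-loop
  n1 <- gene_network(NULL, nodes = "A")
  expect_equal(as.matrix(normalize_adjacency(n1)),
               matrix(1, 1, 1, dimnames = list("A", "A")))

  # two nodes, one edge: degrees 2 after self-loops, all entries 1/2
  n2 <- gene_network(cbind("A", "B"))
  expect_equal(unname(as.matrix(normalize_adjacency(n2))),
               matrix(0.5, 2, 2))

  # path A-B-C: degrees 2, 3, 2 after self-loops
  n3 <- gene_network(cbind(c("A", "B"), c("B", "C")))
  m <- as.matrix(normalize_adjacency(n3))
  expect_equal(m["A", "A"], 1 / 2)
  expect_equal(m["A", "B"], 1 / sqrt(6))
  expect_equal(m["B", "B"], 1 / 3)
  expect_equal(m["B", "C"], 1 / sqrt(6))
  expect_equal(m["C", "C"], 1 / 2)
  expect_equal(m["A", "C"], 0)
})

test_that("normalized adjacency is symmetric and equals (A+I)/(k+1) on regular graphs", {
  withr::local_seed(1)
  for (rep in 1:5) {
    g <- random_graph(12, 0.4)
    m <- as.matrix(normalize_adjacency(g$net))
    expect_equal(m, t(m), tolerance = 1e-14)
    expect_equal(m, dense_normalize(g$a), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # a 4-cycle is 2-regular: every entry of A+I divided by 3
  cyc <- gene_network(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")))
  a <- as.matrix(adjacency_matrix(cyc))
  expect_equal(as.matrix(normalize_adjacency(cyc)), (a + diag(4)) / 3,
               tolerance = 1e-14)
})

test_that("graph convolution layer matches hand examples and rejects bad dims", {
  iso <- gene_network(NULL, nodes = "A")
  adjn <- normalize_adjacency(iso)
  expect_equal(gcn_layer_forward(adjn, matrix(c(1, 0), 1, 2), diag(2)),
               matrix(c(1, 0), 1, 2), ignore_attr = TRUE)

  pair <- normalize_adjacency(gene_network(cbind("A", "B")))
  expect_equal(gcn_layer_forward(pair, matrix(c(1, 0), 2, 1), matrix(1)),
               matrix(c(0.5, 0.5), 2, 1), ignore_attr = TRUE)
  # negative pre-activations are clipped by the ReLU
  expect_equal(gcn_layer_forward(pair, matrix(c(1, 0), 2, 1), matrix(-1)),
               matrix(0, 2, 1), ignore_attr = TRUE)

  expect_error(gcn_layer_forward(pair, matrix(0, 2, 3), matrix(0, 2, 1)),
               "dimension mismatch")
  expect_error(gcn_layer_forward(pair, matrix(0, 3, 2), matrix(0, 2, 1)),
               "rows")
})

test_that("attention weights normalize per neighborhood and handle degenerate logits", {
  withr::local_seed(2)
  h <- matrix(rnorm(8), 4, 2)
  w <- matrix(rnorm(6), 2, 3)
  a <- rnorm(6)

  # single-member neighborhood: softmax of one logit is 1
  al1 <- gat_attention_weights(h, w, a, list(1L, c(1L, 2L), 3:4, 4L))
  expect_equal(al1[1, 1], 1)

  # identical transformed features: equal split
  h_same <- matrix(1, 4, 2)
  al2 <- gat_attention_weights(h_same, w, a, list(c(2L, 3L), 1:2, 3:4, 3:4))
  expect_equal(al2[1, 2], 0.5)
  expect_equal(al2[1, 3], 0.5)

  # zero attention vector: exactly uniform over the neighborhood
  al3 <- gat_attention_weights(h, w, rep(0, 6), list(1:4, 1:4, 1:4, 1:4))
  expect_true(all(as.matrix(al3) == 0.25))

  expect_error(gat_attention_weights(h, w, a, list(1L, integer(), 3L, 4L)),
               "empty neighborhood")
  expect_error(gat_attention_weights(h, w, a[1:4], list(1L, 2L, 3L, 4L)),
               "attention vector")
})

test_that("attention layer matches single-neighbor and duplicated-head limits", {
  withr::local_seed(3)
  h <- matrix(rnorm(6), 3, 2)
  # K=1, node 1 attends only to node 2 (no self), W identity: output is h_2
  head1 <- list(W = diag(2), a = rnorm(4))
  nb <- list(2L, c(2L, 3L), c(1L, 3L))
  out <- gat_layer_forward(h, list(head1), nb, aggregation = "mean")
  expect_equal(out[1, ], h[2, ])

  # two identical heads under mean aggregation equal the single head
  out2 <- gat_layer_forward(h, list(head1, head1), nb, aggregation = "mean")
  expect_equal(out2, out)

  # concat stacks the head outputs side by side
  out3 <- gat_layer_forward(h, list(head1, head1), nb, aggregation = "concat")
  expect_equal(out3, cbind(out, out))

  heads_mixed <- list(head1, list(W = matrix(rnorm(6), 2, 3), a = rnorm(6)))
  expect_error(gat_layer_forward(h, heads_mixed, nb, aggregation = "mean"),
               "equal per-head")
})

test_that("both graph layers agree with dense brute-force references on random graphs", {
  withr::local_seed(4)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    g <- random_graph(n, runif(1, 0.15, 0.5))
    h <- matrix(rnorm(n * 3), n, 3)
    w <- matrix(rnorm(12), 3, 4)
    expect_equal(gcn_layer_forward(normalize_adjacency(g$net), h, w),
                 dense_gcn(g$a, h, w), tolerance = 1e-10, ignore_attr = TRUE)

    nb <- neighborhoods_of(g$a)
    heads <- lapply(1:2, function(k) list(W = matrix(rnorm(12), 3, 4), a = rnorm(8)))
    for (agg in c("concat", "mean")) {
      expect_equal(gat_layer_forward(h, heads, nb, aggregation = agg),
                   dense_gat(h, heads, nb, aggregation = agg),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("embedding concatenation keeps the convolution block first", {
  expect_equal(concat_embeddings(matrix(1:2, 1), matrix(3, 1)),
               matrix(c(1, 2, 3), 1))
  z <- concat_embeddings(matrix(0, 3, 16), matrix(0, 3, 16))
  expect_equal(dim(z), c(3, 32))
  expect_true(all(z == 0))
  expect_error(concat_embeddings(matrix(0, 2, 4), matrix(0, 3, 4)), "rows")
})

test_that("full forward pass is deterministic, in (0,1), and 0.5 at zero weights", {
  withr::local_seed(5)
  ds <- random_dataset()
  mc <- tiny_config(seed = 1)
  set.seed(1)
  params <- gef_init_params(ncol(ds$features), mc)
  p1 <- gef_forward(ds, params)
  p2 <- gef_forward(ds, params)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_equal(names(p1), ds$network$nodes)

  zero <- lapply(params, function(x) x * 0)
  attributes(zero) <- attributes(params)
  expect_true(all(gef_forward(ds, zero) == 0.5))
})

test_that("full forward pass equals the step-by-step composition of the public layers", {
  withr::local_seed(6)
  ds <- random_dataset(n = 10, p = 0.4)
  mc <- tiny_config(seed = 2)
  set.seed(2)
  params <- gef_init_params(ncol(ds$features), mc)

  adjn <- normalize_adjacency(ds$network)
  x <- ds$features
  h <- gcn_layer_forward(adjn, x, params$gcn.W1)
  h <- gcn_layer_forward(adjn, h, params$gcn.W2)
  e_gcn <- gcn_layer_forward(adjn, h, params$gcn.W3, sigma = function(z) z)

  nb <- neighborhoods_of(as.matrix(adjacency_matrix(ds$network)))
  heads <- lapply(seq_len(mc$gat_heads_hidden), function(k) {
    list(W = params[[sprintf("gat.h%d.W", k)]], a = params[[sprintf("gat.h%d.a", k)]])
  })
  hcat <- gat_layer_forward(x, heads, nb, aggregation = "concat",
                            sigma = gefdriver:::elu)
  e_gat <- gat_layer_forward(hcat, list(list(W = params$gat.o1.W, a = params$gat.o1.a)),
                             nb, aggregation = "mean")
  gef <- concat_embeddings(e_gcn, e_gat)
  hm <- pmax(sweep(gef %*% params$mlp.W1, 2, params$mlp.b1, "+"), 0)
  logits <- as.vector(hm %*% params$mlp.W2) + params$mlp.b2
  expected <- 1 / (1 + exp(-logits))

  expect_equal(unname(gef_forward(ds, params)), expected, tolerance = 1e-10)
})

test_that("forward pass is permutation-equivariant", {
  withr::local_seed(7)
  ds <- random_dataset(n = 10, p = 0.4)
  mc <- tiny_config(seed = 3)
  set.seed(3)
  params <- gef_init_params(ncol(ds$features), mc)
  p_orig <- gef_forward(ds, params)

  # relabel nodes so the sorted order changes, then rebuild the dataset
  relabel <- setNames(sprintf("z%02d", sample(10)), ds$network$nodes)
  edges2 <- cbind(relabel[ds$network$edges$gene_a], relabel[ds$network$edges$gene_b])
  net2 <- gene_network(edges2, nodes = unname(relabel))
  x2 <- ds$features
  rownames(x2) <- relabel[rownames(x2)]
  labs2 <- label_catalog(relabel[ds$y == "positive"], relabel[ds$y == "negative"])
  ds2 <- assemble_dataset(net2, x2, labs2)
  p_perm <- gef_forward(ds2, params)
  expect_equal(p_perm[relabel[names(p_orig)]], setNames(p_orig, relabel[names(p_orig)]),
               tolerance = 1e-12)
})

test_that("checkpoints reproduce parameters and inference", {
  withr::local_seed(8)
  ds <- random_dataset()
  mc <- tiny_config(seed = 4)
  set.seed(4)
  params <- gef_init_params(ncol(ds$features), mc)
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(params, f, seed = 4)
  back <- read_checkpoint(f)
  expect_equal(unclass(back)[names(params)], unclass(params)[names(params)],
               tolerance = 1e-15)
  expect_equal(gef_forward(ds, back), gef_forward(ds, params), tolerance = 1e-15)
})
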