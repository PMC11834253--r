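# Independent brute-force reference implementations and fixture builders.
# The oracles here are deliberately written in the most literal form of the
# defining equations (dense loops) and share no code with the package paths
# they check.

# Dense symmetric normalization: D^(-1/2) (A + I) D^(-1/2).
dense_normalize <- function(a) {
  a <- as.matrix(a)
  at <- a + diag(nrow(a))
  d <- rowSums(at)
  diag(1 / sqrt(d)) %*% at %*% diag(1 / sqrt(d))
}

# Dense single-layer graph convolution.
dense_gcn <- function(a, h, w, sigma = function(x) pmax(x, 0)) {
  sigma(dense_normalize(a) %*% h %*% w)
}

# Dense multi-head attention layer, looping explicitly over node pairs:
# logits e_ij = LeakyReLU(a . [W h_i, W h_j]), per-neighborhood softmax,
# aggregation sum_j alpha_ij W h_j; heads concatenated or averaged.
dense_gat <- function(h, heads, neighborhood, aggregation = "concat",
                      sigma = identity, slope = 0.2) {
  n <- nrow(h)
  outs <- lapply(heads, function(head) {
    w <- head$W
    fp <- ncol(w)
    z <- h %*% w
    out <- matrix(0, n, fp)
    for (i in seq_len(n)) {
      js <- neighborhood[[i]]
      e <- numeric(length(js))
      for (t in seq_along(js)) {
        v <- sum(head$a * c(z[i, ], z[js[t], ]))
        e[t] <- if (v > 0) v else slope * v
      }
      al <- exp(e - max(e))
      al <- al / sum(al)
      for (t in seq_along(js)) out[i, ] <- out[i, ] + al[t] * z[js[t], ]
    }
    out
  })
  res <- if (aggregation == "mean") {
    Reduce(`+`, outs) / length(outs)
  } else {
    do.call(cbind, outs)
  }
  sigma(res)
}

# Dense attention weights for one head (same loop, returns the alpha matrix).
dense_gat_alpha <- function(h, w, a, neighborhood, slope = 0.2) {
  n <- nrow(h)
  z <- h %*% w
  al <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- neighborhood[[i]]
    e <- numeric(length(js))
    for (t in seq_along(js)) {
      v <- sum(a * c(z[i, ], z[js[t], ]))
      e[t] <- if (v > 0) v else slope * v
    }
    ex <- exp(e - max(e))
    al[i, js] <- ex / sum(ex)
  }
  al
}

# Exhaustive pairwise AUROC: wins + half-ties over all pos x neg pairs.
pairwise_auroc <- function(y, s) {
  sp <- s[y == 1]; sn <- s[y == 0]
  cmp <- outer(sp, sn, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct confusion-table metrics from the defining formulas.
direct_metrics <- function(tp, tn, fp, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(
    ACC = (tp + tn) / (tp + fp + tn + fn),
    F1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
    MCC = {
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den > 0) (tp * tn - fp * fn) / den else 0
    })
}

# Random Erdos-Renyi fixture: returns the symmetric 0/1 adjacency and the
# corresponding gene_network (node labels n01, n02, ...).
random_graph <- function(n, p) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  labels <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  net <- gene_network(cbind(labels[idx[, 1]], labels[idx[, 2]]), nodes = labels)
  dimnames(a) <- list(labels, labels)
  list(a = a, net = net)
}

# Neighborhoods (self included) from a 0/1 adjacency.
neighborhoods_of <- function(a) {
  lapply(seq_len(nrow(a)), function(i) sort(unique(c(i, which(a[i, ] > 0)))))
}

# Two disconnected 10-cliques with opposite constant features; labels follow
# the cliques. Linearly separable: any sane configuration must solve it.
clique_fixture <- function(d = 4) {
  labels <- sprintf("g%02d", 1:20)
  edges <- NULL
  for (block in list(1:10, 11:20)) {
    pairs <- t(combn(block, 2))
    edges <- rbind(edges, cbind(labels[pairs[, 1]], labels[pairs[, 2]]))
  }
  net <- gene_network(edges, nodes = labels)
  x <- rbind(matrix(1, 10, d), matrix(-1, 10, d))
  rownames(x) <- labels
  colnames(x) <- sprintf("MF_%s", c("BLCA", "BRCA", "CESC", "COAD")[seq_len(d)])
  labs <- label_catalog(labels[1:10], labels[11:20])
  assemble_dataset(net, x, labs)
}

# Small trained-free dataset on a random graph with random features.
random_dataset <- function(n = 10, p = 0.35, d = 6, n_pos = 3, n_neg = 4) {
  g <- random_graph(n, p)
  x <- matrix(rnorm(n * d), n, d, dimnames = list(g$net$nodes, sprintf("MF_%02d", 1:d)))
  labs <- label_catalog(g$net$nodes[seq_len(n_pos)],
                        g$net$nodes[n_pos + seq_len(n_neg)])
  assemble_dataset(g$net, x, labs)
}

# Tiny architecture for fast training/forward tests.
tiny_config <- function(...) {
  model_config(gcn_dims = c(8, 6, 4), gat_hidden_dim = 3, gat_heads_hidden = 2,
               gat_out_dim = 4, mlp_hidden = 4, ...)
}

# Full pipeline on one synthetic study: train every network with repeated CV
# and return per-network results plus the planted truth.
run_synthetic_pipeline <- function(seed, syn_args = list(), mc_args = list()) {
  syn <- do.call(synthetic_config, c(list(seed = seed), syn_args))
  nets <- generate_network_ensemble(syn)
  feats <- generate_features(syn)
  labs <- generate_labels(syn)
  mc <- do.call(model_config, c(list(seed = seed), mc_args))
  cvs <- lapply(nets, function(nw) {
    ds <- assemble_dataset(nw, feats, labs)
    run_cross_validation(ds, mc)
  })
  rankings <- lapply(cvs, function(cv) rank_genes(cv$probs, network = cv$network))
  list(config = syn, cvs = cvs, rankings = rankings,
       drivers = synthetic_drivers(syn), labels = labs)
}

# Mean test AUROC over all folds of all networks of a pipeline run.
pipeline_mean_auroc <- function(run) {
  mean(vapply(run$cvs, function(cv) unname(cv$metrics_mean["AUROC"]), 0))
}
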