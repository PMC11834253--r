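# The two graph layers (spectral convolution and multi-head attention), the
# graph-enhanced embedding concatenation, and the MLP head, as pure forward
# computations given explicit weights.

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` for the undirected adjacency A of the
#' network, the propagation operator of the graph convolution. Self-loops
#' guarantee every diagonal entry is positive, so isolated nodes are allowed.
#'
#' @param network a [gene_network()], or a square symmetric (sparse or dense)
#'   adjacency matrix without self-loops.
#' @return sparse symmetric matrix (`Matrix::dgCMatrix`) with node dimnames.
#' @export
normalize_adjacency <- function(network) {
  a <- if (inherits(network, "gene_network")) adjacency_matrix(network) else {
    m <- methods::as(methods::as(Matrix::Matrix(network, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    assert_that(nrow(m) == ncol(m), "adjacency must be square")
    m
  }
  n <- nrow(a)
  at <- a + Matrix::Diagonal(n)
  d <- Matrix::rowSums(at)
  s <- 1 / sqrt(d)
  out <- methods::as(Matrix::Diagonal(n, s) %*% at %*% Matrix::Diagonal(n, s),
                     "CsparseMatrix")
  dimnames(out) <- dimnames(a)
  out
}

#' Sparse adjacency matrix of a gene network (no self-loops)
#' @param network a [gene_network()].
#' @return sparse symmetric 0/1 matrix with node dimnames.
#' @export
adjacency_matrix <- function(network) {
  n <- length(network$nodes)
  i <- match(network$edges$gene_a, network$nodes)
  j <- match(network$edges$gene_b, network$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(1, 2 * length(i)),
                       dims = c(n, n),
                       dimnames = list(network$nodes, network$nodes))
}

#' One graph-convolution layer
#'
#' Applies the layer rule `sigma(D^(-1/2) (A+I) D^(-1/2) H W)`.
#'
#' @param adj_norm normalized adjacency from [normalize_adjacency()].
#' @param h node feature matrix, |V| rows.
#' @param w weight matrix, `ncol(h)` rows.
#' @param sigma element-wise nonlinearity (default ReLU).
#' @return |V| x `ncol(w)` matrix.
#' @export
gcn_layer_forward <- function(adj_norm, h, w, sigma = relu) {
  h <- as.matrix(h); w <- as.matrix(w)
  assert_that(nrow(h) == nrow(adj_norm),
              "h has %d rows but the graph has %d nodes", nrow(h), nrow(adj_norm))
  assert_that(ncol(h) == nrow(w),
              "dimension mismatch: h has %d columns, w has %d rows",
              ncol(h), nrow(w))
  sigma(as.matrix(adj_norm %*% (h %*% w)))
}

# ---- edge-index machinery ---------------------------------------------------
# Attention is computed over a directed edge list (i attends to j), sorted by
# the attending node i so per-node reductions are contiguous segment
# operations. The structure is built once per graph and reused across heads
# and epochs:
#   ei, ej   : endpoints of each directed edge, self-loops included
#   groups   : list, edge positions grouped by attending node i
#   ends_i   : last edge position of each i-segment (for cumsum reductions)
#   perm_j / ends_j : the same grouping for the neighbor side
#   template / csc_perm : sparse pattern of the attention matrix plus the
#     permutation from edge order to its CSC slot order
edge_index <- function(adjacency, self_loops = TRUE) {
  n <- nrow(adjacency)
  t <- methods::as(methods::as(adjacency, "generalMatrix"), "TsparseMatrix")
  ei <- t@i + 1L
  ej <- t@j + 1L
  keep <- ei != ej
  ei <- ei[keep]; ej <- ej[keep]
  if (self_loops) {
    ei <- c(ei, seq_len(n)); ej <- c(ej, seq_len(n))
  }
  o <- order(ei, ej, method = "radix")
  build_edge_index(n, ei[o], ej[o])
}

edge_index_from_neighborhood <- function(neighborhood) {
  n <- length(neighborhood)
  sizes <- lengths(neighborhood)
  empty <- which(sizes == 0)
  assert_that(length(empty) == 0, "empty neighborhood for node %d",
              if (length(empty)) empty[1] else 0L)
  ei <- rep(seq_len(n), sizes)
  ej <- as.integer(unlist(neighborhood, use.names = FALSE))
  build_edge_index(n, ei, ej)
}

build_edge_index <- function(n, ei, ej) {
  sizes_i <- tabulate(ei, nbins = n)
  s0 <- Matrix::sparseMatrix(i = ei, j = ej, x = as.double(seq_along(ei)),
                             dims = c(n, n))
  list(n = n, ei = as.integer(ei), ej = as.integer(ej),
       ends_i = as.integer(cumsum(sizes_i)),
       template = s0, csc_perm = as.integer(s0@x))
}

# Core attention computation for one head on a prepared edge index (compiled
# kernel). Returns alpha, the raw edge logits, and the aggregated output
# sum_j alpha_ij z_j.
attention_head <- function(z, a_src, a_dst, eidx, negative_slope) {
  res <- .att_forward_cpp(z, a_src, a_dst, eidx$ei, eidx$ej, eidx$ends_i,
                          negative_slope)
  res$alpha <- as.vector(res$alpha)
  res$pre <- as.vector(res$pre)
  res
}

# alpha edge vector -> sparse n x n matrix (row i = attention of node i).
# Reuses the precomputed CSC pattern; only the value slot is replaced.
alpha_matrix <- function(alpha, eidx) {
  am <- eidx$template
  am@x <- alpha[eidx$csc_perm]
  am
}

#' Attention coefficients of one graph-attention head
#'
#' For each node i and neighbor j, computes the logit
#' `e_ij = LeakyReLU(a^T [W h_i || W h_j])` and normalizes per neighborhood
#' with a softmax, so that `sum_j alpha_ij = 1`.
#'
#' @param h node feature matrix (|V| x F).
#' @param w head weight matrix (F x F').
#' @param a attention vector of length 2F' (first half scores the attending
#'   node, second half the neighbor).
#' @param neighborhood list of integer vectors: `neighborhood[[i]]` are the
#'   nodes j that i attends to (conventionally including i itself).
#' @param negative_slope LeakyReLU slope for negative logits.
#' @return sparse |V| x |V| matrix of attention weights; each row sums to 1
#'   over the node's neighborhood.
#' @export
gat_attention_weights <- function(h, w, a, neighborhood, negative_slope = 0.2) {
  h <- as.matrix(h); w <- as.matrix(w)
  fp <- ncol(w)
  assert_that(length(a) == 2 * fp,
              "attention vector has length %d, expected 2 x %d", length(a), fp)
  eidx <- edge_index_from_neighborhood(neighborhood)
  assert_that(nrow(h) == eidx$n, "h rows must match neighborhood length")
  z <- h %*% w
  att <- attention_head(z, a[seq_len(fp)], a[fp + seq_len(fp)], eidx,
                        negative_slope)
  alpha_matrix(att$alpha, eidx)
}

#' One multi-head graph-attention layer
#'
#' Each head k transforms features with its own `W^k`, computes attention
#' weights over the neighborhoods, and aggregates
#' `sum_j alpha_ij^k W^k h_j`. Heads are combined either by concatenation
#' (hidden layers) or by the mean over heads (output layer), then passed
#' through `sigma`.
#'
#' @param h node feature matrix.
#' @param heads list of heads, each a list with elements `W` and `a`.
#' @param neighborhood list of neighbor index vectors (see
#'   [gat_attention_weights()]).
#' @param aggregation `"concat"` or `"mean"`.
#' @param sigma element-wise nonlinearity (default identity).
#' @param negative_slope LeakyReLU slope.
#' @return |V| x (K F') matrix for concat, |V| x F' for mean.
#' @export
gat_layer_forward <- function(h, heads, neighborhood,
                              aggregation = c("concat", "mean"),
                              sigma = identity_fn, negative_slope = 0.2) {
  aggregation <- match.arg(aggregation)
  assert_that(length(heads) >= 1, "heads must be non-empty")
  h <- as.matrix(h)
  eidx <- edge_index_from_neighborhood(neighborhood)
  outs <- lapply(heads, function(head) {
    w <- as.matrix(head$W)
    fp <- ncol(w)
    z <- h %*% w
    attention_head(z, head$a[seq_len(fp)], head$a[fp + seq_len(fp)],
                   eidx, negative_slope)$out
  })
  if (aggregation == "mean") {
    dims <- vapply(outs, ncol, 0L)
    assert_that(length(unique(dims)) == 1,
                "mean aggregation requires equal per-head output dims")
    out <- Reduce(`+`, outs) / length(outs)
  } else {
    out <- do.call(cbind, outs)
  }
  sigma(out)
}

#' Concatenate the two graph embeddings into the graph-enhanced feature
#'
#' Column-binds the spectral-convolution embedding (first block) and the
#' attention embedding (second block), giving one 32-dimensional vector per
#' gene under the default 16+16 configuration.
#'
#' @param gcn_out,gat_out matrices with equal row counts.
#' @return row-aligned matrix with `ncol(gcn_out) + ncol(gat_out)` columns.
#' @export
concat_embeddings <- function(gcn_out, gat_out) {
  assert_that(nrow(gcn_out) == nrow(gat_out),
              "embeddings have %d and %d rows", nrow(gcn_out), nrow(gat_out))
  cbind(gcn_out, gat_out)
}

# ---- full model -------------------------------------------------------------

#' Initialize model parameters
#'
#' Glorot-uniform initialization of every weight matrix and attention vector,
#' using the current RNG state (seed it for reproducibility). The architecture
#' follows `config`: a 3-layer graph convolution stack (`gcn_dims`), one
#' multi-head attention hidden layer plus a single-head attention output
#' layer, and an MLP head on the concatenated embedding.
#'
#' @param d_in input feature dimension.
#' @param config a [model_config()].
#' @return parameter list of class `gef_params`.
#' @export
gef_init_params <- function(d_in, config = model_config()) {
  branches <- config$branches
  p <- list()
  if (branches %in% c("both", "gcn")) {
    dims <- c(d_in, config$gcn_dims)
    for (l in seq_len(length(dims) - 1)) {
      p[[paste0("gcn.W", l)]] <- glorot(dims[l], dims[l + 1])
    }
  }
  if (branches %in% c("both", "gat")) {
    fh <- config$gat_hidden_dim
    for (k in seq_len(config$gat_heads_hidden)) {
      p[[sprintf("gat.h%d.W", k)]] <- glorot(d_in, fh)
      p[[sprintf("gat.h%d.a", k)]] <- as.vector(glorot(2 * fh, 1))
    }
    d_cat <- fh * config$gat_heads_hidden
    fo <- config$gat_out_dim
    for (k in seq_len(config$gat_heads_out)) {
      p[[sprintf("gat.o%d.W", k)]] <- glorot(d_cat, fo)
      p[[sprintf("gat.o%d.a", k)]] <- as.vector(glorot(2 * fo, 1))
    }
  }
  d_emb <- switch(branches,
                  both = config$gcn_dims[length(config$gcn_dims)] + config$gat_out_dim,
                  gcn = config$gcn_dims[length(config$gcn_dims)],
                  gat = config$gat_out_dim)
  p[["mlp.W1"]] <- glorot(d_emb, config$mlp_hidden)
  p[["mlp.b1"]] <- numeric(config$mlp_hidden)
  p[["mlp.W2"]] <- glorot(config$mlp_hidden, 1)
  p[["mlp.b2"]] <- numeric(1)
  structure(p, class = "gef_params", config = config, d_in = d_in)
}

# Forward pass over prepared graph operators. `drop` is NULL at inference or a
# list of inverted-dropout masks (one per learned-layer input) in training.
# With keep_cache = TRUE every intermediate needed by the backward pass is
# returned.
gef_forward_impl <- function(x, adj_norm, eidx, params, config,
                             drop = NULL, keep_cache = FALSE) {
  branches <- config$branches
  slope <- config$negative_slope
  cache <- list()
  dm <- function(nm, mat) if (is.null(drop)) mat else mat * drop[[nm]]

  e_gcn <- NULL
  if (branches %in% c("both", "gcn")) {
    n_layers <- length(config$gcn_dims)
    hcur <- x
    for (l in seq_len(n_layers)) {
      hin <- dm(paste0("gcn", l), hcur)
      z <- as.matrix(adj_norm %*% (hin %*% params[[paste0("gcn.W", l)]]))
      hcur <- if (l < n_layers) relu(z) else z  # linear output embedding
      if (keep_cache) {
        cache[[paste0("gcn.in", l)]] <- hin
        cache[[paste0("gcn.z", l)]] <- z
      }
    }
    e_gcn <- hcur
  }

  e_gat <- NULL
  if (branches %in% c("both", "gat")) {
    xg <- dm("gat_in", x)
    if (keep_cache) cache[["gat.in"]] <- xg
    outs <- vector("list", config$gat_heads_hidden)
    for (k in seq_len(config$gat_heads_hidden)) {
      w <- params[[sprintf("gat.h%d.W", k)]]
      a <- params[[sprintf("gat.h%d.a", k)]]
      fp <- ncol(w)
      z <- xg %*% w
      att <- attention_head(z, a[seq_len(fp)], a[fp + seq_len(fp)], eidx, slope)
      outs[[k]] <- att$out
      if (keep_cache) {
        cache[[sprintf("gat.h%d.z", k)]] <- z
        cache[[sprintf("gat.h%d.alpha", k)]] <- att$alpha
        cache[[sprintf("gat.h%d.pre", k)]] <- att$pre
      }
    }
    hcat_pre <- do.call(cbind, outs)
    hcat <- elu(hcat_pre)
    if (keep_cache) cache[["gat.hcat_pre"]] <- hcat_pre
    hd <- dm("gat_out_in", hcat)
    if (keep_cache) cache[["gat.out_in"]] <- hd
    # output attention layer: mean over K_out heads, linear activation
    k_out <- config$gat_heads_out
    e_gat <- 0
    for (k in seq_len(k_out)) {
      w <- params[[sprintf("gat.o%d.W", k)]]
      a <- params[[sprintf("gat.o%d.a", k)]]
      fp <- ncol(w)
      z <- hd %*% w
      att <- attention_head(z, a[seq_len(fp)], a[fp + seq_len(fp)], eidx, slope)
      e_gat <- e_gat + att$out / k_out
      if (keep_cache) {
        cache[[sprintf("gat.o%d.z", k)]] <- z
        cache[[sprintf("gat.o%d.alpha", k)]] <- att$alpha
        cache[[sprintf("gat.o%d.pre", k)]] <- att$pre
      }
    }
  }

  gef <- switch(branches,
                both = concat_embeddings(e_gcn, e_gat),
                gcn = e_gcn,
                gat = e_gat)
  m <- dm("mlp1", gef)
  a1 <- sweep(m %*% params[["mlp.W1"]], 2, params[["mlp.b1"]], "+")
  h1 <- relu(a1)
  h1d <- dm("mlp2", h1)
  logits <- as.vector(h1d %*% params[["mlp.W2"]]) + params[["mlp.b2"]]
  probs <- sigmoid(logits)
  if (keep_cache) {
    cache[["gef"]] <- gef
    cache[["mlp.in1"]] <- m
    cache[["mlp.a1"]] <- a1
    cache[["mlp.in2"]] <- h1d
    cache[["logits"]] <- logits
  }
  list(probs = probs, cache = cache)
}

#' Full forward pass: per-gene driver probabilities
#'
#' Runs both graph branches on the dataset, concatenates the embeddings and
#' applies the MLP head, returning one probability in (0, 1) per node
#' (labeled and unlabeled alike). Inference is deterministic: no dropout.
#'
#' @param dataset an [assemble_dataset()] result.
#' @param params a [gef_init_params()] parameter set.
#' @param config the [model_config()] describing the architecture; defaults to
#'   the config the parameters were initialized with.
#' @return named numeric vector of probabilities, one per gene.
#' @export
gef_forward <- function(dataset, params, config = attr(params, "config")) {
  adj <- adjacency_matrix(dataset$network)
  adjn <- normalize_adjacency(dataset$network)
  eidx <- edge_index(adj)
  out <- gef_forward_impl(dataset$features, adjn, eidx, params, config)
  stats::setNames(out$probs, dataset$network$nodes)
}

#' Serialize model parameters to a single JSON checkpoint
#' @param params a `gef_params` object.
#' @param path output path.
#' @param seed optional RNG seed to record.
#' @export
write_checkpoint <- function(params, path, seed = NULL) {
  config <- attr(params, "config")
  obj <- list(
    d_in = attr(params, "d_in"),
    seed = seed,
    config = unclass(config),
    shapes = lapply(params, function(p) if (is.matrix(p)) dim(p) else length(p)),
    values = lapply(params, as.vector)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a checkpoint written by [write_checkpoint()]
#' @param path checkpoint path.
#' @return a `gef_params` object (the config is re-attached).
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(model_config, obj$config)
  p <- lapply(names(obj$values), function(nm) {
    v <- as.numeric(obj$values[[nm]])
    shp <- obj$shapes[[nm]]
    if (length(shp) == 2) matrix(v, shp[1], shp[2]) else v
  })
  names(p) <- names(obj$values)
  structure(p, class = "gef_params", config = config, d_in = obj$d_in)
}
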