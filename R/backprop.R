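# Hand-derived reverse-mode gradients for the full model (graph convolution
# stack, multi-head attention stack, MLP head) and the Adam optimizer.
# Gradients with respect to the input features are never needed and are not
# computed.

# Backward through one attention head.
#   z     : transformed features W h (n x F')
#   alpha : edge attention weights, pre: edge logits before LeakyReLU
#   g     : gradient at the head output (n x F')
#   hin   : the head's input features (n x F)
# Returns gradients for W, a = [a_src; a_dst], and (optionally) the input.
attention_head_backward <- function(z, alpha, pre, eidx, a_src, a_dst, g, hin,
                                    w, slope, need_dh = FALSE) {
  res <- .att_backward_cpp(z, alpha, pre, g, eidx$ei, eidx$ej, eidx$ends_i,
                           a_src, a_dst, slope, hin, w, need_dh)
  res$da <- as.vector(res$da)
  res
}

# Full backward pass. `dlogits` is the loss gradient at the MLP logits.
# `drop` holds the same inverted-dropout masks used in the forward pass.
gef_backward <- function(x, adj_norm, eidx, params, config, cache, drop,
                         dlogits) {
  branches <- config$branches
  slope <- config$negative_slope
  g <- list()
  dmask <- function(nm, mat) if (is.null(drop)) mat else mat * drop[[nm]]

  # MLP head
  g[["mlp.W2"]] <- crossprod(cache[["mlp.in2"]], dlogits)
  g[["mlp.b2"]] <- sum(dlogits)
  dh1 <- dmask("mlp2", dlogits %o% params[["mlp.W2"]][, 1])
  da1 <- dh1 * (cache[["mlp.a1"]] > 0)
  g[["mlp.W1"]] <- crossprod(cache[["mlp.in1"]], da1)
  g[["mlp.b1"]] <- colSums(da1)
  dgef <- dmask("mlp1", da1 %*% t(params[["mlp.W1"]]))

  if (branches == "both") {
    d_gcn <- config$gcn_dims[length(config$gcn_dims)]
    de_gcn <- dgef[, seq_len(d_gcn), drop = FALSE]
    de_gat <- dgef[, -seq_len(d_gcn), drop = FALSE]
  } else if (branches == "gcn") {
    de_gcn <- dgef; de_gat <- NULL
  } else {
    de_gcn <- NULL; de_gat <- dgef
  }

  if (!is.null(de_gcn)) {
    n_layers <- length(config$gcn_dims)
    delta <- de_gcn                                      # output layer is linear
    for (l in rev(seq_len(n_layers))) {
      du <- as.matrix(adj_norm %*% delta)                # adj_norm is symmetric
      g[[paste0("gcn.W", l)]] <- crossprod(cache[[paste0("gcn.in", l)]], du)
      if (l > 1) {
        dh <- dmask(paste0("gcn", l),
                    du %*% t(params[[paste0("gcn.W", l)]]))
        delta <- dh * (cache[[paste0("gcn.z", l - 1)]] > 0)
      }
    }
  }

  if (!is.null(de_gat)) {
    k_out <- config$gat_heads_out
    hd <- cache[["gat.out_in"]]
    dhd <- 0
    for (k in seq_len(k_out)) {
      w <- params[[sprintf("gat.o%d.W", k)]]
      a <- params[[sprintf("gat.o%d.a", k)]]
      fp <- ncol(w)
      bk <- attention_head_backward(
        cache[[sprintf("gat.o%d.z", k)]], cache[[sprintf("gat.o%d.alpha", k)]],
        cache[[sprintf("gat.o%d.pre", k)]], eidx,
        a[seq_len(fp)], a[fp + seq_len(fp)], de_gat / k_out, hd, w, slope,
        need_dh = TRUE)
      g[[sprintf("gat.o%d.W", k)]] <- bk$dW
      g[[sprintf("gat.o%d.a", k)]] <- bk$da
      dhd <- dhd + bk$dH
    }
    hcat_pre <- cache[["gat.hcat_pre"]]
    dhcat <- dmask("gat_out_in", dhd) * elu_grad(hcat_pre)
    xg <- cache[["gat.in"]]
    fh <- config$gat_hidden_dim
    for (k in seq_len(config$gat_heads_hidden)) {
      cols <- (k - 1) * fh + seq_len(fh)
      a <- params[[sprintf("gat.h%d.a", k)]]
      bk <- attention_head_backward(
        cache[[sprintf("gat.h%d.z", k)]], cache[[sprintf("gat.h%d.alpha", k)]],
        cache[[sprintf("gat.h%d.pre", k)]], eidx,
        a[seq_len(fh)], a[fh + seq_len(fh)],
        dhcat[, cols, drop = FALSE], xg,
        params[[sprintf("gat.h%d.W", k)]], slope)
      g[[sprintf("gat.h%d.W", k)]] <- bk$dW
      g[[sprintf("gat.h%d.a", k)]] <- bk$da
    }
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step with decoupled-from-nothing classic L2 weight decay folded
# into the gradient (the convention of torch-style Adam with weight_decay).
adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Inverted-dropout masks for the inputs of every learned layer.
make_dropout_masks <- function(n, d_in, config, rate) {
  if (rate <= 0) return(NULL)
  shapes <- list()
  if (config$branches %in% c("both", "gcn")) {
    dims <- c(d_in, config$gcn_dims)
    for (l in seq_along(config$gcn_dims)) {
      shapes[[paste0("gcn", l)]] <- dims[l]
    }
  }
  if (config$branches %in% c("both", "gat")) {
    shapes[["gat_in"]] <- d_in
    shapes[["gat_out_in"]] <- config$gat_hidden_dim * config$gat_heads_hidden
  }
  d_emb <- switch(config$branches,
                  both = config$gcn_dims[length(config$gcn_dims)] + config$gat_out_dim,
                  gcn = config$gcn_dims[length(config$gcn_dims)],
                  gat = config$gat_out_dim)
  shapes[["mlp1"]] <- d_emb
  shapes[["mlp2"]] <- config$mlp_hidden
  lapply(shapes, function(d) {
    m <- (runif(n * d) >= rate) / (1 - rate)
    dim(m) <- c(n, d)
    m
  })
}
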