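# Semi-supervised training on the labeled subset of one network:
# class-weighted cross-entropy, stratified splits, repeated cross-validation,
# early stopping on validation loss, and probabilities for every gene.

#' Model and training configuration
#'
#' Defaults reproduce the reference protocol: a 3-layer graph convolution
#' stack with hidden sizes 300 and 100 and a 16-dimensional output embedding;
#' one attention hidden layer of per-head dimension 100 with 5 heads plus a
#' single-head 16-dimensional attention output layer; an MLP with one hidden
#' layer of 16 units; Adam with learning rate 1e-3 and weight decay 5e-4;
#' dropout 0.5; at most 2000 epochs with early stopping on validation loss
#' (patience 100); ten cross-validation repeats of a stratified 75/25
#' train/test split.
#'
#' @param gcn_dims convolution stack output dims per layer.
#' @param gat_hidden_dim per-head dim of the attention hidden layer.
#' @param gat_heads_hidden,gat_heads_out head counts (hidden layer heads are
#'   concatenated; output layer heads are averaged).
#' @param gat_out_dim attention output embedding dim.
#' @param mlp_hidden MLP hidden layer width.
#' @param learning_rate,weight_decay Adam settings.
#' @param dropout dropout rate on the input of every learned layer (training
#'   only).
#' @param max_epochs,patience training length and early-stopping patience (in
#'   epochs without validation improvement).
#' @param seed master RNG seed; drives splits, initialization and dropout.
#' @param cv_folds number of cross-validation repeats.
#' @param test_fraction held-out test fraction of the labeled genes.
#' @param val_fraction fraction of the train portion held out for early
#'   stopping.
#' @param split_scheme `"repeated_holdout"` (default: `cv_folds` seeded
#'   repeats of a stratified 75/25 split) or `"kfold"` (classic partition
#'   into `cv_folds` stratified folds).
#' @param branches `"both"` (default), `"gcn"` or `"gat"`: which graph
#'   branches feed the MLP (single-branch variants for ablation).
#' @param engine `"cpp"` (default, compiled training loop) or `"reference"`
#'   (the pure-R loop; identical numerics, used for cross-checking).
#' @param negative_slope LeakyReLU slope inside the attention logits.
#' @param threshold decision threshold for ACC/F1/MCC reporting.
#' @return list of class `model_config`.
#' @export
model_config <- function(gcn_dims = c(300, 100, 16),
                         gat_hidden_dim = 100,
                         gat_heads_hidden = 5,
                         gat_heads_out = 1,
                         gat_out_dim = 16,
                         mlp_hidden = 16,
                         learning_rate = 1e-3,
                         weight_decay = 5e-4,
                         dropout = 0.5,
                         max_epochs = 2000,
                         patience = 100,
                         seed = 1,
                         cv_folds = 10,
                         test_fraction = 0.25,
                         val_fraction = 0.1,
                         split_scheme = c("repeated_holdout", "kfold"),
                         branches = c("both", "gcn", "gat"),
                         engine = c("cpp", "reference"),
                         negative_slope = 0.2,
                         threshold = 0.5) {
  split_scheme <- match.arg(split_scheme)
  branches <- match.arg(branches)
  engine <- match.arg(engine)
  assert_that(all(gcn_dims > 0) && gat_hidden_dim > 0 && gat_out_dim > 0 &&
                mlp_hidden > 0 && gat_heads_hidden > 0 && gat_heads_out > 0,
              "all layer dimensions and head counts must be positive")
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must lie in (0, 1)")
  assert_that(max_epochs >= 1 && patience >= 1,
              "max_epochs and patience must be positive")
  structure(list(
    gcn_dims = gcn_dims, gat_hidden_dim = gat_hidden_dim,
    gat_heads_hidden = gat_heads_hidden, gat_heads_out = gat_heads_out,
    gat_out_dim = gat_out_dim, mlp_hidden = mlp_hidden,
    learning_rate = learning_rate, weight_decay = weight_decay,
    dropout = dropout, max_epochs = max_epochs, patience = patience,
    seed = seed, cv_folds = cv_folds, test_fraction = test_fraction,
    val_fraction = val_fraction, split_scheme = split_scheme,
    branches = branches, engine = engine,
    negative_slope = negative_slope,
    threshold = threshold), class = "model_config")
}

#' Positive-class weight from label counts
#'
#' The loss weight `c` applied to positive genes is the negative:positive
#' ratio rounded half-up (e.g. 2187 negatives / 796 positives gives c = 3),
#' never below 1.
#'
#' @param n_pos,n_neg labeled gene counts per class (both >= 1).
#' @return integer weight.
#' @export
compute_class_weight <- function(n_pos, n_neg) {
  assert_that(n_pos >= 1 && n_neg >= 1,
              "both classes need at least one labeled gene")
  max(1, floor(n_neg / n_pos + 0.5))
}

#' Class-weighted binary cross-entropy over a node mask
#'
#' Mean over the masked nodes of `-(c y log p + (1 - y) log(1 - p))`, with
#' probabilities clipped away from 0 and 1 for numerical safety.
#'
#' @param probs probability vector in (0, 1).
#' @param y binary labels (0/1) aligned to `probs`.
#' @param c positive-class weight.
#' @param mask integer indices or logical vector selecting at least one node.
#' @return scalar loss.
#' @export
weighted_bce_loss <- function(probs, y, c = 1, mask = seq_along(probs)) {
  if (is.logical(mask)) mask <- which(mask)
  assert_that(length(mask) >= 1, "mask selects no nodes")
  p <- pmin(pmax(probs[mask], 1e-12), 1 - 1e-12)
  yy <- y[mask]
  -mean(c * yy * log(p) + (1 - yy) * log(1 - p))
}

# Stratified sample of size round(frac * n) per class, at least 1.
strat_take <- function(idx_by_class, frac) {
  lapply(idx_by_class, function(idx) {
    k <- max(1, round(frac * length(idx)))
    idx[seq_len(k)]
  })
}

#' Build the cross-validation split plan
#'
#' Under the default `repeated_holdout` scheme each of the `cv_folds` repeats
#' draws a fresh seeded stratified shuffle of the labeled genes, assigns 25%
#' per class to the test set, and holds out `val_fraction` of the remaining
#' train portion (per class) as the validation set for early stopping. The
#' `kfold` scheme instead partitions the labeled genes into `cv_folds`
#' stratified folds and uses each in turn as the test set.
#'
#' @param y per-node labels (factor with levels positive/negative/unlabeled),
#'   e.g. `dataset$y`.
#' @param config a [model_config()].
#' @return object of class `split_plan`: a list of repeats, each with integer
#'   node-index vectors `train`, `val`, `test` (disjoint; their union is the
#'   labeled set).
#' @export
make_splits <- function(y, config = model_config()) {
  pos <- which(y == "positive")
  neg <- which(y == "negative")
  assert_that(length(pos) >= config$cv_folds && length(neg) >= config$cv_folds,
              "too few labeled nodes: %d positive / %d negative for %d folds",
              length(pos), length(neg), config$cv_folds)
  folds <- vector("list", config$cv_folds)
  if (config$split_scheme == "kfold") {
    set.seed(derive_seed(config$seed, 1))
    pos_f <- sample(rep_len(seq_len(config$cv_folds), length(pos)))
    neg_f <- sample(rep_len(seq_len(config$cv_folds), length(neg)))
    for (r in seq_len(config$cv_folds)) {
      test <- c(pos[pos_f == r], neg[neg_f == r])
      rest_pos <- pos[pos_f != r]; rest_neg <- neg[neg_f != r]
      set.seed(derive_seed(config$seed, 100 + r))
      rest_pos <- sample(rest_pos); rest_neg <- sample(rest_neg)
      val <- unlist(strat_take(list(rest_pos, rest_neg), config$val_fraction))
      train <- setdiff(c(rest_pos, rest_neg), val)
      folds[[r]] <- list(train = sort(train), val = sort(val),
                         test = sort(test), index = r)
    }
  } else {
    for (r in seq_len(config$cv_folds)) {
      set.seed(derive_seed(config$seed, 100 + r))
      p <- sample(pos); n <- sample(neg)
      tst <- strat_take(list(p, n), config$test_fraction)
      test <- c(tst[[1]], tst[[2]])
      rest_pos <- setdiff(p, test); rest_neg <- setdiff(n, test)
      val <- unlist(strat_take(list(rest_pos, rest_neg), config$val_fraction))
      train <- setdiff(c(rest_pos, rest_neg), val)
      folds[[r]] <- list(train = sort(train), val = sort(val),
                         test = sort(test), index = r)
    }
  }
  structure(folds, class = "split_plan", seed = config$seed,
            scheme = config$split_scheme)
}

# Graph operators shared across folds of one dataset.
graph_operators <- function(dataset) {
  adj <- adjacency_matrix(dataset$network)
  list(adj_norm = normalize_adjacency(dataset$network),
       eidx = edge_index(adj))
}

#' Train the model on one cross-validation repeat
#'
#' Optimizes the class-weighted cross-entropy on the train mask with Adam,
#' evaluates the validation loss every epoch, stops when it has not improved
#' for `patience` epochs (or at `max_epochs`), restores the best-validation
#' parameters, and returns probabilities for all genes from the restored
#' model together with test-set metrics.
#'
#' @param dataset an [assemble_dataset()] result.
#' @param split one repeat from [make_splits()] (elements `train`, `val`,
#'   `test`, `index`).
#' @param config a [model_config()].
#' @param graph_ops optional precomputed operators (internal reuse across
#'   folds).
#' @return object of class `fold_result`: `probs` (per-node, named), `metrics`
#'   (test-set [metrics_report()]), `epochs_run`, `best_val_loss`,
#'   `class_weight`, `params`.
#' @export
train_fold <- function(dataset, split, config = model_config(),
                       graph_ops = NULL) {
  ops <- graph_ops %||% graph_operators(dataset)
  x <- dataset$features
  n <- nrow(x)
  y01 <- ifelse(dataset$y == "positive", 1,
                ifelse(dataset$y == "negative", 0, NA_real_))
  tr <- split$train; va <- split$val; te <- split$test
  cw <- compute_class_weight(sum(y01[tr] == 1), sum(y01[tr] == 0))

  set.seed(derive_seed(config$seed, 5000 + split$index))
  params <- gef_init_params(ncol(x), config)

  if ((config$engine %||% "cpp") == "cpp") {
    res <- .train_loop_cpp(
      x, ops$adj_norm, ops$eidx$ei, ops$eidx$ej, ops$eidx$ends_i,
      params, ifelse(is.na(y01), -1, y01), tr, va, cw,
      switch(config$branches, both = 0L, gcn = 1L, gat = 2L),
      config$gat_heads_hidden, config$gat_heads_out, config$negative_slope,
      config$dropout, config$learning_rate, config$weight_decay,
      config$max_epochs, config$patience)
    best_params <- structure(res$params, class = "gef_params",
                             config = config, d_in = ncol(x))
    probs <- stats::setNames(as.vector(res$probs), dataset$network$nodes)
    epochs_run <- res$epochs_run
    best_epoch <- res$best_epoch
    best_loss <- res$best_val_loss
  } else {
    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    n_tr <- length(tr)
    dl <- numeric(n)
    epoch <- 0L
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      drop <- make_dropout_masks(n, ncol(x), config, config$dropout)
      fwd <- gef_forward_impl(x, ops$adj_norm, ops$eidx, params, config,
                              drop = drop, keep_cache = TRUE)
      p <- fwd$probs
      if (any(!is.finite(p))) {
        stop_("training diverged (non-finite probabilities) at epoch %d", epoch)
      }
      # d(loss)/d(logit) for the masked weighted BCE
      dl[] <- 0
      dl[tr] <- (-cw * y01[tr] * (1 - p[tr]) + (1 - y01[tr]) * p[tr]) / n_tr
      grads <- gef_backward(x, ops$adj_norm, ops$eidx, params, config,
                            fwd$cache, drop, dl)
      upd <- adam_step(params, grads, state, config$learning_rate,
                       config$weight_decay)
      params <- upd$params; state <- upd$state

      ev <- gef_forward_impl(x, ops$adj_norm, ops$eidx, params, config)
      val_loss <- weighted_bce_loss(ev$probs, y01, cw, va)
      if (!is.finite(val_loss)) {
        stop_("training diverged (non-finite validation loss) at epoch %d", epoch)
      }
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    best_params <- best$params
    fin <- gef_forward_impl(x, ops$adj_norm, ops$eidx, best_params, config)
    probs <- stats::setNames(fin$probs, dataset$network$nodes)
    epochs_run <- epoch
    best_epoch <- best$epoch
    best_loss <- best$loss
  }

  metrics <- metrics_report(y01[te], probs[te], threshold = config$threshold)
  structure(list(fold = split$index, probs = probs, metrics = metrics,
                 epochs_run = epochs_run, best_epoch = best_epoch,
                 best_val_loss = best_loss, class_weight = cw,
                 params = best_params),
            class = "fold_result")
}

#' Repeated cross-validation on one network
#'
#' Runs [train_fold()] on every repeat of the split plan and aggregates the
#' test-set metrics (mean and standard deviation over repeats). The returned
#' per-node probabilities are the fold averages used for gene ranking.
#'
#' @param dataset an [assemble_dataset()] result.
#' @param config a [model_config()].
#' @param keep_params keep per-fold parameter sets (larger object).
#' @return object of class `cv_result` with `folds`, `metrics_mean`,
#'   `metrics_sd`, `probs` (fold-averaged, named per gene) and `config`.
#' @export
run_cross_validation <- function(dataset, config = model_config(),
                                 keep_params = FALSE) {
  splits <- make_splits(dataset$y, config)
  ops <- graph_operators(dataset)
  folds <- lapply(splits, function(sp) {
    fr <- train_fold(dataset, sp, config, graph_ops = ops)
    if (!keep_params) fr$params <- NULL
    fr
  })
  met <- do.call(rbind, lapply(folds, function(f) unlist(f$metrics[
    c("ACC", "AUROC", "AUPR", "F1", "MCC")])))
  probs <- Reduce(`+`, lapply(folds, `[[`, "probs")) / length(folds)
  structure(list(folds = folds,
                 metrics_mean = colMeans(met),
                 metrics_sd = apply(met, 2, sd),
                 metrics_by_fold = met,
                 probs = probs,
                 network = dataset$network$name,
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result on '%s' (%d repeats)\n", x$network, length(x$folds)))
  m <- x$metrics_mean; s <- x$metrics_sd
  for (nm in names(m)) {
    cat(sprintf("  %-6s %.4f (sd %.4f)\n", nm, m[[nm]], s[[nm]]))
  }
  invisible(x)
}

#' Write per-gene probabilities as TSV
#'
#' Columns: gene, probability, label, fold_count.
#'
#' @param cv a `cv_result` (or a named probability vector plus `y`/`folds`).
#' @param y per-node label factor aligned to the probabilities.
#' @param path output path.
#' @export
write_probabilities <- function(cv, y, path) {
  probs <- if (inherits(cv, "cv_result")) cv$probs else cv
  nfold <- if (inherits(cv, "cv_result")) length(cv$folds) else 1L
  df <- data.frame(gene = names(probs), probability = as.numeric(probs),
                   label = as.character(y[names(probs)]),
                   fold_count = nfold, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probability TSV written by [write_probabilities()]
#' @param path file path.
#' @return data.frame with columns gene, probability, label, fold_count.
#' @export
read_probabilities <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(gene = "character"))
}
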