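# Synthetic study generator: an ensemble of correlated planted-community
# graphs, a 64-column block-structured omics feature matrix in which planted
# driver genes have shifted means, and imbalanced positive/negative label
# sets. Gives every other module a fully controllable offline test bed.

#' Synthetic study configuration
#'
#' Defaults define the standard simulation scenario: 600 genes of which 60
#' are planted drivers; driver-driver edges at probability `p_in` = 0.05 and
#' all other pairs at `p_out` = 0.005 (a planted-community model with a
#' tenfold density contrast); a mean shift of 1.5 standard deviations for
#' drivers in the somatic-mutation (MF) and expression (GE) feature blocks;
#' an ensemble of 6 networks in which each network beyond the first has 20%
#' of its edges resampled; half of the drivers labeled positive and three
#' negatives per positive (mirroring the roughly 1:3 imbalance of curated
#' driver benchmarks).
#'
#' @param n_genes,n_drivers gene counts (drivers < genes).
#' @param p_in,p_out within-community and background edge probabilities
#'   (`p_out <= p_in`).
#' @param omics_effect named vector of per-omics mean shifts for drivers, in
#'   standard-deviation units (names among MF, METH, GE, CNA).
#' @param n_networks ensemble size.
#' @param edge_rewire_fraction fraction of edges independently resampled in
#'   each network after the first.
#' @param label_fraction_pos fraction of drivers labeled positive.
#' @param neg_pos_ratio target negative:positive label ratio.
#' @param label_fraction_neg used instead of `neg_pos_ratio` when the latter
#'   is `NULL`: fraction of non-drivers labeled negative.
#' @param seed master seed; all randomness is derived from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 600, n_drivers = 60,
                             p_in = 0.05, p_out = 0.005,
                             omics_effect = c(MF = 1.5, METH = 0, GE = 1.5, CNA = 0),
                             n_networks = 6, edge_rewire_fraction = 0.2,
                             label_fraction_pos = 0.5,
                             neg_pos_ratio = 3,
                             label_fraction_neg = NULL,
                             seed = 1) {
  assert_that(n_drivers < n_genes, "n_drivers must be smaller than n_genes")
  assert_that(p_out >= 0 && p_out <= p_in && p_in <= 1,
              "need 0 <= p_out <= p_in <= 1")
  assert_that(edge_rewire_fraction >= 0 && edge_rewire_fraction <= 1,
              "edge_rewire_fraction must lie in [0, 1]")
  eff <- stats::setNames(rep(0, length(OMICS_TYPES)), OMICS_TYPES)
  unknown <- setdiff(names(omics_effect), OMICS_TYPES)
  assert_that(length(unknown) == 0, "unknown omics tag in omics_effect: %s",
              paste(unknown, collapse = ", "))
  eff[names(omics_effect)] <- omics_effect
  structure(list(n_genes = n_genes, n_drivers = n_drivers, p_in = p_in,
                 p_out = p_out, omics_effect = eff, n_networks = n_networks,
                 edge_rewire_fraction = edge_rewire_fraction,
                 label_fraction_pos = label_fraction_pos,
                 neg_pos_ratio = neg_pos_ratio,
                 label_fraction_neg = label_fraction_neg, seed = seed),
            class = "synthetic_config")
}

synthetic_gene_symbols <- function(config) {
  sprintf("G%04d", seq_len(config$n_genes))
}

#' Planted driver gene symbols of a synthetic configuration
#' @param config a [synthetic_config()].
#' @return character vector of the driver symbols.
#' @export
synthetic_drivers <- function(config) {
  synthetic_gene_symbols(config)[seq_len(config$n_drivers)]
}

# One planted-community draw at edge probabilities (p_in, p_out); drivers are
# the first block. Returns a two-column character edge matrix.
sample_planted_edges <- function(config, p_in, p_out) {
  pref <- matrix(c(p_in, p_out, p_out, p_out), 2, 2)
  gr <- igraph::sample_sbm(config$n_genes, pref.matrix = pref,
                           block.sizes = c(config$n_drivers,
                                           config$n_genes - config$n_drivers))
  el <- igraph::as_edgelist(gr, names = FALSE)
  symbols <- synthetic_gene_symbols(config)
  cbind(symbols[el[, 1]], symbols[el[, 2]])
}

#' Generate the ensemble of correlated PPI-like networks
#'
#' The first network is a planted-community draw: drivers are densely
#' interconnected at `p_in`, every other pair connects at `p_out`. Each
#' further network keeps every base edge with probability
#' `1 - edge_rewire_fraction` and unions an independent planted-community
#' draw at the downscaled probabilities `edge_rewire_fraction * p`, so
#' expected densities are preserved while networks decorrelate.
#'
#' @param config a [synthetic_config()].
#' @return list of [gene_network()] objects (all sharing the same gene
#'   universe, isolated nodes retained).
#' @export
generate_network_ensemble <- function(config = synthetic_config()) {
  symbols <- synthetic_gene_symbols(config)
  set.seed(derive_seed(config$seed, 11))
  base <- sample_planted_edges(config, config$p_in, config$p_out)
  nets <- vector("list", config$n_networks)
  nets[[1]] <- gene_network(base, nodes = symbols, name = "net1")
  f <- config$edge_rewire_fraction
  for (k in seq_len(config$n_networks - 1)) {
    set.seed(derive_seed(config$seed, 20 + k))
    if (f == 0) {
      edges <- base
    } else {
      keep <- runif(nrow(base)) >= f
      fresh <- sample_planted_edges(config, f * config$p_in, f * config$p_out)
      edges <- rbind(base[keep, , drop = FALSE], fresh)
    }
    nets[[k + 1]] <- gene_network(edges, nodes = symbols,
                                  name = paste0("net", k + 1))
  }
  nets
}

#' Generate the block-structured omics feature table
#'
#' 64 columns (4 omics types x 16 cancer types). Background entries are
#' standard normal; driver genes receive an additive mean shift of
#' `omics_effect[o]` in every column of omics block `o`.
#'
#' @param config a [synthetic_config()].
#' @param networks unused (the feature table is shared by the whole
#'   ensemble); accepted for pipeline symmetry.
#' @return numeric matrix, genes x 64, with dimnames.
#' @export
generate_features <- function(config = synthetic_config(), networks = NULL) {
  symbols <- synthetic_gene_symbols(config)
  cols <- full_feature_grid()
  set.seed(derive_seed(config$seed, 42))
  x <- matrix(rnorm(config$n_genes * length(cols)), config$n_genes,
              length(cols), dimnames = list(symbols, cols))
  drivers <- seq_len(config$n_drivers)
  for (o in OMICS_TYPES) {
    if (config$omics_effect[[o]] != 0) {
      block <- grep(paste0("^", o, "_"), cols)
      x[drivers, block] <- x[drivers, block] + config$omics_effect[[o]]
    }
  }
  x
}

#' Generate the positive/negative label catalog
#'
#' Positives are sampled from the planted drivers
#' (`label_fraction_pos` of them); negatives are sampled from the
#' non-drivers, `neg_pos_ratio` per positive (or `label_fraction_neg` of the
#' non-drivers when the ratio is `NULL`). The remaining genes stay unlabeled.
#'
#' @param config a [synthetic_config()].
#' @return a [label_catalog()].
#' @export
generate_labels <- function(config = synthetic_config()) {
  symbols <- synthetic_gene_symbols(config)
  drivers <- symbols[seq_len(config$n_drivers)]
  others <- symbols[-seq_len(config$n_drivers)]
  n_pos <- round(config$label_fraction_pos * length(drivers))
  n_neg <- if (is.null(config$neg_pos_ratio)) {
    round(config$label_fraction_neg * length(others))
  } else {
    round(config$neg_pos_ratio * n_pos)
  }
  assert_that(n_pos >= 1 && n_pos <= length(drivers),
              "infeasible positive label count %d", n_pos)
  assert_that(n_neg >= 1 && n_neg <= length(others),
              "infeasible negative label count %d (only %d non-drivers)",
              n_neg, length(others))
  set.seed(derive_seed(config$seed, 77))
  label_catalog(sample(drivers, n_pos), sample(others, n_neg))
}

#' Generate and write a complete synthetic study to disk
#'
#' Writes one edge-list TSV per network, the shared feature table, the two
#' label lists and a JSON manifest recording the full configuration and seed
#' -- the same on-disk formats the readers consume.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file paths.
#' @export
simulate_study <- function(config = synthetic_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  networks <- generate_network_ensemble(config)
  features <- generate_features(config, networks)
  labels <- generate_labels(config)
  net_paths <- vapply(networks, function(nw) {
    p <- file.path(out_dir, paste0(nw$name, ".tsv"))
    write_edge_list(nw, p)
    p
  }, "")
  fp <- file.path(out_dir, "features.tsv")
  write_feature_table(features, fp)
  pp <- file.path(out_dir, "positives.txt")
  np <- file.path(out_dir, "negatives.txt")
  write_gene_list(labels$positives, pp)
  write_gene_list(labels$negatives, np)
  manifest <- list(tool = "gefdriver",
                   version = as.character(utils::packageVersion("gefdriver")),
                   command = "simulate",
                   config = unclass(config),
                   seed = config$seed,
                   files = basename(c(net_paths, fp, pp, np)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(list(networks = networks, features = features, labels = labels,
                 paths = list(networks = net_paths, features = fp,
                              positives = pp, negatives = np)))
}
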