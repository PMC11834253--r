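# Consensus calling across PPI networks: rank genes by predicted driver
# probability, take the top K per network, keep genes supported by at least m
# networks, and partition candidates into known vs novel.

#' Rank genes by probability
#'
#' Stable descending sort; ties are broken lexicographically by gene symbol,
#' so the ranking is deterministic.
#'
#' @param probabilities named numeric vector (names are gene symbols), or an
#'   unnamed vector plus `nodes`.
#' @param nodes gene symbols aligned to `probabilities` (defaults to its
#'   names).
#' @param network network identifier attached to the ranking.
#' @return object of class `gene_ranking`: data.frame with columns `gene`,
#'   `probability`, rows in rank order.
#' @export
rank_genes <- function(probabilities, nodes = names(probabilities),
                       network = "network") {
  assert_that(!is.null(nodes), "gene symbols required (names or `nodes`)")
  assert_that(!any(duplicated(nodes)), "duplicate gene symbols in ranking")
  o <- order(-probabilities, nodes, method = "radix")
  structure(data.frame(gene = nodes[o],
                       probability = as.numeric(probabilities)[o],
                       stringsAsFactors = FALSE),
            class = c("gene_ranking", "data.frame"), network = network)
}

#' Top K genes of a ranking
#'
#' @param ranking a [rank_genes()] result.
#' @param k number of genes (default 300); fewer if the ranking is shorter.
#'   Ties at the boundary are resolved by the ranking's deterministic order.
#' @return character vector of gene symbols.
#' @export
top_k <- function(ranking, k = 300) {
  assert_that(k >= 1, "k must be at least 1")
  utils::head(ranking$gene, k)
}

#' Consensus candidate set across network rankings
#'
#' Takes the top `k` genes of each per-network ranking and keeps every gene
#' that appears in at least `m` of them (support count). The reference
#' protocol uses k = 300 and m = 2 over six PPI networks.
#'
#' @param rankings list of [rank_genes()] results (one per network).
#' @param k top-list size per network.
#' @param m minimum number of supporting networks.
#' @return object of class `consensus_result`: data.frame `candidates` with
#'   columns `gene`, `support`, `mean_probability`, plus parameters `k`, `m`.
#' @export
consensus_candidates <- function(rankings, k = 300, m = 2) {
  assert_that(length(rankings) >= m,
              "m = %d exceeds the number of rankings (%d)", m, length(rankings))
  tops <- lapply(rankings, top_k, k = k)
  genes <- unlist(tops, use.names = FALSE)
  support <- table(genes)
  keep <- sort_symbols(names(support)[support >= m])
  # mean probability over the networks whose top-K contains the gene
  probs <- vapply(keep, function(g) {
    vals <- vapply(seq_along(rankings), function(i) {
      if (g %in% tops[[i]]) {
        rankings[[i]]$probability[match(g, rankings[[i]]$gene)]
      } else NA_real_
    }, 0.0)
    mean(vals, na.rm = TRUE)
  }, 0.0)
  cand <- data.frame(gene = keep,
                     support = as.integer(support[keep]),
                     mean_probability = if (length(keep)) unname(probs) else numeric(),
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$support, -cand$mean_probability, cand$gene,
                     method = "radix"), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, k = k, m = m,
                 n_networks = length(rankings)),
            class = "consensus_result")
}

#' Partition consensus candidates into known and novel genes
#'
#' @param result a [consensus_candidates()] result.
#' @param positives a [label_catalog()] or character vector of known driver
#'   genes.
#' @return the result with an added logical `known` column, `known`/`novel`
#'   gene vectors and the known fraction.
#' @export
annotate_known <- function(result, positives) {
  if (inherits(positives, "label_catalog")) positives <- positives$positives
  known <- result$candidates$gene %in% positives
  result$candidates$known <- known
  result$known <- result$candidates$gene[known]
  result$novel <- result$candidates$gene[!known]
  result$known_fraction <- if (nrow(result$candidates)) mean(known) else 0
  result
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d candidates (top %d per network, support >= %d of %d)\n",
              nrow(x$candidates), x$k, x$m, x$n_networks))
  if (!is.null(x$known_fraction)) {
    cat(sprintf("  known: %d (%.1f%%), novel: %d\n", length(x$known),
                100 * x$known_fraction, length(x$novel)))
  }
  invisible(x)
}

#' Write a consensus candidate table as TSV
#'
#' Columns: gene, support_count, mean_probability, known_flag (if annotated).
#'
#' @param result a [consensus_candidates()] result.
#' @param path output path.
#' @export
write_candidates <- function(result, path) {
  df <- result$candidates
  names(df)[names(df) == "support"] <- "support_count"
  names(df)[names(df) == "known"] <- "known_flag"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a gene ranking as TSV (gene, probability)
#' @param ranking a [rank_genes()] result.
#' @param path file path.
#' @export
write_ranking <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @param network identifier attached to the ranking on read.
#' @export
read_ranking <- function(path, network = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(gene = "character"))
  structure(df, class = c("gene_ranking", "data.frame"),
            network = network %||% sub("\\.[^.]*$", "", basename(path)))
}
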