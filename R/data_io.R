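# Readers/writers for the standard inputs (edge lists, feature tables, label
# lists) and assembly of one aligned dataset per PPI network.

#' The omics and cancer types spanned by the full feature grid
#'
#' Feature columns are named `<OMICS>_<CANCER>`: 4 omics types (somatic
#' mutation MF, DNA methylation METH, gene expression GE, copy-number
#' alteration CNA) crossed with 16 pan-cancer cohorts, giving 64 columns.
#' @name feature_grid
#' @keywords internal
NULL

OMICS_TYPES <- c("MF", "METH", "GE", "CNA")
CANCER_TYPES <- c("BLCA", "BRCA", "CESC", "COAD", "ESCA", "HNSC", "KIRC",
                  "KIRP", "LIHC", "LUAD", "LUSC", "PRAD", "READ", "STAD",
                  "THCA", "UCEC")

full_feature_grid <- function(omics = OMICS_TYPES) {
  as.vector(t(outer(omics, CANCER_TYPES, paste, sep = "_")))
}

#' Construct a gene network
#'
#' An undirected, unweighted gene--gene interaction network. Edges are stored
#' canonically (endpoint symbols sorted within each pair, duplicates and
#' self-pairs removed); nodes are the lexicographically sorted union of the
#' given node set and all edge endpoints.
#'
#' @param edges two-column character matrix or data.frame of gene symbol pairs.
#' @param nodes optional character vector of node symbols (isolated nodes are
#'   kept; edge endpoints are always included).
#' @param name network identifier.
#' @return an object of class `gene_network` with elements `nodes`, `edges`
#'   (data.frame with columns `gene_a`, `gene_b`) and `name`.
#' @export
gene_network <- function(edges, nodes = NULL, name = "network") {
  edges <- if (is.null(edges) || length(edges) == 0) {
    matrix(character(), 0, 2)
  } else {
    as.matrix(edges)
  }
  assert_that(ncol(edges) == 2, "edges must have exactly two columns")
  mode(edges) <- "character"
  keep <- edges[, 1] != edges[, 2]
  edges <- edges[keep, , drop = FALSE]
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  dup <- duplicated(cbind(a, b))
  a <- a[!dup]; b <- b[!dup]
  o <- order(a, b, method = "radix")
  nodes <- sort_symbols(c(nodes, a, b))
  structure(
    list(nodes = nodes,
         edges = data.frame(gene_a = a[o], gene_b = b[o],
                            stringsAsFactors = FALSE),
         name = name),
    class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI edge list from a TSV file
#'
#' Each non-comment line holds `gene_a TAB gene_b` with an optional third
#' numeric confidence score. When `score_threshold` is given, only rows with
#' score strictly greater than the threshold are retained (the convention used
#' for confidence-scored PPI databases, e.g. keep CPDB interactions with
#' score > 0.5 and STRING interactions with score > 0.85). The node universe
#' is the set of endpoints of surviving edges.
#'
#' @param path file path.
#' @param score_threshold numeric or `NULL` (no filtering).
#' @param name network identifier; defaults to the file base name.
#' @return a [gene_network()].
#' @export
read_edge_list <- function(path, score_threshold = NULL, name = NULL) {
  assert_that(file.exists(path), "edge list file not found: %s", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(gene_network(NULL, name = name))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad)) {
    stop_("malformed edge list row at line %d of %s (expected 2 or 3 fields, got %d)",
          idx[bad[1]], path, nf[bad[1]])
  }
  has_score <- nf == 3
  if (!is.null(score_threshold)) {
    if (!all(has_score)) {
      stop_("score_threshold given but line %d of %s has no score column",
            idx[which(!has_score)[1]], path)
    }
    score <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
    nonnum <- which(is.na(score))
    if (length(nonnum)) {
      stop_("non-numeric score at line %d of %s", idx[nonnum[1]], path)
    }
    sel <- score > score_threshold
    parts <- parts[sel]
  }
  if (length(parts) == 0) return(gene_network(NULL, name = name))
  edges <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  gene_network(edges, name = name)
}

#' Write a gene network as an edge-list TSV
#'
#' @param network a [gene_network()].
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene x feature table from a TSV file
#'
#' The file must have a header row; the first column holds gene symbols and
#' the remaining columns are numeric features named `<OMICS>_<CANCER>`. With
#' `strict = TRUE` the columns must be exactly the full 4 omics x 16 cancer
#' type grid (64 columns, any order).
#'
#' @param path file path.
#' @param strict validate column names against the full feature grid.
#' @return numeric matrix with gene symbols as row names.
#' @export
read_feature_table <- function(path, strict = FALSE) {
  assert_that(file.exists(path), "feature table file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "#")
  assert_that(ncol(raw) >= 2, "feature table needs a gene column plus features")
  genes <- raw[[1]]
  dup <- which(duplicated(genes))
  if (length(dup)) {
    stop_("duplicate gene row '%s' in %s", genes[dup[1]], path)
  }
  feat_names <- colnames(raw)[-1]
  if (strict) {
    grid <- full_feature_grid()
    assert_that(length(feat_names) == length(grid) && setequal(feat_names, grid),
                "strict mode: columns must be exactly the %d-column omics grid",
                length(grid))
  }
  mat <- matrix(NA_real_, nrow(raw), length(feat_names),
                dimnames = list(genes, feat_names))
  for (j in seq_along(feat_names)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v) & !(raw[[j + 1]] %in% c("NA", "")))
    if (length(bad)) {
      stop_("non-numeric value '%s' at row %d (gene %s), column '%s' of %s",
            raw[[j + 1]][bad[1]], bad[1], genes[bad[1]], feat_names[j], path)
    }
    nav <- which(is.na(v))
    if (length(nav)) {
      stop_("missing value at row %d (gene %s), column '%s' of %s",
            nav[1], genes[nav[1]], feat_names[j], path)
    }
    mat[, j] <- v
  }
  mat
}

#' Write a feature table as TSV
#'
#' @param features numeric matrix, genes in rows (row names required).
#' @param path output path.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(gene = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a feature table to selected omics types
#'
#' Keeps the columns whose `<OMICS>_` prefix belongs to `omics_types`,
#' preserving column order. Used for the omics ablation design (single types
#' and combinations of MF, METH, GE, CNA).
#'
#' @param features feature matrix from [read_feature_table()].
#' @param omics_types non-empty subset of `c("MF","METH","GE","CNA")`.
#' @return feature matrix with the selected columns.
#' @export
subset_omics <- function(features, omics_types) {
  assert_that(length(omics_types) >= 1, "omics_types must be non-empty")
  unknown <- setdiff(omics_types, OMICS_TYPES)
  assert_that(length(unknown) == 0, "unknown omics type: %s",
              paste(unknown, collapse = ", "))
  prefix <- sub("_.*$", "", colnames(features))
  features[, prefix %in% omics_types, drop = FALSE]
}

#' Per-column z-score normalization
#'
#' Optional utility; feature normalization is in general the data producer's
#' responsibility. Columns with zero variance are set to zero.
#'
#' @param features numeric matrix.
#' @return matrix of the same shape.
#' @export
zscore_columns <- function(features) {
  mu <- colMeans(features)
  s <- apply(features, 2, sd)
  s[s == 0] <- Inf
  sweep(sweep(features, 2, mu, "-"), 2, s, "/")
}

#' Construct a label catalog
#'
#' @param positives character vector of known driver gene symbols.
#' @param negatives character vector of confident non-driver gene symbols.
#' @return object of class `label_catalog`.
#' @export
label_catalog <- function(positives, negatives) {
  positives <- sort_symbols(positives)
  negatives <- sort_symbols(negatives)
  both <- intersect(positives, negatives)
  assert_that(length(both) == 0,
              "genes labeled both positive and negative: %s",
              paste(head(both, 5), collapse = ", "))
  structure(list(positives = positives, negatives = negatives),
            class = "label_catalog")
}

#' Read a gene list (one symbol per line)
#'
#' @param path file path; `#` comment lines and blanks are ignored.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  assert_that(file.exists(path), "gene list file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[!grepl("^(#|$)", lines)]
}

#' Write a gene list (one symbol per line)
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Assemble an attributed graph dataset for one network
#'
#' Aligns the feature table and label catalog to the network's node order
#' (lexicographic). Genes present in the network but missing from the feature
#' table receive an all-zero feature row (zero is the neutral value after
#' z-score normalization); a warning reports how many. Labels are restricted
#' to network nodes; it is an error if no labeled gene lies in the network.
#'
#' @param network a [gene_network()].
#' @param features feature matrix with gene row names.
#' @param labels a [label_catalog()].
#' @return object of class `attributed_graph_dataset` with elements `network`,
#'   `features` (|V| x d matrix aligned to `network$nodes`), `y` (factor with
#'   levels positive/negative/unlabeled) and `masks` (`NULL` until a split is
#'   applied).
#' @export
assemble_dataset <- function(network, features, labels) {
  nodes <- network$nodes
  missing <- setdiff(nodes, rownames(features))
  x <- matrix(0, length(nodes), ncol(features),
              dimnames = list(nodes, colnames(features)))
  present <- intersect(nodes, rownames(features))
  x[present, ] <- features[present, , drop = FALSE]
  if (length(missing)) {
    warning(sprintf("%d of %d network genes missing from the feature table; zero-imputed",
                    length(missing), length(nodes)), call. = FALSE)
  }
  y <- factor(rep("unlabeled", length(nodes)),
              levels = c("positive", "negative", "unlabeled"))
  names(y) <- nodes
  y[nodes %in% labels$positives] <- "positive"
  y[nodes %in% labels$negatives] <- "negative"
  assert_that(any(y != "unlabeled"),
              "no labeled gene occurs in network '%s'; dataset untrainable",
              network$name)
  structure(list(network = network, features = x, y = y, masks = NULL),
            class = "attributed_graph_dataset")
}

#' @export
print.attributed_graph_dataset <- function(x, ...) {
  tab <- table(x$y)
  cat(sprintf("attributed_graph_dataset '%s': %d nodes, %d edges, %d features\n",
              x$network$name, length(x$network$nodes), nrow(x$network$edges),
              ncol(x$features)))
  cat(sprintf("  labels: %d positive, %d negative, %d unlabeled\n",
              tab[["positive"]], tab[["negative"]], tab[["unlabeled"]]))
  invisible(x)
}

#' Serialize an attributed graph dataset to a single JSON snapshot
#'
#' The snapshot stores the node order, the adjacency as triplets, the feature
#' matrix, labels and masks; [read_dataset()] reproduces the dataset exactly.
#'
#' @param dataset an [assemble_dataset()] result.
#' @param path output path.
#' @export
write_dataset <- function(dataset, path) {
  net <- dataset$network
  ij <- cbind(match(net$edges$gene_a, net$nodes),
              match(net$edges$gene_b, net$nodes))
  obj <- list(
    name = net$name,
    nodes = net$nodes,
    edge_i = ij[, 1], edge_j = ij[, 2],
    feature_names = colnames(dataset$features),
    features = as.vector(dataset$features),
    y = as.character(dataset$y),
    masks = dataset$masks
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a dataset snapshot written by [write_dataset()]
#' @param path snapshot path.
#' @return an `attributed_graph_dataset`.
#' @export
read_dataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- obj$nodes
  edges <- cbind(nodes[obj$edge_i], nodes[obj$edge_j])
  net <- gene_network(edges, nodes = nodes, name = obj$name)
  x <- matrix(obj$features, length(nodes), length(obj$feature_names),
              dimnames = list(nodes, obj$feature_names))
  y <- factor(obj$y, levels = c("positive", "negative", "unlabeled"))
  names(y) <- nodes
  masks <- obj$masks
  if (!is.null(masks)) masks <- lapply(masks, as.integer)
  structure(list(network = net, features = x, y = y, masks = masks),
            class = "attributed_graph_dataset")
}
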