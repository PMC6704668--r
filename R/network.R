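# Signed lncRNA-mRNA-TF co-expression network assembly, subnetwork
# extraction and hierarchical ordering for heatmap export.

#' Assemble the signed co-expression network
#'
#' One coexpression edge per correlated target pair (weight `|r|`, sign
#' from the correlation), with an optional protein-protein interaction
#' edge table appended verbatim (`relation = "ppi"`, sign `n/a`).
#' Self-edges are forbidden and duplicate edges collapse keeping the
#' maximum `|r|`. Node regulation is colored from a DE table for the
#' designated comparison: up if `log2fc > 0` and called DE, down if
#' `< 0` and called DE, none otherwise.
#'
#' @param target_pairs data.frame of pairs with `lncrna_id`, `gene_id`,
#'   `r` (rows with missing `r`, e.g. cis-only pairs, carry no
#'   co-expression evidence and are skipped).
#' @param de_table DE results (see [differential_expression()]) for the
#'   comparison used to color regulation; may cover any superset of the
#'   nodes.
#' @param node_kinds data.frame `id`, `kind` (`lncRNA`, `mRNA`, `TF`);
#'   every edge endpoint must have a kind.
#' @param ppi_edges Optional data.frame `node_a`, `node_b`.
#' @return List of class `lnc_network` with `nodes` (`id`, `kind`,
#'   `regulation`), `edges` (`node_a`, `node_b`, `relation`, `sign`,
#'   `weight`) and `edge_accounting` (unique coexpression pairs, ppi
#'   edges, collapsed duplicates).
#' @export
build_network <- function(target_pairs, de_table, node_kinds,
                          ppi_edges = NULL) {
  co <- target_pairs[!is.na(target_pairs$r), , drop = FALSE]
  co <- co[co$lncrna_id != co$gene_id, , drop = FALSE]
  n_input <- nrow(co)
  # canonical endpoint order so duplicates collapse regardless of
  # direction
  a <- pmin(co$lncrna_id, co$gene_id)
  b <- pmax(co$lncrna_id, co$gene_id)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -abs(co$r))
  first <- !duplicated(key[ord])
  co <- df0(node_a = a[ord][first], node_b = b[ord][first],
            relation = "coexpression",
            sign = ifelse(co$r[ord][first] > 0, "positive", "negative"),
            weight = abs(co$r[ord][first]))
  n_dup <- n_input - nrow(co)

  edges <- co
  n_ppi <- 0L
  if (!is.null(ppi_edges) && nrow(ppi_edges)) {
    ppi <- df0(node_a = as.character(ppi_edges$node_a),
               node_b = as.character(ppi_edges$node_b),
               relation = "ppi", sign = "n/a", weight = NA_real_)
    ppi <- ppi[ppi$node_a != ppi$node_b, , drop = FALSE]
    n_ppi <- nrow(ppi)
    edges <- rbind(edges, ppi)
  }
  rownames(edges) <- NULL

  ids <- unique(c(edges$node_a, edges$node_b))
  m <- match(ids, node_kinds$id)
  if (anyNA(m))
    lnc_stop("network endpoint without a kind: %s", ids[which(is.na(m))[1]])
  kind <- as.character(node_kinds$kind[m])
  dm <- match(ids, de_table$feature_id)
  regulation <- rep("none", length(ids))
  hit <- !is.na(dm)
  regulation[hit] <- ifelse(de_table$is_de[dm[hit]] & de_table$log2fc[dm[hit]] > 0, "up",
                     ifelse(de_table$is_de[dm[hit]] & de_table$log2fc[dm[hit]] < 0, "down",
                            "none"))
  nodes <- df0(id = ids, kind = kind, regulation = regulation)
  structure(list(nodes = nodes, edges = edges,
                 edge_accounting = c(coexpression_unique = nrow(co),
                                     ppi = n_ppi, collapsed_duplicates = n_dup)),
            class = "lnc_network")
}

#' @export
print.lnc_network <- function(x, ...) {
  cat(sprintf("lnc_network: %d nodes (%s), %d edges (%d coexpression, %d ppi)\n",
              nrow(x$nodes),
              paste(sprintf("%s:%d", names(table(x$nodes$kind)),
                            table(x$nodes$kind)), collapse = ", "),
              nrow(x$edges), sum(x$edges$relation == "coexpression"),
              sum(x$edges$relation == "ppi")))
  invisible(x)
}

#' Extract the subnetwork around seed nodes
#'
#' All nodes within `hops` edges of the seed set, plus every edge
#' induced among them (`hops = 0` keeps only the seeds and the edges
#' among them).
#'
#' @param network An `lnc_network` (see [build_network()]).
#' @param seeds Character vector of node ids present in the network.
#' @param hops Neighborhood radius in edges (default 1).
#' @return An `lnc_network` restricted to the neighborhood.
#' @export
subnetwork <- function(network, seeds, hops = 1) {
  unknown <- setdiff(seeds, network$nodes$id)
  if (length(unknown)) lnc_stop("unknown seed node: %s", unknown[1])
  g <- igraph::graph_from_data_frame(
    network$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = network$nodes$id)
  reach <- unique(names(unlist(lapply(
    igraph::ego(g, order = hops, nodes = seeds), function(v) v))))
  keep_nodes <- network$nodes[network$nodes$id %in% reach, , drop = FALSE]
  keep_edges <- network$edges[network$edges$node_a %in% reach &
                              network$edges$node_b %in% reach, , drop = FALSE]
  rownames(keep_nodes) <- rownames(keep_edges) <- NULL
  structure(list(nodes = keep_nodes, edges = keep_edges,
                 edge_accounting = network$edge_accounting),
            class = "lnc_network")
}

#' Select transcription-factor candidates
#'
#' Applies the TF selection rule: called DE with linear fold change
#' strictly greater than `min_fold` (i.e. `|log2fc| > log2(min_fold)`)
#' and mean FPKM strictly greater than `min_fpkm`, restricted to
#' features annotated as TFs.
#'
#' @param expr [expression_matrix()] covering the DE features.
#' @param de_table DE results for the designated comparison.
#' @param node_kinds data.frame `id`, `kind`; only `kind == "TF"` rows
#'   are eligible.
#' @param min_fold Linear fold-change threshold (default 2).
#' @param min_fpkm Mean-FPKM threshold (default 30).
#' @return Character vector of selected TF ids.
#' @export
select_tf_candidates <- function(expr, de_table, node_kinds,
                                 min_fold = 2, min_fpkm = 30) {
  tf_ids <- node_kinds$id[node_kinds$kind == "TF"]
  de <- de_table[de_table$feature_id %in% tf_ids &
                 de_table$is_de &
                 abs(de_table$log2fc) > log2(min_fold), , drop = FALSE]
  ids <- intersect(de$feature_id, rownames(expr$values))
  ids[rowMeans(expr$values[ids, , drop = FALSE]) > min_fpkm]
}

#' Hierarchical ordering of an expression submatrix for heatmap export
#'
#' Agglomerative clustering of rows (features) and columns (samples)
#' with distance `1 - Pearson` and the given linkage. Constant rows or
#' columns have undefined correlation; they are assigned the maximum
#' distance (2) to everything and reported. Ties are broken by the
#' deterministic merge order of [stats::hclust()].
#'
#' @param mat Numeric matrix with >= 2 rows (e.g. log2(FPKM+1) of DE
#'   features).
#' @param linkage Agglomeration method (default "average").
#' @return List with `row_order`, `col_order` (leaf orders), `row_tree`,
#'   `col_tree` (`hclust` objects) and `constant_features` /
#'   `constant_samples`.
#' @export
hierarchical_order <- function(mat, linkage = "average") {
  if (!is.matrix(mat) || nrow(mat) < 2L)
    lnc_stop("need a matrix with >= 2 rows to cluster")
  if (ncol(mat) < 2L) lnc_stop("need >= 2 columns to cluster")
  cluster_axis <- function(x) {
    const <- apply(x, 1, stats::sd) == 0
    d <- matrix(2, nrow(x), nrow(x))
    if (sum(!const) >= 2) {
      r <- stats::cor(t(x[!const, , drop = FALSE]))
      d[!const, !const] <- 1 - r
    }
    diag(d) <- 0
    rownames(d) <- colnames(d) <- rownames(x)
    list(tree = stats::hclust(stats::as.dist(d), method = linkage),
         const = rownames(x)[const])
  }
  rows <- cluster_axis(mat)
  cols <- cluster_axis(t(mat))
  list(row_order = rownames(mat)[rows$tree$order],
       col_order = colnames(mat)[cols$tree$order],
       row_tree = rows$tree, col_tree = cols$tree,
       constant_features = rows$const, constant_samples = cols$const)
}
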