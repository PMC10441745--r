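#' Induce a thresholded PPI subgraph on a gene set
#'
#' Keeps the scored protein-protein interaction edges whose endpoints both
#' lie in `genes` and whose confidence score is strictly above `threshold`
#' (the conventional 0.4 medium-confidence cut), then returns the undirected
#' simple graph on the connected genes — isolated genes are excluded, as PPI
#' network figures conventionally show only connected nodes. Self-loops are
#' dropped with a warning; parallel edges keep their best score.
#'
#' @param genes character vector of gene ids.
#' @param edges data frame with columns `gene_a`, `gene_b`, `score`
#'   (scores in \[0, 1\]).
#' @param threshold strict lower score bound (default 0.4).
#' @return an igraph undirected graph with a `score` edge attribute.
#' @export
induce_ppi_subgraph <- function(genes, edges, threshold = 0.4) {
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("PPI scores must lie in [0, 1]", call. = FALSE)
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes &
    edges$score > threshold
  edges <- edges[keep, , drop = FALSE]
  # undirected de-duplication: keep the best-scored copy of each pair
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  ord <- order(a, b, -edges$score)
  edges <- data.frame(gene_a = a, gene_b = b, score = edges$score,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Rank hub genes by degree
#'
#' Degree-based hub ranking on a PPI subgraph (the "Degree" method of
#' connection counting): genes sorted by decreasing degree, ties broken
#' lexicographically by id (a message records when ties occur).
#'
#' @param graph an igraph graph, e.g. from [induce_ppi_subgraph()].
#' @param top_k number of hubs to return (default 10; capped at the node
#'   count).
#' @return data frame `gene`, `degree`, in rank order.
#' @export
hub_genes <- function(graph, top_k = 10L) {
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  deg <- igraph::degree(graph)
  if (length(deg) == 0L) {
    return(data.frame(gene = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-deg, names(deg))
  out <- data.frame(gene = names(deg)[ord], degree = as.integer(deg[ord]),
                    stringsAsFactors = FALSE)
  k <- min(top_k, nrow(out))
  if (k < nrow(out) && out$degree[k] == out$degree[k + 1L]) {
    message("degree tie at rank ", k, " broken lexicographically")
  }
  out[seq_len(k), , drop = FALSE]
}
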