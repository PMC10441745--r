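#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of a query gene set
#' against a background universe: p = P[X >= overlap] for X hypergeometric
#' with the universe size, term size and query size as parameters. Genes
#' outside the universe are dropped from the query with a warning, and each
#' term is restricted to the universe before testing. Terms with p < 0.05
#' (strict) are flagged significant; a Benjamini-Hochberg column is reported
#' alongside but does not drive the flag.
#'
#' @param query character vector of query gene ids.
#' @param annotations named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector: the background gene universe
#'   (conventionally all genes measured in the expression table, not the
#'   genome).
#' @return data frame sorted by p: `term`, `term_size`, `overlap`,
#'   `query_size`, `universe_size`, `fold_enrichment`, `p`, `p_adj`,
#'   `significant`, `overlap_genes` (comma-joined ids).
#' @examples
#' anns <- list(T1 = c("g1", "g2", "g3"), T2 = c("g4", "g5"))
#' ora(c("g1", "g2"), anns, universe = paste0("g", 1:10))
#' @export
ora <- function(query, annotations, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("empty query after universe restriction",
                                call. = FALSE)
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(annotations), function(term) {
    genes <- intersect(unique(annotations[[term]]), universe)
    m <- length(genes)
    ov <- intersect(query, genes)
    x <- length(ov)
    # upper tail P[X >= x]
    p <- stats::phyper(x - 1L, m, N - m, q, lower.tail = FALSE)
    fe <- if (m > 0L) (x / q) / (m / N) else NA_real_
    data.frame(term = term, term_size = m, overlap = x, query_size = q,
               universe_size = N, fold_enrichment = fe, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < 0.05
  out <- out[order(out$p, out$term),
             c("term", "term_size", "overlap", "query_size",
               "universe_size", "fold_enrichment", "p", "p_adj",
               "significant", "overlap_genes")]
  rownames(out) <- NULL
  out
}
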