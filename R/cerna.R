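#' Targets of a miRNA set
#'
#' Union of partner ids over the given miRNAs in a two-column target table.
#'
#' @param mirnas character vector of miRNA ids.
#' @param table data frame with columns `mirna_id`, `target_id`.
#' @return character vector of partner ids (unique, unordered set).
#' @export
targets_of <- function(mirnas, table) {
  unique(table$target_id[table$mirna_id %in% mirnas])
}

#' Intersect a target-partner set with a differential-expression set
#'
#' @param partner_set,de_set character vectors.
#' @return their intersection.
#' @export
overlap_with_de <- function(partner_set, de_set) {
  intersect(partner_set, de_set)
}

#' Reverse-identify miRNAs from a surviving target overlap
#'
#' Given the targets that survived a Venn intersection, selects the candidate
#' miRNAs that still have at least one target in that set — the "reverse
#' recognition" step of directional ceRNA construction.
#'
#' @param overlap character vector of surviving target ids.
#' @param table data frame with columns `mirna_id`, `target_id`.
#' @param candidates character vector of candidate miRNA ids.
#' @return character vector: the candidates with >= 1 target in `overlap`.
#' @export
reverse_identify <- function(overlap, table, candidates) {
  hits <- table$mirna_id[table$target_id %in% overlap]
  intersect(candidates, unique(hits))
}

.dedup_pairs <- function(table, what) {
  key <- paste(table$mirna_id, table$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate pairs in ", what, " table de-duplicated",
            call. = FALSE)
    table <- table[!duplicated(key), , drop = FALSE]
  }
  table
}

#' Build a directional lncRNA-miRNA-mRNA ceRNA network
#'
#' Implements the two-branch directional construction of a competing
#' endogenous RNA network from differential-expression sets and miRNA target
#' tables. For `polarity = "up_mir"` (up-regulated miRNAs sponged by
#' down-regulated lncRNAs, de-repressing down-regulated mRNAs):
#'
#' 1. lncRNA branch: intersect the targets of the up-miRNAs with the
#'    down-lncRNAs, then reverse-identify the up-miRNAs hitting that
#'    overlap (set A).
#' 2. mRNA branch: likewise against the down-mRNAs (set B).
#' 3. Final miRNAs = A intersect B. Final lncRNAs/mRNAs are the branch
#'    overlaps restricted to partners of a final miRNA, so no node is left
#'    isolated. Edges are exactly the input target pairs among retained
#'    nodes.
#'
#' `polarity = "down_mir"` mirrors the directions (down-miRNAs with
#' up-lncRNAs/up-mRNAs).
#'
#' @param de_sets per-class up/down id sets as returned by
#'   [split_directions()] (entries `lncrna`, `mirna`, `mrna`).
#' @param tables list with `mir_to_lnc` and `mir_to_mrna` target data frames
#'   (columns `mirna_id`, `target_id`).
#' @param polarity `"up_mir"` or `"down_mir"`.
#' @return object of class `cerna_network`: list with `nodes` (data frame
#'   `id`, `rna_class`, `direction`, `degree`), `edges` (data frame `from`,
#'   `to`, `edge_type`), and `polarity`.
#' @examples
#' de_sets <- list(lncrna = list(up = character(), down = c("L1", "L2")),
#'                 mirna = list(up = c("m1", "m2", "m3"), down = character()),
#'                 mrna = list(up = character(), down = c("G1", "G2", "G3")))
#' tabs <- list(
#'   mir_to_lnc = data.frame(mirna_id = c("m1", "m2", "m3"),
#'                           target_id = c("L1", "L2", "Lx")),
#'   mir_to_mrna = data.frame(mirna_id = c("m1", "m1", "m2", "m3"),
#'                            target_id = c("G1", "G2", "G9", "G3")))
#' build_cerna_network(de_sets, tabs, "up_mir")
#' @export
build_cerna_network <- function(de_sets, tables, polarity = c("up_mir", "down_mir")) {
  polarity <- match.arg(polarity)
  mir_dir <- if (polarity == "up_mir") "up" else "down"
  partner_dir <- if (polarity == "up_mir") "down" else "up"
  mirs <- de_sets$mirna[[mir_dir]]
  lncs <- de_sets$lncrna[[partner_dir]]
  mrnas <- de_sets$mrna[[partner_dir]]

  all_ids <- c(de_sets$lncrna$up, de_sets$lncrna$down,
               de_sets$mirna$up, de_sets$mirna$down,
               de_sets$mrna$up, de_sets$mrna$down)
  cls <- rep(c("lncrna", "mirna", "mrna"),
             times = c(length(de_sets$lncrna$up) + length(de_sets$lncrna$down),
                       length(de_sets$mirna$up) + length(de_sets$mirna$down),
                       length(de_sets$mrna$up) + length(de_sets$mrna$down)))
  if (anyDuplicated(all_ids) &&
      any(tapply(cls, all_ids, function(v) length(unique(v))) > 1L)) {
    stop("feature ids collide across RNA classes", call. = FALSE)
  }

  m2l <- .dedup_pairs(tables$mir_to_lnc, "miRNA-lncRNA")
  m2g <- .dedup_pairs(tables$mir_to_mrna, "miRNA-mRNA")

  lnc_overlap <- overlap_with_de(targets_of(mirs, m2l), lncs)
  mrna_overlap <- overlap_with_de(targets_of(mirs, m2g), mrnas)
  set_a <- reverse_identify(lnc_overlap, m2l, mirs)
  set_b <- reverse_identify(mrna_overlap, m2g, mirs)
  final_mirs <- intersect(set_a, set_b)

  final_lncs <- intersect(lnc_overlap, targets_of(final_mirs, m2l))
  final_mrnas <- intersect(mrna_overlap, targets_of(final_mirs, m2g))

  e_lnc <- m2l[m2l$mirna_id %in% final_mirs & m2l$target_id %in% final_lncs, ]
  e_mrna <- m2g[m2g$mirna_id %in% final_mirs & m2g$target_id %in% final_mrnas, ]
  edges <- rbind(
    data.frame(from = e_lnc$target_id, to = e_lnc$mirna_id,
               edge_type = rep("lncrna-mirna", nrow(e_lnc)),
               stringsAsFactors = FALSE),
    data.frame(from = e_mrna$mirna_id, to = e_mrna$target_id,
               edge_type = rep("mirna-mrna", nrow(e_mrna)),
               stringsAsFactors = FALSE)
  )
  rownames(edges) <- NULL

  nodes <- data.frame(
    id = c(sort(final_lncs), sort(final_mirs), sort(final_mrnas)),
    rna_class = rep(c("lncrna", "mirna", "mrna"),
                    times = c(length(final_lncs), length(final_mirs),
                              length(final_mrnas))),
    stringsAsFactors = FALSE
  )
  nodes$direction <- ifelse(nodes$rna_class == "mirna", mir_dir, partner_dir)
  deg <- table(c(edges$from, edges$to))
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  rownames(nodes) <- NULL

  structure(list(nodes = nodes, edges = edges, polarity = polarity),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat("ceRNA network (", x$polarity, "): ",
      s$n_lncrna, " lncRNA, ", s$n_mirna, " miRNA, ", s$n_mrna,
      " mRNA; ", s$n_edges, " edges\n", sep = "")
  invisible(x)
}

#' Enumerate lncRNA-miRNA-mRNA axes of a ceRNA network
#'
#' Every length-2 path lncRNA-miRNA-mRNA through a shared miRNA; the count
#' equals, per miRNA, (number of lncRNA neighbours) x (number of mRNA
#' neighbours).
#'
#' @param net a `cerna_network`.
#' @return data frame with columns `lncrna`, `mirna`, `mrna` (zero rows for
#'   an empty network).
#' @export
extract_triplets <- function(net) {
  empty <- data.frame(lncrna = character(), mirna = character(),
                      mrna = character(), stringsAsFactors = FALSE)
  if (nrow(net$edges) == 0L) return(empty)
  lnc_e <- net$edges[net$edges$edge_type == "lncrna-mirna", ]
  mrna_e <- net$edges[net$edges$edge_type == "mirna-mrna", ]
  out <- lapply(unique(net$nodes$id[net$nodes$rna_class == "mirna"]),
                function(m) {
    ls <- lnc_e$from[lnc_e$to == m]
    gs <- mrna_e$to[mrna_e$from == m]
    if (!length(ls) || !length(gs)) return(NULL)
    expand.grid(lncrna = ls, mirna = m, mrna = gs,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$lncrna, out$mirna, out$mrna), ]
  rownames(out) <- NULL
  out
}

#' Summarize a ceRNA network
#'
#' @param net a `cerna_network`.
#' @return list with per-class node counts, `n_edges`, `n_triplets` and the
#'   node `degree_table` sorted by decreasing degree.
#' @export
network_summary <- function(net) {
  cls <- net$nodes$rna_class
  deg <- net$nodes[order(-net$nodes$degree, net$nodes$id), ]
  rownames(deg) <- NULL
  list(n_lncrna = sum(cls == "lncrna"),
       n_mirna = sum(cls == "mirna"),
       n_mrna = sum(cls == "mrna"),
       n_edges = nrow(net$edges),
       n_triplets = nrow(extract_triplets(net)),
       degree_table = deg)
}

#' Convert a ceRNA network to igraph / export it
#'
#' `as_igraph` builds an undirected typed igraph object;
#' `export_network` writes node and edge TSVs plus GraphML and SIF files.
#'
#' @param net a `cerna_network`.
#' @return `as_igraph`: an igraph graph with `rna_class` and `direction`
#'   vertex attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = FALSE, vertices = net$nodes)
}

#' @rdname as_igraph
#' @param outdir directory for the exports.
#' @param prefix filename prefix.
#' @return `export_network`: invisibly, the paths written.
#' @export
export_network <- function(net, outdir, prefix = "cerna") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    nodes = file.path(outdir, paste0(prefix, "_nodes.tsv")),
    edges = file.path(outdir, paste0(prefix, "_edges.tsv")),
    graphml = file.path(outdir, paste0(prefix, ".graphml")),
    sif = file.path(outdir, paste0(prefix, ".sif"))
  )
  write_tsv_table(net$nodes, paths[["nodes"]])
  write_tsv_table(net$edges, paths[["edges"]])
  if (nrow(net$nodes) > 0L) {
    igraph::write_graph(as_igraph(net), paths[["graphml"]], format = "graphml")
  } else {
    writeLines(character(), paths[["graphml"]])
  }
  sif <- if (nrow(net$edges)) {
    paste(net$edges$from, net$edges$edge_type, net$edges$to, sep = "\t")
  } else character()
  writeLines(sif, paths[["sif"]])
  invisible(paths)
}
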