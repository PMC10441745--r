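#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [sim_config()] fields under `simulation:` plus optional
#' per-stage thresholds under `thresholds:` (`fc_threshold`, `p_de`,
#' `p_enrich`, `ppi_score`). Missing fields take the package defaults.
#'
#' @param path YAML file path.
#' @return list with elements `simulation` (a `sim_config`) and `thresholds`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$simulation %||% list())
  thr <- raw$thresholds %||% list()
  list(simulation = sim,
       thresholds = list(
         fc_threshold = thr$fc_threshold %||% 2,
         p_de = thr$p_de %||% 0.05,
         p_enrich = thr$p_enrich %||% 0.05,
         ppi_score = thr$ppi_score %||% 0.4
       ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full exosomal ceRNA biomarker pipeline
#'
#' Orchestrates simulate -> differential expression -> directional ceRNA
#' networks (both polarities) -> clinical partial correlation -> enrichment
#' -> PPI hub ranking -> ROC diagnostics, writing each stage's tables to a
#' run directory along with a machine-readable manifest. Any stage failure
#' aborts with the stage name; partial outputs are retained next to a
#' `FAILED` marker file naming the stage.
#'
#' @param config a `sim_config`, a YAML path for [load_config()], or a list
#'   as returned by [load_config()].
#' @param outdir run directory (created).
#' @param seed optional integer overriding the config seed.
#' @param max_roc_triplets cap on the number of triplet axes scored by ROC
#'   (default 25, smallest-first by lncRNA/miRNA/mRNA id order).
#' @return invisibly, a list with the in-memory stage results (`study`,
#'   `de`, `networks`, `correlations`, `enrichment`, `hubs`, `roc`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = NULL,
                         max_roc_triplets = 25L) {
  if (is.character(config)) config <- load_config(config)
  if (inherits(config, "sim_config")) {
    config <- list(simulation = config,
                   thresholds = list(fc_threshold = 2, p_de = 0.05,
                                     p_enrich = 0.05, ppi_score = 0.4))
  }
  sim <- config$simulation
  thr <- config$thresholds
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- "simulate"
  res <- list()
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\nerror: ", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    study <- simulate_study(sim)
    write_study(study, file.path(outdir, "inputs"))
    res$study <- study

    stage <- "de"
    de <- compute_de(study, fc_threshold = thr$fc_threshold,
                     p_threshold = thr$p_de)
    write_tsv_table(de, file.path(outdir, "de_table.tsv"))
    volcano <- de[, c("feature_id", "rna_class", "log2fc", "p_value",
                      "direction")]
    write_tsv_table(volcano, file.path(outdir, "volcano.tsv"))
    res$de <- de

    stage <- "network"
    sets <- split_directions(de)
    nets <- list(up_mir = build_cerna_network(sets, study$targets, "up_mir"),
                 down_mir = build_cerna_network(sets, study$targets,
                                                "down_mir"))
    for (pol in names(nets)) {
      export_network(nets[[pol]], file.path(outdir, "network"),
                     prefix = paste0("cerna_", pol))
    }
    res$networks <- nets

    stage <- "correlate"
    corr <- do.call(rbind, lapply(nets, function(nw) {
      correlate_network_features(nw, study)
    }))
    corr <- corr[!duplicated(corr[, c("feature_id", "score")]), , drop = FALSE]
    rownames(corr) <- NULL
    write_tsv_table(corr, file.path(outdir, "clinical_correlation.tsv"))
    res$correlations <- corr

    stage <- "enrich"
    net_mrnas <- unique(unlist(lapply(nets, function(nw) {
      nw$nodes$id[nw$nodes$rna_class == "mrna"]
    })))
    universe <- rownames(study$expression$mrna)
    enr <- if (length(net_mrnas)) {
      ora(net_mrnas, study$annotations, universe)
    } else {
      ora(universe[1L], study$annotations, universe)[0L, ]
    }
    write_tsv_table(enr, file.path(outdir, "enrichment.tsv"))
    res$enrichment <- enr

    stage <- "ppi"
    g <- induce_ppi_subgraph(net_mrnas, study$ppi,
                             threshold = thr$ppi_score)
    hubs <- hub_genes(g, top_k = 10L)
    write_tsv_table(hubs, file.path(outdir, "ppi_hubs.tsv"))
    res$hubs <- hubs

    stage <- "roc"
    trips <- do.call(rbind, lapply(nets, extract_triplets))
    trips <- unique(trips)
    if (nrow(trips) > max_roc_triplets) {
      trips <- trips[order(trips$lncrna, trips$mirna, trips$mrna), ]
      trips <- trips[seq_len(max_roc_triplets), , drop = FALSE]
    }
    roc <- compare_markers(study, trips)
    write_tsv_table(roc, file.path(outdir, "roc_auc.tsv"))
    res$roc <- roc

    stage <- "manifest"
    manifest <- list(
      package = "exocerna",
      version = as.character(utils::packageVersion("exocerna")),
      seed = sim$seed,
      config = unclass(sim),
      thresholds = thr,
      config_hash = .config_hash(sim, thr),
      stages = list(
        inputs = "inputs/", de = "de_table.tsv", volcano = "volcano.tsv",
        network = "network/", correlation = "clinical_correlation.tsv",
        enrichment = "enrichment.tsv", ppi = "ppi_hubs.tsv",
        roc = "roc_auc.tsv"
      )
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
  }, error = on_fail)
  invisible(res)
}

# order-stable hash of the effective configuration, with no digest
# dependency: sum over serialized bytes in two weighted passes
.config_hash <- function(sim, thr) {
  bytes <- as.integer(serialize(list(unclass(sim)[order(names(sim))],
                                     thr[order(names(thr))]),
                                connection = NULL, version = 2L))
  w1 <- sum(bytes * (seq_along(bytes) %% 251)) %% 1e9
  w2 <- sum(bytes * (seq_along(bytes) %% 241)) %% 1e9
  sprintf("%09d%09d", w1, w2)
}
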