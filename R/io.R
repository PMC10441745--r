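#' Write a simulated study to disk as plain-text pipeline inputs
#'
#' Emits the five input families the pipeline consumes: one expression TSV
#' per RNA class (first column `feature_id`, remaining columns sample ids),
#' a clinical metadata TSV, two target-pair TSVs (`mirna_id`, `target_id`),
#' a GMT annotation file and a scored PPI TSV. All files are UTF-8 and
#' tab-delimited with header rows (GMT excepted, per the format).
#'
#' @param study a `cerna_study` from [simulate_study()].
#' @param outdir output directory; created if missing.
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "cerna_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    lncrna = file.path(outdir, "expression_lncrna.tsv"),
    mirna = file.path(outdir, "expression_mirna.tsv"),
    mrna = file.path(outdir, "expression_mrna.tsv"),
    clinical = file.path(outdir, "clinical.tsv"),
    mir_to_lnc = file.path(outdir, "targets_mir_to_lnc.tsv"),
    mir_to_mrna = file.path(outdir, "targets_mir_to_mrna.tsv"),
    annotations = file.path(outdir, "annotations.gmt"),
    ppi = file.path(outdir, "ppi.tsv")
  )
  for (cl in c("lncrna", "mirna", "mrna")) {
    write_expression_tsv(study$expression[[cl]], paths[[cl]])
  }
  write_tsv_table(study$clinical, paths[["clinical"]])
  write_tsv_table(study$targets$mir_to_lnc, paths[["mir_to_lnc"]])
  write_tsv_table(study$targets$mir_to_mrna, paths[["mir_to_mrna"]])
  write_gmt(study$annotations, paths[["annotations"]])
  write_tsv_table(study$ppi, paths[["ppi"]])
  invisible(paths)
}

#' @rdname write_study
#' @param mat feature-by-sample numeric matrix with feature ids as rownames.
#' @param path file path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
}

#' Read a feature-by-sample expression TSV
#'
#' First column is the feature id; remaining columns are samples.
#' @param path file path.
#' @return numeric matrix with feature ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  mat
}

#' Read and write GMT gene-set files
#'
#' The GMT format is one tab-separated line per term: term id, description,
#' then member gene ids. [write_gmt()] takes a named list of character
#' vectors; descriptions default to the term name.
#'
#' @param path file path.
#' @param sets named list of gene-id character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @return [read_gmt()]: a named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
}

#' Read pipeline input tables
#'
#' `read_targets_tsv` expects columns `mirna_id` and `target_id`;
#' `read_ppi_tsv` expects `gene_a`, `gene_b`, `score`; `read_clinical_tsv`
#' expects the clinical metadata layout written by [write_study()].
#' @param path file path.
#' @return a data frame.
#' @export
read_targets_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mirna_id", "target_id") %in% names(df)))
  unique(df[, c("mirna_id", "target_id")])
}

#' @rdname read_targets_tsv
#' @export
read_ppi_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(df)))
  df
}

#' @rdname read_targets_tsv
#' @export
read_clinical_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
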