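#' Simulation configuration for a planted ceRNA study
#'
#' Builds and validates the configuration object consumed by
#' [simulate_study()]. Defaults emulate a small two-arm plasma-exosome
#' case/control design (10 cases vs 10 controls) with a handful of planted
#' competing-endogenous-RNA (ceRNA) triplets: for each triplet the miRNA is
#' shifted down in cases while its partner lncRNA and mRNA are shifted up by
#' the same log2 magnitude, the sponge signature the downstream network
#' construction is designed to recover.
#'
#' @param n_per_group samples per arm (cases and controls each).
#' @param n_lncrna,n_mirna,n_mrna feature counts per RNA class.
#' @param n_triplets number of planted ceRNA axes (one lncRNA, one miRNA,
#'   one mRNA each); must not exceed the smallest class size.
#' @param planted_log2fc magnitude of the case-vs-control shift on the log2
#'   scale for planted features. The miRNA of each triplet is shifted by
#'   `-planted_log2fc`, its lncRNA and mRNA partners by `+planted_log2fc`.
#' @param noise_sigma standard deviation of per-observation Gaussian noise on
#'   the log2 scale; must be positive.
#' @param background_target_density probability that a random (non-planted)
#'   miRNA-lncRNA or miRNA-mRNA target edge is emitted.
#' @param clinical_link_r target Pearson correlation, within cases, between
#'   clinically linked planted features (the planted lncRNAs and mRNAs) and
#'   the total PANSS severity score.
#' @param n_terms,genes_per_term shape of the synthetic annotation (GMT)
#'   collection; the first term concentrates the planted mRNAs.
#' @param ppi_density probability of a background protein-protein interaction
#'   edge between two mRNA-encoded proteins.
#' @param ppi_score_range length-2 numeric range for background PPI
#'   confidence scores (planted mRNAs are wired as a high-confidence clique).
#' @param seed integer random seed; identical config + seed gives
#'   byte-identical simulated files.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_study()], [write_study()]
#' @export
sim_config <- function(n_per_group = 10,
                       n_lncrna = 60,
                       n_mirna = 30,
                       n_mrna = 120,
                       n_triplets = 5,
                       planted_log2fc = 2,
                       noise_sigma = 0.5,
                       background_target_density = 0.02,
                       clinical_link_r = 0.8,
                       n_terms = 20,
                       genes_per_term = 15,
                       ppi_density = 0.05,
                       ppi_score_range = c(0.1, 0.95),
                       seed = 1L) {
  cfg <- list(
    n_per_group = n_per_group, n_lncrna = n_lncrna, n_mirna = n_mirna,
    n_mrna = n_mrna, n_triplets = n_triplets,
    planted_log2fc = planted_log2fc, noise_sigma = noise_sigma,
    background_target_density = background_target_density,
    clinical_link_r = clinical_link_r, n_terms = n_terms,
    genes_per_term = genes_per_term, ppi_density = ppi_density,
    ppi_score_range = ppi_score_range, seed = as.integer(seed)
  )
  stop_field <- function(field, msg) {
    stop("invalid simulation config: field '", field, "' ", msg, call. = FALSE)
  }
  for (f in c("n_per_group", "n_lncrna", "n_mirna", "n_mrna")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 2 || v != round(v)) {
      stop_field(f, "must be an integer >= 2")
    }
  }
  if (!is.numeric(cfg$n_triplets) || cfg$n_triplets < 0 ||
      cfg$n_triplets != round(cfg$n_triplets)) {
    stop_field("n_triplets", "must be a non-negative integer")
  }
  if (cfg$n_triplets > min(cfg$n_lncrna, cfg$n_mirna, cfg$n_mrna)) {
    stop_field("n_triplets", "exceeds the smallest feature-class size")
  }
  if (!is.numeric(cfg$noise_sigma) || cfg$noise_sigma <= 0) {
    stop_field("noise_sigma", "must be > 0")
  }
  for (f in c("background_target_density", "clinical_link_r", "ppi_density")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop_field(f, "must lie in [0, 1]")
    }
  }
  if (!is.numeric(cfg$planted_log2fc) || length(cfg$planted_log2fc) != 1L) {
    stop_field("planted_log2fc", "must be a single number")
  }
  if (length(cfg$ppi_score_range) != 2L ||
      any(cfg$ppi_score_range < 0) || any(cfg$ppi_score_range > 1) ||
      diff(cfg$ppi_score_range) < 0) {
    stop_field("ppi_score_range", "must be an increasing pair within [0, 1]")
  }
  for (f in c("n_terms", "genes_per_term")) {
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      stop_field(f, "must be a positive integer")
    }
  }
  if (is.na(cfg$seed)) stop_field("seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ceRNA simulation config:",
      x$n_per_group, "samples/arm;",
      x$n_lncrna, "lncRNA,", x$n_mirna, "miRNA,", x$n_mrna, "mRNA;",
      x$n_triplets, "planted triplets (|log2FC| =", x$planted_log2fc,
      ", sigma =", x$noise_sigma, "); seed", x$seed, "\n")
  invisible(x)
}

# PANSS subscore calibration: shared latent severity factor z drives the
# three subscales so that totals centre near 75.6 with SD ~18.6 and the
# subscale floors (7/7/16) are respected.
.panss_params <- list(
  mu = c(positive = 19, negative = 20, general = 36.6),
  load = c(positive = 4.2, negative = 4.4, general = 8.0),
  resid_sd = c(positive = 4, negative = 4, general = 6),
  floor = c(positive = 7, negative = 7, general = 16)
)

.simulate_clinical <- function(cfg) {
  n <- cfg$n_per_group
  n_all <- 2L * n
  sample_id <- c(sprintf("case_%02d", seq_len(n)),
                 sprintf("control_%02d", seq_len(n)))
  group <- rep(c("case", "control"), each = n)
  age <- pmax(18, round(stats::rnorm(n_all, mean = 34, sd = 12)))
  education <- pmax(1, round(stats::rnorm(n_all, mean = 10.4, sd = 3.4)))
  # balanced sex per arm (coded 0/1)
  half <- function(k) sample(rep(c(0L, 1L), length.out = k))
  sex <- c(half(n), half(n))

  z <- stats::rnorm(n)  # latent severity, cases only
  pp <- .panss_params
  sub <- sapply(names(pp$mu), function(s) {
    raw <- pp$mu[[s]] + pp$load[[s]] * z +
      stats::rnorm(n, sd = pp$resid_sd[[s]])
    pmax(pp$floor[[s]], round(raw))
  })
  clinical <- data.frame(
    sample_id = sample_id, group = group, age = age, sex = sex,
    education = education,
    panss_positive = c(sub[, "positive"], rep(NA_real_, n)),
    panss_negative = c(sub[, "negative"], rep(NA_real_, n)),
    panss_general = c(sub[, "general"], rep(NA_real_, n)),
    stringsAsFactors = FALSE
  )
  clinical$panss_total <- clinical$panss_positive +
    clinical$panss_negative + clinical$panss_general
  list(clinical = clinical, latent = z)
}

.simulate_class <- function(ids, n_case, n_control, shift, linked,
                            severity_std, cfg) {
  n_feat <- length(ids)
  n_all <- n_case + n_control
  base <- stats::runif(n_feat, min = 5, max = 10)
  log2x <- matrix(base, nrow = n_feat, ncol = n_all) +
    matrix(stats::rnorm(n_feat * n_all, sd = cfg$noise_sigma),
           nrow = n_feat)
  case_cols <- seq_len(n_case)
  log2x[, case_cols] <- log2x[, case_cols] + shift
  # clinically linked features: replace case-sample noise with a mixture
  # correlated with the standardized PANSS total at clinical_link_r
  # (marginal SD stays noise_sigma, so DE behaviour is unchanged)
  r <- cfg$clinical_link_r
  for (i in which(linked)) {
    eps <- stats::rnorm(n_case)
    log2x[i, case_cols] <- base[i] + shift[i] +
      cfg$noise_sigma * (r * severity_std + sqrt(1 - r^2) * eps)
  }
  x <- 2^log2x
  rownames(x) <- ids
  x
}

.simulate_targets <- function(mirna_ids, partner_ids, planted_pairs, density) {
  grid <- expand.grid(mirna_id = mirna_ids, target_id = partner_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < density
  bg <- grid[keep, , drop = FALSE]
  out <- unique(rbind(planted_pairs, bg))
  rownames(out) <- NULL
  out
}

#' Simulate a complete planted ceRNA study
#'
#' Generates every input the pipeline consumes — per-class expression tables,
#' sample metadata with PANSS scores, miRNA target tables, annotation sets
#' and a scored PPI edge list — with known ground truth: `n_triplets`
#' lncRNA-miRNA-mRNA axes in which the miRNA moves opposite to its partners
#' between cases and controls, planted target/PPI edges linking them, one
#' annotation term concentrating the planted mRNAs, and planted lncRNAs and
#' mRNAs whose case-sample expression tracks the total PANSS score.
#'
#' Abundances are log-normal: Gaussian on the log2 scale around a per-feature
#' baseline, exponentiated, so the downstream t-tests on log2 values meet
#' their normality assumption. Emitted values are already-normalized
#' abundances; no count model or library-size step is simulated.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `cerna_study` with elements `expression` (named
#'   list of lncrna/mirna/mrna feature-by-sample matrices), `samples`,
#'   `group`, `clinical`, `targets` (`mir_to_lnc`, `mir_to_mrna` data frames),
#'   `annotations` (named list of gene-id vectors), `ppi` (gene_a, gene_b,
#'   score), `truth` (planted triplets, linked feature ids, enriched term)
#'   and `config`.
#' @examples
#' study <- simulate_study(sim_config(seed = 42))
#' names(study$expression)
#' study$truth$triplets
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_per_group

  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
  mir_ids <- sprintf("MIR%04d", seq_len(config$n_mirna))
  mrna_ids <- sprintf("GENE%04d", seq_len(config$n_mrna))

  k <- config$n_triplets
  triplets <- data.frame(
    lncrna = lnc_ids[seq_len(k)], mirna = mir_ids[seq_len(k)],
    mrna = mrna_ids[seq_len(k)], stringsAsFactors = FALSE
  )

  clin <- .simulate_clinical(config)
  clinical <- clin$clinical
  total <- clinical$panss_total[seq_len(n)]
  severity_std <- as.numeric(scale(total))
  if (any(!is.finite(severity_std))) severity_std <- rep(0, n)

  fc <- config$planted_log2fc
  shift_for <- function(ids, planted, sign) {
    s <- numeric(length(ids))
    s[ids %in% planted] <- sign * fc
    s
  }
  linked_lnc <- lnc_ids %in% triplets$lncrna
  linked_mrna <- mrna_ids %in% triplets$mrna
  expression <- list(
    lncrna = .simulate_class(lnc_ids, n, n, shift_for(lnc_ids, triplets$lncrna, +1),
                             linked_lnc, severity_std, config),
    mirna = .simulate_class(mir_ids, n, n, shift_for(mir_ids, triplets$mirna, -1),
                            rep(FALSE, length(mir_ids)), severity_std, config),
    mrna = .simulate_class(mrna_ids, n, n, shift_for(mrna_ids, triplets$mrna, +1),
                           linked_mrna, severity_std, config)
  )
  sample_id <- clinical$sample_id
  for (cl in names(expression)) colnames(expression[[cl]]) <- sample_id

  targets <- list(
    mir_to_lnc = .simulate_targets(
      mir_ids, lnc_ids,
      data.frame(mirna_id = triplets$mirna, target_id = triplets$lncrna,
                 stringsAsFactors = FALSE),
      config$background_target_density),
    mir_to_mrna = .simulate_targets(
      mir_ids, mrna_ids,
      data.frame(mirna_id = triplets$mirna, target_id = triplets$mrna,
                 stringsAsFactors = FALSE),
      config$background_target_density)
  )

  annotations <- vector("list", config$n_terms)
  names(annotations) <- sprintf("TERM%03d", seq_len(config$n_terms))
  fill_n <- max(0L, config$genes_per_term - k)
  pool <- setdiff(mrna_ids, triplets$mrna)
  annotations[[1L]] <- c(triplets$mrna,
                         sample(pool, min(fill_n, length(pool))))
  for (t in seq_len(config$n_terms)[-1L]) {
    annotations[[t]] <- sample(mrna_ids,
                               min(config$genes_per_term, length(mrna_ids)))
  }

  # background PPI plus a high-confidence clique over planted mRNAs
  pairs <- t(utils::combn(mrna_ids, 2L))
  keep <- stats::runif(nrow(pairs)) < config$ppi_density
  ppi <- data.frame(gene_a = pairs[keep, 1L], gene_b = pairs[keep, 2L],
                    score = stats::runif(sum(keep),
                                         config$ppi_score_range[1L],
                                         config$ppi_score_range[2L]),
                    stringsAsFactors = FALSE)
  if (k >= 2L) {
    cl_pairs <- t(utils::combn(triplets$mrna, 2L))
    clique <- data.frame(gene_a = cl_pairs[, 1L], gene_b = cl_pairs[, 2L],
                         score = stats::runif(nrow(cl_pairs), 0.6, 0.95),
                         stringsAsFactors = FALSE)
    ppi <- rbind(ppi[!(paste(ppi$gene_a, ppi$gene_b) %in%
                         paste(clique$gene_a, clique$gene_b)), ], clique)
    rownames(ppi) <- NULL
  }

  structure(list(
    expression = expression, samples = sample_id,
    group = clinical$group, clinical = clinical, targets = targets,
    annotations = annotations, ppi = ppi,
    truth = list(triplets = triplets,
                 linked_features = c(triplets$lncrna, triplets$mrna),
                 enriched_term = names(annotations)[1L]),
    config = config
  ), class = "cerna_study")
}

#' @export
print.cerna_study <- function(x, ...) {
  cat("Simulated ceRNA study:", length(x$samples), "samples (",
      sum(x$group == "case"), "case /", sum(x$group == "control"),
      "control );", nrow(x$truth$triplets), "planted triplets\n")
  cat("  features:", nrow(x$expression$lncrna), "lncRNA,",
      nrow(x$expression$mirna), "miRNA,", nrow(x$expression$mrna), "mRNA\n")
  cat("  target pairs:", nrow(x$targets$mir_to_lnc), "miRNA-lncRNA,",
      nrow(x$targets$mir_to_mrna), "miRNA-mRNA;",
      nrow(x$ppi), "PPI edges;", length(x$annotations), "annotation terms\n")
  invisible(x)
}
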