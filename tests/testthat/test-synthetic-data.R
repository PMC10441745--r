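small_cfg <- function(...) {
  sim_config(n_lncrna = 8, n_mirna = 6, n_mrna = 12, n_triplets = 2, ...)
}

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_study(small_cfg(seed = 11))
  s2 <- simulate_study(small_cfg(seed = 11))
  expect_identical(s1, s2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_study(s1, d1)
  p2 <- write_study(s2, d2)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[[i]]), readLines(p2[[i]]))
  }
  s3 <- simulate_study(small_cfg(seed = 12))
  expect_false(identical(s1$expression$mrna, s3$expression$mrna))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(noise_sigma = 0), "noise_sigma")
  expect_error(sim_config(n_triplets = 100), "n_triplets")
  expect_error(sim_config(background_target_density = 1.5),
               "background_target_density")
  expect_error(sim_config(clinical_link_r = -0.1), "clinical_link_r")
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(ppi_score_range = c(0.9, 0.1)), "ppi_score_range")
})

test_that("planted features shift by the configured log2 fold change", {
  cfg <- small_cfg(seed = 3, planted_log2fc = 2, noise_sigma = 0.5)
  st <- simulate_study(cfg)
  case <- st$group == "case"
  lfc <- function(mat, id) {
    mean(log2(mat[id, case])) - mean(log2(mat[id, !case]))
  }
  tol <- 3 * cfg$noise_sigma / sqrt(cfg$n_per_group)
  tr <- st$truth$triplets
  for (i in seq_len(nrow(tr))) {
    expect_lt(abs(lfc(st$expression$lncrna, tr$lncrna[i]) - 2), tol)
    expect_lt(abs(lfc(st$expression$mirna, tr$mirna[i]) + 2), tol)
    expect_lt(abs(lfc(st$expression$mrna, tr$mrna[i]) - 2), tol)
  }
})

test_that("planted log2FC recovery holds for >=95% of planted features over 100 seeds", {
  hits <- 0L; total <- 0L
  for (seed in 1:100) {
    cfg <- small_cfg(seed = seed)
    st <- simulate_study(cfg)
    case <- st$group == "case"
    tol <- 3 * cfg$noise_sigma / sqrt(cfg$n_per_group)
    tr <- st$truth$triplets
    obs <- c(
      vapply(tr$lncrna, function(id) {
        mean(log2(st$expression$lncrna[id, case])) -
          mean(log2(st$expression$lncrna[id, !case])) - cfg$planted_log2fc
      }, numeric(1)),
      vapply(tr$mirna, function(id) {
        mean(log2(st$expression$mirna[id, case])) -
          mean(log2(st$expression$mirna[id, !case])) + cfg$planted_log2fc
      }, numeric(1)),
      vapply(tr$mrna, function(id) {
        mean(log2(st$expression$mrna[id, case])) -
          mean(log2(st$expression$mrna[id, !case])) - cfg$planted_log2fc
      }, numeric(1))
    )
    hits <- hits + sum(abs(obs) < tol)
    total <- total + length(obs)
  }
  expect_gte(hits / total, 0.95)
})

test_that("structural contracts hold: targets, PANSS, clinical table, PPI, GMT", {
  st <- simulate_study(small_cfg(seed = 5))
  tr <- st$truth$triplets
  # planted target edges present
  key_l <- paste(st$targets$mir_to_lnc$mirna_id, st$targets$mir_to_lnc$target_id)
  key_g <- paste(st$targets$mir_to_mrna$mirna_id, st$targets$mir_to_mrna$target_id)
  expect_true(all(paste(tr$mirna, tr$lncrna) %in% key_l))
  expect_true(all(paste(tr$mirna, tr$mrna) %in% key_g))
  expect_false(any(duplicated(key_l)))

  cl <- st$clinical
  case <- cl$group == "case"
  expect_equal(cl$panss_total[case],
               cl$panss_positive[case] + cl$panss_negative[case] +
                 cl$panss_general[case])
  expect_true(all(is.na(cl$panss_total[!case])))
  expect_true(all(cl$age > 0) && all(cl$education > 0))
  expect_true(all(cl$sex %in% 0:1))
  expect_equal(sum(cl$sex[case]), sum(cl$sex[!case]))  # balanced arms
  expect_identical(cl$sample_id, st$samples)
  for (m in st$expression) expect_identical(colnames(m), st$samples)
  expect_true(all(vapply(st$expression, function(m) all(m >= 0), logical(1))))

  # feature ids disjoint across classes
  ids <- lapply(st$expression, rownames)
  expect_equal(length(unique(unlist(ids))), sum(lengths(ids)))

  # first annotation term concentrates the planted mRNAs
  expect_true(all(tr$mrna %in% st$annotations[[st$truth$enriched_term]]))
  # planted mRNAs wired above the 0.4 PPI threshold
  planted_ppi <- st$ppi[st$ppi$gene_a %in% tr$mrna &
                          st$ppi$gene_b %in% tr$mrna, ]
  expect_true(all(planted_ppi$score > 0.4))
  expect_true(all(st$ppi$score >= 0 & st$ppi$score <= 1))
})

test_that("PANSS totals and the clinical link are calibrated", {
  totals <- unlist(lapply(1:60, function(seed) {
    st <- simulate_study(sim_config(n_lncrna = 3, n_mirna = 3, n_mrna = 3,
                                    n_triplets = 1, seed = seed))
    st$clinical$panss_total[st$clinical$group == "case"]
  }))
  expect_lt(abs(mean(totals) - 75.6), 3)
  expect_lt(abs(sd(totals) - 18.6), 4)

  # linked features correlate with the PANSS total near clinical_link_r
  rs <- vapply(1:60, function(seed) {
    st <- simulate_study(small_cfg(seed = seed, clinical_link_r = 0.8))
    case <- st$group == "case"
    id <- st$truth$triplets$lncrna[1]
    cor(log2(st$expression$lncrna[id, case]),
        st$clinical$panss_total[case])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.1)
})

test_that("round-trip through the plain-text writers preserves the study", {
  st <- simulate_study(small_cfg(seed = 9))
  d <- withr::local_tempdir()
  paths <- write_study(st, d)
  mat <- read_expression_tsv(paths[["mrna"]])
  expect_equal(mat, st$expression$mrna, tolerance = 1e-12)
  expect_equal(read_targets_tsv(paths[["mir_to_lnc"]]),
               st$targets$mir_to_lnc)
  gmt <- read_gmt(paths[["annotations"]])
  expect_identical(names(gmt), names(st$annotations))
  expect_identical(gmt[[1]], st$annotations[[1]])
  clin <- read_clinical_tsv(paths[["clinical"]])
  expect_equal(clin$panss_total, st$clinical$panss_total)
  ppi <- read_ppi_tsv(paths[["ppi"]])
  expect_equal(ppi$score, st$ppi$score, tolerance = 1e-10)
})
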