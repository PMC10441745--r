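toy_instance <- function() {
  list(
    de_sets = list(
      lncrna = list(up = character(), down = c("L1", "L2")),
      mirna = list(up = c("m1", "m2", "m3"), down = character()),
      mrna = list(up = character(), down = c("G1", "G2", "G3"))
    ),
    tables = list(
      mir_to_lnc = data.frame(mirna_id = c("m1", "m2", "m3"),
                              target_id = c("L1", "L2", "Lx"),
                              stringsAsFactors = FALSE),
      mir_to_mrna = data.frame(mirna_id = c("m1", "m1", "m2", "m3"),
                               target_id = c("G1", "G2", "G9", "G3"),
                               stringsAsFactors = FALSE)
    )
  )
}

test_that("set primitives match direct lookups", {
  tab <- data.frame(mirna_id = c("m1", "m1", "m2"),
                    target_id = c("L1", "L2", "L3"))
  expect_setequal(targets_of("m1", tab), c("L1", "L2"))
  expect_length(targets_of(character(), tab), 0)
  expect_setequal(overlap_with_de(c("a", "b"), c("b", "c")), "b")
  expect_length(overlap_with_de(c("a"), c("b")), 0)
  expect_setequal(reverse_identify("L1", tab, c("m1", "m2")), "m1")
  expect_length(reverse_identify(character(), tab, c("m1", "m2")), 0)

  set.seed(501)
  for (i in 1:50) {
    inst <- random_cerna_instance()
    pool <- unlist(inst$de_sets$mirna)
    if (length(pool) < 1) next
    mirs <- sample(pool, min(3, length(pool)))
    tab <- inst$tables$mir_to_lnc
    # brute-force scan over all pairs
    expect_setequal(targets_of(mirs, tab),
                    unique(tab$target_id[tab$mirna_id %in% mirs]))
    ov <- sample(unique(tab$target_id), min(3, length(unique(tab$target_id))))
    brute_rev <- mirs[vapply(mirs, function(m) {
      any(tab$mirna_id == m & tab$target_id %in% ov)
    }, logical(1))]
    expect_setequal(reverse_identify(ov, tab, mirs), brute_rev)
  }
})

test_that("the hand-traceable toy network is built exactly", {
  inst <- toy_instance()
  net <- build_cerna_network(inst$de_sets, inst$tables, "up_mir")
  expect_setequal(net$nodes$id, c("m1", "L1", "G1", "G2"))
  expect_equal(nrow(net$edges), 3)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("L1 m1", "m1 G1", "m1 G2"))
  deg <- setNames(net$nodes$degree, net$nodes$id)
  expect_equal(deg[["m1"]], 3)
  expect_equal(unname(deg[c("L1", "G1", "G2")]), c(1, 1, 1))
  # direction consistency
  expect_true(all(net$nodes$direction[net$nodes$rna_class == "mirna"] == "up"))
  expect_true(all(net$nodes$direction[net$nodes$rna_class != "mirna"] == "down"))

  trips <- extract_triplets(net)
  expect_equal(nrow(trips), 2)
  expect_setequal(paste(trips$lncrna, trips$mirna, trips$mrna),
                  c("L1 m1 G1", "L1 m1 G2"))

  s <- network_summary(net)
  expect_equal(c(s$n_lncrna, s$n_mirna, s$n_mrna, s$n_edges), c(1, 1, 2, 3))
  expect_equal(sum(net$nodes$degree), 2 * s$n_edges)
})

test_that("an empty miRNA intersection yields an empty network", {
  inst <- toy_instance()
  inst$tables$mir_to_mrna <- inst$tables$mir_to_mrna[3, , drop = FALSE]  # only m2->G9
  net <- build_cerna_network(inst$de_sets, inst$tables, "up_mir")
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(extract_triplets(net)), 0)
  s <- network_summary(net)
  expect_equal(c(s$n_lncrna, s$n_mirna, s$n_mrna, s$n_edges, s$n_triplets),
               rep(0, 5))
})

test_that("construction matches brute-force triple enumeration on random instances", {
  set.seed(502)
  for (i in 1:150) {
    inst <- random_cerna_instance(n_lnc = sample(3:8, 1),
                                  n_mir = sample(3:6, 1),
                                  n_mrna = sample(3:10, 1),
                                  density = runif(1, 0.1, 0.5))
    for (pol in c("up_mir", "down_mir")) {
      net <- build_cerna_network(inst$de_sets, inst$tables, pol)
      oracle <- brute_cerna(inst$de_sets, inst$tables, pol)
      expect_true(cerna_matches_bruteforce(net, oracle))
      # structural invariants
      expect_true(all(net$nodes$degree >= 1) || nrow(net$nodes) == 0)
      expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
      cls <- setNames(net$nodes$rna_class, net$nodes$id)
      if (nrow(net$edges)) {
        lm <- net$edges$edge_type == "lncrna-mirna"
        expect_true(all(cls[net$edges$from[lm]] == "lncrna"))
        expect_true(all(cls[net$edges$to[lm]] == "mirna"))
        expect_true(all(cls[net$edges$from[!lm]] == "mirna"))
        expect_true(all(cls[net$edges$to[!lm]] == "mrna"))
        # every edge comes from the input tables
        in_tab <- c(paste(inst$tables$mir_to_lnc$target_id,
                          inst$tables$mir_to_lnc$mirna_id),
                    paste(inst$tables$mir_to_mrna$mirna_id,
                          inst$tables$mir_to_mrna$target_id))
        expect_true(all(paste(net$edges$from, net$edges$to) %in% in_tab))
      }
      # triplet count identity: sum over miRNAs of lnc-degree x mrna-degree
      trips <- extract_triplets(net)
      expect_setequal(paste(trips$lncrna, trips$mirna, trips$mrna),
                      oracle$triplets %||% character(0))
    }
  }
})

test_that("adding a target pair never removes a node (monotonicity)", {
  set.seed(503)
  for (i in 1:40) {
    inst <- random_cerna_instance()
    net1 <- build_cerna_network(inst$de_sets, inst$tables, "up_mir")
    extra <- data.frame(
      mirna_id = sample(unlist(inst$de_sets$mirna), 1),
      target_id = sample(unlist(inst$de_sets$lncrna), 1),
      stringsAsFactors = FALSE)
    inst$tables$mir_to_lnc <- unique(rbind(inst$tables$mir_to_lnc, extra))
    net2 <- build_cerna_network(inst$de_sets, inst$tables, "up_mir")
    expect_true(all(net1$nodes$id %in% net2$nodes$id))
  }
})

test_that("id collisions across classes and duplicate pairs are handled", {
  inst <- toy_instance()
  inst$de_sets$mrna$down <- c(inst$de_sets$mrna$down, "L1")
  expect_error(build_cerna_network(inst$de_sets, inst$tables, "up_mir"),
               "collide")
  inst <- toy_instance()
  inst$tables$mir_to_lnc <- rbind(inst$tables$mir_to_lnc,
                                  inst$tables$mir_to_lnc[1, ])
  expect_warning(build_cerna_network(inst$de_sets, inst$tables, "up_mir"),
                 "duplicate")
})

test_that("triplet extraction on a star miRNA gives the degree product", {
  de_sets <- list(
    lncrna = list(up = character(), down = c("L1", "L2")),
    mirna = list(up = "m1", down = character()),
    mrna = list(up = character(), down = c("G1", "G2", "G3"))
  )
  tables <- list(
    mir_to_lnc = data.frame(mirna_id = "m1", target_id = c("L1", "L2")),
    mir_to_mrna = data.frame(mirna_id = "m1", target_id = c("G1", "G2", "G3"))
  )
  net <- build_cerna_network(de_sets, tables, "up_mir")
  expect_equal(nrow(extract_triplets(net)), 6)
})

test_that("network export writes consistent plain-text artifacts", {
  inst <- toy_instance()
  net <- build_cerna_network(inst$de_sets, inst$tables, "up_mir")
  d <- withr::local_tempdir()
  paths <- export_network(net, d)
  expect_true(all(file.exists(paths)))
  nodes <- read.delim(paths[["nodes"]])
  expect_setequal(nodes$id, net$nodes$id)
  sif <- readLines(paths[["sif"]])
  expect_length(sif, nrow(net$edges))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
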