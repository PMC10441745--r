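# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (full enumeration / direct formulas) and share
# no code with the package internals.

# ceRNA network by exhaustive triple enumeration: a (lncRNA, miRNA, mRNA)
# triple is admissible when the miRNA has the right direction, both partners
# have the opposite direction, and both target edges exist. The network is
# the union of admissible triples.
brute_cerna <- function(de_sets, tables, polarity) {
  mir_dir <- if (polarity == "up_mir") "up" else "down"
  partner_dir <- if (polarity == "up_mir") "down" else "up"
  mirs <- de_sets$mirna[[mir_dir]]
  lncs <- de_sets$lncrna[[partner_dir]]
  mrnas <- de_sets$mrna[[partner_dir]]
  has <- function(tab, m, t) any(tab$mirna_id == m & tab$target_id == t)
  triples <- list()
  for (m in mirs) for (L in lncs) for (G in mrnas) {
    if (has(tables$mir_to_lnc, m, L) && has(tables$mir_to_mrna, m, G)) {
      triples[[length(triples) + 1L]] <- c(L, m, G)
    }
  }
  if (!length(triples)) {
    return(list(lncrna = character(), mirna = character(),
                mrna = character(), edges = character()))
  }
  tri <- do.call(rbind, triples)
  edges <- unique(c(paste(tri[, 1], tri[, 2]), paste(tri[, 2], tri[, 3])))
  list(lncrna = sort(unique(tri[, 1])), mirna = sort(unique(tri[, 2])),
       mrna = sort(unique(tri[, 3])), edges = sort(edges),
       triplets = unique(paste(tri[, 1], tri[, 2], tri[, 3])))
}

# random ceRNA instance: feature universes, random direction splits, random
# target tables
random_cerna_instance <- function(n_lnc = 8, n_mir = 6, n_mrna = 10,
                                  density = 0.25) {
  lnc <- sprintf("L%02d", seq_len(n_lnc))
  mir <- sprintf("m%02d", seq_len(n_mir))
  mrna <- sprintf("G%02d", seq_len(n_mrna))
  split2 <- function(ids) {
    lab <- sample(c("up", "down", "none"), length(ids), replace = TRUE)
    list(up = ids[lab == "up"], down = ids[lab == "down"])
  }
  rand_pairs <- function(ms, ts) {
    g <- expand.grid(mirna_id = ms, target_id = ts,
                     stringsAsFactors = FALSE)
    g[runif(nrow(g)) < density, , drop = FALSE]
  }
  list(de_sets = list(lncrna = split2(lnc), mirna = split2(mir),
                      mrna = split2(mrna)),
       tables = list(mir_to_lnc = rand_pairs(mir, lnc),
                     mir_to_mrna = rand_pairs(mir, mrna)))
}

cerna_matches_bruteforce <- function(net, oracle) {
  node_of <- function(cl) sort(net$nodes$id[net$nodes$rna_class == cl])
  isTRUE(all.equal(node_of("lncrna"), oracle$lncrna)) &&
    isTRUE(all.equal(node_of("mirna"), oracle$mirna)) &&
    isTRUE(all.equal(node_of("mrna"), oracle$mrna)) &&
    setequal(paste(net$edges$from, net$edges$to), oracle$edges)
}

# AUC by exhaustive case-control pair counting, ties credited one half
brute_auc <- function(scores, case) {
  s1 <- scores[case]; s0 <- scores[!case]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

# partial correlation by the classical recursion, peeling one covariate at a
# time: r_{xy.z,W} = (r_{xy.W} - r_{xz.W} r_{yz.W}) /
#                    sqrt((1 - r_{xz.W}^2)(1 - r_{yz.W}^2))
recursive_pcor <- function(x, y, covars) {
  vars <- cbind(x = x, y = y, covars)
  pc <- function(i, j, given) {
    if (!length(given)) return(cor(vars[, i], vars[, j]))
    k <- given[length(given)]
    rest <- given[-length(given)]
    rij <- pc(i, j, rest); rik <- pc(i, k, rest); rjk <- pc(j, k, rest)
    (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
  }
  pc(1L, 2L, seq_len(ncol(covars)) + 2L)
}

# partial correlation from the inverse of the full correlation matrix
invmat_pcor <- function(x, y, covars) {
  P <- solve(cor(cbind(x, y, covars)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# hypergeometric upper tail by direct pmf summation from binomial
# coefficients (no phyper)
enum_hyper_p <- function(overlap, term, universe, query) {
  xs <- overlap:min(term, query)
  sum(choose(term, xs) * choose(universe - term, query - xs)) /
    choose(universe, query)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small helper: recovered planted triplets in a network
recovered_triplets <- function(net, truth) {
  key <- function(d) paste(d$lncrna, d$mirna, d$mrna)
  sum(key(truth) %in% key(extract_triplets(net)))
}
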