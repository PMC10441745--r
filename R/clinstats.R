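#' Chi-square test of equal proportions on a 2x2 table
#'
#' Pearson chi-square test of independence, as used for case/control sex
#' comparisons in demographic tables. A zero statistic gives p = 1 whether or
#' not the continuity correction is applied.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param correction apply Yates continuity correction (default `FALSE`).
#' @return list with `chi2`, `p` and `df`.
#' @examples
#' chisq_proportions(matrix(c(5, 5, 5, 5), 2))  # p = 1
#' @export
chisq_proportions <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal total: chi-square undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correction))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the least-squares residuals of `x` and `y`
#' after regressing each on an intercept plus the covariate columns. The
#' p-value comes from t = r * sqrt(df / (1 - r^2)) with df = n - 2 - k on a
#' two-sided t reference, k being the number of covariates. With no
#' covariates this reduces to the plain Pearson correlation test.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix/data frame (n rows, k columns),
#'   full column rank required.
#' @return list with `r`, `p`, `n`, `k` and `df`.
#' @examples
#' n <- 20; age <- rnorm(n); x <- age + rnorm(n); y <- age + rnorm(n)
#' partial_correlation(x, y, cbind(age))
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (is.null(covariates)) {
    Z <- matrix(1, nrow = n, ncol = 1L)
    k <- 0L
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per observation", call. = FALSE)
    }
    k <- ncol(covariates)
    Z <- cbind(`(intercept)` = 1, covariates)
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      bad <- colnames(Z)[qrz$pivot[seq.int(qrz$rank + 1L, ncol(Z))]]
      stop("rank-deficient covariates (collinear: ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  df <- n - 2L - k
  if (df < 1L) stop("need n - 2 - k >= 1 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant x or y: correlation undefined", call. = FALSE)
  }
  rx <- stats::lsfit(Z, x, intercept = FALSE)$residuals
  ry <- stats::lsfit(Z, y, intercept = FALSE)$residuals
  r <- stats::cor(rx, ry)
  r <- max(-1, min(1, r))
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n, k = k, df = df)
}

#' Correlate ceRNA-network features with PANSS severity scores
#'
#' For every feature of the network, computes the partial correlation of its
#' log2 expression with each PANSS subscore (positive, negative, general
#' psychopathology) and the total, controlling for age, sex and education.
#' Computed on case samples only, since controls carry no PANSS scores. Raw
#' p-values drive the `significant` flag (p < 0.05); a Benjamini-Hochberg
#' column over the feature-by-score grid is reported for transparency.
#'
#' @param net a `cerna_network`.
#' @param study a `cerna_study` (or list with `expression`, `group`,
#'   `clinical`).
#' @param pseudocount added before the log2 transform (default 1).
#' @return data frame: `feature_id`, `rna_class`, `score`, `r`, `p`,
#'   `p_adj`, `n`, `k`, `significant`.
#' @export
correlate_network_features <- function(net, study, pseudocount = 1) {
  scores <- c(positive = "panss_positive", negative = "panss_negative",
              general = "panss_general", total = "panss_total")
  empty <- data.frame(feature_id = character(), rna_class = character(),
                      score = character(), r = numeric(), p = numeric(),
                      p_adj = numeric(), n = integer(), k = integer(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (nrow(net$nodes) == 0L) return(empty)

  case <- study$group == "case"
  clin <- study$clinical[case, , drop = FALSE]
  covars <- as.matrix(clin[, c("age", "sex", "education")])

  expr_all <- do.call(rbind, study$expression)
  missing <- setdiff(net$nodes$id, rownames(expr_all))
  if (length(missing)) {
    stop("network features missing from expression tables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(net$nodes)), function(i) {
    fid <- net$nodes$id[i]
    x <- log2(expr_all[fid, case] + pseudocount)
    do.call(rbind, lapply(names(scores), function(s) {
      y <- clin[[scores[[s]]]]
      pc <- partial_correlation(x, y, covars)
      data.frame(feature_id = fid, rna_class = net$nodes$rna_class[i],
                 score = s, r = pc$r, p = pc$p, n = pc$n, k = pc$k,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < 0.05
  out <- out[, c("feature_id", "rna_class", "score", "r", "p", "p_adj",
                 "n", "k", "significant")]
  rownames(out) <- NULL
  out
}
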