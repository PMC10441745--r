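#' Two-sample Student's t-test
#'
#' Pooled-variance Student's t (the default, df = n1 + n2 - 2) or Welch's
#' unequal-variance t, returning the statistic and two-sided p-value.
#'
#' @param x,y numeric vectors for the two groups (each needs >= 2 finite
#'   values).
#' @param pooled if `TRUE` (default) use the pooled-variance Student's t;
#'   otherwise Welch.
#' @return list with `t`, `p` (two-sided) and `df`.
#' @examples
#' ttest_two_sample(rnorm(10, 1), rnorm(10, 0))
#' @export
ttest_two_sample <- function(x, y, pooled = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, p = 1, df = length(x) + length(y) - 2L))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both groups with unequal means: t undefined",
         call. = FALSE)
  }
  ttest_from_summary(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y), pooled = pooled)
}

#' Two-sample t-test from summary statistics
#'
#' Identical contract to [ttest_two_sample()] but computed from group means,
#' standard deviations and sizes, as needed to reproduce demographic-table
#' comparisons reported only as mean +/- SD.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @param pooled pooled-variance Student's t if `TRUE` (default), else Welch.
#' @return list with `t`, `p` (two-sided) and `df`.
#' @examples
#' # age comparison from a demographic table: p ~ 0.9124
#' ttest_from_summary(34.2, 12.01, 10, 33.6, 12.05, 10)$p
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) return(list(t = 0, p = 1, df = n1 + n2 - 2))
    stop("zero variance in both groups with unequal means: t undefined",
         call. = FALSE)
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Per-feature differential expression with a fold-change + p-value gate
#'
#' For every feature of every RNA class, computes the case/control log2 fold
#' change from pseudocount-shifted group means of the raw abundances and a
#' two-sample t-test on log2(value + pseudocount), then applies the
#' conjunctive gate |log2FC| >= log2(`fc_threshold`) AND p <= `p_threshold`
#' (both boundaries inclusive). Features passing the gate are labelled
#' `up` (log2FC positive) or `down`; everything else `none`. A
#' Benjamini-Hochberg adjusted column is reported for transparency but plays
#' no part in the gate, mirroring raw-p filtering practice.
#'
#' @param study a `cerna_study`, or any list with `expression` (named list of
#'   feature-by-sample matrices) and `group` (case/control labels).
#' @param fc_threshold fold-change threshold on the natural scale
#'   (default 2, i.e. |log2FC| >= 1).
#' @param p_threshold p-value threshold (default 0.05, inclusive).
#' @param pseudocount added before log2 transform and to group means
#'   (default 1).
#' @param pooled passed to the t-test (default pooled Student's t).
#' @param log_transform t-test on log2(value + pseudocount) if `TRUE`
#'   (default); on raw values otherwise.
#' @return data frame of class `de_table`: `feature_id`, `rna_class`,
#'   `mean_case`, `mean_control`, `log2fc`, `t`, `p_value`, `p_adj` (BH),
#'   `passes_filter`, `direction`.
#' @examples
#' de <- compute_de(simulate_study(sim_config(seed = 1)))
#' table(de$rna_class, de$direction)
#' @export
compute_de <- function(study, fc_threshold = 2, p_threshold = 0.05,
                       pseudocount = 1, pooled = TRUE, log_transform = TRUE) {
  group <- study$group
  if (length(unique(group)) != 2L || !all(group %in% c("case", "control"))) {
    stop("group labels must contain both 'case' and 'control'", call. = FALSE)
  }
  case <- group == "case"
  if (sum(case) < 2L || sum(!case) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  lfc_cut <- log2(fc_threshold)
  res <- lapply(names(study$expression), function(cl) {
    mat <- study$expression[[cl]]
    xs <- mat[, case, drop = FALSE]
    ys <- mat[, !case, drop = FALSE]
    mean_case <- rowMeans(xs)
    mean_control <- rowMeans(ys)
    log2fc <- log2(mean_case + pseudocount) - log2(mean_control + pseudocount)
    tx <- if (log_transform) log2(xs + pseudocount) else xs
    ty <- if (log_transform) log2(ys + pseudocount) else ys
    tt <- .row_ttest(tx, ty, pooled = pooled)
    data.frame(feature_id = rownames(mat), rna_class = cl,
               mean_case = mean_case, mean_control = mean_control,
               log2fc = log2fc, t = tt$t, p_value = tt$p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  de <- do.call(rbind, res)
  de$p_adj <- stats::ave(de$p_value, de$rna_class,
                         FUN = function(p) stats::p.adjust(p, "BH"))
  de$passes_filter <- abs(de$log2fc) >= lfc_cut & de$p_value <= p_threshold
  de$direction <- ifelse(!de$passes_filter, "none",
                         ifelse(de$log2fc > 0, "up", "down"))
  class(de) <- c("de_table", "data.frame")
  attr(de, "thresholds") <- list(fc_threshold = fc_threshold,
                                 p_threshold = p_threshold,
                                 pseudocount = pseudocount)
  de
}

# vectorized row-wise two-sample t; zero-variance rows get p = 1 when the
# means coincide, otherwise t = +/-Inf, p = 0
.row_ttest <- function(x, y, pooled = TRUE) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (pooled) {
    se <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) *
                 (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  t[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 0,
                          sign(m1 - m2)[degenerate] * Inf)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  list(t = t, p = p)
}

#' Split a differential-expression table into up/down id sets per class
#'
#' @param de a `de_table` from [compute_de()].
#' @return named list (one entry per RNA class) of lists with `up` and
#'   `down` character vectors of feature ids; the two are disjoint and their
#'   union is the class's filtered feature set.
#' @export
split_directions <- function(de) {
  classes <- unique(de$rna_class)
  out <- lapply(classes, function(cl) {
    sub <- de[de$rna_class == cl, ]
    list(up = sub$feature_id[sub$direction == "up"],
         down = sub$feature_id[sub$direction == "down"])
  })
  names(out) <- classes
  out
}
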