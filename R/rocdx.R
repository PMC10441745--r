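#' Empirical AUC by Mann-Whitney pair counting
#'
#' Area under the empirical ROC curve, computed as the Mann-Whitney
#' probability that a randomly chosen case outscores a randomly chosen
#' control, with ties credited one half. Orientation is fixed a priori:
#' higher scores indicate cases, and AUCs below 0.5 are reported as-is,
#' never flipped.
#'
#' @param scores numeric per-sample marker values.
#' @param labels case/control labels (anything with exactly two levels;
#'   `"case"`/`"control"`, logical with `TRUE` = case, or a factor whose
#'   second level is the case).
#' @return the AUC in \[0, 1\].
#' @examples
#' auc_score(c(5, 4, 3, 1), c("case", "case", "control", "control"))
#' @export
auc_score <- function(scores, labels) {
  lab <- .as_case_logical(labels)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- unique(labels)
  if (length(u) != 2L) stop("labels must have exactly two classes",
                            call. = FALSE)
  if (all(u %in% c("case", "control"))) return(labels == "case")
  if (is.factor(labels)) return(labels == levels(labels)[2L])
  labels == sort(u)[2L]
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the unique score values and returns
#' the (false-positive rate, true-positive rate) sequence from (0, 0) to
#' (1, 1); the trapezoidal area of the curve equals [auc_score()] exactly
#' (ties produce diagonal segments).
#'
#' @inheritParams auc_score
#' @param marker optional marker name stored on the result.
#' @return object of class `roc_result`: list with `marker`, `points`
#'   (data frame `fpr`, `tpr`, `threshold`), `auc`, `n_case`, `n_control`.
#' @export
roc_points <- function(scores, labels, marker = "score") {
  lab <- .as_case_logical(labels)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present",
                                 call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[lab] >= t) / n1, numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores[!lab] >= t) / n0, numeric(1L))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(marker = marker, points = pts, auc = auc,
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC for ", x$marker, ": AUC = ", format(x$auc, digits = 4),
      " (", x$n_case, " case vs ", x$n_control, " control)\n", sep = "")
  invisible(x)
}

#' Combine a marker triplet into one diagnostic score
#'
#' Fits an in-sample logistic regression of case status on the standardized
#' marker values and returns the linear predictor as the combined score —
#' the standard way to pool an lncRNA-miRNA-mRNA axis into a single ROC
#' curve. The fit is deterministic. Under perfect separation (common at
#' small n) the maximum-likelihood fit diverges, so the combiner falls back
#' to a fixed small-ridge logistic fit and records `stabilized = TRUE`.
#' An optional leave-one-out mode refits without each sample to score it,
#' giving the honest (non-optimistic) combined AUC.
#'
#' @param features numeric matrix or data frame, samples x markers (any
#'   number of markers, typically 3).
#' @param labels case/control labels.
#' @param loo use leave-one-out scoring (default `FALSE`: in-sample).
#' @return list with `score` (per-sample combined score), `coefficients`,
#'   `stabilized` flag and `loo` flag.
#' @export
combine_triplet <- function(features, labels, loo = FALSE) {
  X <- as.matrix(features)
  lab <- .as_case_logical(labels)
  if (nrow(X) != length(lab)) {
    stop("features must have one row per sample", call. = FALSE)
  }
  if (any(!is.finite(X))) stop("features must be complete", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  Xs <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  if (loo) {
    score <- vapply(seq_len(nrow(Xs)), function(i) {
      fit <- .fit_logistic(Xs[-i, , drop = FALSE], lab[-i])
      drop(cbind(1, Xs[i, , drop = FALSE]) %*% fit$beta)
    }, numeric(1L))
    fit <- .fit_logistic(Xs, lab)  # reported coefficients: full-data fit
  } else {
    fit <- .fit_logistic(Xs, lab)
    score <- drop(cbind(1, Xs) %*% fit$beta)
  }
  list(score = score, coefficients = fit$beta,
       stabilized = fit$stabilized, loo = loo)
}

.fit_logistic <- function(Xs, lab) {
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, Xs), as.numeric(lab),
                   family = stats::binomial()),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # aliased (duplicate) columns contribute nothing
  if (!separated && !fit$converged) separated <- TRUE
  if (!separated && any(abs(beta[-1L]) > 1e3)) separated <- TRUE
  if (!separated) {
    return(list(beta = beta, stabilized = FALSE))
  }
  message("perfect separation detected: using ridge-stabilized logistic fit")
  # small-sample class-size warnings are expected at n = 10/10
  rf <- suppressWarnings(
    glmnet::glmnet(Xs, factor(lab), family = "binomial", alpha = 0,
                   lambda = 0.1, standardize = FALSE))
  beta <- c(rf$a0, as.numeric(rf$beta))
  list(beta = beta, stabilized = TRUE)
}

#' Compare single markers and combined triplet axes by AUC
#'
#' Computes the empirical AUC of each named feature alone and of each
#' logistic-combined lncRNA-miRNA-mRNA axis, the single-vs-network
#' comparison used to ask whether a ceRNA axis outperforms its members as a
#' diagnostic marker.
#'
#' @param study a `cerna_study` (or list with `expression`, `group`).
#' @param triplets data frame with columns `lncrna`, `mirna`, `mrna`
#'   (e.g. from [extract_triplets()]); may have zero rows.
#' @param markers optional character vector of single features to report;
#'   defaults to all features appearing in `triplets`.
#' @param pseudocount log2 transform offset (default 1).
#' @param loo leave-one-out combined scoring (default `FALSE`).
#' @return data frame: `marker`, `kind` ("single" or "combined"), `auc`,
#'   `n_case`, `n_control`, `stabilized`.
#' @export
compare_markers <- function(study, triplets, markers = NULL,
                            pseudocount = 1, loo = FALSE) {
  expr_all <- do.call(rbind, study$expression)
  lab <- study$group == "case"
  if (is.null(markers)) {
    markers <- unique(unlist(triplets[, c("lncrna", "mirna", "mrna")]))
  }
  missing <- setdiff(unique(c(markers,
                              unlist(triplets[, c("lncrna", "mirna", "mrna")]))),
                     rownames(expr_all))
  if (length(missing)) {
    stop("features missing from expression tables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lg <- function(id) log2(expr_all[id, ] + pseudocount)
  singles <- data.frame(
    marker = markers, kind = "single",
    auc = vapply(markers, function(id) auc_score(lg(id), lab), numeric(1L)),
    n_case = sum(lab), n_control = sum(!lab), stabilized = FALSE,
    stringsAsFactors = FALSE
  )
  combined <- NULL
  if (nrow(triplets) > 0L) {
    combined <- do.call(rbind, lapply(seq_len(nrow(triplets)), function(i) {
      ids <- unlist(triplets[i, c("lncrna", "mirna", "mrna")])
      X <- sapply(ids, lg)
      cmb <- combine_triplet(X, lab, loo = loo)
      data.frame(marker = paste(ids, collapse = "|"), kind = "combined",
                 auc = auc_score(cmb$score, lab),
                 n_case = sum(lab), n_control = sum(!lab),
                 stabilized = cmb$stabilized, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(singles, combined)
  rownames(out) <- NULL
  out
}
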