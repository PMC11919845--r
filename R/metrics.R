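#' @title Classification and virtual-screening metrics
#' @name metrics
NULL

#' Area under the ROC curve
#'
#' Computed from the Wilcoxon rank statistic with midranks, so tied scores
#' contribute 1/2 per discordant-tied pair.
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (0/1)
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  check_two_classes(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation over descending score thresholds (tied scores are
#' grouped into a single step): `sum over thresholds of (R_i - R_{i-1}) P_i`.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`
#' @export
aupr <- function(scores, labels) {
  check_two_classes(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  n1 <- sum(labels == 1)
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    stop("metric undefined: only one class present in labels")
  }
  invisible(TRUE)
}

#' Full metrics report for scored pairs
#'
#' AUROC and AUPR plus threshold metrics (accuracy, precision, recall, F1)
#' at a fixed decision threshold. Precision and F1 are reported as 0 when no
#' pair is predicted positive.
#'
#' @inheritParams auroc
#' @param threshold decision threshold for the binary metrics
#' @return list of class `metrics_report` with `auroc`, `aupr`, `acc`,
#'   `precision`, `recall`, `f1`
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  check_two_classes(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(
    list(auroc = auroc(scores, labels), aupr = aupr(scores, labels),
         acc = mean(pred == labels), precision = precision, recall = recall,
         f1 = f1),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUROC %.4f | AUPR %.4f | ACC %.4f | PR %.4f | RE %.4f | F1 %.4f\n",
              x$auroc, x$aupr, x$acc, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Enrichment factor at a top fraction of a ranked library
#'
#' `EF_x = (actives in top m / m) / (A / N)` with `m = ceiling(x N / 100)`,
#' `A` actives and `N` candidates. Ranking is by descending score with ties
#' broken by candidate id (stable).
#'
#' @param scores candidate scores
#' @param labels binary activity labels
#' @param pct top percentage (e.g. 10 for the top tenth of the library)
#' @param ids optional candidate ids for deterministic tie-breaking
#' @return enrichment factor (>= 0)
#' @export
enrichment_factor <- function(scores, labels, pct, ids = seq_along(scores)) {
  if (sum(labels == 1) == 0L) stop("enrichment factor undefined: no actives in library")
  n <- length(scores)
  m <- ceiling(pct * n / 100)
  o <- order(-scores, ids)
  (sum(labels[o][seq_len(m)] == 1) / m) / (sum(labels == 1) / n)
}

#' ROC enrichment at a fixed false-positive rate
#'
#' `Re = TPR(FPR = t) / t`, with the true-positive rate read off the
#' empirical ROC curve by linear interpolation at the requested
#' false-positive rate.
#'
#' @inheritParams enrichment_factor
#' @param fpr_pct false-positive-rate threshold in percent (e.g. 1 or 5)
#' @return ROC enrichment (>= 0)
#' @export
roc_enrichment <- function(scores, labels, fpr_pct, ids = seq_along(scores)) {
  check_two_classes(labels)
  o <- order(-scores, ids)
  y <- labels[o]; s <- scores[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(1 - y))
  t_frac <- fpr_pct / 100
  tpr_at <- stats::approx(fpr, tpr, xout = t_frac, ties = max, rule = 2)$y
  tpr_at / t_frac
}

#' Rank a candidate library against a query entity
#'
#' Scores every candidate drug against a query target (or every candidate
#' target against a query drug), sorts by descending score with stable
#' id tie-breaks, and, when activity labels are supplied, computes
#' enrichment factors and ROC enrichments.
#'
#' @param model a trained `dti_model`
#' @param dataset a [dti_dataset()] holding the query and candidates
#' @param query_target id of the query target (rank drugs), or `NULL`
#' @param query_drug id of the query drug (rank targets), or `NULL`
#' @param candidates character vector of candidate ids
#' @param labels optional named binary activity labels for the candidates
#' @param ef_pct top-fraction percentages for enrichment factors
#' @param re_fpr_pct false-positive-rate percentages for ROC enrichment
#' @return list of class `ranking_result`: `ranking` (data frame of
#'   candidate, score and optional label in rank order), `ef`, `re`, `auroc`
#' @export
rank_candidates <- function(model, dataset, query_target = NULL,
                            query_drug = NULL, candidates, labels = NULL,
                            ef_pct = c(1, 5, 10), re_fpr_pct = c(1, 5)) {
  if (is.null(query_target) == is.null(query_drug)) {
    stop("supply exactly one of query_target or query_drug")
  }
  pairs <- if (!is.null(query_target)) {
    data.frame(drug_id = candidates, target_id = query_target,
               stringsAsFactors = FALSE)
  } else {
    data.frame(drug_id = query_drug, target_id = candidates,
               stringsAsFactors = FALSE)
  }
  pairs$label <- 0
  scores <- predict.dti_model(model, dataset, pairs)
  o <- order(-scores, candidates)
  ranking <- data.frame(candidate = candidates[o], score = scores[o],
                        stringsAsFactors = FALSE)
  ef <- re <- auc <- NULL
  if (!is.null(labels)) {
    lab <- as.numeric(labels[candidates])
    if (sum(lab == 1) == 0L) stop("candidate library contains no actives")
    ranking$label <- lab[o]
    ef <- vapply(ef_pct, function(p) enrichment_factor(scores, lab, p, candidates),
                 numeric(1))
    names(ef) <- paste0(ef_pct, "%")
    re <- vapply(re_fpr_pct, function(p) roc_enrichment(scores, lab, p, candidates),
                 numeric(1))
    names(re) <- paste0(re_fpr_pct, "%")
    auc <- auroc(scores, lab)
  }
  structure(list(ranking = ranking, ef = ef, re = re, auroc = auc),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("<ranking_result> ", nrow(x$ranking), " candidates\n", sep = "")
  if (!is.null(x$ef)) {
    cat("  EF:", paste(names(x$ef), sprintf("%.2f", x$ef), collapse = ", "), "\n")
    cat("  Re:", paste(names(x$re), sprintf("%.2f", x$re), collapse = ", "), "\n")
    cat("  AUROC:", sprintf("%.4f", x$auroc), "\n")
  }
  print(utils::head(x$ranking, 10L))
  invisible(x)
}
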