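#' Binary-classifier evaluation suite
#'
#' Contingency construction at a cutoff, the Youden-index optimal cutoff,
#' threshold-free ranking metrics (ROC AUC by the Mann-Whitney formulation,
#' PR AUC by the average-precision convention) and the derived rates used to
#' score agonist/antagonist activity models: sensitivity (= recall),
#' specificity, balanced accuracy BAC = (sensitivity + specificity)/2,
#' accuracy, precision, F-measure and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#'
#' Degenerate ratios (0/0) are reported as 0 and flagged; a single-class
#' evaluation set yields ROC AUC 0.5 (and PR AUC equal to prevalence) with a
#' `degenerate` flag rather than an error, so that imbalanced assays with an
#' empty positive stratum in one split still produce a comparable report.
#'
#' @name metrics
NULL

#' Build a 2x2 contingency table from probabilities at a cutoff
#'
#' A case is predicted positive iff its probability is greater than or equal
#' to the cutoff.
#'
#' @param probs numeric vector of probabilities in \[0,1\].
#' @param labels integer vector of 0/1 true labels, same length.
#' @param cutoff scalar decision threshold.
#' @return list of class `contingency_table` with integer fields TP, FP, TN, FN.
#' @export
contingency <- function(probs, labels, cutoff) {
  check_probs_labels(probs, labels, need_both = FALSE)
  if (!is_scalar_number(cutoff)) stop_snap("snap_value", "cutoff must be a finite scalar")
  pred <- probs >= cutoff
  tab <- list(
    TP = sum(pred & labels == 1L), FP = sum(pred & labels == 0L),
    TN = sum(!pred & labels == 0L), FN = sum(!pred & labels == 1L)
  )
  tab <- lapply(tab, as.integer)
  structure(tab, class = "contingency_table")
}

check_probs_labels <- function(probs, labels, need_both = TRUE) {
  if (length(probs) != length(labels))
    stop_snap("snap_value", "probs and labels differ in length (%d vs %d)",
              length(probs), length(labels))
  if (length(probs) < 1L) stop_snap("snap_value", "need at least one observation")
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop_snap("snap_value", "probs must lie in [0,1]")
  if (!all(labels %in% c(0L, 1L)))
    stop_snap("snap_value", "labels must be 0/1")
  if (need_both && length(unique(labels)) < 2L)
    stop_snap("snap_degenerate", "both classes must be present")
  invisible(TRUE)
}

div0 <- function(num, den) if (den == 0) 0 else num / den

#' Rates and correlation metrics from a contingency table
#'
#' @param table a `contingency_table` (or list with TP/FP/TN/FN).
#' @return named list: sensitivity, specificity, BAC, Acc, precision, recall,
#'   F, MCC, plus `degenerate_flags` naming any 0/0 ratio reported as 0.
#' @export
basic_metrics <- function(table) {
  tp <- table$TP; fp <- table$FP; tn <- table$TN; fn <- table$FN
  n <- tp + fp + tn + fn
  if (n <= 0) stop_snap("snap_value", "empty contingency table")
  flags <- character(0)
  flag <- function(cond, name) if (cond) flags <<- c(flags, name)
  flag(tp + fn == 0, "sensitivity"); flag(tn + fp == 0, "specificity")
  flag(tp + fp == 0, "precision")
  sens <- div0(tp, tp + fn)
  spec <- div0(tn, tn + fp)
  prec <- div0(tp, tp + fp)
  f <- if (sens + prec == 0) { flags <- c(flags, "F"); 0 } else
    2 * sens * prec / (sens + prec)
  k <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (k == 0) { flags <- c(flags, "MCC"); 0 } else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(k)
  list(
    sensitivity = sens, specificity = spec, BAC = (sens + spec) / 2,
    Acc = (tp + tn) / n, precision = prec, recall = sens, F = f, MCC = mcc,
    degenerate_flags = unique(flags)
  )
}

youden_candidates <- function(probs) {
  u <- sort(unique(probs))
  mids <- if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2 else numeric(0)
  # sentinels: below every prob (predict all positive) and above (all negative)
  c(min(u) - 0.5, mids, max(u) + 0.5)
}

#' Optimal cutoff by the Youden index
#'
#' Scans the midpoints between consecutive sorted unique probabilities plus
#' below/above sentinels and returns the cutoff maximizing
#' J = sensitivity + specificity - 1, ties broken toward the smallest cutoff.
#'
#' @inheritParams contingency
#' @return list(cutoff =, J =)
#' @export
youden_cutoff <- function(probs, labels) {
  check_probs_labels(probs, labels, need_both = TRUE)
  cand <- youden_candidates(probs)
  best_j <- -Inf; best_c <- cand[1L]
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  for (ct in cand) {
    pred <- probs >= ct
    j <- sum(pred & labels == 1L) / npos + sum(!pred & labels == 0L) / nneg - 1
    if (j > best_j + 1e-12) { best_j <- j; best_c <- ct }
  }
  list(cutoff = best_c, J = best_j)
}

#' ROC AUC (Mann-Whitney formulation, ties counted 1/2)
#'
#' Probability that a uniformly drawn positive outranks a uniformly drawn
#' negative; identical to the trapezoidal area under the empirical ROC curve.
#' With a single-class label vector the value is undefined and 0.5 is
#' returned with attribute `degenerate = TRUE`.
#'
#' @inheritParams contingency
#' @return scalar in \[0,1\].
#' @export
roc_auc <- function(probs, labels) {
  check_probs_labels(probs, labels, need_both = FALSE)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    return(structure(0.5, degenerate = TRUE))
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' PR AUC by the average-precision convention
#'
#' Area under the precision-recall curve computed by stepping through the
#' unique predicted probabilities in decreasing order with right-continuous
#' precision: AP = sum over thresholds of (R_t - R_{t-1}) * P_t.
#'
#' @inheritParams contingency
#' @return scalar in (0,1\].
#' @export
pr_auc <- function(probs, labels) {
  check_probs_labels(probs, labels, need_both = FALSE)
  npos <- sum(labels == 1L)
  if (npos == 0L) return(structure(0, degenerate = TRUE))
  thr <- sort(unique(probs), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (t in thr) {
    sel <- probs >= t
    prec <- sum(labels[sel] == 1L) / sum(sel)
    rec <- sum(labels[sel] == 1L) / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

#' Full metric report for one evaluation split
#'
#' Chooses (or receives) a cutoff, builds the contingency table and assembles
#' every metric plus the ranking AUCs into one flat report.
#'
#' @inheritParams contingency
#' @param cutoff decision threshold; `NULL` selects it by [youden_cutoff()]
#'   on these same probabilities (self policy).
#' @param losses optional named list (loss_train/loss_valid/loss_test) copied
#'   into the report.
#' @return list of class `metric_report`.
#' @export
metric_report <- function(probs, labels, cutoff = NULL, losses = NULL) {
  check_probs_labels(probs, labels, need_both = FALSE)
  flags <- character(0)
  single_class <- length(unique(labels)) < 2L
  if (is.null(cutoff)) {
    if (single_class) {
      cutoff <- 0.5; j <- 0; flags <- c(flags, "youden")
    } else {
      yc <- youden_cutoff(probs, labels); cutoff <- yc$cutoff; j <- yc$J
    }
  } else {
    j <- NA_real_
    if (!single_class) {
      tab0 <- contingency(probs, labels, cutoff)
      bm0 <- basic_metrics(tab0)
      j <- bm0$sensitivity + bm0$specificity - 1
    }
  }
  tab <- contingency(probs, labels, cutoff)
  bm <- basic_metrics(tab)
  auc <- roc_auc(probs, labels)
  pr <- pr_auc(probs, labels)
  if (isTRUE(attr(auc, "degenerate"))) flags <- c(flags, "ROC_AUC")
  if (isTRUE(attr(pr, "degenerate"))) flags <- c(flags, "PR_AUC")
  rep <- c(
    list(TP = tab$TP, FP = tab$FP, TN = tab$TN, FN = tab$FN),
    bm[setdiff(names(bm), "degenerate_flags")],
    list(youden_J = j, cutoff = cutoff,
         ROC_AUC = as.numeric(auc), PR_AUC = as.numeric(pr),
         n = tab$TP + tab$FP + tab$TN + tab$FN,
         degenerate_flags = unique(c(bm$degenerate_flags, flags)))
  )
  if (!is.null(losses)) rep[names(losses)] <- losses
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report (n =", x$n, ")\n")
  num <- vapply(x, is_scalar_number, logical(1))
  v <- unlist(x[num])
  cat(paste(sprintf("  %-12s %.4f", names(v), v), collapse = "\n"), "\n")
  if (length(x$degenerate_flags))
    cat("  degenerate:", paste(x$degenerate_flags, collapse = ", "), "\n")
  invisible(x)
}

#' ROC and PR curve points (for plotting / TSV dumps)
#'
#' @inheritParams contingency
#' @return list with data.frames `roc` (fpr, tpr, cutoff) and `pr`
#'   (recall, precision, cutoff).
#' @export
curve_points <- function(probs, labels) {
  check_probs_labels(probs, labels, need_both = TRUE)
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  roc <- do.call(rbind, lapply(thr, function(t) {
    sel <- probs >= t
    data.frame(fpr = sum(labels[sel] == 0L) / nneg,
               tpr = sum(labels[sel] == 1L) / npos, cutoff = t)
  }))
  pr <- do.call(rbind, lapply(thr[-1L], function(t) {
    sel <- probs >= t
    data.frame(recall = sum(labels[sel] == 1L) / npos,
               precision = sum(labels[sel] == 1L) / sum(sel), cutoff = t)
  }))
  list(roc = roc, pr = pr)
}
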