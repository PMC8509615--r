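# Oracles used throughout: brute-force per-item loops, exhaustive cutoff
# scans and all-pairs counting, independent of the vectorized implementations.

oracle_contingency <- function(probs, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(probs)) {
    pred <- probs[i] >= cutoff
    if (pred && labels[i] == 1) tp <- tp + 1L
    else if (pred && labels[i] == 0) fp <- fp + 1L
    else if (!pred && labels[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

oracle_auc_pairs <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("contingency matches an element-wise loop oracle and handles edges", {
  set.seed(11)
  for (rep in 1:5) {
    probs <- runif(50); labels <- rbinom(50, 1, 0.3)
    for (ct in c(0, 0.25, 0.5, 0.9)) {
      got <- contingency(probs, labels, ct)
      exp <- oracle_contingency(probs, labels, ct)
      expect_identical(unclass(got)[names(exp)], exp)
    }
  }
  tab <- contingency(c(0.9, 0.1), c(1L, 0L), 0.5)
  expect_identical(unclass(tab), list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  # cutoff 0: everything predicted positive
  tab0 <- contingency(runif(20), rep(c(0L, 1L), 10), 0)
  expect_identical(tab0$FP, 10L)
  expect_identical(tab0$FN, 0L)
  expect_error(contingency(c(0.5), c(1L, 0L), 0.5), class = "snap_value")
})

test_that("basic_metrics reproduces the arithmetic oracle and conventions", {
  m <- basic_metrics(list(TP = 3L, FP = 1L, TN = 4L, FN = 2L))
  expect_equal(m$sensitivity, 3 / 5)
  expect_equal(m$specificity, 4 / 5)
  expect_equal(m$BAC, 0.7)
  expect_equal(m$Acc, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$F, 2 * 0.6 * 0.75 / (0.6 + 0.75))
  expect_equal(m$MCC, (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6))
  expect_equal(round(m$MCC, 4), 0.4082)   # agreement at printed precision

  perfect <- basic_metrics(list(TP = 5L, FP = 0L, TN = 7L, FN = 0L))
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "BAC",
                                   "Acc", "precision", "F", "MCC")]) == 1))
  # no positives at all: sensitivity defined-as-0 with a flag
  deg <- basic_metrics(list(TP = 0L, FP = 2L, TN = 5L, FN = 0L))
  expect_equal(deg$sensitivity, 0)
  expect_true("sensitivity" %in% deg$degenerate_flags)
  expect_error(basic_metrics(list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)),
               class = "snap_value")
})

test_that("BAC identity and MCC bounds hold on fuzzed tables; MCC symmetries", {
  set.seed(42)
  for (i in 1:10000) {
    tb <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    if (sum(unlist(tb)) == 0) next
    m <- basic_metrics(tb)
    expect_identical(m$BAC, (m$sensitivity + m$specificity) / 2)
    expect_true(m$MCC >= -1 - 1e-12 && m$MCC <= 1 + 1e-12)
    # simultaneous swap TP<->TN, FP<->FN leaves MCC unchanged
    sw <- basic_metrics(list(TP = tb$TN, FP = tb$FN, TN = tb$TP, FN = tb$FP))
    expect_equal(sw$MCC, m$MCC, tolerance = 1e-12)
  }
})

test_that("label inversion flips MCC and reflects ROC AUC", {
  set.seed(7)
  for (rep in 1:20) {
    probs <- runif(40); labels <- rbinom(40, 1, 0.4)
    if (length(unique(labels)) < 2) next
    ct <- 0.5
    m1 <- basic_metrics(contingency(probs, labels, ct))
    m2 <- basic_metrics(contingency(probs, 1L - labels, ct))
    expect_equal(m2$MCC, -m1$MCC, tolerance = 1e-12)
    expect_equal(roc_auc(probs, 1L - labels), 1 - roc_auc(probs, labels),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc equals brute-force pair counting and honors conventions", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    probs <- round(runif(n), 2)       # rounding forces some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(probs, labels), oracle_auc_pairs(probs, labels),
                 tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(as.numeric(roc_auc(rep(0.3, 10), rep(c(0, 1), 5))), 0.5)
  deg <- roc_auc(runif(5), rep(1L, 5))
  expect_equal(as.numeric(deg), 0.5)
  expect_true(attr(deg, "degenerate"))
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  set.seed(9)
  probs <- runif(60); labels <- rbinom(60, 1, 0.3)
  a <- roc_auc(probs, labels)
  expect_equal(roc_auc(probs^2, labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(plogis(5 * probs - 2), labels), a, tolerance = 1e-12)
})

test_that("youden_cutoff matches an exhaustive scan and the ROC identity", {
  oracle_youden <- function(probs, labels) {
    cand <- sort(unique(c(min(probs) - 0.5, max(probs) + 0.5,
                          (sort(unique(probs))[-1] +
                           utils::head(sort(unique(probs)), -1)) / 2)))
    best <- c(cutoff = NA, J = -Inf)
    for (ct in cand) {
      tb <- oracle_contingency(probs, labels, ct)
      j <- tb$TP / (tb$TP + tb$FN) + tb$TN / (tb$TN + tb$FP) - 1
      if (j > best["J"] + 1e-12) best <- c(cutoff = ct, J = j)
    }
    best
  }
  set.seed(3)
  for (rep in 1:10) {
    probs <- round(runif(20), 1); labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2) next
    got <- youden_cutoff(probs, labels)
    exp <- oracle_youden(probs, labels)
    expect_equal(got$cutoff, unname(exp["cutoff"]))
    expect_equal(got$J, unname(exp["J"]), tolerance = 1e-12)
    # J equals the max of TPR - FPR over the empirical ROC
    cp <- curve_points(probs, labels)
    expect_equal(got$J, max(cp$roc$tpr - cp$roc$fpr), tolerance = 1e-12)
  }
  # perfect separation: J = 1; independent labels at large n: J near 0
  expect_equal(youden_cutoff(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$J, 1)
  set.seed(10)
  jnull <- youden_cutoff(runif(2000), rbinom(2000, 1, 0.5))$J
  expect_lt(jnull, 0.12)
})

test_that("pr_auc matches threshold enumeration and the prevalence baseline", {
  # tie-free oracle: AP = mean over positives of precision at that positive
  oracle_ap <- function(probs, labels) {
    ord <- order(-probs)
    lab <- labels[ord]
    cum_tp <- cumsum(lab == 1)
    prec_at <- cum_tp / seq_along(lab)
    mean(prec_at[lab == 1])
  }
  set.seed(21)
  for (rep in 1:10) {
    probs <- runif(20); labels <- rbinom(20, 1, 0.4)
    if (sum(labels) == 0) next
    expect_equal(pr_auc(probs, labels), oracle_ap(probs, labels),
                 tolerance = 1e-12)
  }
  expect_equal(pr_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  set.seed(30)
  labels <- rbinom(5000, 1, 0.3)
  expect_equal(pr_auc(runif(5000), labels), 0.3, tolerance = 0.05)
  deg <- pr_auc(runif(4), rep(0L, 4))
  expect_true(attr(deg, "degenerate"))
})

test_that("metric_report assembles the suite consistently", {
  probs <- c(0.95, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  rep <- metric_report(probs, labels)
  expect_s3_class(rep, "metric_report")
  expect_equal(rep$BAC, (rep$sensitivity + rep$specificity) / 2)
  yc <- youden_cutoff(probs, labels)
  expect_equal(rep$cutoff, yc$cutoff)
  expect_equal(rep$youden_J, yc$J)
  # single-class set: flagged, ROC pinned at 0.5
  deg <- metric_report(runif(5), rep(0L, 5))
  expect_equal(deg$ROC_AUC, 0.5)
  expect_true(all(c("ROC_AUC", "youden") %in% deg$degenerate_flags))
  # losses pass through
  rl <- metric_report(probs, labels, losses = list(loss_valid = 0.12))
  expect_equal(rl$loss_valid, 0.12)
})
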