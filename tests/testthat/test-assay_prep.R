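test_that("percent_activity: boundary cases, linearity, degenerate controls", {
  expect_equal(percent_activity(100, 10, 100), 100)
  expect_equal(percent_activity(10, 10, 100), 0)
  expect_equal(percent_activity(55, 10, 100), 50)
  expect_error(percent_activity(5, 7, 7), class = "snap_degenerate")
  # affine invariance: the map is unchanged under v -> a*v + b
  set.seed(1)
  for (i in 1:50) {
    v <- runif(3, -5, 5) * c(1, 1, 1) + c(0, 0, 10)   # ensure pos != dmso
    a <- runif(1, 0.1, 4) * sample(c(-1, 1), 1); b <- runif(1, -10, 10)
    expect_equal(percent_activity(a * v[1] + b, a * v[2] + b, a * v[3] + b),
                 percent_activity(v[1], v[2], v[3]), tolerance = 1e-9)
  }
})

test_that("classify_activity follows the 0 / (0,40) / [40,100] bands", {
  expect_identical(as.character(classify_activity(40)$ternary_class), "active")
  expect_identical(classify_activity(40)$label, 1L)
  expect_identical(as.character(classify_activity(39)$ternary_class), "inconclusive")
  expect_identical(classify_activity(39)$label, 0L)
  expect_identical(as.character(classify_activity(0)$ternary_class), "inactive")
  expect_identical(classify_activity(0)$label, 0L)
  grid <- seq(0, 100, by = 0.25)
  expect_identical(classify_activity(grid)$label, as.integer(grid >= 40))
  expect_error(classify_activity(101), class = "snap_range")
  expect_error(classify_activity(-0.5), class = "snap_range")
})

test_that("read_assay_table handles CSV/TSV, raw wells and score validation", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles,activity_score",
               "A,CCO,55.5", "B,CCN,0"), f)
  df <- read_assay_table(f)
  expect_equal(df$activity_score, c(55.5, 0))
  # TSV with raw wells: normalized and clamped, raw kept
  g <- tempfile(fileext = ".tsv")
  writeLines(c("smiles\tv_compound\tv_dmso\tv_pos",
               "CCO\t55\t10\t100", "CCN\t5\t10\t100"), g)
  dg <- read_assay_table(g)
  expect_equal(dg$activity_score, c(50, 0))       # clamped at 0
  expect_equal(dg$raw_score, c(50, -100 / 18), tolerance = 1e-9)
  expect_match(dg$compound_id[1], "^CMPD")
  h <- tempfile(fileext = ".csv")
  writeLines(c("smiles,activity_score", "CCO,140"), h)
  expect_error(read_assay_table(h), class = "snap_range")
  writeLines(c("smiles,foo", "CCO,1"), h)
  expect_error(read_assay_table(h), class = "snap_format")
})

test_that("deduplication keeps one record per canonical SMILES (max score)", {
  assay <- data.frame(
    compound_id = c("A", "B", "C", "D"),
    smiles = c("X1", "X1", "X2", "X1"),
    activity_score = c(10, 80, 50, 80),
    stringsAsFactors = FALSE
  )
  out <- deduplicate(assay, canonicalize = FALSE)
  expect_equal(nrow(out), 2L)
  # max score kept; tie (B vs D at 80) broken toward first occurrence
  expect_equal(out$compound_id[out$canonical_smiles == "X1"], "B")
  expect_equal(out$activity_score[out$canonical_smiles == "X1"], 80)
  empty <- deduplicate(assay[0, ], canonicalize = FALSE)
  expect_equal(nrow(empty), 0L)
  two <- deduplicate(assay[c(2, 3), ], canonicalize = FALSE)
  expect_equal(nrow(two), 2L)
})

test_that("deduplication recognizes equivalent SMILES via canonicalization", {
  assay <- data.frame(compound_id = c("A", "B"),
                      smiles = c("OCC", "CCO"),   # both ethanol
                      activity_score = c(10, 60), stringsAsFactors = FALSE)
  out <- deduplicate(assay)
  expect_equal(nrow(out), 1L)
  expect_equal(out$activity_score, 60)
  # unparseable SMILES: dropped with a warning, not fatal
  bad <- data.frame(compound_id = c("A", "B"), smiles = c("C(", "CCO"),
                    activity_score = c(10, 20), stringsAsFactors = FALSE)
  expect_warning(outb <- prepare_molecules(bad), "unparseable")
  expect_equal(outb$compound_id, "B")
})

test_that("apportion implements largest-remainder (brute-force oracle)", {
  oracle_lr <- function(n, w) {
    # enumerate every allocation summing to n; pick min total deviation from
    # quota, ties resolved toward earlier positions getting the extra seat
    q <- n * w / sum(w)
    best <- NULL; best_dev <- Inf
    for (a in 0:n) for (b in 0:(n - a)) {
      c3 <- n - a - b
      dev <- sum(abs(c(a, b, c3) - q))
      if (dev < best_dev - 1e-12) { best_dev <- dev; best <- c(a, b, c3) }
    }
    best
  }
  cases <- list(c(6, 1, 1, 1), c(12, 3, 1, 2), c(10, 7, 1, 4), c(23, 5, 3, 4),
                c(9, 4, 2, 3), c(17, 5, 1, 3))
  for (cs in cases) {
    got <- apportion(cs[1], cs[2:4])
    expect_equal(sum(got), cs[1])
    expect_equal(sum(abs(got - cs[1] * cs[2:4] / sum(cs[2:4]))),
                 sum(abs(oracle_lr(cs[1], cs[2:4]) - cs[1] * cs[2:4] / sum(cs[2:4]))),
                 tolerance = 1e-9)
  }
  expect_equal(apportion(6, c(1, 1, 1)), c(2L, 2L, 2L))
  expect_equal(apportion(12, c(3, 1, 2)), c(6L, 2L, 4L))
  expect_equal(apportion(10, c(7, 1, 4)), c(6L, 1L, 3L))
})

test_that("split_dataset: sizes, disjoint cover, determinism, stratification", {
  mols <- make_mols(12)
  plan <- split_plan(ratios = c(3, 1, 2), seed = 5)
  out <- split_dataset(mols, plan)
  expect_equal(as.integer(table(out$split)[c("train", "valid", "test")]),
               c(6L, 2L, 4L))
  expect_setequal(out$compound_id, mols$compound_id)      # cover, no loss
  expect_false(any(duplicated(out$compound_id)))          # disjoint
  # byte-identical rerun
  expect_identical(out, split_dataset(mols, plan))
  # different seed: same sizes, different membership (usually)
  out2 <- split_dataset(mols, split_plan(ratios = c(3, 1, 2), seed = 99))
  expect_equal(table(out2$split), table(out$split))
  # stratification: per-split active fraction within apportionment rounding
  big <- make_mols(60, n_active = 12)
  sp <- split_dataset(big, split_plan(ratios = c(1, 1, 1), seed = 1))
  for (s in c("train", "valid", "test")) {
    sel <- sp$split == s
    expect_equal(sum(sp$label[sel]), 4L)    # 12 actives over 3 equal splits
  }
})

test_that("foldout is carved first and pinned against the tvt seed", {
  mols <- make_mols(40, n_active = 8)
  p1 <- split_plan(ratios = c(1, 1, 1), foldout_fraction = 0.25, seed = 1)
  p2 <- split_plan(ratios = c(1, 1, 1), foldout_fraction = 0.25, seed = 777)
  o1 <- split_dataset(mols, p1); o2 <- split_dataset(mols, p2)
  expect_equal(sum(o1$split == "foldout"), 10L)
  expect_identical(o1$compound_id[o1$split == "foldout"],
                   o2$compound_id[o2$split == "foldout"])
  # inner membership does respond to the tvt seed
  expect_false(identical(o1$split, o2$split))
  # stratified foldout: 8/40 actives -> 2 of 10
  expect_equal(sum(o1$label[o1$split == "foldout"]), 2L)
})

test_that("tiny strata trigger a best-effort warning, not an error", {
  mols <- make_mols(7, n_active = 2)
  expect_warning(out <- split_dataset(mols, split_plan(c(1, 1, 1), seed = 2)),
                 "stratum")
  expect_setequal(out$split, c("train", "valid", "test"))
})
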