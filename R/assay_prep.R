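#' Normalize a raw well reading to percent activity
#'
#' \% activity = (Vcompound - Vdmso) / (Vpos - Vdmso) * 100, where Vdmso and
#' Vpos are the median solvent-control and positive-control well values of
#' the reporter-gene assay. The value is returned unclamped (it may fall
#' outside \[0,100\]); callers clamp before class assignment and keep the raw
#' value for provenance.
#'
#' @param v_compound compound-well signal (vectorized).
#' @param v_dmso median DMSO-only well signal.
#' @param v_pos median positive-control well signal.
#' @return numeric percent activity.
#' @export
percent_activity <- function(v_compound, v_dmso, v_pos) {
  if (any(v_pos == v_dmso))
    stop_snap("snap_degenerate",
              "degenerate normalization: positive control equals DMSO control")
  (v_compound - v_dmso) / (v_pos - v_dmso) * 100
}

#' Assign the ternary activity class and the binary label
#'
#' Scores are grouped into three bands: 0 (inactive), above 0 and below 40
#' (inconclusive), and 40-100 (active). The binary label is 1 iff the score
#' is at least 40; inactive and inconclusive compounds are both label 0.
#'
#' @param score numeric vector of activity scores in \[0,100\].
#' @return data.frame with columns `ternary_class` (factor) and `label`.
#' @export
classify_activity <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 100))
    stop_snap("snap_range", "activity score outside [0,100]")
  ternary <- ifelse(score >= 40, "active",
                    ifelse(score > 0, "inconclusive", "inactive"))
  data.frame(
    ternary_class = factor(ternary, levels = c("inactive", "inconclusive", "active")),
    label = as.integer(score >= 40)
  )
}

#' Read a chemical activity table (CSV or TSV)
#'
#' Requires a header with a `smiles` column and either `activity_score` or
#' the raw triple `v_compound, v_dmso, v_pos`; `compound_id` is optional and
#' synthesized when absent. The delimiter is auto-detected from the header
#' line. Raw readings are normalized with [percent_activity()] and clamped to
#' \[0,100\] for scoring; the unclamped value is kept in `raw_score`.
#'
#' @param path file path.
#' @return data.frame with compound_id, smiles, activity_score, raw_score.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop_snap("snap_io", "no such file: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  names(df) <- tolower(names(df))
  if (!"smiles" %in% names(df))
    stop_snap("snap_format", "required column 'smiles' missing")
  if (!"compound_id" %in% names(df))
    df$compound_id <- sprintf("CMPD%05d", seq_len(nrow(df)))
  df$compound_id <- as.character(df$compound_id)
  has_score <- "activity_score" %in% names(df)
  has_raw <- all(c("v_compound", "v_dmso", "v_pos") %in% names(df))
  if (!has_score && !has_raw)
    stop_snap("snap_format",
              "need either an activity_score column or v_compound,v_dmso,v_pos")
  if (has_raw) {
    raw <- percent_activity(df$v_compound, df$v_dmso, df$v_pos)
  } else raw <- rep(NA_real_, nrow(df))
  score <- if (has_score) df$activity_score else pmin(pmax(raw, 0), 100)
  if (has_score && any(!is.finite(score) | score < 0 | score > 100))
    stop_snap("snap_range", "activity_score outside [0,100]")
  data.frame(compound_id = df$compound_id, smiles = df$smiles,
             activity_score = score,
             raw_score = if (has_raw) raw else score,
             stringsAsFactors = FALSE)
}

#' Build the molecules table: canonicalize, score, classify, deduplicate
#'
#' SMILES are canonicalized (isomeric canonical form of the ingest toolkit,
#' RDKit); records whose SMILES fail to parse are dropped with a warning,
#' never fatally. Duplicates (same canonical SMILES) are collapsed to the
#' record with the maximum activity score, ties going to the first
#' occurrence; output order is first-appearance order of the kept records.
#'
#' @param assay data.frame from [read_assay_table()] (or with those columns).
#' @param canonicalize canonicalize via RDKit; set FALSE only when the input
#'   SMILES are already canonical and unique (used by toy fixtures for speed).
#' @return molecules data.frame: compound_id, canonical_smiles,
#'   activity_score, raw_score, ternary_class, label, split ("unassigned").
#' @export
prepare_molecules <- function(assay, canonicalize = TRUE) {
  stopifnot(all(c("compound_id", "smiles", "activity_score") %in% names(assay)))
  canon <- if (canonicalize) canonicalize_smiles(assay$smiles) else assay$smiles
  bad <- is.na(canon) | canon == ""
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with unparseable SMILES: %s",
                    sum(bad), paste(utils::head(assay$compound_id[bad], 5L),
                                    collapse = ", ")))
    assay <- assay[!bad, , drop = FALSE]
    canon <- canon[!bad]
  }
  if (nrow(assay) == 0L) {
    return(data.frame(compound_id = character(0), canonical_smiles = character(0),
                      activity_score = numeric(0), raw_score = numeric(0),
                      ternary_class = factor(character(0),
                        levels = c("inactive", "inconclusive", "active")),
                      label = integer(0), split = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(compound_id = assay$compound_id, canonical_smiles = canon,
                   activity_score = assay$activity_score,
                   raw_score = assay$raw_score %||% assay$activity_score,
                   stringsAsFactors = FALSE)
  # dedup: keep max score per canonical SMILES, first occurrence on ties
  ord <- order(df$canonical_smiles, -df$activity_score, seq_len(nrow(df)))
  keep <- !duplicated(df$canonical_smiles[ord])
  kept_rows <- sort(ord[keep])           # restore first-appearance order
  df <- df[kept_rows, , drop = FALSE]
  cls <- classify_activity(df$activity_score)
  df$ternary_class <- cls$ternary_class
  df$label <- cls$label
  df$split <- "unassigned"
  rownames(df) <- NULL
  df
}

#' Deduplicate assay records by canonical SMILES
#'
#' Thin wrapper over the dedup step of [prepare_molecules()] for callers that
#' only need collapsing: one record per canonical SMILES, keeping the maximum
#' activity score (conservative toward activity), deterministic order.
#'
#' @inheritParams prepare_molecules
#' @return deduplicated molecules data.frame.
#' @export
deduplicate <- function(assay, canonicalize = TRUE) {
  prepare_molecules(assay, canonicalize = canonicalize)
}

#' Describe a train/validation/test(/foldout) split plan
#'
#' @param ratios positive integers train:valid:test, e.g. `c(3,1,2)`.
#' @param foldout_fraction fraction in \[0,1) carved out first as the
#'   permanently fixed external evaluation set.
#' @param seed integer seed for the train/valid/test shuffle.
#' @param stratified stratify on the binary label (default TRUE; the real
#'   assays are highly imbalanced and plain random splits would not hold the
#'   active fraction constant at small n).
#' @param foldout_seed seed governing foldout membership only; deliberately
#'   separate from `seed` so re-seeding the inner split never moves a
#'   molecule in or out of foldout.
#' @return list of class `split_plan`.
#' @export
split_plan <- function(ratios = c(1, 1, 1), foldout_fraction = 0, seed = 1L,
                       stratified = TRUE, foldout_seed = 1234L) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3L || any(!is.finite(ratios)) || any(ratios <= 0))
    stop_snap("snap_value", "ratios must be three positive numbers")
  if (!is_scalar_number(foldout_fraction) ||
      foldout_fraction < 0 || foldout_fraction >= 1)
    stop_snap("snap_value", "foldout_fraction must lie in [0,1)")
  structure(list(ratios = ratios, foldout_fraction = foldout_fraction,
                 seed = as.integer(seed), stratified = isTRUE(stratified),
                 foldout_seed = as.integer(foldout_seed)),
            class = "split_plan")
}

#' Largest-remainder apportionment of n seats by weights
#'
#' Ties in the fractional remainders are broken by position order
#' (train, valid, test).
#' @param n total count.
#' @param weights positive weights.
#' @return integer vector summing to n.
#' @export
apportion <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  left <- round(n - sum(base))
  if (left > 0) {
    ord <- order(-(q - base), seq_along(q))   # largest remainder, then position
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Assign molecules to train/validation/test and foldout splits
#'
#' The foldout set (if requested) is carved out first under the plan's
#' dedicated foldout seed and is invariant to the train/valid/test seed.
#' Remaining molecules are apportioned to the three inner splits by
#' largest-remainder on the plan ratios; with stratification, active-label
#' counts are apportioned by the same rule and inactive counts make up the
#' difference, so the active fraction of every split matches the global
#' fraction to within apportionment rounding. Assignment is a deterministic
#' function of (records, plan).
#'
#' @param records molecules data.frame from [prepare_molecules()].
#' @param plan a [split_plan()].
#' @return `records` with the `split` column filled in
#'   (train/valid/test/foldout).
#' @export
split_dataset <- function(records, plan) {
  stopifnot(inherits(plan, "split_plan"))
  if (!all(c("label", "compound_id") %in% names(records)))
    stop_snap("snap_value", "records must carry compound_id and label")
  n <- nrow(records)
  if (n == 0L) return(records)
  records$split <- "unassigned"
  idx_all <- seq_len(n)

  pick_stratified <- function(idx, sizes, labels, seed) {
    # sizes: integer per split (same order as split names used by caller)
    k <- length(sizes)
    out <- vector("list", k)
    if (plan$stratified && length(unique(labels)) > 1L) {
      pos <- idx[labels == 1L]; neg <- idx[labels == 0L]
      if (length(pos) < k || length(neg) < k)
        warning("a stratum is smaller than the number of splits; best-effort assignment")
      pos_sizes <- apportion(length(pos), sizes / sum(sizes))
      neg_sizes <- sizes - pos_sizes
      # repair if any stratum allocation is infeasible
      while (any(neg_sizes < 0)) {
        i <- which.min(neg_sizes); j <- which.max(neg_sizes)
        pos_sizes[i] <- pos_sizes[i] - 1L; pos_sizes[j] <- pos_sizes[j] + 1L
        neg_sizes <- sizes - pos_sizes
      }
      pos <- with_seed(seed, sample(pos))
      neg <- with_seed(seed + 1L, sample(neg))
      cp <- c(0L, cumsum(pos_sizes)); cn <- c(0L, cumsum(neg_sizes))
      for (s in seq_len(k))
        out[[s]] <- c(pos[seq_len(pos_sizes[s]) + cp[s]][pos_sizes[s] > 0],
                      neg[seq_len(neg_sizes[s]) + cn[s]][neg_sizes[s] > 0])
      out <- lapply(out, function(v) v[!is.na(v)])
    } else {
      shuf <- with_seed(seed, sample(idx))
      cs <- c(0L, cumsum(sizes))
      for (s in seq_len(k))
        out[[s]] <- shuf[seq_len(sizes[s]) + cs[s]][sizes[s] > 0]
      out <- lapply(out, function(v) v[!is.na(v)])
    }
    out
  }

  rest <- idx_all
  if (plan$foldout_fraction > 0) {
    n_fold <- round(n * plan$foldout_fraction)
    if (n_fold > 0) {
      sel <- pick_stratified(idx_all, c(n_fold, n - n_fold),
                             records$label, plan$foldout_seed)
      records$split[sel[[1L]]] <- "foldout"
      rest <- sort(sel[[2L]])
    }
  }
  sizes <- apportion(length(rest), plan$ratios)
  sel <- pick_stratified(rest, sizes, records$label[rest], plan$seed)
  records$split[sel[[1L]]] <- "train"
  records$split[sel[[2L]]] <- "valid"
  records$split[sel[[3L]]] <- "test"
  records
}

#' Write / read the molecules table
#' @param molecules molecules data.frame.
#' @param path CSV path.
#' @export
write_molecules <- function(molecules, path) {
  utils::write.csv(molecules, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_molecules
#' @export
read_molecules <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$ternary_class <- factor(df$ternary_class,
                             levels = c("inactive", "inconclusive", "active"))
  df
}
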