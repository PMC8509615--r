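#' Generate a seedable toy assay with a structure-correlated signal
#'
#' Builds `n` unique, valid SMILES from a small template grammar of alkyl
#' and aryl scaffolds. Exactly `round(n * prevalence)` records are active
#' (activity score drawn in \[40,100\]) and every active molecule carries a
#' geometry-visible marker — a dibromoaryl substituent whose heavy bromine
#' spheres dominate the rendered ball-and-stick image — while inactives
#' (scores in \[0,40)) are bromine-free. The label signal therefore lives in
#' the rendered image channel, which is what the snapshot classifier is
#' meant to learn; it emulates the imbalanced agonist/antagonist screens
#' only in form (CSV of SMILES + scores), not in chemistry-space coverage.
#'
#' @param n number of records (>= 4).
#' @param prevalence active fraction in (0,1). Default 0.25: desk-scale runs
#'   (tens of molecules) need several actives per split for stable metrics;
#'   the real screens' imbalance (about 5 percent) is reachable by setting
#'   this down.
#' @param seed integer seed; identical seeds give identical assays.
#' @return list of class `toy_assay`: records (compound_id, smiles,
#'   activity_score), prevalence, signal_rule, seed.
#' @export
generate_toy_assay <- function(n, prevalence = 0.25, seed = 0L) {
  if (!is_scalar_number(n) || n < 4) stop_snap("snap_value", "n must be >= 4")
  if (!is_scalar_number(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop_snap("snap_value", "prevalence must lie in (0,1)")
  n <- as.integer(n)
  n_active <- round(n * prevalence)
  if (n_active < 1) stop_snap("snap_value", "infeasible: n * prevalence < 1")
  if (n - n_active < 1) stop_snap("snap_value", "infeasible: no inactive records")

  # inactive grammar: alkyl chain (length ell) + terminal group, or an
  # aryl scaffold with an alkyl tail; all bromine-free
  terminals <- c("O", "N", "C(=O)O", "C(=O)N", "OC", "C(C)C", "")
  chain <- function(ell) strrep("C", ell)
  inactive_pool <- c(
    as.vector(outer(2:15, terminals,
                    function(l, t) paste0(chain(l), t))),
    paste0("c1ccccc1", chain(1:12)),
    paste0("c1ccc(", chain(1:10), ")cc1O"),
    paste0("C1CCCCC1", chain(1:8))
  )
  # active grammar: same kinds of scaffolds decorated with the dibromoaryl
  # marker (two heavy Br spheres)
  active_pool <- c(
    paste0(chain(1:15), "c1ccc(Br)c(Br)c1"),
    paste0("OC", chain(1:10), "c1cc(Br)ccc1Br"),
    paste0("N", chain(1:10), "c1ccc(Br)cc1Br")
  )
  if (n_active > length(active_pool) || (n - n_active) > length(inactive_pool))
    stop_snap("snap_value", "toy grammar exhausted: n too large (max ~%d)",
              length(active_pool) + length(inactive_pool))
  rec <- with_seed(seed, {
    act <- sample(active_pool, n_active)
    inact <- sample(inactive_pool, n - n_active)
    score_act <- stats::runif(n_active, 40, 100)
    score_inact <- stats::runif(n - n_active, 0, 39.9)
    df <- data.frame(
      smiles = c(act, inact),
      activity_score = c(score_act, score_inact),
      stringsAsFactors = FALSE
    )
    df <- df[sample(nrow(df)), , drop = FALSE]
    df$compound_id <- sprintf("TOY%04d", seq_len(nrow(df)))
    rownames(df) <- NULL
    df[c("compound_id", "smiles", "activity_score")]
  })
  structure(list(records = rec, prevalence = prevalence,
                 signal_rule = "active iff dibromoaryl marker substructure",
                 seed = as.integer(seed)),
            class = "toy_assay")
}

#' Render a complete toy snapshot dataset
#'
#' Runs the full prepare -> embed -> render chain on a toy assay at desk
#' scale and returns the image manifest, which satisfies the count law
#' n_molecules * prod(ceiling(360 / theta)).
#'
#' @param toy_assay a [generate_toy_assay()] result.
#' @param theta per-axis angle increments (degrees).
#' @param seed seed driving the split shuffle and conformer embedding.
#' @param out_dir image output directory (default: under `tempdir()`).
#' @param ratios train:valid:test ratios (default 1:1:1).
#' @param image_size snapshot side in pixels.
#' @param background background color name or RGB.
#' @return manifest data.frame (attributes: `molecules`, `spec`).
#' @export
generate_image_fixture <- function(toy_assay, theta = c(195, 195, 195),
                                   seed = 0L, out_dir = NULL,
                                   ratios = c(1, 1, 1), image_size = 256,
                                   background = "white") {
  stopifnot(inherits(toy_assay, "toy_assay"))
  out_dir <- out_dir %||% file.path(tempdir(),
                                    sprintf("snapfix_%s", hash_object(list(
                                      toy_assay$seed, theta, seed, ratios,
                                      image_size, background))))
  assay <- toy_assay$records
  assay$raw_score <- assay$activity_score
  # the grammar already emits unique canonical-enough SMILES; skip the
  # RDKit canonicalization round-trip for speed (structures are re-parsed
  # during embedding anyway)
  mols <- prepare_molecules(assay, canonicalize = FALSE)
  mols <- split_dataset(mols, split_plan(ratios = ratios, seed = seed))
  emb <- embed_conformers(mols$compound_id, mols$canonical_smiles,
                          embed_seed = seed + 100L)
  failed <- emb$status$compound_id[emb$status$status != "ok"]
  if (length(failed))
    warning(sprintf("skipping %d molecule(s) that failed embedding", length(failed)))
  mols <- mols[!mols$compound_id %in% failed, , drop = FALSE]
  spec <- snapshot_spec(theta = theta, image_size = image_size,
                        background = background)
  manifest <- generate_snapshots(emb$conformers, spec, out_dir,
                                 molecules = mols)
  attr(manifest, "molecules") <- mols
  attr(manifest, "spec") <- spec
  manifest
}

#' Permute molecule labels of a manifest (null control)
#'
#' Shuffles the label among molecules (all snapshots of one molecule keep a
#' common label) so the structure-label link is broken while the image set
#' and class balance are unchanged. Used as the permutation control a real
#' run must beat.
#'
#' @param manifest image manifest.
#' @param seed permutation seed.
#' @return manifest with permuted labels.
#' @export
permute_manifest_labels <- function(manifest, seed = 0L) {
  ids <- unique(manifest$compound_id)
  lab <- vapply(ids, function(id)
    as.numeric(manifest$label[match(id, manifest$compound_id)]), numeric(1))
  new_lab <- with_seed(seed, sample(lab))
  manifest$label <- as.integer(new_lab[match(manifest$compound_id, ids)])
  manifest
}
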