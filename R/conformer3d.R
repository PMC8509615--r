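#' Embed SMILES as single explicit-hydrogen 3D conformers
#'
#' Batch front-end to the RDKit bridge: each SMILES is reduced to its
#' largest covalent fragment, protonated with explicit hydrogens, embedded
#' by seeded distance geometry (ETKDGv3, retrying with shifted seeds) and
#' relaxed with MMFF94 (UFF fallback). Deterministic for fixed
#' (smiles, embed_seed). Embedding failures are reported per record, never
#' fatally, so the pipeline can skip and log them.
#'
#' @param ids character vector of compound ids.
#' @param smiles character vector of SMILES, same length.
#' @param embed_seed integer seed (scalar or per-record vector).
#' @return list with `conformers` (list of [conformer3d()]; names are the
#'   ids that succeeded) and `status` (data.frame: compound_id, status,
#'   canonical_smiles).
#' @export
embed_conformers <- function(ids, smiles, embed_seed = 42L) {
  stopifnot(length(ids) == length(smiles))
  if (length(ids) == 0L)
    return(list(conformers = list(),
                status = data.frame(compound_id = character(0),
                                    status = character(0),
                                    canonical_smiles = character(0))))
  seeds <- rep_len(as.integer(embed_seed), length(ids))
  fin <- tempfile(fileext = ".tsv"); fsdf <- tempfile(fileext = ".sdf")
  fst <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fsdf, fst)))
  writeLines(paste(ids, smiles, seeds, sep = "\t"), fin)
  run_rdkit(c("embed", shQuote(fin), shQuote(fsdf), shQuote(fst)))
  status <- utils::read.table(fst, sep = "\t", header = FALSE, quote = "",
                              fill = TRUE, comment.char = "",
                              col.names = c("compound_id", "status",
                                            "canonical_smiles"),
                              colClasses = "character")
  confs <- list()
  if (file.exists(fsdf) && file.info(fsdf)$size > 0) {
    confs <- read_sdf(fsdf)
    if (inherits(confs, "conformer3d")) confs <- list(confs)
    names(confs) <- vapply(confs, `[[`, character(1), "id")
    ok <- status$compound_id[status$status == "ok"]
    for (cid in names(confs)) {
      confs[[cid]]$source_smiles <-
        status$canonical_smiles[match(cid, status$compound_id)]
      confs[[cid]]$embed_seed <- seeds[match(cid, ids)]
    }
    confs <- confs[intersect(ok, names(confs))]
  }
  list(conformers = confs, status = status)
}

#' Embed one SMILES string as a 3D conformer
#'
#' @param smiles a single SMILES string.
#' @param embed_seed integer seed for the distance-geometry embedding.
#' @return a [conformer3d()].
#' @export
smiles_to_conformer <- function(smiles, embed_seed = 42L) {
  stopifnot(length(smiles) == 1L)
  res <- embed_conformers("mol", smiles, embed_seed)
  st <- res$status$status[1L]
  if (identical(st, "parse_error"))
    stop_snap("snap_smiles", "invalid SMILES: %s", smiles)
  if (identical(st, "embed_error"))
    stop_snap("snap_embed", "3D embedding failed for: %s", smiles)
  res$conformers[[1L]]
}
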