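# Bridge to the system Python + RDKit used for SMILES parsing,
# canonicalization and 3D embedding. Everything downstream (SDF parsing,
# rotation, rendering, learning, metrics) is native R.

find_python <- function() {
  cand <- c(getOption("snapqsar.python", ""),
            Sys.getenv("SNAPQSAR_PYTHON", ""),
            Sys.which("python"), Sys.which("python3"))
  cand <- cand[nzchar(cand)]
  if (length(cand) == 0L)
    stop_snap("snap_python", "no python interpreter found on PATH")
  cand[[1L]]
}

rdkit_script <- function() {
  p <- system.file("python", "rdkit_embed.py", package = "snapqsar")
  if (!nzchar(p)) stop_snap("snap_python", "rdkit_embed.py not found in package")
  p
}

run_rdkit <- function(args) {
  py <- find_python()
  res <- suppressWarnings(system2(py, c(shQuote(rdkit_script()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop_snap("snap_python", "python/rdkit call failed (exit %d):\n%s",
              status, paste(utils::tail(res, 10L), collapse = "\n"))
  res
}

#' Is an RDKit-capable Python available?
#' @return logical scalar (cached per session).
#' @export
rdkit_available <- function() {
  cached <- getOption("snapqsar.rdkit_ok")
  if (!is.null(cached)) return(cached)
  ok <- tryCatch(identical(run_rdkit("check")[1L], "CCO"),
                 error = function(e) FALSE)
  options(snapqsar.rdkit_ok = ok)
  ok
}

#' Canonical isomeric SMILES via RDKit
#'
#' Salts/mixtures are reduced to the largest covalent fragment first.
#' Unparseable SMILES yield `NA` (callers decide whether to drop or fail).
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)))
  ids <- sprintf("S%06d", seq_along(smiles))
  writeLines(paste(ids, smiles, sep = "\t"), fin)
  run_rdkit(c("canon", shQuote(fin), shQuote(fout)))
  res <- utils::read.table(fout, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", fill = TRUE,
                           col.names = c("id", "canon"),
                           colClasses = "character")
  out <- res$canon[match(ids, res$id)]
  out[is.na(out) | out == ""] <- NA_character_
  out
}
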