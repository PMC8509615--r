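#' Load and normalize a pipeline configuration
#'
#' Accepts a YAML/JSON file path or an already-built list with sections
#' `data` (input_csv or toy generator settings, split ratios,
#' foldout_fraction, seed, stratified), `render` (theta, image_size,
#' background, style), `train` (see [train_config()]) and `output` (dir).
#' Missing fields take defaults.
#'
#' @param config path or list.
#' @return normalized config list of class `snap_config`.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_snap("snap_io", "no such config: %s", config)
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  d <- config$data %||% list()
  r <- config$render %||% list()
  t <- config$train %||% list()
  o <- config$output %||% list()
  cfg <- list(
    data = list(
      input_csv = d$input_csv %||% NULL,
      toy = d$toy %||% NULL,
      ratios = as.numeric(d$ratios %||% c(1, 1, 1)),
      foldout_fraction = d$foldout_fraction %||% 0,
      seed = as.integer(d$seed %||% 1L),
      stratified = d$stratified %||% TRUE,
      canonicalize = d$canonicalize %||% is.null(d$toy)
    ),
    render = list(
      theta = as.numeric(r$theta %||% c(195, 195, 195)),
      image_size = as.integer(r$image_size %||% 256L),
      background = r$background %||% "white",
      atom_scale = r$atom_scale %||% 0.9,
      bond_radius = r$bond_radius %||% 0.16,
      margin_fraction = r$margin_fraction %||% 0.10
    ),
    train = list(
      learning_rate = t$learning_rate %||% 1e-3,
      batch_size = as.integer(t$batch_size %||% 16L),
      max_epochs = as.integer(t$max_epochs %||% 30L),
      seed = as.integer(t$seed %||% 0L),
      architecture = t$architecture %||% "small_cnn",
      replicate_count = as.integer(t$replicate_count %||% 3L),
      input_size = as.integer(t$input_size %||% 32L),
      aggregate = t$aggregate %||% "mean",
      cutoff_policy = t$cutoff_policy %||% "self"
    ),
    output = list(dir = o$dir %||% "run")
  )
  class(cfg) <- "snap_config"
  cfg
}

stage_cache_ok <- function(hash_file, hash, outputs) {
  file.exists(hash_file) && identical(readLines(hash_file, n = 1L), hash) &&
    all(file.exists(outputs))
}

write_stage_hash <- function(hash_file, hash) writeLines(hash, hash_file)

#' Execute the full pipeline from one configuration
#'
#' Runs prepare -> conformers -> snapshots -> train -> evaluate sequentially
#' as one unit. Each stage's outputs are cached under the run directory,
#' keyed by a content hash of its inputs and config subsection: a rerun with
#' an identical configuration reuses every cached stage (skip-if-present)
#' and reproduces identical metrics. A failure in any stage halts the run
#' with an error tagged by stage name.
#'
#' @param config path to a YAML/JSON config or a config list
#'   (see [load_config()]).
#' @param stop_after optional stage name ("prepare", "conformers",
#'   "snapshots") to end the run early; default runs everything.
#' @return list of class `run_record`: config hash, per-stage hashes,
#'   cache-hit flags and timings, output paths, averaged `metric_report`s
#'   per split. Also written to `<dir>/run_record.json`.
#' @export
run_all <- function(config, stop_after = NULL) {
  cfg <- load_config(config)
  dir <- cfg$output$dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  record <- list(config_hash = hash_object(unclass(cfg)), stages = list(),
                 paths = list(), reports = NULL)
  stage <- function(name, hash_input, outputs, compute) {
    t0 <- proc.time()[["elapsed"]]
    h <- hash_object(hash_input)
    hf <- file.path(dir, paste0(".", name, ".hash"))
    cached <- stage_cache_ok(hf, h, outputs)
    res <- tryCatch(compute(cached), error = function(e) {
      stop_snap("snap_stage", "stage '%s' failed: %s", name, conditionMessage(e))
    })
    if (!cached) write_stage_hash(hf, h)
    record$stages[[name]] <<- list(hash = h, cached = cached,
                                   seconds = proc.time()[["elapsed"]] - t0)
    res
  }

  # -- prepare ---------------------------------------------------------
  input_key <- if (!is.null(cfg$data$toy)) cfg$data$toy
  else list(md5 = unname(tools::md5sum(cfg$data$input_csv)))
  mol_csv <- file.path(dir, "molecules.csv")
  molecules <- stage("prepare", list(cfg$data, input_key), mol_csv, function(cached) {
    if (cached) return(read_molecules(mol_csv))
    assay <- if (!is.null(cfg$data$toy)) {
      ta <- generate_toy_assay(cfg$data$toy$n, cfg$data$toy$prevalence %||% 0.25,
                               cfg$data$toy$seed %||% 0L)
      df <- ta$records; df$raw_score <- df$activity_score; df
    } else read_assay_table(cfg$data$input_csv)
    mols <- prepare_molecules(assay, canonicalize = isTRUE(cfg$data$canonicalize))
    plan <- split_plan(ratios = cfg$data$ratios,
                       foldout_fraction = cfg$data$foldout_fraction,
                       seed = cfg$data$seed, stratified = cfg$data$stratified)
    mols <- split_dataset(mols, plan)
    write_molecules(mols, mol_csv)
    mols
  })
  record$paths$molecules <- mol_csv
  if (identical(stop_after, "prepare")) return(finish_record(record, dir, cfg))

  # -- conformers ------------------------------------------------------
  sdf_path <- file.path(dir, "conformers.sdf")
  status_csv <- file.path(dir, "embed_status.csv")
  conformers <- stage("conformers",
                      list(molecules$compound_id, molecules$canonical_smiles,
                           seed = cfg$data$seed),
                      c(sdf_path, status_csv), function(cached) {
    if (cached) {
      cf <- read_sdf(sdf_path)
      if (inherits(cf, "conformer3d")) cf <- list(cf)
      names(cf) <- vapply(cf, `[[`, character(1), "id")
      return(cf)
    }
    emb <- embed_conformers(molecules$compound_id, molecules$canonical_smiles,
                            embed_seed = cfg$data$seed + 100L)
    if (length(emb$conformers) == 0L)
      stop_snap("snap_embed", "no molecule could be embedded")
    write_sdf(emb$conformers, sdf_path)
    utils::write.csv(emb$status, status_csv, row.names = FALSE)
    bad <- emb$status$compound_id[emb$status$status != "ok"]
    if (length(bad))
      warning(sprintf("embedding skipped %d molecule(s): %s", length(bad),
                      paste(utils::head(bad, 5L), collapse = ", ")))
    emb$conformers
  })
  record$paths$conformers <- sdf_path
  if (identical(stop_after, "conformers")) return(finish_record(record, dir, cfg))

  # -- snapshots -------------------------------------------------------
  img_dir <- file.path(dir, "images")
  man_csv <- file.path(dir, "manifest.csv")
  manifest <- stage("snapshots",
                    list(cfg$render, record$stages$conformers$hash),
                    man_csv, function(cached) {
    spec <- snapshot_spec(theta = cfg$render$theta,
                          image_size = cfg$render$image_size,
                          background = cfg$render$background,
                          atom_scale = cfg$render$atom_scale,
                          bond_radius = cfg$render$bond_radius,
                          margin_fraction = cfg$render$margin_fraction)
    if (cached) {
      mf <- read_manifest(man_csv)
      if (all(file.exists(mf$image_path))) return(mf)
    }
    keep <- molecules[molecules$compound_id %in% names(conformers), , drop = FALSE]
    mf <- generate_snapshots(conformers, spec, img_dir, molecules = keep,
                             overwrite = FALSE)
    write_manifest(mf, man_csv)
    mf
  })
  record$paths$manifest <- man_csv
  record$paths$images <- img_dir
  if (identical(stop_after, "snapshots")) return(finish_record(record, dir, cfg))

  # -- train + evaluate ------------------------------------------------
  tcfg <- cfg$train
  n_rep <- tcfg$replicate_count
  reports <- list()
  stage("train", list(tcfg, record$stages$snapshots$hash), character(0),
        function(cached) {
    per_split <- list()
    for (rep_i in seq_len(n_rep)) {
      cf <- train_config(learning_rate = tcfg$learning_rate,
                         batch_size = tcfg$batch_size,
                         max_epochs = tcfg$max_epochs,
                         seed = tcfg$seed + rep_i - 1L,
                         architecture = tcfg$architecture,
                         replicate_count = n_rep,
                         input_size = tcfg$input_size,
                         aggregate = tcfg$aggregate,
                         cutoff_policy = tcfg$cutoff_policy)
      run <- train_model(manifest, cf)
      for (sp in names(run$probs))
        per_split[[sp]] <- c(per_split[[sp]], list(evaluate_split(run, sp)))
    }
    reports <<- lapply(per_split, replicate_average)
    invisible(NULL)
  })
  record$reports <- reports
  rep_dir <- file.path(dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  for (sp in names(reports))
    jsonlite::write_json(unclass(reports[[sp]]),
                         file.path(rep_dir, paste0(sp, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  record$paths$reports <- rep_dir
  finish_record(record, dir, cfg)
}

finish_record <- function(record, dir, cfg) {
  record$versions <- list(snapqsar = as.character(utils::packageVersion("snapqsar")),
                          R = paste(R.version$major, R.version$minor, sep = "."))
  record$seeds <- list(data = cfg$data$seed, train = cfg$train$seed)
  out <- record
  out$reports <- lapply(record$reports, unclass)
  jsonlite::write_json(out, file.path(dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  class(record) <- "run_record"
  record
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record", substr(x$config_hash, 1, 8), ">\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %s  %.2fs\n", s,
                if (x$stages[[s]]$cached) "cached" else "run   ",
                x$stages[[s]]$seconds))
  if (!is.null(x$reports))
    for (sp in names(x$reports))
      cat(sprintf("  %-8s ROC_AUC %.3f  BAC %.3f  MCC %.3f\n", sp,
                  x$reports[[sp]]$ROC_AUC, x$reports[[sp]]$BAC,
                  x$reports[[sp]]$MCC))
  invisible(x)
}

sweep_dims <- c("theta", "ratios", "learning_rate", "batch_size", "background")

#' Run a hyperparameter sweep
#'
#' Expands a grid over any of angle triples (`theta`), split ratios
#' (`ratios`), `learning_rate`, `batch_size` and `background`, runs the full
#' pipeline at every grid point with `replicate_count` replicates, and
#' returns one averaged result row per point. Results are appended to
#' `<out dir>/sweep_results.csv` after each point, and points already
#' present there are skipped, so an interrupted sweep resumes to an
#' identical final table.
#'
#' @param grid named list; each element a vector (or list of triples for
#'   theta/ratios) of values to sweep.
#' @param base_config pipeline config (path or list); swept fields override
#'   its data/render/train sections per point.
#' @return data.frame with one row per grid point: the point's full
#'   configuration echo plus averaged validation and test metrics.
#' @export
run_sweep <- function(grid, base_config) {
  stopifnot(is.list(grid))
  unknown <- setdiff(names(grid), sweep_dims)
  if (length(unknown))
    stop_snap("snap_config", "unknown sweep dimension(s): %s",
              paste(unknown, collapse = ", "))
  base <- load_config(base_config)
  dims <- grid[intersect(sweep_dims, names(grid))]
  if (length(dims) == 0L || prod(lengths(dims)) == 0L)
    return(data.frame())
  for (d in c("theta", "ratios"))
    if (!is.null(dims[[d]]) && !is.list(dims[[d]])) dims[[d]] <- list(dims[[d]])
  idx <- expand.grid(lapply(dims, seq_along), KEEP.OUT.ATTRS = FALSE)
  csv <- file.path(base$output$dir, "sweep_results.csv")
  dir.create(base$output$dir, showWarnings = FALSE, recursive = TRUE)
  done <- if (file.exists(csv)) utils::read.csv(csv, stringsAsFactors = FALSE)
  else NULL
  rows <- list()
  for (g in seq_len(nrow(idx))) {
    cfg <- base
    point <- list()
    for (d in names(dims)) {
      v <- dims[[d]][[idx[g, d]]]
      point[[d]] <- v
      if (d == "theta") cfg$render$theta <- v
      else if (d == "ratios") cfg$data$ratios <- v
      else if (d == "background") cfg$render$background <- v
      else cfg$train[[d]] <- v
    }
    ph <- hash_object(point)
    if (!is.null(done) && ph %in% done$point_hash) {
      rows[[g]] <- done[done$point_hash == ph, , drop = FALSE][1L, ]
      next
    }
    cfg$output$dir <- file.path(base$output$dir, paste0("point_", substr(ph, 1, 10)))
    rec <- run_all(cfg)
    row <- data.frame(
      point_hash = ph,
      theta = paste(cfg$render$theta, collapse = "x"),
      ratios = paste(cfg$data$ratios, collapse = ":"),
      learning_rate = cfg$train$learning_rate,
      batch_size = cfg$train$batch_size,
      background = if (is.character(cfg$render$background))
        cfg$render$background else paste(cfg$render$background, collapse = ","),
      N = rec$reports$valid$N %||% NA_integer_,
      stringsAsFactors = FALSE
    )
    for (sp in c("valid", "test")) {
      r <- rec$reports[[sp]]
      if (is.null(r)) next
      for (m in c("ROC_AUC", "PR_AUC", "BAC", "Acc", "F", "MCC",
                  "sensitivity", "specificity"))
        row[[paste(sp, m, sep = "_")]] <- r[[m]]
    }
    for (m in c("loss_train", "loss_valid", "loss_test"))
      row[[m]] <- rec$reports$valid[[m]] %||% NA_real_
    rows[[g]] <- row
    tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    utils::write.csv(tab, csv, row.names = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  utils::write.csv(res, csv, row.names = FALSE)
  res
}
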