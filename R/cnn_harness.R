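#' Training configuration
#'
#' @param learning_rate Adam step size (> 0). The reference sweeps span
#'   1e-5 to 4e-3; default 1e-3.
#' @param batch_size minibatch size (>= 1, <= training-set size; checked at
#'   train time). Reference sweeps span 2-70.
#' @param max_epochs epoch budget for early stopping (default 30).
#' @param seed integer seed covering weight init and batch order.
#' @param architecture "small_cnn" (3 conv blocks) or "googlenet_like"
#'   (4 wider blocks).
#' @param replicate_count N replicate runs averaged into reported metrics
#'   (default 3).
#' @param input_size square side the snapshots are area-averaged down to
#'   before entering the network (default 32; must be divisible by 2^blocks).
#' @param aggregate image-to-molecule pooling: "mean", "median" or "max".
#' @param cutoff_policy "self" (Youden cutoff from the evaluated split) or
#'   "valid" (cutoff transferred from the validation split).
#' @param patience epochs without validation improvement before stopping
#'   early (default Inf: examine the full budget, keep the minimum).
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16L,
                         max_epochs = 30L, seed = 0L,
                         architecture = c("small_cnn", "googlenet_like"),
                         replicate_count = 3L, input_size = 32L,
                         aggregate = c("mean", "median", "max"),
                         cutoff_policy = c("self", "valid"),
                         patience = Inf) {
  architecture <- match.arg(architecture)
  aggregate <- match.arg(aggregate)
  cutoff_policy <- match.arg(cutoff_policy)
  if (!is_scalar_number(learning_rate) || learning_rate < 0)
    stop_snap("snap_config", "learning_rate must be >= 0")
  if (!is_scalar_number(batch_size) || batch_size < 1)
    stop_snap("snap_config", "batch_size must be >= 1")
  if (!is_scalar_number(max_epochs) || max_epochs < 1)
    stop_snap("snap_config", "max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 architecture = architecture,
                 replicate_count = as.integer(replicate_count),
                 input_size = as.integer(input_size), aggregate = aggregate,
                 cutoff_policy = cutoff_policy, patience = patience),
            class = "train_config")
}

# area-averaging resize matrix from side S to side s (handles non-divisible)
resize_matrix <- function(S, s) {
  P <- matrix(0, s, S)
  for (i in seq_len(s)) {
    lo <- (i - 1) * S / s; hi <- i * S / s
    ks <- floor(lo):min(S - 1, ceiling(hi) - 1)
    w <- pmin(hi, ks + 1) - pmax(lo, ks)
    P[i, ks + 1] <- w / (hi - lo)
  }
  P
}

.img_cache <- new.env(parent = emptyenv())

load_image_resized <- function(path, input_size) {
  key <- paste(path, input_size, file.mtime(path))
  hit <- .img_cache[[key]]
  if (!is.null(hit)) return(hit)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  S <- dim(img)[1]
  P <- resize_matrix(S, input_size)
  out <- array(0, c(input_size, input_size, 3))
  for (ch in 1:3) out[, , ch] <- P %*% img[, , ch] %*% t(P)
  .img_cache[[key]] <- out
  out
}

# load every image of one manifest split into a [s,s,3,n] batch
load_split_images <- function(manifest, split, input_size) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  x <- array(0, c(input_size, input_size, 3L, nrow(rows)))
  for (k in seq_len(nrow(rows)))
    x[, , , k] <- load_image_resized(rows$image_path[k], input_size)
  x <- x - 0.5                      # center pixel values around zero
  list(x = x, y = as.integer(rows$label), compound_id = rows$compound_id,
       path = rows$image_path)
}

assert_no_leakage <- function(manifest) {
  tab <- unique(manifest[c("compound_id", "split")])
  dup <- duplicated(tab$compound_id)
  if (any(dup))
    stop_snap("snap_leakage",
              "molecule(s) present in more than one split: %s",
              paste(utils::head(unique(tab$compound_id[dup]), 5L), collapse = ", "))
  invisible(TRUE)
}

#' Train an image classifier on a snapshot manifest
#'
#' Trains on the train split, records per-epoch training and validation
#' cross-entropy, and returns the checkpoint with the minimum validation
#' loss within the epoch budget (early stopping). Fully seeded: identical
#' (manifest, config) inputs give identical histories, selected epochs and
#' probabilities on CPU. Per-image class-1 probabilities at the selected
#' checkpoint are kept for the valid, test and foldout splits.
#'
#' @param manifest image manifest with image_path, compound_id, split, label.
#' @param config a [train_config()].
#' @return list of class `trained_run`: history (epoch, loss_train,
#'   loss_valid), selected_epoch, losses, probs per split, config.
#' @export
train_model <- function(manifest, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  need <- c("image_path", "compound_id", "split", "label")
  if (!all(need %in% names(manifest)))
    stop_snap("snap_value", "manifest must have columns %s", paste(need, collapse = ", "))
  assert_no_leakage(manifest)
  tr <- load_split_images(manifest, "train", config$input_size)
  va <- load_split_images(manifest, "valid", config$input_size)
  if (is.null(tr) || is.null(va))
    stop_snap("snap_degenerate", "train and valid splits must be non-empty")
  if (length(unique(tr$y)) < 2L)
    stop_snap("snap_degenerate", "training split has a single class")
  if (length(unique(va$y)) < 2L)
    stop_snap("snap_degenerate", "validation split has a single class")
  n_train <- dim(tr$x)[4]
  if (config$batch_size > n_train)
    stop_snap("snap_config", "batch_size (%d) exceeds training split size (%d)",
              config$batch_size, n_train)
  te <- load_split_images(manifest, "test", config$input_size)
  fo <- load_split_images(manifest, "foldout", config$input_size)

  run <- with_seed(config$seed, {
    model <- init_cnn(config$input_size, config$architecture)
    state <- adam_init(model)
    history <- data.frame(epoch = integer(0), loss_train = numeric(0),
                          loss_valid = numeric(0))
    best <- list(loss = Inf, model = model, epoch = 0L)
    stale <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n_train)
      loss_sum <- 0
      for (start in seq(1L, n_train, by = config$batch_size)) {
        ix <- ord[start:min(n_train, start + config$batch_size - 1L)]
        xb <- tr$x[, , , ix, drop = FALSE]
        fwd <- cnn_forward(model, xb)
        sx <- softmax_xent(fwd$logits, tr$y[ix])
        loss_sum <- loss_sum + sx$loss * length(ix)
        if (config$learning_rate > 0) {
          grads <- cnn_backward(model, fwd, sx$dlogits)
          st <- adam_step(model, grads, state, config$learning_rate)
          model <- st$model; state <- st$state
        }
      }
      loss_train <- loss_sum / n_train
      ev <- cnn_evaluate(model, va$x, va$y)
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss_train = loss_train,
                                           loss_valid = ev$loss))
      if (ev$loss < best$loss - 1e-12) {
        best <- list(loss = ev$loss, model = model, epoch = epoch)
        stale <- 0L
      } else stale <- stale + 1L
      if (stale >= config$patience) break
    }
    list(model = best$model, history = history, selected_epoch = best$epoch)
  })

  probs <- list()
  split_data <- list(valid = va, test = te, foldout = fo)
  losses <- list(loss_train = run$history$loss_train[run$selected_epoch],
                 loss_valid = min(run$history$loss_valid))
  for (sp in names(split_data)) {
    d <- split_data[[sp]]
    if (is.null(d)) next
    ev <- cnn_evaluate(run$model, d$x, d$y)
    probs[[sp]] <- data.frame(compound_id = d$compound_id, label = d$y,
                              prob = ev$probs, image_path = d$path,
                              stringsAsFactors = FALSE)
    if (sp == "test") losses$loss_test <- ev$loss
  }
  structure(list(history = run$history, selected_epoch = run$selected_epoch,
                 losses = losses, probs = probs, config = config,
                 # replicates share a hash: the seed is excluded so N seeded
                 # reruns of one configuration can be averaged
                 config_hash = hash_object(
                   unclass(config)[setdiff(names(config), "seed")])),
            class = "trained_run")
}

#' @export
print.trained_run <- function(x, ...) {
  cat(sprintf("<trained_run: %d epochs, selected %d, loss_valid %.4f>\n",
              nrow(x$history), x$selected_epoch, x$losses$loss_valid))
  invisible(x)
}

#' Pool per-image probabilities into one molecule-level probability
#'
#' @param image_probs non-empty numeric vector of probabilities in \[0,1\].
#' @param method "mean" (default), "median" or "max".
#' @return scalar probability.
#' @export
aggregate_molecule <- function(image_probs, method = c("mean", "median", "max")) {
  method <- match.arg(method)
  if (length(image_probs) == 0L)
    stop_snap("snap_value", "no image probabilities to aggregate")
  if (any(!is.finite(image_probs)) || any(image_probs < 0 | image_probs > 1))
    stop_snap("snap_value", "probabilities must lie in [0,1]")
  switch(method, mean = mean(image_probs),
         median = stats::median(image_probs), max = max(image_probs))
}

molecule_level <- function(prob_df, method) {
  ids <- sort(unique(prob_df$compound_id))
  prob <- vapply(ids, function(id)
    aggregate_molecule(prob_df$prob[prob_df$compound_id == id], method),
    numeric(1))
  label <- as.integer(vapply(ids, function(id)
    as.numeric(prob_df$label[match(id, prob_df$compound_id)]), numeric(1)))
  data.frame(compound_id = ids, label = label, prob = unname(prob),
             stringsAsFactors = FALSE)
}

#' Score one split of a trained run
#'
#' Per-image probabilities are pooled per molecule ([aggregate_molecule()]),
#' a Youden cutoff is chosen according to the policy, and the full metric
#' suite is computed ([metric_report()]). If the split (or, under the
#' "valid" policy, the validation split) has a single class, the report is
#' produced at cutoff 0.5 with degenerate flags (ROC AUC reported as 0.5).
#'
#' @param run a `trained_run`.
#' @param split "valid", "test" or "foldout".
#' @param cutoff_policy overrides the config's policy if given.
#' @return a `metric_report` with losses attached and molecule-level
#'   predictions as attribute `molecules`.
#' @export
evaluate_split <- function(run, split, cutoff_policy = NULL) {
  stopifnot(inherits(run, "trained_run"))
  policy <- cutoff_policy %||% run$config$cutoff_policy
  if (is.null(run$probs[[split]]))
    stop_snap("snap_value", "no predictions for split '%s'", split)
  mol <- molecule_level(run$probs[[split]], run$config$aggregate)
  cutoff <- NULL
  if (identical(policy, "valid") && split != "valid") {
    vmol <- molecule_level(run$probs$valid, run$config$aggregate)
    if (length(unique(vmol$label)) > 1L)
      cutoff <- youden_cutoff(vmol$prob, vmol$label)$cutoff
    else cutoff <- 0.5
  }
  rep <- metric_report(mol$prob, mol$label, cutoff = cutoff, losses = run$losses)
  attr(rep, "molecules") <- mol
  attr(rep, "split") <- split
  attr(rep, "config_hash") <- run$config_hash
  rep
}

#' Average metric reports over replicate runs
#'
#' Field-wise arithmetic mean of every numeric metric across N replicates of
#' the same configuration; mixing configurations is an error. Degenerate
#' flags are unioned; N is recorded.
#'
#' @param reports non-empty list of `metric_report`s with identical configs.
#' @return averaged `metric_report` with field `N`.
#' @export
replicate_average <- function(reports) {
  if (length(reports) == 0L) stop_snap("snap_value", "no reports to average")
  hashes <- vapply(reports, function(r)
    attr(r, "config_hash") %||% NA_character_, character(1))
  hashes <- hashes[!is.na(hashes)]
  if (length(unique(hashes)) > 1L)
    stop_snap("snap_config", "cannot average reports from mixed configurations")
  fields <- names(reports[[1L]])
  out <- list()
  for (f in fields) {
    vals <- lapply(reports, `[[`, f)
    if (all(vapply(vals, is_scalar_number, logical(1))))
      out[[f]] <- mean(unlist(vals))
    else out[[f]] <- reports[[1L]][[f]]
  }
  out$degenerate_flags <- unique(unlist(lapply(reports, `[[`, "degenerate_flags")))
  out$N <- length(reports)
  structure(out, class = "metric_report")
}
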