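# Shared helpers: tiny deterministic objects built in code (no stored data).

# a hand-built asymmetric 4-atom conformer (no embedding needed)
toy_conformer <- function(id = "toy") {
  conformer3d(
    atoms = data.frame(element = c("C", "O", "N", "H"),
                       x = c(0, 1.2, -0.6, 0.3),
                       y = c(0, 0.1, 1.0, -0.9),
                       z = c(0, 0.4, -0.3, 0.8)),
    bonds = data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = c(1, 1, 1)),
    id = id
  )
}

# minimal manifest-free probability frame for harness tests
fake_prob_df <- function(ids, labels, probs) {
  data.frame(compound_id = ids, label = labels, prob = probs,
             image_path = NA_character_, stringsAsFactors = FALSE)
}

# labeled molecules table without any chemistry (for split tests)
make_mols <- function(n, n_active = max(2L, round(n / 4))) {
  df <- data.frame(
    compound_id = sprintf("M%03d", 1:n),
    canonical_smiles = sprintf("S%03d", 1:n),
    activity_score = c(rep(80, n_active), rep(5, n - n_active)),
    stringsAsFactors = FALSE
  )
  cls <- classify_activity(df$activity_score)
  df$ternary_class <- cls$ternary_class; df$label <- cls$label
  df$split <- "unassigned"
  df
}

# quick synthetic image manifest rendered from hand-built conformers;
# n molecules, half labeled 1 with an extra heavy "Br" atom as marker
tiny_rendered_manifest <- function(n = 8, out_dir = tempfile("imgs"),
                                   theta = c(360, 360, 360), image_size = 64,
                                   seed = 1) {
  set.seed(seed)
  confs <- list(); mols <- list()
  for (i in seq_len(n)) {
    lab <- as.integer(i <= n / 2)
    at <- data.frame(
      element = c("C", "C", "O", if (lab == 1L) "Br"),
      x = c(0, 1.5, -1.2, if (lab == 1L) 2.8) + stats::rnorm(3 + lab, 0, 0.05),
      y = c(0, 0.3, 0.8, if (lab == 1L) -0.5) + stats::rnorm(3 + lab, 0, 0.05),
      z = c(0, -0.2, 0.4, if (lab == 1L) 0.9) + stats::rnorm(3 + lab, 0, 0.05)
    )
    bd <- data.frame(i = c(1, 1, if (lab == 1L) 2), j = c(2, 3, if (lab == 1L) 4),
                     order = 1)
    id <- sprintf("M%03d", i)
    confs[[id]] <- conformer3d(at, bd, id = id)
    mols[[i]] <- data.frame(compound_id = id, label = lab,
                            split = c("train", "valid", "test")[1 + (i %% 3)],
                            stringsAsFactors = FALSE)
  }
  molecules <- do.call(rbind, mols)
  spec <- snapshot_spec(theta = theta, image_size = image_size)
  generate_snapshots(confs, spec, out_dir, molecules = molecules)
}
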