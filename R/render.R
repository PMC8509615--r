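#' Snapshot rendering recipe
#'
#' Style constants for the deterministic ball-and-stick rasterizer:
#' orthographic projection, painter-free z-buffer occlusion, Lambert shading
#' with a fixed light, CPK-like element colors.
#'
#' @param theta length-3 per-axis angle increments in degrees, each (0,360].
#' @param image_size square image side in pixels (>= 32; default 256).
#' @param background palette name or RGB triple in \[0,1\]^3.
#' @param atom_scale multiplier on the per-element ball radius (Angstrom).
#' @param bond_radius stick radius in Angstrom.
#' @param margin_fraction fraction of the half-frame kept clear around the
#'   molecule's bounding sphere; guarantees background-colored corners.
#' @param element_palette named list element -> RGB, merged over the CPK
#'   defaults.
#' @return list of class `snapshot_spec`.
#' @export
snapshot_spec <- function(theta = c(195, 195, 195), image_size = 256,
                          background = "white", atom_scale = 0.9,
                          bond_radius = 0.16, margin_fraction = 0.10,
                          element_palette = list()) {
  theta <- as.numeric(theta)
  if (length(theta) == 1L) theta <- rep(theta, 3L)
  if (any(theta <= 0) || any(theta > 360) || length(theta) != 3L)
    stop_snap("snap_range", "theta must be three increments in (0,360]")
  if (!is_scalar_number(image_size) || image_size < 32)
    stop_snap("snap_range", "image_size must be >= 32")
  if (margin_fraction < 0 || margin_fraction >= 1)
    stop_snap("snap_range", "margin_fraction must lie in [0,1)")
  pal <- utils::modifyList(default_element_palette, element_palette)
  structure(list(theta = theta, image_size = as.integer(image_size),
                 background = resolve_background_color(background),
                 background_name = if (is.character(background)) background else NA,
                 atom_scale = atom_scale, bond_radius = bond_radius,
                 margin_fraction = margin_fraction, element_palette = pal),
            class = "snapshot_spec")
}

elem_color <- function(pal, e) pal[[e]] %||% fallback_element_color
elem_radius <- function(e) {
  r <- element_radii[e]
  ifelse(is.na(r), fallback_element_radius, r)
}

light_dir <- local({
  v <- c(-0.40, -0.50, 0.77)
  v / sqrt(sum(v^2))
})

# Paint a shaded primitive into the scene (environment with R,G,B,Z matrices).
# rows/cols: integer index vectors; mask/z/shade: matrices over that window.
paint <- function(scene, rows, cols, mask, z, shade, color) {
  if (!length(rows) || !length(cols)) return(invisible())
  win <- scene$Z[rows, cols, drop = FALSE]
  upd <- mask & (z > win)
  if (!any(upd)) return(invisible())
  win[upd] <- z[upd]
  scene$Z[rows, cols] <- win
  for (ch in 1:3) {
    m <- scene[[c("R", "G", "B")[ch]]]
    w <- m[rows, cols, drop = FALSE]
    w[upd] <- color[ch] * shade[upd]
    m[rows, cols] <- w
    scene[[c("R", "G", "B")[ch]]] <- m
  }
  invisible()
}

shade_from_normal <- function(nx, ny, nz) {
  lam <- nx * light_dir[1] + ny * light_dir[2] + nz * light_dir[3]
  0.35 + 0.65 * pmax(lam, 0)
}

draw_sphere <- function(scene, size, cx, cy, cz, r, color) {
  cols <- max(1L, floor(cx - r)):min(size, ceiling(cx + r))
  rows <- max(1L, floor(cy - r)):min(size, ceiling(cy + r))
  if (cols[1] > cols[length(cols)] || rows[1] > rows[length(rows)]) return()
  dx <- outer(rep(1, length(rows)), cols - 0.5 - cx)
  dy <- outer(rows - 0.5 - cy, rep(1, length(cols)))
  d2 <- dx * dx + dy * dy
  mask <- d2 <= r * r
  nz2 <- pmax(1 - d2 / (r * r), 0)
  z <- cz + r * sqrt(nz2)
  shade <- shade_from_normal(dx / r, dy / r, sqrt(nz2))
  paint(scene, rows, cols, mask, z, shade, color)
}

draw_capsule <- function(scene, size, p, q, r, color) {
  # p, q: xyz in pixel space (y = screen row direction)
  x0 <- min(p[1], q[1]) - r; x1 <- max(p[1], q[1]) + r
  y0 <- min(p[2], q[2]) - r; y1 <- max(p[2], q[2]) + r
  cols <- max(1L, floor(x0)):min(size, ceiling(x1))
  rows <- max(1L, floor(y0)):min(size, ceiling(y1))
  if (cols[1] > cols[length(cols)] || rows[1] > rows[length(rows)]) return()
  px <- outer(rep(1, length(rows)), cols - 0.5)
  py <- outer(rows - 0.5, rep(1, length(cols)))
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  l2 <- vx * vx + vy * vy
  t <- if (l2 < 1e-12) 0 else pmin(pmax(((px - p[1]) * vx + (py - p[2]) * vy) / l2, 0), 1)
  nx <- px - (p[1] + t * vx); ny <- py - (p[2] + t * vy)
  d2 <- nx * nx + ny * ny
  mask <- d2 <= r * r
  nz2 <- pmax(1 - d2 / (r * r), 0)
  z <- p[3] + t * (q[3] - p[3]) + r * sqrt(nz2)
  shade <- shade_from_normal(nx / r, ny / r, sqrt(nz2))
  paint(scene, rows, cols, mask, z, shade, color)
}

#' Rasterize one snapshot of a conformer
#'
#' The conformer is rotated to the viewpoint, centered, and uniformly scaled
#' so its bounding sphere (atom centers plus ball radii) fits within
#' `1 - margin_fraction` of the frame; atoms are drawn as shaded spheres
#' colored by element, bonds as half-sticks colored by their end atoms, with
#' occlusion resolved by a z-buffer. Identical inputs yield identical pixel
#' arrays (values are pre-quantized to the 8-bit grid written to PNG).
#'
#' @param conformer a [conformer3d()].
#' @param viewpoint list/row with rx, ry, rz in degrees.
#' @param spec a [snapshot_spec()].
#' @return numeric array image_size x image_size x 3 in \[0,1\].
#' @export
render_snapshot <- function(conformer, viewpoint = list(rx = 0, ry = 0, rz = 0),
                            spec = snapshot_spec()) {
  stopifnot(inherits(conformer, "conformer3d"), inherits(spec, "snapshot_spec"))
  if (nrow(conformer$atoms) < 1L) stop_snap("snap_value", "zero-atom conformer")
  size <- spec$image_size
  rc <- rotate_conformer(conformer, viewpoint)
  xyz <- coords_matrix(rc)
  ctr <- colMeans(xyz)
  radii <- spec$atom_scale * elem_radius(rc$atoms$element)
  world_r <- max(sqrt(rowSums(sweep(xyz, 2, ctr)^2)) + radii, spec$bond_radius)
  s <- (size / 2) * (1 - spec$margin_fraction) / world_r
  cx <- (xyz[, 1] - ctr[1]) * s + size / 2
  cy <- size / 2 - (xyz[, 2] - ctr[2]) * s
  cz <- (xyz[, 3] - ctr[3]) * s
  bg <- spec$background
  scene <- new.env(parent = emptyenv())
  scene$R <- matrix(bg[1], size, size); scene$G <- matrix(bg[2], size, size)
  scene$B <- matrix(bg[3], size, size); scene$Z <- matrix(-Inf, size, size)
  rb <- spec$bond_radius * s
  if (nrow(rc$bonds) > 0L) {
    for (k in seq_len(nrow(rc$bonds))) {
      i <- rc$bonds$i[k]; j <- rc$bonds$j[k]
      a <- c(cx[i], cy[i], cz[i]); b <- c(cx[j], cy[j], cz[j])
      m <- (a + b) / 2
      draw_capsule(scene, size, a, m, rb,
                   elem_color(spec$element_palette, rc$atoms$element[i]))
      draw_capsule(scene, size, m, b, rb,
                   elem_color(spec$element_palette, rc$atoms$element[j]))
    }
  }
  for (i in seq_len(nrow(rc$atoms)))
    draw_sphere(scene, size, cx[i], cy[i], cz[i], radii[i] * s,
                elem_color(spec$element_palette, rc$atoms$element[i]))
  img <- array(0, c(size, size, 3))
  img[, , 1] <- scene$R; img[, , 2] <- scene$G; img[, , 3] <- scene$B
  round(pmin(pmax(img, 0), 1) * 255) / 255
}

fmt_angle <- function(a) gsub("\\.", "p", sprintf("%g", a))

#' Render the full snapshot set for a list of conformers
#'
#' Writes one 8-bit RGB PNG per (molecule, viewpoint) into `out_dir` and
#' returns the image manifest. File names encode the compound id and the
#' viewpoint triple. With `overwrite = FALSE` existing files are kept
#' (idempotent re-run); the manifest always lists every image.
#'
#' @param conformers non-empty list of [conformer3d()].
#' @param spec a [snapshot_spec()].
#' @param out_dir output directory (created if missing).
#' @param molecules optional molecules table supplying split and label per
#'   compound_id.
#' @param overwrite re-render files that already exist.
#' @return data.frame manifest: image_path, compound_id, rx, ry, rz, split,
#'   label.
#' @export
generate_snapshots <- function(conformers, spec, out_dir, molecules = NULL,
                               overwrite = FALSE) {
  if (inherits(conformers, "conformer3d")) conformers <- list(conformers)
  if (length(conformers) == 0L)
    stop_snap("snap_value", "empty conformer list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop_snap("snap_io", "output directory not writable: %s", out_dir)
  vps <- enumerate_viewpoints(spec$theta)
  rows <- vector("list", length(conformers) * nrow(vps))
  n <- 0L
  for (cf in conformers) {
    for (v in seq_len(nrow(vps))) {
      vp <- vps[v, ]
      fname <- sprintf("%s_x%s_y%s_z%s.png", cf$id,
                       fmt_angle(vp$rx), fmt_angle(vp$ry), fmt_angle(vp$rz))
      path <- file.path(out_dir, fname)
      if (overwrite || !file.exists(path)) {
        img <- render_snapshot(cf, vp, spec)
        png::writePNG(img, path)
      }
      n <- n + 1L
      rows[[n]] <- data.frame(image_path = path, compound_id = cf$id,
                              rx = vp$rx, ry = vp$ry, rz = vp$rz,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(molecules)) {
    m <- match(manifest$compound_id, molecules$compound_id)
    manifest$split <- molecules$split[m]
    manifest$label <- molecules$label[m]
  } else {
    manifest$split <- NA_character_; manifest$label <- NA_integer_
  }
  rownames(manifest) <- NULL
  manifest
}

#' Write / read an image manifest CSV
#' @param manifest manifest data.frame.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
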