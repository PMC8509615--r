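#' Enumerate rotational viewpoints from per-axis angle increments
#'
#' For each axis the angle set is the half-open grid \{k*theta : k >= 0,
#' k*theta < 360\} so that an increment exactly dividing 360 never duplicates
#' the identity view at 360 degrees; the count per axis is ceiling(360/theta)
#' and the total count is the product over the three axes. The result is the
#' Cartesian product in lexicographic order (x slowest, z fastest).
#'
#' The pairs printed for the real assays follow directly: 195 or 185 degrees
#' give 2 angles per axis (8 images), 176 down to 145 give 3 (27 images),
#' 100 or 95 give 4 (64 images).
#'
#' @param theta numeric length-3 increments (degrees), each in (0, 360].
#' @return data.frame with columns rx, ry, rz (degrees in \[0,360)).
#' @export
enumerate_viewpoints <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) == 1L) theta <- rep(theta, 3L)
  if (length(theta) != 3L || any(!is.finite(theta)) ||
      any(theta <= 0) || any(theta > 360))
    stop_snap("snap_range", "theta must be three increments in (0, 360]")
  axis_angles <- lapply(theta, function(t) {
    k <- 0:(ceiling(360 / t - 1e-9) - 1L)
    a <- k * t
    a[a < 360 - 1e-9]
  })
  g <- expand.grid(rz = axis_angles[[3L]], ry = axis_angles[[2L]],
                   rx = axis_angles[[1L]], KEEP.OUT.ATTRS = FALSE)
  data.frame(rx = g$rx, ry = g$ry, rz = g$rz)
}

rotation_matrix <- function(rx, ry, rz) {
  d2r <- pi / 180
  cx <- cos(rx * d2r); sx <- sin(rx * d2r)
  cy <- cos(ry * d2r); sy <- sin(ry * d2r)
  cz <- cos(rz * d2r); sz <- sin(rz * d2r)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Rotate a conformer about its centroid
#'
#' Applies Rz(rz) Ry(ry) Rx(rx) about the unweighted atom centroid;
#' interatomic distances and the centroid itself are preserved.
#'
#' @param conformer a [conformer3d()].
#' @param viewpoint list/row with rx, ry, rz in degrees.
#' @return rotated `conformer3d`.
#' @export
rotate_conformer <- function(conformer, viewpoint) {
  stopifnot(inherits(conformer, "conformer3d"))
  R <- rotation_matrix(viewpoint$rx, viewpoint$ry, viewpoint$rz)
  xyz <- coords_matrix(conformer)
  ctr <- colMeans(xyz)
  rot <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, `+`)
  conformer$atoms$x <- rot[, 1]; conformer$atoms$y <- rot[, 2]
  conformer$atoms$z <- rot[, 3]
  conformer
}
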