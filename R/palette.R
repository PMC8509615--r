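# Named background colors. Values are the PyMOL color values the rendering
# stage was calibrated against (primary names) plus the extended set used in
# the background-color sweeps.
background_palette <- list(
  aquamarine      = c(0.50, 1.00, 1.00),
  `blue-white`    = c(0.85, 0.85, 1.00),
  grey70          = c(0.70, 0.70, 0.70),
  grey80          = c(0.80, 0.80, 0.80),
  grey90          = c(0.90, 0.90, 0.90),
  `light blue`    = c(0.75, 0.75, 1.00),
  `light pink`    = c(1.00, 0.75, 0.87),
  `pale cyan`     = c(0.80, 1.00, 1.00),
  `pale green`    = c(0.65, 0.90, 0.65),
  `pale yellow`   = c(1.00, 1.00, 0.50),
  violet          = c(1.00, 0.50, 1.00),
  `bright orange` = c(1.00, 0.70, 0.20),
  `deep salmon`   = c(1.00, 0.50, 0.50),
  gold            = c(1.00, 0.82, 0.14),
  `light orange`  = c(1.00, 0.80, 0.50),
  salmon          = c(1.00, 0.60, 0.60),
  tv_orange       = c(1.00, 0.55, 0.15),
  `yellow-orange` = c(1.00, 0.87, 0.37),
  black           = c(0.00, 0.00, 0.00),
  blue            = c(0.00, 0.00, 1.00),
  cyan            = c(0.00, 1.00, 1.00),
  green           = c(0.00, 1.00, 0.00),
  magenta         = c(1.00, 0.00, 1.00),
  orange          = c(1.00, 0.50, 0.00),
  red             = c(1.00, 0.00, 0.00),
  wheat           = c(0.99, 0.82, 0.65),
  white           = c(1.00, 1.00, 1.00),
  yellow          = c(1.00, 1.00, 0.00)
)

#' Resolve a background color name or RGB triple
#'
#' Names are matched case-insensitively, treating space, hyphen and
#' underscore as interchangeable ("blue-white", "tv_orange", "Grey70", ...).
#' Explicit triples in \[0,1\]^3 pass through unchanged.
#'
#' @param name_or_rgb a palette name or numeric length-3 RGB in \[0,1\].
#' @return numeric RGB triple.
#' @export
resolve_background_color <- function(name_or_rgb) {
  if (is.numeric(name_or_rgb)) {
    if (length(name_or_rgb) != 3L || any(!is.finite(name_or_rgb)) ||
        any(name_or_rgb < 0 | name_or_rgb > 1))
      stop_snap("snap_color", "RGB triple must be three values in [0,1]")
    return(as.numeric(name_or_rgb))
  }
  key <- gsub("[-_ ]+", " ", tolower(trimws(name_or_rgb)))
  tab <- stats::setNames(background_palette,
                         gsub("[-_ ]+", " ", tolower(names(background_palette))))
  if (!key %in% names(tab))
    stop_snap("snap_color", "unknown background color '%s'; valid names: %s",
              name_or_rgb, paste(names(background_palette), collapse = ", "))
  tab[[key]]
}

# CPK-like element colors (overridable via snapshot_spec)
default_element_palette <- list(
  H = c(0.95, 0.95, 0.95), C = c(0.35, 0.35, 0.35), N = c(0.19, 0.31, 0.97),
  O = c(1.00, 0.05, 0.05), S = c(1.00, 0.90, 0.20), P = c(1.00, 0.50, 0.00),
  F = c(0.56, 0.88, 0.31), Cl = c(0.12, 0.94, 0.12), Br = c(0.65, 0.16, 0.16),
  I = c(0.58, 0.00, 0.58), B = c(1.00, 0.71, 0.71), Si = c(0.94, 0.78, 0.63)
)
fallback_element_color <- c(0.85, 0.45, 0.85)

# ball radii in Angstrom (roughly covalent+), scaled by atom_scale at render
element_radii <- c(H = 0.45, C = 0.72, N = 0.68, O = 0.64, S = 1.02, P = 1.00,
                   F = 0.60, Cl = 0.98, Br = 1.14, I = 1.33, B = 0.82,
                   Si = 1.11)
fallback_element_radius <- 0.9
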