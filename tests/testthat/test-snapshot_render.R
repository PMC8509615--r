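test_that("enumerate_viewpoints obeys the product count law (brute force)", {
  brute_count <- function(t) {
    per_axis <- function(th) { k <- 0; while (k * th < 360 - 1e-9) k <- k + 1; k }
    per_axis(t[1]) * per_axis(t[2]) * per_axis(t[3])
  }
  set.seed(4)
  thetas <- c(runif(30, 1, 360), 120, 90, 180, 360, 176, 195)  # incl. exact divisors
  for (t in thetas) {
    th <- c(t, t, t)
    vp <- enumerate_viewpoints(th)
    expect_equal(nrow(vp), brute_count(th))
    expect_equal(nrow(vp), prod(ceiling(360 / th - 1e-9)))
    expect_true(all(vp$rx >= 0 & vp$rx < 360))
    expect_true(all(vp$rx %% t < 1e-6 | t - vp$rx %% t < 1e-6))
  }
  # mixed increments and lexicographic order
  vp <- enumerate_viewpoints(c(195, 176, 360))
  expect_equal(nrow(vp), 2 * 3 * 1)
  expect_equal(vp$rx, c(0, 0, 0, 195, 195, 195))
  expect_equal(vp$ry, c(0, 176, 352, 0, 176, 352))
  expect_equal(nrow(enumerate_viewpoints(c(360, 360, 360))), 1)
  expect_error(enumerate_viewpoints(c(0, 10, 10)), class = "snap_range")
  expect_error(enumerate_viewpoints(c(-5, 10, 10)), class = "snap_range")
})

test_that("rotate_conformer: identity, composition, centroid, rigidity", {
  cf <- toy_conformer()
  xyz0 <- as.matrix(cf$atoms[c("x", "y", "z")])
  id <- rotate_conformer(cf, list(rx = 0, ry = 0, rz = 0))
  expect_equal(as.matrix(id$atoms[c("x", "y", "z")]), xyz0, tolerance = 1e-12)

  # applying (90,0,0) twice equals (180,0,0)
  twice <- rotate_conformer(rotate_conformer(cf, list(rx = 90, ry = 0, rz = 0)),
                            list(rx = 90, ry = 0, rz = 0))
  once <- rotate_conformer(cf, list(rx = 180, ry = 0, rz = 0))
  expect_equal(as.matrix(twice$atoms[c("x", "y", "z")]),
               as.matrix(once$atoms[c("x", "y", "z")]), tolerance = 1e-9)

  set.seed(6)
  for (i in 1:10) {
    vp <- list(rx = runif(1, 0, 360), ry = runif(1, 0, 360), rz = runif(1, 0, 360))
    r <- rotate_conformer(cf, vp)
    xyz <- as.matrix(r$atoms[c("x", "y", "z")])
    expect_equal(colMeans(xyz), colMeans(xyz0), tolerance = 1e-9)
    expect_equal(as.vector(dist(xyz)), as.vector(dist(xyz0)), tolerance = 1e-9)
  }
})

test_that("background colors resolve to their published RGB values", {
  expect_equal(resolve_background_color("aquamarine"), c(0.5, 1.0, 1.0))
  expect_equal(resolve_background_color("blue-white"), c(0.85, 0.85, 1.00))
  expect_equal(resolve_background_color("Grey70"), c(0.7, 0.7, 0.7))
  expect_equal(resolve_background_color("Grey80"), c(0.8, 0.8, 0.8))
  expect_equal(resolve_background_color("Grey90"), c(0.9, 0.9, 0.9))
  expect_equal(resolve_background_color("light blue"), c(0.75, 0.75, 1.00))
  expect_equal(resolve_background_color("light pink"), c(1.00, 0.75, 0.87))
  expect_equal(resolve_background_color("pale cyan"), c(0.8, 1.0, 1.0))
  expect_equal(resolve_background_color("pale green"), c(0.65, 0.90, 0.65))
  expect_equal(resolve_background_color("pale yellow"), c(1.0, 1.0, 0.5))
  expect_equal(resolve_background_color("violet"), c(1.0, 0.5, 1.0))
  expect_equal(resolve_background_color("bright orange"), c(1.0, 0.7, 0.2))
  expect_equal(resolve_background_color("deep salmon"), c(1.0, 0.5, 0.5))
  expect_equal(resolve_background_color("gold"), c(1.00, 0.82, 0.14))
  expect_equal(resolve_background_color("light orange"), c(1.0, 0.8, 0.5))
  expect_equal(resolve_background_color("salmon"), c(1.0, 0.6, 0.6))
  expect_equal(resolve_background_color("tv_orange"), c(1.00, 0.55, 0.15))
  expect_equal(resolve_background_color("yellow-orange"), c(1.00, 0.87, 0.37))
  expect_equal(resolve_background_color("black"), c(0, 0, 0))
  for (nm in c("blue", "cyan", "green", "magenta", "orange", "red",
               "wheat", "white", "yellow")) {
    v <- resolve_background_color(nm)
    expect_length(v, 3); expect_true(all(v >= 0 & v <= 1))
  }
  expect_equal(resolve_background_color(c(0.2, 0.3, 0.4)), c(0.2, 0.3, 0.4))
  err <- tryCatch(resolve_background_color("no-such-color"), error = identity)
  expect_s3_class(err, "snap_color")
  expect_match(conditionMessage(err), "aquamarine")   # lists valid names
  expect_error(resolve_background_color(c(1, 2, 3)), class = "snap_color")
})

test_that("render_snapshot honors the pixel contract", {
  cf <- toy_conformer()
  spec <- snapshot_spec(image_size = 64, background = "wheat")
  img <- render_snapshot(cf, list(rx = 0, ry = 0, rz = 0), spec)
  expect_equal(dim(img), c(64, 64, 3))
  bg <- round(resolve_background_color("wheat") * 255) / 255
  for (rc in list(c(1, 1), c(1, 64), c(64, 1), c(64, 64)))
    expect_equal(img[rc[1], rc[2], ], bg)
  # deterministic re-render
  img2 <- render_snapshot(cf, list(rx = 0, ry = 0, rz = 0), spec)
  expect_identical(img, img2)
  # viewpoint sensitivity on an asymmetric molecule
  rot <- render_snapshot(cf, list(rx = 90, ry = 45, rz = 0), spec)
  expect_false(identical(img, rot))
  # default size is 256
  big <- render_snapshot(cf, list(rx = 0, ry = 0, rz = 0), snapshot_spec())
  expect_equal(dim(big), c(256, 256, 3))
})

test_that("changing only the background recolors only old-background pixels", {
  cf <- toy_conformer()
  a <- render_snapshot(cf, list(rx = 10, ry = 20, rz = 30),
                       snapshot_spec(image_size = 64, background = "white"))
  b <- render_snapshot(cf, list(rx = 10, ry = 20, rz = 30),
                       snapshot_spec(image_size = 64, background = "grey70"))
  diff <- which(a != b, arr.ind = TRUE)
  changed <- unique(diff[, 1:2, drop = FALSE])
  for (k in seq_len(nrow(changed)))
    expect_equal(a[changed[k, 1], changed[k, 2], ], c(1, 1, 1))
})

test_that("generate_snapshots: counts, manifest, idempotent re-run", {
  cfs <- list(toy_conformer("m1"))
  spec <- snapshot_spec(theta = c(195, 195, 195), image_size = 48)
  d <- tempfile("snaps")
  mf <- generate_snapshots(cfs, spec, d)
  expect_equal(nrow(mf), 8L)
  expect_length(list.files(d, pattern = "\\.png$"), 8L)
  expect_true(all(file.exists(mf$image_path)))

  # two molecules at 176 degrees: 2 x 27 files
  cfs2 <- list(toy_conformer("m1"), toy_conformer("m2"))
  d2 <- tempfile("snaps")
  mf2 <- generate_snapshots(cfs2, snapshot_spec(theta = c(176, 176, 176),
                                                image_size = 32), d2)
  expect_equal(nrow(mf2), 54L)
  expect_length(list.files(d2, pattern = "\\.png$"), 54L)

  # idempotent: overwrite = FALSE leaves existing files untouched
  before <- file.mtime(mf$image_path)
  mfr <- generate_snapshots(cfs, spec, d, overwrite = FALSE)
  expect_identical(mfr$image_path, mf$image_path)
  expect_identical(file.mtime(mf$image_path), before)

  expect_error(generate_snapshots(list(), spec, tempfile()),
               class = "snap_value")
})

test_that("written PNGs round-trip the rendered array (external decoder check)", {
  cf <- toy_conformer()
  img <- render_snapshot(cf, list(rx = 0, ry = 0, rz = 0),
                         snapshot_spec(image_size = 48, background = "salmon"))
  f <- tempfile(fileext = ".png")
  png::writePNG(img, f)
  back <- png::readPNG(f)
  expect_equal(back, img, tolerance = 1e-12)
})
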