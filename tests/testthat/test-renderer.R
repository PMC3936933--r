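ortho_cam <- function(half = 10, dist = 50) {
  camera("orthographic", eye = c(0, 0, dist), target = c(0, 0, 0),
         half_height = half, near = 1, far = 200)
}

test_that("projection maps target to center and half-height to the top edge", {
  cam <- ortho_cam(half = 10)
  p <- project(cam, c(0, 0, 0), viewport = c(200, 100))
  expect_equal(p$x_px, 100)
  expect_equal(p$y_px, 50)

  top <- project(cam, c(0, 10, 0), viewport = c(200, 100))
  expect_equal(top$y_px, 0)
  expect_equal(top$x_px, 100)

  pc <- camera("perspective", eye = c(0, 0, 50), target = c(0, 0, 0),
               fov_deg = 45, near = 1, far = 200)
  ctr <- project(pc, c(0, 0, 0), viewport = c(100, 100))
  expect_equal(ctr$x_px, 50)
  expect_error(project(pc, c(0, 0, 60), viewport = c(100, 100)),
               class = "molscene_error_behind_camera")
})

test_that("camera invariants are enforced", {
  expect_error(camera("perspective", near = -1))
  expect_error(camera("orthographic", near = 5, far = 2))
  expect_error(camera(eye = c(0, 0, 10), target = c(0, 0, 0),
                      up = c(0, 0, 1)))
})

test_that("empty scenes fill with the requested background", {
  for (bg in c("black", "grey", "white")) {
    img <- rasterize(list(), width = 20, height = 10, background = bg)
    expect_equal(dim(img), c(10, 20, 3))
    val <- c(black = 0, grey = 0.5, white = 1)[[bg]]
    expect_true(all(img == val))
  }
})

test_that("triangle fill matches the half-plane pixel oracle", {
  cam <- ortho_cam(half = 10)
  # screen-aligned triangle with known world vertices
  verts <- rbind(c(-5, -5, 0), c(5, -5, 0), c(0, 6, 0))
  batch <- molscene:::new_geometry_batch(
    "triangles", verts, matrix(c(1, 0, 0), 3, 3, byrow = TRUE),
    matrix(1:3, 1), 1:3)
  batch$normals <- matrix(c(0, 0, 1), 3, 3, byrow = TRUE)
  width <- 100; height <- 100
  img <- rasterize(list(batch), cam, width, height, "black")
  filled <- sum(img[, , 1] > 0)
  sv <- as.matrix(project(cam, verts, viewport = c(width, height)))
  oracle <- triangle_pixel_oracle(sv, width, height)
  perimeter <- sum(sqrt(rowSums((sv[c(2, 3, 1), 1:2] - sv[, 1:2])^2)))
  expect_lte(abs(filled - oracle), perimeter)
})

test_that("the z-buffer resolves overlap by depth", {
  cam <- ortho_cam()
  near_tri <- rbind(c(-4, -4, 5), c(4, -4, 5), c(0, 4, 5))
  far_tri <- rbind(c(-4, -4, -5), c(4, -4, -5), c(0, 4, -5))
  mk <- function(v, col) {
    b <- molscene:::new_geometry_batch(
      "triangles", v, matrix(col, 3, 3, byrow = TRUE), matrix(1:3, 1), 1:3)
    b$normals <- matrix(c(0, 0, 1), 3, 3, byrow = TRUE)
    b
  }
  # draw far-first and near-first: overlap pixels must agree (near wins)
  img1 <- rasterize(list(mk(far_tri, c(0, 1, 0)), mk(near_tri, c(1, 0, 0))),
                    cam, 60, 60, "black")
  img2 <- rasterize(list(mk(near_tri, c(1, 0, 0)), mk(far_tri, c(0, 1, 0))),
                    cam, 60, 60, "black")
  expect_identical(img1, img2)
  # the overlap center shows the near triangle's red
  expect_gt(img1[30, 30, 1], 0)
  expect_equal(img1[30, 30, 2], 0)
})

test_that("translucent surfaces blend against opaque geometry", {
  cam <- ortho_cam()
  tri <- rbind(c(-4, -4, 0), c(4, -4, 0), c(0, 4, 0))
  b <- molscene:::new_geometry_batch(
    "triangles", tri, matrix(c(1, 1, 1), 3, 3, byrow = TRUE),
    matrix(1:3, 1), 1:3)
  b$normals <- matrix(c(0, 0, 1), 3, 3, byrow = TRUE)
  img <- rasterize(list(b), cam, 40, 40, "black", opacity = 0.5)
  ctr <- img[20, 20, 1]
  expect_gt(ctr, 0.2)
  expect_lt(ctr, 0.8)  # half-blended toward the black background
})

test_that("repeated renders are byte-identical through PNG", {
  hx <- parse_pdb(synth_pdb("mini_helix", n = 10))
  cam <- default_camera(hx)
  batch <- build_secondary(hx, "ribbon")
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_image_png(rasterize(list(batch), cam, 120, 90, "white"), f1)
  write_image_png(rasterize(list(batch), cam, 120, 90, "white"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("anaglyph disparity is zero at zero separation and monotone in it", {
  # sphere in front of the convergence target, so the two converging
  # views see it at different horizontal positions
  at <- single_atom(r = 2)
  ctr <- c(0, 0, 6)
  at$z <- ctr[3]
  sph <- build_primary(at, "sphere")
  cam <- camera("orthographic", eye = c(0, 0, 20), target = c(0, 0, 0),
                half_height = 5, near = 1, far = 100)

  an0 <- render_anaglyph(list(sph), cam, 0, 80, 80)
  expect_identical(an0[, , 1], an0[, , 2])
  expect_identical(an0[, , 2], an0[, , 3])

  centroid_x <- function(channel) sum(col(channel) * channel) / sum(channel)
  disparity <- vapply(c(0, 1, 2, 4), function(sep) {
    an <- render_anaglyph(list(sph), cam, sep, 80, 80)
    abs(centroid_x(an[, , 1]) - centroid_x(an[, , 2]))
  }, numeric(1))
  expect_equal(disparity[1], 0)
  expect_true(all(diff(disparity) > 0))

  # projection oracle: build the displaced converging cameras explicitly
  # and project the sphere center through each
  sep <- 3
  cam_l <- camera("orthographic", eye = c(-sep / 2, 0, 20),
                  target = c(0, 0, 0), half_height = 5, near = 1, far = 100)
  cam_r <- camera("orthographic", eye = c(sep / 2, 0, 20),
                  target = c(0, 0, 0), half_height = 5, near = 1, far = 100)
  expected_px <- project(cam_r, ctr, c(80, 80))$x_px -
    project(cam_l, ctr, c(80, 80))$x_px
  an <- render_anaglyph(list(sph), cam, sep, 80, 80)
  measured <- centroid_x(an[, , 2]) - centroid_x(an[, , 1])
  expect_lt(abs(measured - expected_px), 1)

  # empty scene: background only
  bgonly <- render_anaglyph(list(), cam, 3, 30, 30, "grey")
  expect_true(all(abs(bgonly - 0.5) < 1e-12))
})

test_that("labels draw at projected anchors and skip off-screen ones", {
  cam <- ortho_cam(half = 10)
  img <- rasterize(list(), cam, 100, 100, "black")
  lbl <- tibble::tibble(text = "A:GLY 1:N", x = 0, y = 0, z = 0,
                        serial = 1L)
  out <- draw_labels(img, lbl, cam)
  expect_gt(sum(out != img), 0)
  # drawn near the projected center plus the fixed offset
  changed <- which(out[, , 1] != img[, , 1], arr.ind = TRUE)
  expect_true(all(changed[, 1] >= 40 & changed[, 1] <= 60))

  off <- tibble::tibble(text = "X", x = 1e5, y = 0, z = 0, serial = 1L)
  expect_identical(draw_labels(img, off, cam), img)

  behind <- tibble::tibble(text = "X", x = 0, y = 0, z = 500, serial = 1L)
  expect_identical(draw_labels(img, behind, cam), img)

  expect_identical(draw_labels(img, lbl[0, ], cam), img)
})
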