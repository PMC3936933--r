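test_that("grids enclose inflated atoms and honor the dimension cap", {
  one <- single_atom(r = 2)
  g <- build_grid(one, probe_radius = 0, target_resolution = 4)
  expect_equal(g$spacing, 0.25)
  # box side ~ 2*r plus margins: (2*2) * 4 voxels + 1 + 2*2 margin
  expect_equal(g$dims, rep(21L, 3))
  expect_true(all(g$dims <= 180))
  # atom sphere plus margin is inside the box
  expect_true(all(g$origin <= -2))
  expect_true(all(g$origin + (g$dims - 1) * g$spacing >= 2))

  # a 200 A-spanning structure coarsens, never crops
  wide <- atoms_at(rbind(c(-100, 0, 0), c(100, 0, 0)))
  gw <- build_grid(wide, 0, 4)
  expect_true(all(gw$dims <= 180))
  expect_gt(gw$spacing, 0.25)

  gc <- build_grid(wide, 0, 4, cap = 10)
  expect_true(all(gc$dims <= 10))

  expect_error(build_grid(atoms_at(matrix(0, 0, 3))),
               class = "molscene_error_no_atoms")
})

test_that("signed distance field matches the closed form and tie-breaks by index", {
  at <- single_atom(r = 1.5)
  g <- structure(list(origin = c(-4, -4, -4), spacing = 0.25,
                      dims = c(33L, 33L, 33L)), class = "grid_spec")
  f <- min_signed_distance_field(at, g)
  ax <- seq(g$origin[1], by = g$spacing, length.out = g$dims[1])
  ic <- which(abs(ax) < 1e-9)
  expect_equal(f$values[ic, ic, ic], -1.5)
  i3 <- which(abs(ax - 3) < 1e-9)
  expect_equal(f$values[i3, ic, ic], 1.5)

  # two equidistant atoms: the midpoint voxel goes to the lower index
  two <- atoms_at(rbind(c(-2, 0, 0), c(2, 0, 0)), r = 1)
  g2 <- build_grid(two, 0, 2)
  f2 <- min_signed_distance_field(two, g2)
  ax2 <- seq(g2$origin[1], by = g2$spacing, length.out = g2$dims[1])
  mid <- which(abs(ax2) < 1e-9)
  i0 <- which(abs(ax2) < 1e-9)
  expect_equal(f2$nearest[mid, i0, i0], 1L)
})

test_that("exact EDT equals the brute-force nearest-feature scan", {
  # degenerate cases
  all_on <- array(TRUE, c(4, 4, 4))
  expect_true(all(exact_edt(all_on)$values == 0))
  one_on <- array(FALSE, c(5, 5, 5))
  one_on[3, 3, 3] <- TRUE
  ed <- exact_edt(one_on)
  expect_equal(ed$values[1, 1, 1], sqrt(12), tolerance = 1e-12)
  expect_error(exact_edt(array(FALSE, c(3, 3, 3))),
               class = "molscene_error_no_features")

  # 20 random masks vs the oracle
  set.seed(7)
  for (rep in 1:20) {
    d <- sample(4:10, 3, replace = TRUE)
    mask <- array(stats::runif(prod(d)) < 0.1, dim = d)
    if (!any(mask)) mask[1, 1, 1] <- TRUE
    expect_equal(exact_edt(mask)$values, brute_edt(mask), tolerance = 1e-12)
  }
})

test_that("isosurfaces reproduce analytic solids and are watertight", {
  # uniform field: no crossing, empty mesh
  g <- structure(list(origin = c(0, 0, 0), spacing = 1,
                      dims = c(6L, 6L, 6L)), class = "grid_spec")
  uni <- molscene:::new_scalar_field(g, array(1, c(6, 6, 6)))
  expect_equal(nrow(extract_isosurface(uni)$triangles), 0)

  # axis-aligned box via its signed (Chebyshev) distance: volume within 2%
  dims <- c(61L, 51L, 41L)
  h <- 0.1
  gb <- structure(list(origin = c(0, 0, 0), spacing = h, dims = dims),
                  class = "grid_spec")
  ctr <- (dims - 1) * h / 2
  half <- c(2.0, 1.5, 1.0)
  qx <- abs(seq(0, by = h, length.out = dims[1]) - ctr[1]) - half[1]
  qy <- abs(seq(0, by = h, length.out = dims[2]) - ctr[2]) - half[2]
  qz <- abs(seq(0, by = h, length.out = dims[3]) - ctr[3]) - half[3]
  vals <- pmax(array(qx, dims),
               aperm(array(qy, dims[c(2, 1, 3)]), c(2, 1, 3)),
               aperm(array(qz, dims[c(3, 1, 2)]), c(2, 3, 1)))
  mesh <- extract_isosurface(molscene:::new_scalar_field(gb, vals))
  av <- mesh_area_volume(mesh)
  expect_equal(unname(av["volume"]), prod(2 * half), tolerance = 0.02)
  expect_true(is_watertight(mesh))

  # sphere fully inside: watertight, orientable, unit normals
  at <- single_atom(r = 2)
  f <- min_signed_distance_field(at, build_grid(at, 0, 4))
  ms <- extract_isosurface(f)
  expect_true(is_watertight(ms))
  expect_true(is_orientable(ms))
  expect_lt(max(abs(sqrt(rowSums(ms$normals^2)) - 1)), 1e-6)
  expect_true(all(ms$vertex_atom == 1))
  expect_true(all(ms$triangles >= 1 & ms$triangles <= nrow(ms$vertices)))
})

test_that("surface areas converge to the analytic sphere values", {
  # VdW of one atom: 4 pi r^2 within 5% at 4 voxels/A
  at <- single_atom(r = 2)
  m <- compute_surface(at, "vdw", target_resolution = 4)
  expect_equal(unname(mesh_area_volume(m)["area"]), 4 * pi * 4,
               tolerance = 0.05)

  # convergence: finer grid gets closer
  err_at <- function(res) {
    a <- mesh_area_volume(compute_surface(at, "vdw", target_resolution = res))["area"]
    abs(a / (4 * pi * 4) - 1)
  }
  expect_lt(err_at(5), 0.05)
  expect_lt(err_at(2.5), 0.08)

  # SES of one atom is the atom itself (closing of a single sphere)
  a17 <- single_atom(r = 1.7)
  ses <- compute_surface(a17, "ses", probe_radius = 1.4,
                         target_resolution = 4)
  expect_equal(unname(mesh_area_volume(ses)["area"]), 4 * pi * 1.7^2,
               tolerance = 0.05)

  # SAS of two far-apart atoms: two disjoint inflated spheres
  two <- atoms_at(rbind(c(0, 0, 0), c(20, 0, 0)), r = 1.7)
  sas <- compute_surface(two, "sas", probe_radius = 1.4,
                         target_resolution = 4)
  expect_equal(unname(mesh_area_volume(sas)["area"]), 2 * 4 * pi * 3.1^2,
               tolerance = 0.05)
})

test_that("solids nest (VdW in SES/MS in SAS) and the two SES routes agree to one voxel", {
  cl <- atoms_at(rbind(c(0, 0, 0), c(2.6, 0.4, 0), c(1.2, 2.1, 0.8),
                       c(0.4, 0.9, 2.2)), r = c(1.7, 1.55, 1.52, 1.8))
  sol <- molscene:::surface_solids(cl, probe_radius = 1.4,
                                   target_resolution = 3)
  expect_true(all(sol$ses[sol$vdw]))
  expect_true(all(sol$ms[sol$vdw]))
  expect_true(all(sol$sas[sol$ses]))
  expect_true(all(sol$sas[sol$ms]))

  # erosion vs closing: any differing voxel touches the solid boundary
  diff <- which(sol$ses != sol$ms, arr.ind = TRUE)
  if (nrow(diff) > 0) {
    near_boundary <- vapply(seq_len(nrow(diff)), function(r) {
      i <- diff[r, 1]; j <- diff[r, 2]; k <- diff[r, 3]
      nb <- expand.grid(i = i + (-1:1), j = j + (-1:1), k = k + (-1:1))
      nb <- nb[nb$i >= 1 & nb$i <= dim(sol$ses)[1] &
                 nb$j >= 1 & nb$j <= dim(sol$ses)[2] &
                 nb$k >= 1 & nb$k <= dim(sol$ses)[3], ]
      v <- sol$ses[cbind(nb$i, nb$j, nb$k)]
      any(v) && !all(v)
    }, logical(1))
    expect_true(all(near_boundary))
  }
  succeed()
})

test_that("Laplacian smoothing preserves topology and flat patches", {
  at <- single_atom(r = 2)
  m <- compute_surface(at, "vdw")
  expect_identical(smooth_mesh(m, 0), m)

  sm <- smooth_mesh(m, 2)
  expect_identical(sm$triangles, m$triangles)
  a0 <- mesh_area_volume(m)["area"]
  a2 <- mesh_area_volume(sm)["area"]
  expect_lt(abs(a2 / a0 - 1), 0.05)
  # per-iteration drift bounded by the voxel spacing
  s1 <- smooth_mesh(m, 1)
  drift <- max(sqrt(rowSums((s1$vertices - m$vertices)^2)))
  expect_lte(drift, m$grid$spacing)

  # flat triangulated grid: interior vertices are fixed points
  nx <- 6
  gpts <- as.matrix(expand.grid(x = 1:nx, y = 1:nx))
  verts <- cbind(gpts, 0)
  id <- function(i, j) (j - 1) * nx + i
  tri <- matrix(0L, 0, 3)
  for (j in 1:(nx - 1)) for (i in 1:(nx - 1)) {
    tri <- rbind(tri,
                 c(id(i, j), id(i + 1, j), id(i, j + 1)),
                 c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  flat <- molscene:::new_mol_mesh(verts, matrix(rep(c(0, 0, 1), each = nx^2), ncol = 3),
                                  tri)
  out <- smooth_mesh(flat, 1)
  interior <- which(gpts[, 1] > 1 & gpts[, 1] < nx &
                      gpts[, 2] > 1 & gpts[, 2] < nx)
  # staying in the plane is the harmonic fixed-point property
  expect_lt(max(abs(out$vertices[interior, 3])), 1e-6)
})

test_that("area and volume match closed forms", {
  rt <- molscene:::new_mol_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                                matrix(c(0, 0, 1), 3, 3, byrow = TRUE),
                                matrix(c(1L, 2L, 3L), 1))
  expect_equal(unname(mesh_area_volume(rt)), c(0.5, 0), tolerance = 1e-12)

  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6)   # x = 1
  )
  cube <- molscene:::new_mol_mesh(v, matrix(0, 8, 3), tri)
  av <- mesh_area_volume(cube)
  expect_equal(unname(av["area"]), 6)
  expect_equal(unname(av["volume"]), 1)
  expect_true(is_watertight(cube))

  expect_equal(unname(mesh_area_volume(molscene:::empty_mesh())), c(0, 0))
})

test_that("mesh writers emit valid OBJ and PLY", {
  at <- single_atom(r = 1.5)
  m <- compute_surface(at, "vdw", target_resolution = 2)
  fo <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, fo)
  lines <- readLines(fo)
  expect_equal(sum(startsWith(lines, "v ")), nrow(m$vertices))
  expect_equal(sum(startsWith(lines, "vn ")), nrow(m$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(m$triangles))

  fw <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, fw, wireframe = TRUE)
  expect_gt(sum(startsWith(readLines(fw), "l ")), 0)

  fp <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, fp)
  hdr <- readLines(fp, n = 3, warn = FALSE)
  expect_equal(hdr[1], "ply")
  expect_match(hdr[2], "binary_little_endian")
})
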