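# EDT-based macromolecular surface construction on a capped voxel grid.
#
# The pipeline mirrors the classic distance-transform surface algorithm:
# voxelize the atom spheres, take exact Euclidean distances, and extract a
# triangulated isosurface. The calculation grid is capped (default
# 180x180x180); when a molecule would exceed the cap the grid is uniformly
# coarsened, never cropped.

#' Build a capped voxel grid around a set of atoms
#'
#' The grid box encloses every atom sphere inflated by
#' `vdw_radius + probe_radius`, plus a margin of `margin_voxels` voxels on
#' each side. Spacing starts at `1/target_resolution` and is uniformly
#' coarsened until every dimension is at most `cap` (default 180).
#'
#' @param atoms A `mol_structure` or data frame with `x`, `y`, `z`,
#'   `vdw_radius` columns.
#' @param probe_radius Probe inflation in Angstrom.
#' @param target_resolution Target voxels per Angstrom.
#' @param cap Maximum grid dimension.
#' @param margin_voxels Margin voxels added on every side.
#' @return A `grid_spec`: list with `origin` (A), `spacing` (A/voxel,
#'   isotropic) and `dims` (3 integers, each `<= cap`).
#' @export
build_grid <- function(atoms, probe_radius = 0, target_resolution = 4,
                       cap = 180, margin_voxels = 2) {
  atoms <- as_atom_table(atoms, "atoms")
  if (nrow(atoms) == 0) msg_abort("no atoms to grid", "no_atoms")
  r_inf <- atoms$vdw_radius + probe_radius
  lo <- c(min(atoms$x - r_inf), min(atoms$y - r_inf), min(atoms$z - r_inf))
  hi <- c(max(atoms$x + r_inf), max(atoms$y + r_inf), max(atoms$z + r_inf))
  extent <- hi - lo
  spacing <- 1 / target_resolution
  dims_for <- function(h) as.integer(ceiling(extent / h) + 1L + 2L * margin_voxels)
  dims <- dims_for(spacing)
  if (max(dims) > cap) {
    # uniform coarsening: solve for the spacing that puts the largest axis
    # exactly at the cap
    spacing <- max(extent) / (cap - 1 - 2 * margin_voxels)
    dims <- pmin(dims_for(spacing), cap)
  }
  origin <- lo - margin_voxels * spacing
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid_spec")
}

grid_n_voxels <- function(grid) prod(as.double(grid$dims))

new_scalar_field <- function(grid, values, nearest = NULL) {
  structure(list(grid = grid,
                 values = array(values, dim = grid$dims),
                 nearest = if (!is.null(nearest)) array(nearest, dim = grid$dims)),
            class = "scalar_field")
}

#' Minimum signed distance field over atom spheres
#'
#' `value(v) = min_a (||v - c_a|| - (vdw_radius_a + inflation))` at every
#' voxel center; `nearest` holds the argmin atom index (ties go to the
#' lowest atom index). The zero level set of this field is the van der
#' Waals surface (`inflation = 0`) or the solvent accessible surface
#' (`inflation = probe_radius`).
#'
#' @param atoms Atom table with `x`, `y`, `z`, `vdw_radius`.
#' @param grid A `grid_spec`.
#' @param inflation Radius inflation in Angstrom.
#' @return A `scalar_field` with `values` (A) and `nearest` atom indices.
#' @export
min_signed_distance_field <- function(atoms, grid, inflation = 0) {
  atoms <- as_atom_table(atoms, "atoms")
  if (nrow(atoms) == 0) msg_abort("no atoms", "no_atoms")
  res <- min_signed_field_cpp(
    cbind(atoms$x, atoms$y, atoms$z), atoms$vdw_radius + inflation,
    grid$origin, grid$spacing, grid$dims
  )
  new_scalar_field(grid, res$values, res$nearest)
}

#' Exact Euclidean distance transform of a binary mask
#'
#' Per-voxel exact Euclidean distance, in voxel units, to the nearest
#' feature voxel (Felzenszwalb-Huttenlocher separable algorithm on squared
#' distances). Labels attached to feature voxels (e.g. nearest-atom
#' indices) are propagated to every voxel along with the distance.
#'
#' @param mask A logical array, or a `scalar_field` whose non-zero values
#'   mark features.
#' @param labels Optional integer array of per-feature-voxel labels.
#' @param grid Optional `grid_spec` (taken from `mask` when it is a
#'   `scalar_field`).
#' @return A `scalar_field` with distances (voxels) and propagated labels.
#' @export
exact_edt <- function(mask, labels = NULL, grid = NULL) {
  if (inherits(mask, "scalar_field")) {
    grid <- grid %||% mask$grid
    if (is.null(labels)) labels <- mask$nearest
    mask <- mask$values != 0
  }
  dims <- dim(mask)
  if (is.null(grid)) {
    grid <- structure(list(origin = c(0, 0, 0), spacing = 1,
                           dims = as.integer(dims)), class = "grid_spec")
  }
  if (!any(mask)) msg_abort("mask has no feature voxels", "no_features")
  res <- edt_cpp(as.logical(mask), as.integer(dims))
  nearest <- res$nearest
  if (!is.null(labels)) {
    lab <- as.integer(labels)
    nearest <- ifelse(is.na(nearest), NA_integer_, lab[nearest])
  }
  new_scalar_field(grid, res$dist, nearest)
}

new_mol_mesh <- function(vertices, normals, triangles, vertex_atom = NULL,
                         vertex_color = NULL, grid = NULL) {
  structure(list(vertices = vertices, normals = normals,
                 triangles = triangles, vertex_atom = vertex_atom,
                 vertex_color = vertex_color, grid = grid),
            class = "mol_mesh")
}

empty_mesh <- function() {
  new_mol_mesh(matrix(0, 0, 3), matrix(0, 0, 3),
               matrix(0L, 0, 3), integer(0))
}

#' Extract a triangulated isosurface from a scalar field
#'
#' Marching tetrahedra over the Kuhn 6-tetrahedra decomposition of each
#' grid cell: crossings are linearly interpolated along cell edges, vertex
#' normals come from the interpolated field gradient, and each vertex
#' inherits the nearest-atom label of the edge endpoint with the smaller
#' `|value - isovalue|`. The decomposition shares face diagonals across
#' neighboring cells, so level sets strictly inside the grid come out
#' watertight; a uniform field yields an empty mesh. Triangles of area
#' below 1e-12 are dropped.
#'
#' @param field A `scalar_field`.
#' @param isovalue Level to extract.
#' @return A `mol_mesh` with `vertices`, unit `normals`, `triangles`
#'   (1-based index triples) and `vertex_atom`.
#' @export
extract_isosurface <- function(field, isovalue = 0) {
  stopifnot(inherits(field, "scalar_field"))
  g <- field$grid
  nearest <- field$nearest
  res <- march_tets_cpp(
    as.numeric(field$values), as.integer(g$dims), g$origin, g$spacing,
    isovalue,
    if (is.null(nearest)) integer(0) else as.integer(nearest)
  )
  if (nrow(res$vertices) == 0) return(empty_mesh())
  weld_mesh(new_mol_mesh(res$vertices, res$normals, res$triangles,
                         vertex_atom = res$vertex_atom, grid = g),
            tol = g$spacing * 1e-5)
}

# merge vertices closer than tol and drop the sliver triangles that
# collapse to a repeated index; keeps level sets watertight when exact
# grid-vertex hits spawn near-coincident crossings
weld_mesh <- function(m, tol) {
  v <- m$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- match(key, key)
  keep <- which(first == seq_along(first))
  newid <- match(first, keep)
  tri <- matrix(newid[m$triangles], ncol = 3)
  ok <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
  # area-based degenerate cleanup on the welded mesh
  tri <- tri[ok, , drop = FALSE]
  a <- v[keep, , drop = FALSE][tri[, 1], , drop = FALSE]
  b <- v[keep, , drop = FALSE][tri[, 2], , drop = FALSE]
  cc <- v[keep, , drop = FALSE][tri[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  tri <- tri[row_norms(cr) / 2 >= 1e-12, , drop = FALSE]
  new_mol_mesh(v[keep, , drop = FALSE], m$normals[keep, , drop = FALSE],
               tri, vertex_atom = m$vertex_atom[keep], grid = m$grid)
}

# Solid voxel masks for the four surface kinds; the SES/MS masks come from
# the exact EDT measured from the solvent-accessible exterior. Used by the
# nesting diagnostics and by compute_surface().
surface_solids <- function(atoms, probe_radius = 1.4, target_resolution = 4,
                           cap = 180) {
  atoms <- as_atom_table(atoms, "atoms")
  grid <- build_grid(atoms, probe_radius = probe_radius,
                     target_resolution = target_resolution, cap = cap)
  f_vdw <- min_signed_distance_field(atoms, grid, inflation = 0)
  f_sas <- min_signed_distance_field(atoms, grid, inflation = probe_radius)
  exterior <- f_sas$values > 0
  edt <- exact_edt(exterior, grid = grid)  # nearest = exterior voxel index
  d_A <- edt$values * grid$spacing  # distance to SAS-exterior voxel centers
  # sub-voxel boundary refinement: outside the SAS solid the signed field
  # is the exact distance to the SAS surface, so subtracting the nearest
  # exterior voxel's own penetration tightens the center-to-center distance
  # into a distance-to-surface estimate
  q <- as.integer(edt$nearest)
  pen <- pmax(as.numeric(f_sas$values)[q], 0)
  d_surf <- pmax(d_A - array(pen, dim = grid$dims), 0)
  nearest_atom <- array(as.integer(f_sas$nearest)[q], dim = grid$dims)
  list(
    grid = grid,
    vdw = f_vdw$values <= 0,
    sas = f_sas$values <= 0,
    ses = d_A >= probe_radius,
    ms = (f_vdw$values <= 0) | (d_A >= probe_radius),
    f_vdw = f_vdw, f_sas = f_sas, edt = edt,
    d_surf = d_surf, nearest_atom = nearest_atom
  )
}

#' Compute a macromolecular surface mesh
#'
#' Builds one of the four standard surface representations:
#' * `vdw` - zero level set of the signed distance to the atom spheres.
#' * `sas` - same with every radius inflated by `probe_radius`.
#' * `ses` - erosion route: the level set at distance `probe_radius` of
#'   the exact EDT measured inward from the solvent-accessible exterior.
#' * `ms` - closing route: the van der Waals solid united with the
#'   accessible-interior voxels no probe center can reach, then surfaced.
#'
#' `ses` and `ms` are the same surface morphologically (erosion of the SAS
#' solid by the probe equals the closing of the VdW solid by the probe);
#' the two discrete derivations agree within one voxel spacing. The
#' EDT-based field is refined to sub-voxel accuracy by subtracting each
#' nearest exterior voxel's own exact penetration beyond the accessible
#' surface. `swap_ses_ms = TRUE` exchanges which label maps to which
#' derivation.
#'
#' @param s A `mol_structure` or atom table with radii assigned.
#' @param kind One of `"vdw"`, `"sas"`, `"ses"`, `"ms"`.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param target_resolution Voxels per Angstrom (default 4).
#' @param cap Grid dimension cap (default 180).
#' @param smooth_iterations Laplacian smoothing iterations applied to the
#'   EDT-derived kinds (`ses`, `ms`) to reduce voxel staircase; the
#'   analytic kinds (`vdw`, `sas`) are already smooth and get none.
#' @param swap_ses_ms Swap the erosion/closing derivations.
#' @return A `mol_mesh`.
#' @export
compute_surface <- function(s, kind = c("vdw", "sas", "ses", "ms"),
                            probe_radius = 1.4, target_resolution = 4,
                            cap = 180, smooth_iterations = 2,
                            swap_ses_ms = FALSE) {
  kind <- match.arg(kind)
  atoms <- as_atom_table(s, "s")
  if (nrow(atoms) == 0) msg_abort("no atoms", "no_atoms")
  if (any(is.na(atoms$vdw_radius))) {
    atoms <- assign_elements_and_radii(atoms)
  }
  if (swap_ses_ms && kind %in% c("ses", "ms")) {
    kind <- if (kind == "ses") "ms" else "ses"
  }

  if (kind %in% c("vdw", "sas")) {
    grid <- build_grid(atoms,
                       probe_radius = if (kind == "sas") probe_radius else 0,
                       target_resolution = target_resolution, cap = cap)
    f <- min_signed_distance_field(atoms, grid,
                                   inflation = if (kind == "sas") probe_radius else 0)
    return(extract_isosurface(f, 0))
  }

  sol <- surface_solids(atoms, probe_radius = probe_radius,
                        target_resolution = target_resolution, cap = cap)
  grid <- sol$grid
  f_ses <- probe_radius - sol$d_surf      # outside-positive
  fld <- if (kind == "ses") {
    f_ses
  } else {
    pmin(sol$f_vdw$values, f_ses)         # union with the VdW solid
  }
  field <- new_scalar_field(grid, fld, sol$nearest_atom)
  mesh <- extract_isosurface(field, 0)
  if (smooth_iterations > 0) mesh <- smooth_mesh(mesh, smooth_iterations)
  mesh
}

#' Laplacian mesh smoothing
#'
#' Moves each vertex half-way toward the centroid of its edge neighbors
#' per iteration (fixed weight 0.5). Topology is unchanged; interior
#' vertices of an already-flat patch are fixed points.
#'
#' @param m A `mol_mesh`.
#' @param iterations Number of smoothing sweeps (0 returns the mesh as-is).
#' @return The smoothed `mol_mesh`.
#' @export
smooth_mesh <- function(m, iterations = 1) {
  stopifnot(inherits(m, "mol_mesh"))
  if (iterations <= 0 || nrow(m$vertices) == 0 || nrow(m$triangles) == 0) {
    return(m)
  }
  tri <- m$triangles
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  edges <- unique(rbind(edges, edges[, c(2, 1)]))
  deg <- tabulate(edges[, 1], nbins = nrow(m$vertices))
  v <- m$vertices
  for (it in seq_len(iterations)) {
    nb_sum <- rowsum(v[edges[, 2], , drop = FALSE], edges[, 1],
                     reorder = TRUE)
    idx <- as.integer(rownames(nb_sum))
    centroid <- v
    centroid[idx, ] <- nb_sum / deg[idx]
    v <- v + 0.5 * (centroid - v)
  }
  m$vertices <- v
  # refresh normals from the smoothed geometry (area-weighted face normals)
  m$normals <- vertex_normals(v, tri)
  m
}

vertex_normals <- function(vertices, triangles) {
  n <- matrix(0, nrow(vertices), 3)
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  cc <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  idx <- c(triangles[, 1], triangles[, 2], triangles[, 3])
  acc <- rowsum(rbind(fn, fn, fn), idx, reorder = TRUE)
  n[as.integer(rownames(acc)), ] <- acc
  len <- row_norms(n)
  len[len < 1e-12] <- 1
  n / len
}

#' Mesh surface area and enclosed volume
#'
#' Area is the sum of triangle areas; volume is the absolute sum of signed
#' tetrahedron volumes (meaningful for closed meshes).
#'
#' @param m A `mol_mesh` or anything with `vertices` and `triangles`.
#' @return Named numeric vector `c(area = , volume = )` in square/cubic
#'   Angstrom.
#' @export
mesh_area_volume <- function(m) {
  v <- m$vertices; tri <- m$triangles
  if (is.null(tri) || nrow(tri) == 0) return(c(area = 0, volume = 0))
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  cc <- v[tri[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  area <- sum(row_norms(cr)) / 2
  vol <- abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
                 a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
                 a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))) / 6
  c(area = area, volume = vol)
}

#' @export
print.mol_mesh <- function(x, ...) {
  av <- mesh_area_volume(x)
  cat(sprintf("<mol_mesh> %d vertices, %d triangles, area %.1f A^2\n",
              nrow(x$vertices), nrow(x$triangles), av["area"]))
  invisible(x)
}

#' @export
tidy.mol_mesh <- function(x, ...) {
  out <- tibble::tibble(
    vertex = seq_len(nrow(x$vertices)),
    x = x$vertices[, 1], y = x$vertices[, 2], z = x$vertices[, 3],
    nx = x$normals[, 1], ny = x$normals[, 2], nz = x$normals[, 3]
  )
  if (!is.null(x$vertex_atom)) out$atom <- x$vertex_atom
  out
}

#' @export
glance.mol_mesh <- function(x, ...) {
  av <- mesh_area_volume(x)
  tibble::tibble(
    n_vertices = nrow(x$vertices), n_triangles = nrow(x$triangles),
    area = unname(av["area"]), volume = unname(av["volume"]),
    watertight = is_watertight(x)
  )
}

#' Check mesh watertightness
#'
#' A mesh is watertight when every undirected edge is shared by exactly
#' two triangles, and orientable when every directed edge appears exactly
#' once.
#'
#' @param m A `mol_mesh`.
#' @return Logical.
#' @export
is_watertight <- function(m) {
  tri <- m$triangles
  if (nrow(tri) == 0) return(FALSE)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(und) == 2)
}

#' Write a mesh or geometry batch as Wavefront OBJ
#'
#' Triangle meshes are written as `v`/`vn`/`f` elements; line batches as
#' `v`/`l` elements (wireframe export); point batches as `v`/`p`.
#'
#' @param m A `mol_mesh` or `geometry_batch`.
#' @param path Output file.
#' @param wireframe Write triangle edges as line elements instead of faces.
#' @return `path`, invisibly.
#' @export
write_obj <- function(m, path, wireframe = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(m, "geometry_batch")) {
    v <- m$positions
    writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    if (m$kind == "triangles" && nrow(m$indices) > 0) {
      writeLines(sprintf("f %d %d %d", m$indices[, 1], m$indices[, 2],
                         m$indices[, 3]), con)
    } else if (m$kind == "lines" && nrow(m$indices) > 0) {
      writeLines(sprintf("l %d %d", m$indices[, 1], m$indices[, 2]), con)
    } else if (m$kind == "points") {
      writeLines(sprintf("p %d", seq_len(nrow(v))), con)
    }
    return(invisible(path))
  }
  v <- m$vertices; n <- m$normals; tri <- m$triangles
  writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("vn %.6f %.6f %.6f", n[, 1], n[, 2], n[, 3]), con)
  if (wireframe) {
    e <- unique(rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)]))
    writeLines(sprintf("l %d %d", e[, 1], e[, 2]), con)
  } else if (nrow(tri) > 0) {
    writeLines(sprintf("f %d//%d %d//%d %d//%d",
                       tri[, 1], tri[, 1], tri[, 2], tri[, 2],
                       tri[, 3], tri[, 3]), con)
  }
  invisible(path)
}

#' Write a mesh as binary PLY with per-vertex color
#'
#' @param m A `mol_mesh`; `vertex_color` (n x 3 in `[0,1]`) is written
#'   when present, white otherwise.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(m, path) {
  nv <- nrow(m$vertices); nt <- nrow(m$triangles)
  col <- m$vertex_color %||% matrix(1, nv, 3)
  header <- c(
    "ply", "format binary_little_endian 1.0",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    "property uchar red", "property uchar green", "property uchar blue",
    sprintf("element face %d", nt),
    "property list uchar int vertex_indices", "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  for (i in seq_len(nv)) {
    writeBin(as.numeric(c(m$vertices[i, ], m$normals[i, ])), con,
             size = 4, endian = "little")
    writeBin(as.integer(round(col[i, ] * 255)), con, size = 1)
  }
  for (t in seq_len(nt)) {
    writeBin(3L, con, size = 1)
    writeBin(as.integer(m$triangles[t, ] - 1L), con, size = 4,
             endian = "little")
  }
  invisible(path)
}
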