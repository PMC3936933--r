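# Renderable geometry for primary/secondary-structure representations and
# the per-atom color schemes.
#
# A geometry_batch holds one homogeneous primitive soup: kind in
# {points, lines, triangles}, vertex positions (A), per-vertex RGB in
# [0,1], an index matrix (m x 1 / m x 2 / m x 3) and the source atom of
# every vertex.

new_geometry_batch <- function(kind, positions, colors, indices,
                               source_atoms = NULL) {
  positions <- matrix(positions, ncol = 3)
  structure(list(
    kind = kind,
    positions = positions,
    colors = matrix(colors, ncol = 3),
    indices = matrix(as.integer(indices),
                     ncol = switch(kind, points = 1L, lines = 2L,
                                   triangles = 3L)),
    source_atoms = source_atoms %||% rep(NA_integer_, nrow(positions))
  ), class = "geometry_batch")
}

empty_batch <- function(kind = "triangles") {
  new_geometry_batch(kind, matrix(0, 0, 3), matrix(0, 0, 3), integer(0),
                     integer(0))
}

# concatenate batches of the same kind
merge_batches <- function(batches) {
  batches <- purrr::discard(batches, ~ nrow(.x$positions) == 0)
  if (length(batches) == 0) return(empty_batch())
  kind <- batches[[1]]$kind
  stopifnot(all(vapply(batches, function(b) b$kind, "") == kind))
  offs <- cumsum(c(0, purrr::map_dbl(batches, ~ nrow(.x$positions))))
  new_geometry_batch(
    kind,
    do.call(rbind, purrr::map(batches, "positions")),
    do.call(rbind, purrr::map(batches, "colors")),
    do.call(rbind, purrr::imap(batches, ~ .x$indices + offs[.y])),
    unlist(purrr::map(batches, "source_atoms"))
  )
}

#' @export
print.geometry_batch <- function(x, ...) {
  cat(sprintf("<geometry_batch> %s: %d vertices, %d primitive(s)\n",
              x$kind, nrow(x$positions), nrow(x$indices)))
  invisible(x)
}

# ---- color schemes ---------------------------------------------------------

.cpk_colors <- c(
  H = "#FFFFFF", C = "#909090", N = "#3050F8", O = "#FF0D0D",
  S = "#FFFF30", P = "#FF8000", F = "#90E050", CL = "#1FF01F",
  BR = "#A62929", I = "#940094", FE = "#E06633", ZN = "#7D80B0",
  MG = "#8AFF00", CA = "#3DFF00", "NA" = "#AB5CF2", K = "#8F40D4"
)
.cpk_default <- "#FFC0CB"

.chain_palette <- c("#4E79A7", "#F28E2B", "#59A14F", "#E15759", "#B07AA1",
                    "#76B7B2", "#EDC948", "#FF9DA7", "#9C755F", "#BAB0AC")

.ss_colors <- c(helix = "#FF0080", sheet = "#FFC800", coil = "#B0B0B0")

.residue_palette <- c(
  ALA = "#C8C8C8", ARG = "#145AFF", ASN = "#00DCDC", ASP = "#E60A0A",
  CYS = "#E6E600", GLN = "#00DCDC", GLU = "#E60A0A", GLY = "#EBEBEB",
  HIS = "#8282D2", ILE = "#0F820F", LEU = "#0F820F", LYS = "#145AFF",
  MET = "#E6E600", PHE = "#3232AA", PRO = "#DC9682", SER = "#FA9600",
  THR = "#FA9600", TRP = "#B45AB4", TYR = "#3232AA", VAL = "#0F820F"
)
.residue_default <- "#BEA06E"

# polar amino-acid class for the 2-color polarity scheme
.polar_residues <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LYS",
                     "SER", "THR", "TYR", "CYS", "TRP")
.polarity_colors <- c(polar = "#00C832", nonpolar = "#C8C8C8")

hex_to_rgb <- function(hex) t(grDevices::col2rgb(hex)) / 255

#' Per-atom colors for a scheme
#'
#' Supported schemes:
#' * `spectrum` - rainbow (hue 240 deg to 0 deg) over residue rank per chain.
#' * `chain` - fixed palette cycled by chain.
#' * `secondary` - helix/sheet/coil palette.
#' * `bfactor` - B factor mapped monotonically onto a cold-to-hot ramp.
#' * `residue` - palette keyed by residue name.
#' * `polarity` - two-color polar/nonpolar amino-acid classes.
#' * `atom` - CPK-style element colors.
#'
#' @param s A `mol_structure` or atom table (with `element`/`ss` assigned
#'   as the scheme requires).
#' @param scheme Scheme name.
#' @return An `n x 3` numeric matrix of RGB values in `[0,1]`.
#' @export
atom_colors <- function(s, scheme = c("spectrum", "chain", "secondary",
                                      "bfactor", "residue", "polarity",
                                      "atom")) {
  atoms <- as_atom_table(s)
  if (is.character(scheme) && length(scheme) == 1 &&
      !scheme %in% eval(formals(atom_colors)$scheme)) {
    msg_abort(sprintf("unknown color scheme '%s'", scheme), "unknown_scheme")
  }
  scheme <- match.arg(scheme)
  n <- nrow(atoms)
  switch(scheme,
    spectrum = {
      key <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code)
      out <- matrix(0, n, 3)
      for (ch in unique(atoms$chain_id)) {
        sel <- atoms$chain_id == ch
        ranks <- match(key[sel], unique(key[sel]))
        tmax <- max(ranks)
        t <- if (tmax > 1) (ranks - 1) / (tmax - 1) else rep(0.5, sum(sel))
        hue <- (240 - 240 * t) / 360
        out[sel, ] <- t(grDevices::col2rgb(grDevices::hsv(hue, 1, 1))) / 255
      }
      out
    },
    chain = {
      idx <- match(atoms$chain_id, unique(atoms$chain_id))
      hex_to_rgb(.chain_palette[(idx - 1) %% length(.chain_palette) + 1])
    },
    secondary = {
      ss <- atoms$ss %||% rep("coil", n)
      hex_to_rgb(.ss_colors[ss])
    },
    bfactor = {
      b <- atoms$b_factor
      rng <- range(b)
      t <- if (diff(rng) > 0) (b - rng[1]) / diff(rng) else rep(0.5, n)
      cbind(t, 0, 1 - t)  # cold (blue) to hot (red), monotone in B
    },
    residue = {
      hex <- .residue_palette[toupper(atoms$res_name)]
      hex[is.na(hex)] <- .residue_default
      hex_to_rgb(hex)
    },
    polarity = {
      cls <- ifelse(toupper(atoms$res_name) %in% .polar_residues,
                    "polar", "nonpolar")
      hex_to_rgb(.polarity_colors[cls])
    },
    atom = {
      hex <- .cpk_colors[atoms$element]
      hex[is.na(hex)] <- .cpk_default
      hex_to_rgb(hex)
    }
  )
}

# ---- bond derivation -------------------------------------------------------

#' Derive covalent bonds by the distance rule
#'
#' Two atoms are bonded iff their separation is below
#' `tolerance x (covalent radii sum)`; candidate pairs come from a spatial
#' hash (cell list) so the scan is near-linear. CONECT records parsed from
#' the file are honored additively, regardless of distance.
#'
#' @param s A `mol_structure` or atom table with elements assigned.
#' @param tolerance Multiplier on the covalent radii sum (default 1.2).
#' @return A tibble with columns `i`, `j` (row indices, `i < j`) and
#'   `dist` (A).
#' @export
derive_bonds <- function(s, tolerance = 1.2) {
  atoms <- as_atom_table(s)
  n <- nrow(atoms)
  out <- tibble::tibble(i = integer(), j = integer(), dist = double())
  if (n >= 2) {
    cov <- unname(.cov_radii[atoms$element])
    cov[is.na(cov)] <- .cov_default
    cell_size <- 2 * max(cov) * tolerance
    ci <- floor(atoms$x / cell_size)
    cj <- floor(atoms$y / cell_size)
    ck <- floor(atoms$z / cell_size)
    cell_key <- paste(ci, cj, ck)
    cell_of <- split(seq_len(n), cell_key)
    # candidate pairs: same cell or one of the 26 neighbors
    neighbors <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    pairs_i <- integer(0); pairs_j <- integer(0)
    for (key in names(cell_of)) {
      idx <- cell_of[[key]]
      base <- as.integer(strsplit(key, " ")[[1]])
      for (r in seq_len(nrow(neighbors))) {
        nb_key <- paste(base[1] + neighbors$dx[r], base[2] + neighbors$dy[r],
                        base[3] + neighbors$dz[r])
        jdx <- cell_of[[nb_key]]
        if (is.null(jdx)) next
        grid <- expand.grid(i = idx, j = jdx)
        keep <- grid$i < grid$j
        pairs_i <- c(pairs_i, grid$i[keep])
        pairs_j <- c(pairs_j, grid$j[keep])
      }
    }
    if (length(pairs_i) > 0) {
      dup <- duplicated(cbind(pairs_i, pairs_j))
      pairs_i <- pairs_i[!dup]; pairs_j <- pairs_j[!dup]
      d <- sqrt((atoms$x[pairs_i] - atoms$x[pairs_j])^2 +
                  (atoms$y[pairs_i] - atoms$y[pairs_j])^2 +
                  (atoms$z[pairs_i] - atoms$z[pairs_j])^2)
      thresh <- tolerance * (cov[pairs_i] + cov[pairs_j])
      keep <- d < thresh
      out <- tibble::tibble(i = pairs_i[keep], j = pairs_j[keep],
                            dist = d[keep])
    }
  }
  # CONECT records win even beyond the distance threshold
  conect <- attr(s, "conect")
  if (!is.null(conect) && nrow(conect) > 0) {
    ii <- match(conect[, 1], atoms$serial)
    jj <- match(conect[, 2], atoms$serial)
    ok <- !is.na(ii) & !is.na(jj) & ii != jj
    if (any(ok)) {
      add <- tibble::tibble(
        i = pmin(ii[ok], jj[ok]), j = pmax(ii[ok], jj[ok]),
        dist = sqrt((atoms$x[ii[ok]] - atoms$x[jj[ok]])^2 +
                      (atoms$y[ii[ok]] - atoms$y[jj[ok]])^2 +
                      (atoms$z[ii[ok]] - atoms$z[jj[ok]])^2)
      )
      out <- dplyr::distinct(dplyr::bind_rows(out, add), .data$i, .data$j,
                             .keep_all = TRUE)
    }
  }
  dplyr::arrange(out, .data$i, .data$j)
}

# ---- tessellation primitives ----------------------------------------------

# icosphere: icosahedron + midpoint subdivision, 20 * 4^s faces
icosphere <- local({
  cache <- list()
  function(subdivision = 2) {
    key <- as.character(subdivision)
    if (!is.null(cache[[key]])) return(cache[[key]])
    phi <- (1 + sqrt(5)) / 2
    v <- rbind(
      c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
      c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
      c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
    )
    v <- v / row_norms(v)
    f <- rbind(
      c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
      c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
      c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
      c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
    )
    for (s in seq_len(subdivision)) {
      mid_cache <- new.env()
      midpoint <- function(a, b) {
        key <- paste(min(a, b), max(a, b))
        hit <- mid_cache[[key]]
        if (!is.null(hit)) return(hit)
        p <- v[a, ] + v[b, ]
        p <- p / vnorm(p)
        v <<- rbind(v, p)
        mid_cache[[key]] <- nrow(v)
        nrow(v)
      }
      nf <- matrix(0L, 0, 3)
      for (t in seq_len(nrow(f))) {
        a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
        ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
        nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
      }
      f <- nf
    }
    out <- list(vertices = v, faces = f)
    cache[[key]] <<- out
    out
  }
})

# open cylinder wall between p and q, n-sided: 2n vertices, 2n triangles
cylinder_mesh <- function(p, q, radius, nsides = 8) {
  axis <- q - p
  len <- vnorm(axis)
  if (len < 1e-9) return(NULL)
  w <- axis / len
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- vnormalize(vcross(w, ref))
  vv <- vcross(w, u)
  ang <- 2 * pi * (seq_len(nsides) - 1) / nsides
  ring <- t(vapply(ang, function(a) u * cos(a) + vv * sin(a), numeric(3)))
  bottom <- sweep(ring * radius, 2, p, "+")
  top <- sweep(ring * radius, 2, q, "+")
  verts <- rbind(bottom, top)
  tri <- matrix(0L, 0, 3)
  for (i in seq_len(nsides)) {
    i2 <- i %% nsides + 1
    tri <- rbind(tri,
                 c(i, i2, nsides + i),
                 c(i2, nsides + i2, nsides + i))
  }
  list(vertices = verts, faces = tri)
}

# ---- primary-structure representations -------------------------------------

#' Build primary-structure geometry
#'
#' * `line` - one segment per bond, split at the midpoint so each half
#'   takes its atom's color (bicolor convention).
#' * `stick` - one cylinder per bond half (radius `stick_radius`,
#'   `nsides`-gonal).
#' * `ball_stick` - sticks plus spheres at `ball_scale` x the van der
#'   Waals radius.
#' * `sphere` - one icosphere per atom at the full van der Waals radius.
#' * `dot` - one point per atom.
#'
#' @param s A `mol_structure` or atom table with radii.
#' @param rep Representation name.
#' @param colors Optional `n x 3` per-atom RGB (default: `atom` scheme).
#' @param stick_radius Stick cylinder radius (A).
#' @param nsides Cylinder tessellation.
#' @param subdivision Icosphere subdivision (faces = `20 * 4^subdivision`).
#' @param ball_scale Sphere scale for `ball_stick`.
#' @param bonds Optional pre-computed bond table from [derive_bonds()].
#' @return A `geometry_batch`.
#' @export
build_primary <- function(s, rep = c("line", "stick", "ball_stick", "sphere",
                                     "dot"),
                          colors = NULL, stick_radius = 0.25, nsides = 8,
                          subdivision = 2, ball_scale = 0.4, bonds = NULL) {
  if (is.character(rep) && length(rep) == 1 &&
      !rep %in% eval(formals(build_primary)$rep)) {
    msg_abort(sprintf("unknown representation '%s'", rep),
              "unknown_representation")
  }
  rep <- match.arg(rep)
  atoms <- as_atom_table(s)
  n <- nrow(atoms)
  colors <- colors %||% atom_colors(atoms, "atom")
  pos <- cbind(atoms$x, atoms$y, atoms$z)

  if (rep == "dot") {
    return(new_geometry_batch("points", pos, colors, seq_len(n), seq_len(n)))
  }
  if (rep %in% c("line", "stick", "ball_stick")) {
    bonds <- bonds %||% derive_bonds(s)
    if (nrow(bonds) == 0 && rep != "ball_stick") {
      return(empty_batch(if (rep == "line") "lines" else "triangles"))
    }
  }
  if (rep == "line") {
    mid <- (pos[bonds$i, , drop = FALSE] + pos[bonds$j, , drop = FALSE]) / 2
    m <- nrow(bonds)
    verts <- matrix(0, 4 * m, 3)
    cols <- matrix(0, 4 * m, 3)
    src <- integer(4 * m)
    verts[seq(1, 4 * m, 4), ] <- pos[bonds$i, , drop = FALSE]
    verts[seq(2, 4 * m, 4), ] <- mid
    verts[seq(3, 4 * m, 4), ] <- mid
    verts[seq(4, 4 * m, 4), ] <- pos[bonds$j, , drop = FALSE]
    cols[seq(1, 4 * m, 4), ] <- colors[bonds$i, , drop = FALSE]
    cols[seq(2, 4 * m, 4), ] <- colors[bonds$i, , drop = FALSE]
    cols[seq(3, 4 * m, 4), ] <- colors[bonds$j, , drop = FALSE]
    cols[seq(4, 4 * m, 4), ] <- colors[bonds$j, , drop = FALSE]
    src[seq(1, 4 * m, 4)] <- bonds$i; src[seq(2, 4 * m, 4)] <- bonds$i
    src[seq(3, 4 * m, 4)] <- bonds$j; src[seq(4, 4 * m, 4)] <- bonds$j
    idx <- cbind(seq(1, 4 * m, 2), seq(2, 4 * m, 2))
    return(new_geometry_batch("lines", verts, cols, idx, src))
  }

  batches <- list()
  stick_part <- function() {
    purrr::pmap(bonds, function(i, j, dist) {
      mid <- (pos[i, ] + pos[j, ]) / 2
      purrr::compact(list(
        list(mesh = cylinder_mesh(pos[i, ], mid, stick_radius, nsides),
             color = colors[i, ], atom = i),
        list(mesh = cylinder_mesh(mid, pos[j, ], stick_radius, nsides),
             color = colors[j, ], atom = j)
      ))
    })
  }
  sphere_part <- function(scale_fun) {
    ico <- icosphere(subdivision)
    purrr::map(seq_len(n), function(i) {
      r <- scale_fun(atoms$vdw_radius[i])
      list(mesh = list(vertices = sweep(ico$vertices * r, 2, pos[i, ], "+"),
                       faces = ico$faces),
           color = colors[i, ], atom = i)
    })
  }
  parts <- switch(rep,
    stick = purrr::flatten(stick_part()),
    sphere = sphere_part(identity),
    ball_stick = c(purrr::flatten(stick_part()),
                   sphere_part(function(r) ball_scale * r))
  )
  parts <- purrr::discard(parts, ~ is.null(.x$mesh))
  if (length(parts) == 0) return(empty_batch("triangles"))
  batches <- purrr::map(parts, function(p) {
    nv <- nrow(p$mesh$vertices)
    new_geometry_batch("triangles", p$mesh$vertices,
                       matrix(p$color, nv, 3, byrow = TRUE),
                       p$mesh$faces, rep(p$atom, nv))
  })
  merge_batches(batches)
}

# ---- secondary-structure representations -----------------------------------

# uniform Catmull-Rom spline through control points, with endpoint
# duplication; returns subdivided curve and, for each curve point, the
# index of the nearest control point (for color/width lookups)
catmull_rom <- function(points, subdivisions = 8) {
  n <- nrow(points)
  if (n < 2) return(NULL)
  p <- rbind(points[1, ], points, points[n, ])
  curve <- matrix(0, 0, 3)
  ctrl <- numeric(0)
  for (seg in seq_len(n - 1)) {
    p0 <- p[seg, ]; p1 <- p[seg + 1, ]; p2 <- p[seg + 2, ]; p3 <- p[seg + 3, ]
    tt <- seq(0, 1, length.out = subdivisions + 1)
    if (seg < n - 1) tt <- tt[-length(tt)]
    for (t in tt) {
      t2 <- t * t; t3 <- t2 * t
      pt <- 0.5 * ((2 * p1) + (-p0 + p2) * t +
                     (2 * p0 - 5 * p1 + 4 * p2 - p3) * t2 +
                     (-p0 + 3 * p1 - 3 * p2 + p3) * t3)
      curve <- rbind(curve, pt)
      ctrl <- c(ctrl, if (t < 0.5) seg else seg + 1)
    }
  }
  list(curve = curve, control = as.integer(ctrl))
}

# orthonormal frames along a curve by parallel transport, optionally
# steered by reference normals (e.g. peptide-plane normals)
curve_frames <- function(curve, ref_normals = NULL) {
  m <- nrow(curve)
  tangents <- matrix(0, m, 3)
  tangents[-m, ] <- curve[-1, ] - curve[-m, ]
  tangents[m, ] <- tangents[m - 1, ]
  tangents <- tangents / pmax(row_norms(tangents), 1e-12)
  normals <- matrix(0, m, 3)
  n0 <- if (!is.null(ref_normals)) ref_normals[1, ] else {
    ref <- if (abs(tangents[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    vcross(tangents[1, ], ref)
  }
  n0 <- n0 - sum(n0 * tangents[1, ]) * tangents[1, ]
  normals[1, ] <- vnormalize(n0)
  for (i in 2:m) {
    prev <- normals[i - 1, ]
    guide <- if (!is.null(ref_normals)) ref_normals[i, ] else prev
    # keep continuity: flip the guide if it points the other way
    if (sum(guide * prev) < 0) guide <- -guide
    nn <- guide - sum(guide * tangents[i, ]) * tangents[i, ]
    if (vnorm(nn) < 1e-9) nn <- prev
    normals[i, ] <- vnormalize(nn)
  }
  binormals <- t(vapply(seq_len(m), function(i) {
    vcross(tangents[i, ], normals[i, ])
  }, numeric(3)))
  list(tangent = tangents, normal = normals, binormal = binormals)
}

ribbon_strip <- function(left, right, colors, src) {
  m <- nrow(left)
  verts <- rbind(left, right)
  cols <- rbind(colors, colors)
  tri <- matrix(0L, 0, 3)
  for (i in seq_len(m - 1)) {
    a <- i; b <- i + 1; c1 <- m + i; d <- m + i + 1
    tri <- rbind(tri, c(a, b, c1), c(b, d, c1))
  }
  new_geometry_batch("triangles", verts, cols, tri, c(src, src))
}

tube_mesh <- function(curve, radii, colors, src, nsides = 8) {
  fr <- curve_frames(curve)
  m <- nrow(curve)
  ang <- 2 * pi * (seq_len(nsides) - 1) / nsides
  verts <- matrix(0, m * nsides, 3)
  cols <- matrix(0, m * nsides, 3)
  vsrc <- integer(m * nsides)
  for (i in seq_len(m)) {
    ring <- t(vapply(ang, function(a) {
      curve[i, ] + radii[i] * (cos(a) * fr$normal[i, ] +
                                 sin(a) * fr$binormal[i, ])
    }, numeric(3)))
    rows <- ((i - 1) * nsides + 1):(i * nsides)
    verts[rows, ] <- ring
    cols[rows, ] <- matrix(colors[i, ], nsides, 3, byrow = TRUE)
    vsrc[rows] <- src[i]
  }
  tri <- matrix(0L, 0, 3)
  for (i in seq_len(m - 1)) {
    for (k in seq_len(nsides)) {
      k2 <- k %% nsides + 1
      a <- (i - 1) * nsides + k; b <- (i - 1) * nsides + k2
      cc <- i * nsides + k; d <- i * nsides + k2
      tri <- rbind(tri, c(a, b, cc), c(b, d, cc))
    }
  }
  new_geometry_batch("triangles", verts, cols, tri, vsrc)
}

# least-squares line (first principal axis) through points
principal_axis <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  dir <- sv$v[, 1]
  t <- as.numeric(sweep(points, 2, ctr) %*% dir)
  list(center = ctr, dir = dir, t_range = range(t))
}

#' Build secondary-structure geometry
#'
#' A uniform Catmull-Rom spline (8 subdivisions per residue, endpoint
#' duplication) is threaded through the consecutive C-alpha atoms of each
#' chain, then extruded according to the representation:
#' * `ribbon` - flat extrusion of width `width`, oriented by
#'   carbonyl-oxygen peptide-plane normals when O atoms are present, by
#'   parallel transport otherwise.
#' * `strand` - the unextruded spline polyline.
#' * `ca_trace` - straight polyline through the C-alpha atoms.
#' * `tube_b` - tube of per-residue radius `tube_scale * B / mean(B)`.
#' * `cylinder_plate` - one cylinder per helix run (least-squares axis),
#'   a flat plate per sheet run, a thin tube elsewhere.
#'
#' Chains with fewer than two C-alpha atoms contribute an empty batch with
#' a warning.
#'
#' @param s A `mol_structure` with `ss` assigned.
#' @param rep Representation name.
#' @param colors Optional per-atom RGB (default: `secondary` scheme).
#' @param subdivisions Spline subdivisions per residue.
#' @param width Ribbon/plate width (A).
#' @param tube_scale Base tube radius (A); also the `tube_b` radius at
#'   mean B.
#' @param nsides Tube/cylinder tessellation.
#' @return A `geometry_batch`.
#' @export
build_secondary <- function(s, rep = c("ribbon", "strand", "ca_trace",
                                       "tube_b", "cylinder_plate"),
                            colors = NULL, subdivisions = 8, width = 1.6,
                            tube_scale = 0.3, nsides = 8) {
  if (is.character(rep) && length(rep) == 1 &&
      !rep %in% eval(formals(build_secondary)$rep)) {
    msg_abort(sprintf("unknown representation '%s'", rep),
              "unknown_representation")
  }
  rep <- match.arg(rep)
  atoms <- as_atom_table(s)
  colors <- colors %||% atom_colors(atoms, "secondary")
  batches <- list()

  for (ch in unique(atoms$chain_id[!atoms$is_hetero])) {
    ca_idx <- which(!atoms$is_hetero & atoms$chain_id == ch &
                      atoms$name == "CA" & atoms$element == "C")
    if (length(ca_idx) < 2) {
      msg_warn(sprintf("chain %s has fewer than 2 C-alpha atoms; skipped", ch),
               "chain_too_short")
      next
    }
    ca <- cbind(atoms$x[ca_idx], atoms$y[ca_idx], atoms$z[ca_idx])
    if (rep == "ca_trace") {
      m <- length(ca_idx)
      idx <- cbind(seq_len(m - 1), seq(2, m))
      batches[[length(batches) + 1]] <- new_geometry_batch(
        "lines", ca, colors[ca_idx, , drop = FALSE], idx, ca_idx)
      next
    }
    sp <- catmull_rom(ca, subdivisions)
    curve <- sp$curve
    src <- ca_idx[sp$control]
    ccol <- colors[src, , drop = FALSE]

    if (rep == "strand") {
      m <- nrow(curve)
      idx <- cbind(seq_len(m - 1), seq(2, m))
      batches[[length(batches) + 1]] <- new_geometry_batch(
        "lines", curve, ccol, idx, src)
    } else if (rep == "ribbon") {
      # peptide-plane normals from carbonyl O where available
      ref <- NULL
      o_idx <- vapply(ca_idx, function(i) {
        hit <- which(!atoms$is_hetero & atoms$chain_id == ch &
                       atoms$res_seq == atoms$res_seq[i] &
                       atoms$i_code == atoms$i_code[i] & atoms$name == "O")
        if (length(hit) > 0) hit[1] else NA_integer_
      }, integer(1))
      if (all(!is.na(o_idx))) {
        nrm <- cbind(atoms$x[o_idx], atoms$y[o_idx], atoms$z[o_idx]) - ca
        nrm <- nrm / pmax(row_norms(nrm), 1e-12)
        ref <- nrm[sp$control, , drop = FALSE]
      }
      fr <- curve_frames(curve, ref)
      half <- width / 2
      left <- curve - half * fr$binormal
      right <- curve + half * fr$binormal
      batches[[length(batches) + 1]] <- ribbon_strip(left, right, ccol, src)
    } else if (rep == "tube_b") {
      b <- atoms$b_factor[ca_idx]
      mb <- mean(b)
      rad_res <- if (mb > 0) tube_scale * b / mb else rep(tube_scale,
                                                          length(b))
      radii <- rad_res[sp$control]
      batches[[length(batches) + 1]] <- tube_mesh(curve, radii, ccol, src,
                                                  nsides)
    } else {  # cylinder_plate
      ss_res <- atoms$ss[ca_idx]
      runs <- rle(ss_res)
      pos <- 1
      for (r in seq_along(runs$lengths)) {
        len <- runs$lengths[r]
        rows <- pos:(pos + len - 1)
        pos <- pos + len
        pts <- ca[rows, , drop = FALSE]
        ridx <- ca_idx[rows]
        rcol <- colors[ridx, , drop = FALSE]
        if (runs$values[r] == "helix" && len >= 3) {
          ax <- principal_axis(pts)
          p0 <- ax$center + ax$t_range[1] * ax$dir
          p1 <- ax$center + ax$t_range[2] * ax$dir
          cyl <- cylinder_mesh(p0, p1, 2.3, nsides)
          if (!is.null(cyl)) {
            nv <- nrow(cyl$vertices)
            batches[[length(batches) + 1]] <- new_geometry_batch(
              "triangles", cyl$vertices,
              matrix(colMeans(rcol), nv, 3, byrow = TRUE),
              cyl$faces, rep(ridx[1], nv))
          }
        } else if (runs$values[r] == "sheet" && len >= 2) {
          ax <- principal_axis(pts)
          p0 <- ax$center + ax$t_range[1] * ax$dir
          p1 <- ax$center + ax$t_range[2] * ax$dir
          line <- rbind(p0, p1)
          lat <- if (abs(ax$dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
          side <- vnormalize(vcross(ax$dir, lat)) * width / 2
          batches[[length(batches) + 1]] <- ribbon_strip(
            sweep(line, 2, side, "-"), sweep(line, 2, side, "+"),
            matrix(colMeans(rcol), 2, 3, byrow = TRUE), rep(ridx[1], 2))
        } else if (len >= 2) {
          spc <- catmull_rom(pts, subdivisions)
          batches[[length(batches) + 1]] <- tube_mesh(
            spc$curve, rep(0.2, nrow(spc$curve)),
            rcol[spc$control, , drop = FALSE], ridx[spc$control], nsides)
        }
      }
    }
  }
  if (length(batches) == 0) return(empty_batch())
  merge_batches(batches)
}
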