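# Headless software rendering: perspective/orthographic cameras, z-buffer
# rasterization to PNG, label overlays and anaglyph stereo compositing.
# Everything is deterministic: the same scene and camera always produce a
# byte-identical image.

#' Create a camera
#'
#' @param kind `"perspective"` or `"orthographic"`.
#' @param eye,target,up Camera position, look-at point and up vector (A).
#' @param fov_deg Vertical field of view (perspective).
#' @param half_height Half of the visible height at the target
#'   (orthographic).
#' @param near,far Clip distances (A); the slab manipulation mode is
#'   realized by tightening these.
#' @return A `mol_camera`.
#' @export
camera <- function(kind = c("perspective", "orthographic"),
                   eye = c(0, 0, 50), target = c(0, 0, 0), up = c(0, 1, 0),
                   fov_deg = 45, half_height = 20, near = 0.1, far = 1000) {
  kind <- match.arg(kind)
  stopifnot(far > near)
  if (kind == "perspective") stopifnot(near > 0)
  dir <- target - eye
  if (vnorm(dir) < 1e-9) stop("eye and target coincide")
  if (vnorm(vcross(vnormalize(dir), vnormalize(up))) < 1e-9) {
    stop("up vector is parallel to the view direction")
  }
  structure(list(kind = kind, eye = eye, target = target, up = up,
                 fov_deg = fov_deg, half_height = half_height,
                 near = near, far = far),
            class = "mol_camera")
}

#' Default camera for a structure
#'
#' Eye on the +z axis of the molecule's bounding-sphere center, at twice
#' the bounding-sphere radius.
#'
#' @param s A `mol_structure`, atom table, or `n x 3` coordinate matrix.
#' @param kind Camera kind.
#' @param ... Passed to [camera()].
#' @return A `mol_camera`.
#' @export
default_camera <- function(s, kind = "orthographic", ...) {
  pts <- if (is.matrix(s)) s else {
    a <- as_atom_table(s)
    cbind(a$x, a$y, a$z)
  }
  ctr <- colMeans(pts)
  rad <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2)), 1)
  camera(kind, eye = ctr + c(0, 0, 2 * rad), target = ctr,
         half_height = 1.2 * rad, near = 0.1, far = 10 * rad, ...)
}

# 4x4 view matrix (world -> eye, looking down -z)
view_matrix <- function(cam) {
  f <- vnormalize(cam$target - cam$eye)
  r <- vnormalize(vcross(f, cam$up))
  u <- vcross(r, f)
  m <- rbind(c(r, -sum(r * cam$eye)),
             c(u, -sum(u * cam$eye)),
             c(-f, sum(f * cam$eye)),
             c(0, 0, 0, 1))
  m
}

# world positions (n x 3) -> eye space (n x 3)
to_eye <- function(cam, p) {
  m <- view_matrix(cam)
  t(m[1:3, 1:3] %*% t(p)) + matrix(m[1:3, 4], nrow(p), 3, byrow = TRUE)
}

# eye space -> screen: x_px, y_px (y down), depth linear in eye z
eye_to_screen <- function(cam, pe, width, height) {
  aspect <- width / height
  zc <- -pe[, 3]
  if (cam$kind == "orthographic") {
    xn <- pe[, 1] / (cam$half_height * aspect)
    yn <- pe[, 2] / cam$half_height
  } else {
    f <- 1 / tan(cam$fov_deg * pi / 360)
    xn <- f * pe[, 1] / (aspect * zc)
    yn <- f * pe[, 2] / zc
  }
  depth <- (zc - cam$near) / (cam$far - cam$near)
  cbind((xn + 1) / 2 * width, (1 - yn) / 2 * height, depth)
}

#' Project a world-space point to pixel coordinates
#'
#' Standard view, projection and viewport transform. Orthographic depth is
#' linear; the perspective path divides by eye-space depth and refuses
#' points at or behind the eye plane.
#'
#' @param cam A `mol_camera`.
#' @param p A length-3 vector or `n x 3` matrix of world coordinates (A).
#' @param viewport `c(width, height)` in pixels.
#' @return A tibble with `x_px`, `y_px`, `depth` (depth in `[0,1]` inside
#'   the near/far slab).
#' @export
project <- function(cam, p, viewport = c(400, 400)) {
  p <- matrix(p, ncol = 3)
  pe <- to_eye(cam, p)
  if (cam$kind == "perspective" && any(-pe[, 3] <= cam$near)) {
    msg_abort("point at or behind the camera eye plane", "behind_camera")
  }
  sc <- eye_to_screen(cam, pe, viewport[1], viewport[2])
  tibble::tibble(x_px = unname(sc[, 1]), y_px = unname(sc[, 2]),
                 depth = unname(sc[, 3]))
}

.backgrounds <- list(black = c(0, 0, 0), grey = c(0.5, 0.5, 0.5),
                     white = c(1, 1, 1))

new_image <- function(width, height, background) {
  stopifnot(width >= 1, height >= 1)
  bg <- if (is.character(background)) {
    .backgrounds[[match.arg(background, names(.backgrounds))]]
  } else background
  img <- array(0, dim = c(height, width, 3))
  img[, , 1] <- bg[1]; img[, , 2] <- bg[2]; img[, , 3] <- bg[3]
  structure(img, class = "mol_image")
}

# Lambert shading with a single headlight at the eye, ambient 0.2
shade_colors <- function(colors, normals_eye) {
  lambert <- abs(normals_eye[, 3])
  k <- 0.2 + 0.8 * lambert
  pmin(colors * k, 1)
}

# clip eye-space triangles against the z = -near and z = -far planes
clip_triangles_eye <- function(pe, cols, tri, near, far) {
  keepz <- function(z) z <= -near & z >= -far
  out_v <- list(); out_c <- list(); out_t <- list()
  nv <- 0
  for (t in seq_len(nrow(tri))) {
    idx <- tri[t, ]
    poly_v <- pe[idx, , drop = FALSE]
    poly_c <- cols[idx, , drop = FALSE]
    for (plane in list(c(-1, -near), c(1, far))) {
      # plane: sign * z >= sign*bound form; keep z inside the slab
      if (nrow(poly_v) == 0) break
      inside <- if (plane[1] < 0) poly_v[, 3] <= -plane[2] else
        poly_v[, 3] >= -plane[2]
      if (all(inside)) next
      nvp <- nrow(poly_v)
      new_v <- matrix(0, 0, 3); new_c <- matrix(0, 0, 3)
      for (i in seq_len(nvp)) {
        j <- i %% nvp + 1
        a_in <- inside[i]; b_in <- inside[j]
        if (a_in) {
          new_v <- rbind(new_v, poly_v[i, ]); new_c <- rbind(new_c, poly_c[i, ])
        }
        if (xor(a_in, b_in)) {
          zbound <- if (plane[1] < 0) -plane[2] else -plane[2]
          tt <- (zbound - poly_v[i, 3]) / (poly_v[j, 3] - poly_v[i, 3])
          new_v <- rbind(new_v, poly_v[i, ] + tt * (poly_v[j, ] - poly_v[i, ]))
          new_c <- rbind(new_c, poly_c[i, ] + tt * (poly_c[j, ] - poly_c[i, ]))
        }
      }
      poly_v <- new_v; poly_c <- new_c
    }
    if (nrow(poly_v) >= 3) {
      for (k in 2:(nrow(poly_v) - 1)) {
        out_t[[length(out_t) + 1]] <- nv + c(1, k, k + 1)
      }
      out_v[[length(out_v) + 1]] <- poly_v
      out_c[[length(out_c) + 1]] <- poly_c
      nv <- nv + nrow(poly_v)
    }
  }
  if (length(out_v) == 0) {
    return(list(pe = matrix(0, 0, 3), cols = matrix(0, 0, 3),
                tri = matrix(0L, 0, 3)))
  }
  list(pe = do.call(rbind, out_v), cols = do.call(rbind, out_c),
       tri = matrix(as.integer(do.call(rbind, out_t)), ncol = 3))
}

as_batch_list <- function(batches, surface_color = c(0.8, 0.8, 0.85)) {
  if (inherits(batches, "geometry_batch") || inherits(batches, "mol_mesh")) {
    batches <- list(batches)
  }
  purrr::map(batches, function(b) {
    if (inherits(b, "mol_mesh")) mesh_to_batch(b, surface_color) else b
  })
}

#' Convert a surface mesh to a renderable geometry batch
#'
#' @param m A `mol_mesh`.
#' @param color Either a single RGB triple recycled over vertices or an
#'   `n x 3` matrix; `m$vertex_color` wins when present.
#' @return A triangle `geometry_batch` carrying the mesh normals.
#' @export
mesh_to_batch <- function(m, color = c(0.8, 0.8, 0.85)) {
  nv <- nrow(m$vertices)
  cols <- m$vertex_color %||%
    (if (is.matrix(color)) color else matrix(color, nv, 3, byrow = TRUE))
  b <- new_geometry_batch("triangles", m$vertices, cols, m$triangles,
                          m$vertex_atom %||% rep(NA_integer_, nv))
  b$normals <- m$normals
  b
}

#' Rasterize geometry to an image
#'
#' Z-buffered triangle fill with Gouraud shading from a single headlight
#' at the eye (ambient 0.2), one-pixel lines and points. Opaque batches
#' draw first with depth write; translucent batches (opacity < 1)
#' composite back-to-front against the opaque depth buffer. Output is
#' deterministic for a fixed scene and camera.
#'
#' @param batches A `geometry_batch`, `mol_mesh`, or list of them.
#' @param cam A `mol_camera` (default: fitted to the geometry).
#' @param width,height Image size in pixels.
#' @param background `"black"`, `"grey"` or `"white"`.
#' @param opacity Single opacity in `[0.5, 1]` applied to triangle
#'   batches, or a vector (one per batch).
#' @return A `mol_image`: `height x width x 3` array in `[0,1]`.
#' @export
rasterize <- function(batches, cam = NULL, width = 400, height = 300,
                      background = "black", opacity = 1) {
  batches <- as_batch_list(batches)
  img <- new_image(width, height, background)
  if (length(batches) == 0) return(img)
  all_pos <- do.call(rbind, purrr::map(batches, "positions"))
  if (nrow(all_pos) == 0) return(img)
  cam <- cam %||% default_camera(all_pos)
  zbuf <- matrix(Inf, height, width)
  opacity <- rep(opacity, length.out = length(batches))

  draw_one <- function(b, alpha) {
    pe <- to_eye(cam, b$positions)
    if (b$kind == "triangles" && nrow(b$indices) > 0) {
      normals <- b$normals %||% vertex_normals(b$positions, b$indices)
      ne <- to_eye(cam, normals + matrix(cam$eye, nrow(normals), 3,
                                         byrow = TRUE))
      shaded <- shade_colors(b$colors, ne)
      cl <- clip_triangles_eye(pe, shaded, b$indices, cam$near, cam$far)
      if (nrow(cl$tri) == 0) return(invisible())
      sv <- eye_to_screen(cam, cl$pe, width, height)
      if (alpha < 1) {
        # back-to-front for translucency
        depth_c <- (sv[cl$tri[, 1], 3] + sv[cl$tri[, 2], 3] +
                      sv[cl$tri[, 3], 3]) / 3
        cl$tri <- cl$tri[order(depth_c, decreasing = TRUE), , drop = FALSE]
      }
      fill_triangles_cpp(img, zbuf, sv, cl$cols, cl$tri, alpha, alpha >= 1)
    } else if (b$kind == "lines" && nrow(b$indices) > 0) {
      sv <- eye_to_screen(cam, pe, width, height)
      keep <- -pe[, 3] >= cam$near & -pe[, 3] <= cam$far
      segs <- b$indices[keep[b$indices[, 1]] & keep[b$indices[, 2]], ,
                        drop = FALSE]
      if (nrow(segs) > 0) draw_lines_cpp(img, zbuf, sv, b$colors, segs)
    } else if (b$kind == "points" && nrow(b$indices) > 0) {
      sv <- eye_to_screen(cam, pe, width, height)
      keep <- -pe[, 3] >= cam$near & -pe[, 3] <= cam$far
      pts <- b$indices[keep[b$indices[, 1]], 1]
      if (length(pts) > 0) draw_points_cpp(img, zbuf, sv, b$colors, pts)
    }
    invisible()
  }
  ord <- order(opacity < 1)  # opaque first, then translucent
  for (i in ord) draw_one(batches[[i]], opacity[i])
  img
}

#' Render an anaglyph stereo image
#'
#' Renders left/right views with the eye displaced by half the separation
#' along the camera's right vector (both converging on the target), then
#' encodes the left view's luminance in the red channel and the right
#' view's in green+blue - chromatically opposite filters, gray-anaglyph
#' style.
#'
#' @inheritParams rasterize
#' @param eye_separation Interocular separation in Angstrom; 0 yields
#'   identical red and cyan channels.
#' @return A `mol_image`.
#' @export
render_anaglyph <- function(batches, cam, eye_separation, width = 400,
                            height = 300, background = "black",
                            opacity = 1) {
  f <- vnormalize(cam$target - cam$eye)
  r <- vnormalize(vcross(f, cam$up))
  shift <- r * eye_separation / 2
  cam_l <- cam; cam_l$eye <- cam$eye - shift
  cam_r <- cam; cam_r$eye <- cam$eye + shift
  left <- rasterize(batches, cam_l, width, height, background, opacity)
  right <- rasterize(batches, cam_r, width, height, background, opacity)
  lum <- function(im) 0.2126 * im[, , 1] + 0.7152 * im[, , 2] +
    0.0722 * im[, , 3]
  out <- new_image(width, height, background)
  out[, , 1] <- lum(left)
  out[, , 2] <- lum(right)
  out[, , 3] <- lum(right)
  out
}

#' Overlay text labels on a rendered image
#'
#' Each label anchor is projected through the camera; visible anchors get
#' their text drawn with the package's 5x7 bitmap font at the projected
#' pixel plus a fixed offset, in deterministic order (by `serial` when
#' present). Off-screen anchors are skipped.
#'
#' @param img A `mol_image`.
#' @param labels A tibble with `text`, `x`, `y`, `z` (and optionally
#'   `serial`), e.g. from [make_labels()].
#' @param cam The `mol_camera` used to render `img`.
#' @param offset Pixel offset `c(dx, dy)` from the projected anchor.
#' @param color Label RGB.
#' @return A new `mol_image`.
#' @export
draw_labels <- function(img, labels, cam, offset = c(6, -6),
                        color = c(1, 1, 0)) {
  if (nrow(labels) == 0) return(img)
  if (!is.null(labels$serial)) {
    labels <- labels[order(labels$serial), , drop = FALSE]
  }
  height <- dim(img)[1]; width <- dim(img)[2]
  p <- cbind(labels$x, labels$y, labels$z)
  pe <- to_eye(cam, p)
  sc <- eye_to_screen(cam, pe, width, height)
  for (i in seq_len(nrow(labels))) {
    if (-pe[i, 3] < cam$near || -pe[i, 3] > cam$far) next
    px <- round(sc[i, 1]) + offset[1]
    py <- round(sc[i, 2]) + offset[2]
    if (px < 1 || px > width || py < 1 || py > height) next
    img <- draw_text(img, labels$text[i], px, py, color)
  }
  img
}

#' Write an image to PNG
#'
#' @param img A `mol_image`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' @export
print.mol_image <- function(x, ...) {
  cat(sprintf("<mol_image> %d x %d px\n", dim(x)[2], dim(x)[1]))
  invisible(x)
}

#' @export
autoplot.mol_image <- function(object, ...) {
  h <- dim(object)[1]; w <- dim(object)[2]
  df <- expand.grid(y = seq_len(h), x = seq_len(w))
  df$fill <- grDevices::rgb(object[, , 1], object[, , 2], object[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
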