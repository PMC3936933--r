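# shared helpers: tiny structures built in code and brute-force oracles

single_atom <- function(r = 2, element = "C") {
  tibble::tibble(serial = 1L, name = element, alt_loc = " ", res_name = "GLY",
                 chain_id = "A", res_seq = 1L, i_code = " ",
                 x = 0, y = 0, z = 0, occupancy = 1, b_factor = 0,
                 element = element, vdw_radius = r,
                 pdbqt_type = NA_character_, partial_charge = NA_real_,
                 is_hetero = FALSE, ss = "coil")
}

atoms_at <- function(centers, r = 1.7, element = "C", hetero = FALSE) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  tibble::tibble(serial = seq_len(n), name = element, alt_loc = " ",
                 res_name = if (hetero) "LIG" else "GLY", chain_id = "A",
                 res_seq = seq_len(n), i_code = " ",
                 x = centers[, 1], y = centers[, 2], z = centers[, 3],
                 occupancy = 1, b_factor = 0, element = element,
                 vdw_radius = r, pdbqt_type = NA_character_,
                 partial_charge = NA_real_, is_hetero = hetero, ss = "coil")
}

# brute-force nearest-feature scan, the independent EDT oracle
brute_edt <- function(mask) {
  d <- dim(mask)
  feat <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        out[i, j, k] <- sqrt(min((feat[, 1] - i)^2 + (feat[, 2] - j)^2 +
                                   (feat[, 3] - k)^2))
      }
    }
  }
  out
}

# scanline half-plane oracle: count pixels whose center lies inside the
# triangle (screen coordinates)
triangle_pixel_oracle <- function(v, width, height) {
  count <- 0
  for (py in seq_len(height)) {
    for (px in seq_len(width)) {
      xc <- px - 0.5; yc <- py - 0.5
      w0 <- (v[2, 1] - v[1, 1]) * (yc - v[1, 2]) -
        (v[2, 2] - v[1, 2]) * (xc - v[1, 1])
      w1 <- (v[3, 1] - v[2, 1]) * (yc - v[2, 2]) -
        (v[3, 2] - v[2, 2]) * (xc - v[2, 1])
      w2 <- (v[1, 1] - v[3, 1]) * (yc - v[3, 2]) -
        (v[1, 2] - v[3, 2]) * (xc - v[3, 1])
      if ((w0 >= 0 && w1 >= 0 && w2 >= 0) || (w0 <= 0 && w1 <= 0 && w2 <= 0)) {
        count <- count + 1
      }
    }
  }
  count
}

is_orientable <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  all(table(paste(e[, 1], e[, 2])) == 1)
}
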