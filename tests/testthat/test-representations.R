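test_that("every scheme yields valid RGB and the documented orderings", {
  s <- parse_pdb(synth_assembly(n_copies = 2, helix_n = 8, n_waters = 2))
  for (scheme in c("spectrum", "chain", "secondary", "bfactor", "residue",
                   "polarity", "atom")) {
    cols <- atom_colors(s, scheme)
    expect_equal(dim(cols), c(nrow(s), 3))
    expect_true(all(cols >= 0 & cols <= 1))
  }
  expect_error(atom_colors(s, "sparkles"),
               class = "molscene_error_unknown_scheme")

  # single chain under the chain scheme: one color
  hx <- parse_pdb(synth_pdb("mini_helix", n = 5))
  cc <- atom_colors(hx, "chain")
  expect_equal(nrow(unique(cc)), 1)

  # B-factor ramp is monotone in B
  bb <- atoms_at(cbind(1:3 * 5, 0, 0))
  bb$b_factor <- c(10, 20, 30)
  cb <- atom_colors(bb, "bfactor")
  expect_true(all(diff(cb[, 1]) > 0))   # red rises
  expect_true(all(diff(cb[, 3]) < 0))   # blue falls

  # CPK: carbon and oxygen differ
  co <- atoms_at(rbind(c(0, 0, 0), c(5, 0, 0)), element = c("C", "O"))
  ca <- atom_colors(co, "atom")
  expect_false(all(ca[1, ] == ca[2, ]))
})

test_that("the distance rule and CONECT records drive bond derivation", {
  nh <- atoms_at(rbind(c(0, 0, 0), c(1.01, 0, 0)), element = c("N", "H"))
  expect_equal(nrow(derive_bonds(nh)), 1)

  cc <- atoms_at(rbind(c(0, 0, 0), c(2.5, 0, 0)), element = c("C", "C"))
  expect_equal(nrow(derive_bonds(cc)), 0)

  # explicit CONECT wins beyond the threshold
  lines <- strsplit(synth_pdb("diatomic", separation = 2.5,
                              elements = c("C", "C")), "\n")[[1]]
  text <- paste(c(lines[1:2], "CONECT    1    2", "END"), collapse = "\n")
  s <- parse_pdb(text)
  b <- derive_bonds(s)
  expect_equal(nrow(b), 1)
  expect_equal(b$dist, 2.5, tolerance = 1e-6)
})

test_that("primary representations tessellate with closed-form counts", {
  di <- parse_pdb(synth_pdb("diatomic", separation = 1.4,
                            elements = c("C", "C")))
  ln <- build_primary(di, "line")
  expect_equal(ln$kind, "lines")
  expect_equal(nrow(ln$indices), 2)  # bicolor split: 2 segments per bond
  # each half carries its atom's color
  expect_equal(ln$colors[1, ], ln$colors[2, ])
  expect_equal(ln$colors[3, ], ln$colors[4, ])

  sp <- build_primary(di, "sphere", subdivision = 2)
  expect_equal(nrow(sp$indices), 2 * 20 * 4^2)
  expect_equal(nrow(sp$positions), 2 * (4^2 * 10 + 2))

  st <- build_primary(di, "stick", nsides = 8)
  expect_equal(nrow(st$indices), 2 * 2 * 8)  # two half-cylinders

  bs <- build_primary(di, "ball_stick", nsides = 6, subdivision = 1)
  expect_equal(nrow(bs$indices), 2 * 2 * 6 + 2 * 20 * 4)

  dot <- build_primary(di, "dot")
  expect_equal(dot$kind, "points")
  expect_equal(nrow(dot$indices), 2)

  # no bonds: stick is empty
  lone <- build_primary(single_atom(), "stick")
  expect_equal(nrow(lone$indices), 0)

  expect_error(build_primary(di, "squiggle"),
               class = "molscene_error_unknown_representation")

  # indices and source atoms always in range
  for (b in list(ln, sp, st, bs, dot)) {
    expect_true(all(b$indices >= 1 & b$indices <= nrow(b$positions)))
    expect_true(all(b$source_atoms >= 1 & b$source_atoms <= nrow(di)))
  }
})

test_that("the spline passes through every C-alpha and reps honor flags", {
  hx <- parse_pdb(synth_pdb("mini_helix", n = 12))
  st <- build_secondary(hx, "strand")
  ca <- cbind(hx$x, hx$y, hx$z)
  derr <- max(apply(ca, 1, function(p) {
    min(sqrt(colSums((t(st$positions) - p)^2)))
  }))
  expect_lte(derr, 0.5)

  rib <- build_secondary(hx, "ribbon", width = 1.6)
  expect_equal(rib$kind, "triangles")
  expect_gt(nrow(rib$indices), 0)
  # ribbon rails straddle the spline at half-width
  expect_equal(nrow(rib$positions), 2 * nrow(st$positions))

  tr <- build_secondary(hx, "ca_trace")
  expect_equal(nrow(tr$indices), nrow(hx) - 1)
  expect_equal(tr$positions, ca, ignore_attr = TRUE)

  # uniform B: tube radius is exactly the scale everywhere
  tb <- build_secondary(dplyr::mutate(hx, b_factor = 7), "tube_b",
                        tube_scale = 0.4, nsides = 6)
  curve_rad <- sqrt(rowSums((
    tb$positions - st$positions[rep(seq_len(nrow(st$positions)), each = 6), ]
  )^2))
  expect_equal(curve_rad, rep(0.4, length(curve_rad)), tolerance = 1e-9)

  cp <- build_secondary(hx, "cylinder_plate")
  expect_equal(cp$kind, "triangles")
  expect_gt(nrow(cp$indices), 0)

  # a chain with one C-alpha warns and contributes nothing
  short <- parse_pdb(synth_pdb("sphere_cluster",
                               centers = matrix(c(0, 0, 0), 1)))
  short$name <- "CA"
  expect_warning(b <- build_secondary(short, "ribbon"),
                 class = "molscene_warning_chain_too_short")
  expect_equal(nrow(b$positions), 0)

  expect_error(build_secondary(hx, "noodle"),
               class = "molscene_error_unknown_representation")
})
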