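test_that("PDB parsing recovers the generator's atoms, chains and coordinates", {
  centers <- rbind(c(0, 0, 0), c(1.234, -2.5, 3.75), c(-4.001, 0.125, 9.999))
  s <- parse_pdb(synth_pdb("sphere_cluster", centers = centers))
  expect_s3_class(s, "mol_structure")
  expect_equal(nrow(s), 3)
  expect_equal(length(unique(s$chain_id)), 1)
  expect_equal(cbind(s$x, s$y, s$z), centers, tolerance = 1e-3,
               ignore_attr = TRUE)

  d <- parse_pdb(synth_pdb("diatomic", separation = 3.4))
  expect_equal(d$x[2] - d$x[1], 3.4, tolerance = 1e-3)
})

test_that("degenerate and malformed PDB input is handled", {
  expect_error(parse_pdb(""), class = "molscene_error_empty_input")
  expect_error(parse_pdb("REMARK nothing here"),
               class = "molscene_error_empty_input")
  # a short record is skipped with a warning, the good one survives
  good <- synth_pdb("diatomic", separation = 2)
  lines <- strsplit(good, "\n")[[1]]
  text <- paste(c(lines[1], "ATOM      9  N", lines[2]), collapse = "\n")
  expect_warning(s <- parse_pdb(text), class = "molscene_warning_malformed_record")
  expect_equal(nrow(s), 2)
})

test_that("multi-model PDB keeps model 1 only; alt-locs restricted to ' '/'A'", {
  base <- strsplit(synth_pdb("diatomic", separation = 2), "\n")[[1]]
  atoms <- base[1:2]
  shifted <- gsub("   0\\.000", "   9.000", atoms)
  text <- paste(c("MODEL        1", atoms, "ENDMDL",
                  "MODEL        2", shifted, "ENDMDL", "END"),
                collapse = "\n")
  s <- parse_pdb(text)
  expect_equal(nrow(s), 2)
  expect_equal(s$x[2], 2)

  # alt_loc B dropped, A kept
  withB <- atoms
  substr(withB[1], 17, 17) <- "B"
  substr(withB[2], 17, 17) <- "A"
  s2 <- parse_pdb(paste(withB, collapse = "\n"))
  expect_equal(nrow(s2), 1)
  expect_equal(s2$alt_loc, "A")
})

test_that("PDBQT ensembles carry per-model energies and types", {
  ens <- parse_pdbqt(synth_pdbqt(k = 2, energies = c(-9.1, -8.4)))
  expect_s3_class(ens, "docked_ensemble")
  expect_length(ens$models, 2)
  expect_equal(ens$energies, c(-9.1, -8.4))
  expect_true("OA" %in% ens$models[[1]]$pdbqt_type)
  expect_equal(ens$models[[1]]$partial_charge[1], 0.05)

  g <- glance(ens)
  expect_equal(g$model, 1:2)
  expect_equal(g$energy, c(-9.1, -8.4))

  # single block, no REMARK -> one model, absent energy
  one <- parse_pdbqt(synth_pdbqt(k = 1, energies = NULL))
  expect_length(one$models, 1)
  expect_true(is.na(one$energies))
})

test_that("inconsistent PDBQT models fail loudly", {
  a <- synth_pdbqt(k = 1, energies = NULL, polar = TRUE)
  b <- synth_pdbqt(k = 1, energies = NULL, polar = FALSE)
  expect_error(parse_pdbqt(paste(a, b, sep = "\n")),
               class = "molscene_error_inconsistent_models")
})

test_that("element inference handles CA disambiguation, PDBQT types and unknowns", {
  s <- parse_pdb(synth_pdb("mini_helix", n = 3))
  expect_true(all(s$element == "C"))  # " CA " in ALA is an alpha carbon
  expect_true(all(s$vdw_radius == 1.70))

  ens <- parse_pdbqt(synth_pdbqt(k = 1))
  m <- ens$models[[1]]
  expect_equal(m$element[m$name == "N1"], "N")
  expect_equal(m$element[m$name == "HN"], "H")
  # AutoDock type "NA" maps to nitrogen
  expect_equal(molscene:::pdbqt_type_to_element("NA"), "N")

  odd <- single_atom()
  odd$name <- "XX1"; odd$element <- ""; odd$vdw_radius <- NA_real_
  expect_warning(out <- assign_elements_and_radii(odd),
                 class = "molscene_warning_unknown_element")
  expect_equal(out$vdw_radius, 1.70)

  # idempotence
  once <- suppressWarnings(assign_elements_and_radii(odd))
  twice <- suppressWarnings(assign_elements_and_radii(once))
  expect_identical(once$element, twice$element)
  expect_identical(once$vdw_radius, twice$vdw_radius)
})

test_that("secondary structure ranges flag helix/sheet residues, rest coil", {
  n <- 30
  ca <- cbind(seq_len(n) * 3.8, 0, 0)
  s <- parse_pdb(synth_pdb("sphere_cluster", centers = ca))
  s$name <- "CA"
  out <- assign_secondary_structure(
    s,
    helix_ranges = tibble::tibble(chain = "A", from = 5, to = 10),
    sheet_ranges = tibble::tibble(chain = "A", from = 20, to = 24)
  )
  expect_equal(sum(out$ss == "helix"), 6)
  expect_equal(sum(out$ss == "sheet"), 5)
  expect_equal(sum(out$ss == "coil"), n - 11)

  # record referencing absent residues is ignored with a warning
  expect_warning(
    assign_secondary_structure(
      s, helix_ranges = tibble::tibble(chain = "Z", from = 1, to = 5)),
    class = "molscene_warning_ss_out_of_range"
  )
  # no records at all -> everything coil
  none <- assign_secondary_structure(s)
  expect_true(all(none$ss == "coil"))
})

test_that("parsing agrees with an independent PDB reader on a fixture", {
  skip_if_not_installed("bio3d")
  text <- synth_pdb("mini_helix", n = 10)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(text, tf)
  ours <- parse_pdb(text)
  ref <- bio3d::read.pdb(tf)
  expect_equal(nrow(ours), nrow(ref$atom))
  expect_equal(ours$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(ours$y, ref$atom$y, tolerance = 1e-6)
  expect_equal(ours$res_seq, ref$atom$resno)
})

test_that("a two-complex assembly parses into two polymer chains", {
  s <- parse_pdb(synth_assembly(n_copies = 2))
  expect_equal(n_polymer_chains(s), 2)
  # waters are parsed and retained
  expect_true(any(s$res_name == "HOH"))
})
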