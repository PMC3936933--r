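make_rec_n <- function(pos = c(0, 0, 0)) {
  a <- atoms_at(matrix(pos, 1), element = "N")
  a$name <- "N"  # backbone nitrogen
  a
}

make_lig_o <- function(pos = c(3.4, 0, 0)) {
  atoms_at(matrix(pos, 1), element = "O", hetero = TRUE)
}

test_that("donor/acceptor roles follow the PDBQT type chemistry", {
  ens <- parse_pdbqt(synth_pdbqt(k = 1))
  m <- assign_donors_acceptors(ens$models[[1]])
  expect_true(m$is_acceptor[m$pdbqt_type == "OA"])
  # N with an HD hydrogen 1.01 A away is a donor
  expect_true(m$is_donor[m$name == "N1"])
  # carbons are neither
  expect_false(any(m$is_donor[m$element == "C"]))
  expect_false(any(m$is_acceptor[m$element == "C"]))
  # the HD hydrogen itself is neither donor nor acceptor heavy atom
  expect_false(m$is_donor[m$name == "HN"])
})

test_that("PDB-route chemistry covers backbone, side chains and hetero atoms", {
  res <- c("GLY", "LYS", "SER", "HIS", "ALA")
  ats <- atoms_at(cbind(seq_along(res) * 10, 0, 0), element = "N")
  ats$res_name <- res
  ats$name <- c("N", "NZ", "OG", "ND1", "CB")
  ats$element <- c("N", "N", "O", "N", "C")
  out <- assign_donors_acceptors(ats)
  # backbone N, Lys NZ, Ser OG and His ND1 all donate; carbon does not
  expect_equal(out$is_donor, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # His side-chain N accepts; Ser OG is an O so it accepts too
  expect_equal(out$is_acceptor, c(FALSE, FALSE, TRUE, TRUE, FALSE))

  het <- make_lig_o()
  expect_true(assign_donors_acceptors(het)$is_donor)
  expect_true(assign_donors_acceptors(het)$is_acceptor)
})

test_that("bonds appear exactly at the 3.5 A heavy-atom threshold", {
  rec <- make_rec_n()
  hb <- detect_hbonds(rec, make_lig_o(c(3.4, 0, 0)))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$length, 3.4, tolerance = 1e-9)
  expect_equal(hb$donor_molecule, "receptor")

  expect_equal(nrow(detect_hbonds(rec, make_lig_o(c(3.6, 0, 0)))), 0)
  # boundary: exactly 3.5 is included
  expect_equal(nrow(detect_hbonds(rec, make_lig_o(c(3.5, 0, 0)))), 1)

  # apolar ligand finds nothing
  apolar <- atoms_at(matrix(c(3, 0, 0), 1), element = "C", hetero = TRUE)
  expect_equal(nrow(detect_hbonds(rec, apolar)), 0)
})

test_that("bond count is monotone in cutoff and symmetric under swap", {
  set.seed(11)
  rec <- atoms_at(cbind(stats::runif(6, 0, 6), stats::runif(6, 0, 6), 0),
                  element = "N")
  rec$name <- "N"
  lig <- atoms_at(cbind(stats::runif(6, 0, 6), stats::runif(6, 0, 6), 1),
                  element = "O", hetero = TRUE)
  counts <- vapply(seq(1, 8, by = 0.5),
                   function(cut) nrow(detect_hbonds(rec, lig, cut)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))

  ab <- detect_hbonds(rec, lig)
  ba <- detect_hbonds(lig, rec)
  expect_equal(nrow(ab), nrow(ba))
  key <- function(h, flip) {
    a <- paste(h$donor_molecule, h$donor_serial)
    b <- paste(h$acceptor_molecule, h$acceptor_serial)
    if (flip) {
      a <- sub("receptor", "tmp", a); a <- sub("ligand", "receptor", a)
      a <- sub("tmp", "ligand", a)
      b <- sub("receptor", "tmp", b); b <- sub("ligand", "receptor", b)
      b <- sub("tmp", "ligand", b)
    }
    sort(paste(pmin(a, b), pmax(a, b)))
  }
  expect_equal(key(ab, FALSE), key(ba, TRUE))
})

test_that("labels cover each distinct bonded atom once", {
  rec <- make_rec_n()
  lig <- make_lig_o(c(3.0, 0, 0))
  hb <- detect_hbonds(rec, lig)
  lbl <- make_labels(hb, rec, lig)
  expect_equal(nrow(lbl), 2)
  expect_match(lbl$text[1], "^A:")
  expect_match(lbl$text, ":", all = TRUE)

  # two donors sharing one acceptor -> 3 labels
  rec2 <- atoms_at(rbind(c(0, 0, 0), c(0, 3, 0)), element = "N")
  rec2$name <- "N"
  hb2 <- detect_hbonds(rec2, make_lig_o(c(2, 1.5, 0)))
  expect_equal(nrow(hb2), 2)
  expect_equal(nrow(make_labels(hb2, rec2, make_lig_o(c(2, 1.5, 0)))), 3)

  empty <- detect_hbonds(rec, atoms_at(matrix(c(50, 0, 0), 1),
                                       element = "O", hetero = TRUE))
  expect_equal(nrow(make_labels(empty, rec, lig)), 0)
})
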