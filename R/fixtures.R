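# Deterministic synthetic-structure generators. Every generator is pure
# text-out: the same spec and seed always produce byte-identical files, so
# goldens are bit-stable. The only pseudo-randomness (ligand_blob jitter)
# comes from a package-local LCG, never from R's global RNG.

pdb_format_name <- function(name) {
  # short names start at column 14 by convention
  if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
}

pdb_atom_record <- function(serial, name, res_name, chain, res_seq, xyz,
                            occ = 1, b = 0, element = "", hetero = FALSE) {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (hetero) "HETATM" else "ATOM", serial, pdb_format_name(name),
          " ", res_name, chain, res_seq, " ",
          xyz[1], xyz[2], xyz[3], occ, b,
          formatC(element, width = 2, flag = " "))
}

pdbqt_atom_record <- function(serial, name, res_name, chain, res_seq, xyz,
                              charge, type, hetero = FALSE) {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f%10.4f %-2s",
          if (hetero) "HETATM" else "ATOM", serial, pdb_format_name(name),
          " ", res_name, chain, res_seq, " ",
          xyz[1], xyz[2], xyz[3], 1, 0, charge, type)
}

# ideal alpha-helix C-alpha trace: rise 1.5 A/residue, 100 deg/residue,
# radius 2.3 A
helix_ca_coords <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta) + origin[1],
        2.3 * sin(theta) + origin[2],
        1.5 * i + origin[3])
}

#' Generate synthetic PDB text
#'
#' Deterministic generators used throughout the test surface so no
#' structure ever needs to be downloaded:
#' * `diatomic` - two atoms at a stated separation along x.
#' * `mini_helix` - `n` C-alpha atoms on an ideal alpha helix (rise 1.5
#'   A/residue, 100 deg/residue, radius 2.3 A) plus a HELIX record.
#' * `ligand_blob` - a HETATM cluster with exact per-axis extents (six
#'   extreme atoms on the axes plus seeded jittered interior atoms).
#' * `sphere_cluster` - atoms at stated centers with stated elements.
#'
#' @param kind Fixture kind.
#' @param separation Diatomic separation in Angstrom.
#' @param elements Elements of the two diatomic atoms, or of cluster atoms.
#' @param hetero Write diatomic/cluster atoms as HETATM records.
#' @param n Number of residues (mini_helix) or interior atoms (ligand_blob).
#' @param chain Chain identifier.
#' @param extents Per-axis extents (A) of the ligand blob.
#' @param center Blob / cluster center.
#' @param res_name HETATM residue name for the blob.
#' @param centers Numeric matrix (m x 3) of sphere_cluster atom centers.
#' @param seed Integer seed for the blob jitter (package-local LCG).
#' @return A single string of PDB text.
#' @export
synth_pdb <- function(kind = c("diatomic", "mini_helix", "ligand_blob",
                               "sphere_cluster"),
                      separation = 3.4, elements = NULL,
                      hetero = FALSE, n = 12, chain = "A",
                      extents = c(10, 6, 4), center = c(0, 0, 0),
                      res_name = "LIG", centers = NULL, seed = 1) {
  kind <- match.arg(kind)
  lines <- character(0)
  if (kind == "diatomic") {
    elements <- elements %||% c("N", "O")
    if (!is.finite(separation) || separation < 0) {
      msg_abort("invalid spec: separation must be a non-negative number", "invalid_spec")
    }
    lines <- c(
      pdb_atom_record(1, elements[1], if (hetero) "LG1" else "GLY", chain, 1,
                      c(0, 0, 0), element = elements[1], hetero = hetero),
      pdb_atom_record(2, elements[2], if (hetero) "LG2" else "GLY", chain, 2,
                      c(separation, 0, 0), element = elements[2], hetero = hetero)
    )
  } else if (kind == "mini_helix") {
    if (n < 2) msg_abort("invalid spec: mini_helix needs n >= 2", "invalid_spec")
    ca <- helix_ca_coords(n, origin = center)
    lines <- c(
      sprintf("HELIX    1   1 ALA %1s    1  ALA %1s %4d  1 %31d", chain, chain, n, n),
      vapply(seq_len(n), function(i) {
        pdb_atom_record(i, "CA", "ALA", chain, i, ca[i, ], element = "C")
      }, character(1))
    )
  } else if (kind == "ligand_blob") {
    if (any(!is.finite(extents)) || length(extents) != 3) {
      msg_abort("invalid spec: extents must be three finite numbers", "invalid_spec")
    }
    half <- extents / 2
    ext <- rbind(
      center + c(-half[1], 0, 0), center + c(half[1], 0, 0),
      center + c(0, -half[2], 0), center + c(0, half[2], 0),
      center + c(0, 0, -half[3]), center + c(0, 0, half[3])
    )
    rng <- make_lcg(seed)
    jit <- matrix(rng(3 * n), ncol = 3)
    interior <- sweep(sweep(jit - 0.5, 2, pmin(extents * 0.8, extents - 0.2), "*"),
                      2, center, "+")
    coords <- rbind(ext, interior)
    lines <- vapply(seq_len(nrow(coords)), function(i) {
      pdb_atom_record(i, sprintf("C%d", i), res_name, chain, 1, coords[i, ],
                      element = "C", hetero = TRUE)
    }, character(1))
  } else {
    if (is.null(centers)) {
      msg_abort("invalid spec: sphere_cluster needs a centers matrix", "invalid_spec")
    }
    centers <- as.matrix(centers)
    elements <- elements %||% "C"
    if (length(elements) == 1) elements <- rep(elements, nrow(centers))
    if (length(elements) != nrow(centers)) {
      msg_abort("invalid spec: one element per center required", "invalid_spec")
    }
    lines <- vapply(seq_len(nrow(centers)), function(i) {
      pdb_atom_record(i, elements[i], if (hetero) res_name else "GLY", chain,
                      i, centers[i, ], element = elements[i], hetero = hetero)
    }, character(1))
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate synthetic multi-model PDBQT text
#'
#' Writes `k` MODEL blocks of a small rigid ligand (AutoDock atom types
#' including an OA acceptor and an HD polar hydrogen bonded to N when
#' `polar = TRUE`), each block translated deterministically and stamped
#' with the requested REMARK energy. Atom order is identical across models
#' by construction; `permute_atoms = TRUE` is refused because it would
#' break the ensemble invariant.
#'
#' @param k Number of models.
#' @param energies Numeric energies (kcal/mol), length `k`, or `NULL`
#'   (default) to write no REMARK energy lines.
#' @param polar Include polar atoms (N + HD hydrogen, OA oxygen).
#' @param shift Per-model translation step along x (A).
#' @param center Position of the first model.
#' @param permute_atoms Must stay `FALSE`; permuted atom lines violate the
#'   identical-ordering invariant and the generator refuses to write them.
#' @param seed Unused placeholder for interface symmetry; generation is
#'   closed-form.
#' @return A single string of PDBQT text.
#' @export
synth_pdbqt <- function(k = 2, energies = NULL, polar = TRUE,
                        shift = 1.0, center = c(0, 0, 0),
                        permute_atoms = FALSE, seed = 1) {
  if (k < 1) msg_abort("invalid spec: k must be >= 1", "invalid_spec")
  if (isTRUE(permute_atoms)) {
    msg_abort("invalid spec: permuted atom lines would break the identical-atom-ordering invariant",
              "invalid_spec")
  }
  if (!is.null(energies) && length(energies) != k) {
    msg_abort("invalid spec: need one energy per model (or NULL)", "invalid_spec")
  }
  template <- list(
    list(name = "C1", type = "C", q = 0.05, p = c(0, 0, 0)),
    list(name = "C2", type = "C", q = 0.03, p = c(1.5, 0, 0))
  )
  if (polar) {
    template <- c(template, list(
      list(name = "N1", type = "N", q = -0.35, p = c(0, 1.4, 0)),
      list(name = "HN", type = "HD", q = 0.16, p = c(0, 2.41, 0)),
      list(name = "O1", type = "OA", q = -0.40, p = c(2.2, 1.1, 0))
    ))
  }
  blocks <- vapply(seq_len(k), function(m) {
    off <- center + c((m - 1) * shift, 0, 0)
    body <- vapply(seq_along(template), function(i) {
      a <- template[[i]]
      pdbqt_atom_record(i, a$name, "LIG", "X", 1, a$p + off, a$q, a$type,
                        hetero = TRUE)
    }, character(1))
    hdr <- sprintf("MODEL %8d", m)
    rem <- if (!is.null(energies)) {
      sprintf("REMARK FREE ENERGY PREDICTED: %8.2f KCAL/MOL", energies[m])
    } else character(0)
    paste(c(hdr, rem, "ROOT", body, "ENDROOT", "TORSDOF 0", "ENDMDL"),
          collapse = "\n")
  }, character(1))
  paste(blocks, collapse = "\n")
}

#' Generate a synthetic two-complex crystal assembly
#'
#' A programmatically built stand-in emulating the layout of a crystal
#' asymmetric unit containing `n_copies` receptor-ligand complexes: per
#' copy, one polymer chain (an ideal mini-helix) plus one multi-atom
#' HETATM ligand group, and a shared set of crystallographic waters. It is
#' synthetic - generated entirely in code, not derived from any deposited
#' entry - and exists so chain counting, largest-ligand detection and
#' surface construction can be exercised without downloads.
#'
#' @param n_copies Number of receptor-ligand copies (polymer chains).
#' @param helix_n Residues per receptor helix.
#' @param ligand_atoms Atoms per ligand group.
#' @param n_waters Number of water molecules appended.
#' @param offset Translation between copies (A).
#' @param seed Seed for ligand jitter.
#' @return A single string of PDB text.
#' @export
synth_assembly <- function(n_copies = 2, helix_n = 20, ligand_atoms = 18,
                           n_waters = 10, offset = 30, seed = 1) {
  if (n_copies < 1) msg_abort("invalid spec: n_copies must be >= 1", "invalid_spec")
  rng <- make_lcg(seed)
  lines <- character(0)
  serial <- 0
  for (cp in seq_len(n_copies)) {
    chain <- LETTERS[cp]
    org <- c((cp - 1) * offset, 0, 0)
    lines <- c(lines, sprintf("HELIX    1   1 ALA %1s    1  ALA %1s %4d  1 %31d",
                              chain, chain, helix_n, helix_n))
    ca <- helix_ca_coords(helix_n, origin = org)
    for (i in seq_len(helix_n)) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_record(serial, "CA", "ALA", chain, i,
                                        ca[i, ], element = "C"))
    }
    lig_center <- org + c(6, 0, helix_n * 1.5 / 2)
    jit <- (matrix(rng(3 * ligand_atoms), ncol = 3) - 0.5) * 6
    for (i in seq_len(ligand_atoms)) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_record(serial, sprintf("C%d", i), "MVC",
                                        chain, 500, lig_center + jit[i, ],
                                        element = "C", hetero = TRUE))
    }
  }
  for (i in seq_len(n_waters)) {
    serial <- serial + 1
    w <- c(rng(1) * offset * n_copies, rng(1) * 10 - 5, rng(1) * 20)
    lines <- c(lines, pdb_atom_record(serial, "O", "HOH", "W", 1000 + i, w,
                                      element = "O", hetero = TRUE))
  }
  paste(c(lines, "END"), collapse = "\n")
}
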