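# Geometric intermolecular hydrogen-bond detection.
#
# The criterion is the conventional heavy-atom donor-acceptor distance
# (default cutoff 3.5 A); no angular term is applied.

# PDB-route donor/acceptor chemistry (structures without hydrogens).
.sidechain_donor_n <- c("LYS", "ARG", "HIS", "TRP", "ASN", "GLN")
.sidechain_donor_o <- c("SER", "THR", "TYR")

#' Annotate hydrogen-bond donors and acceptors
#'
#' Two routes, chosen per atom by whether an AutoDock type is present:
#' * PDBQT route - acceptors are atoms typed `OA`, `NA` or `SA`; donors
#'   are N/O heavy atoms with a covalently attached `HD` polar hydrogen
#'   (attachment = distance < 1.3 A).
#' * PDB route (no hydrogens) - donors: backbone N, side-chain N of
#'   Lys/Arg/His/Trp/Asn/Gln, hydroxyl O of Ser/Thr/Tyr; acceptors: every
#'   O, side-chain N of His. HETATM N/O atoms take both roles.
#'
#' These chemistry tables are documented defaults, not a force field.
#'
#' @param s A `mol_structure`, one model of a `docked_ensemble`, or an
#'   atom table with elements assigned.
#' @return The atom table with logical `is_donor` / `is_acceptor` columns.
#' @export
assign_donors_acceptors <- function(s) {
  atoms <- as_atom_table(s)
  n <- nrow(atoms)
  donor <- logical(n)
  acceptor <- logical(n)
  has_type <- !is.null(atoms$pdbqt_type) &&
    any(!is.na(atoms$pdbqt_type) & nzchar(atoms$pdbqt_type))

  if (has_type) {
    type <- toupper(trimws(atoms$pdbqt_type))
    acceptor <- type %in% c("OA", "NA", "SA")
    hd <- which(type == "HD")
    heavy <- which(atoms$element %in% c("N", "O"))
    if (length(hd) > 0 && length(heavy) > 0) {
      hp <- cbind(atoms$x[hd], atoms$y[hd], atoms$z[hd])
      for (i in heavy) {
        d <- sqrt((hp[, 1] - atoms$x[i])^2 + (hp[, 2] - atoms$y[i])^2 +
                    (hp[, 3] - atoms$z[i])^2)
        if (any(d < 1.3)) donor[i] <- TRUE
      }
    }
  } else {
    el <- atoms$element
    res <- toupper(atoms$res_name)
    het <- atoms$is_hetero
    # polymer rules
    donor <- !het & (
      (el == "N" & atoms$name == "N") |                       # backbone N
        (el == "N" & res %in% .sidechain_donor_n & atoms$name != "N") |
        (el == "O" & res %in% .sidechain_donor_o & atoms$name != "O")
    )
    acceptor <- !het & (
      el == "O" |
        (el == "N" & res == "HIS" & atoms$name != "N")
    )
    # hetero atoms: any N/O can take both roles
    both <- het & el %in% c("N", "O")
    donor <- donor | both
    acceptor <- acceptor | both
  }
  atoms$is_donor <- donor
  atoms$is_acceptor <- acceptor
  if (inherits(s, "mol_structure")) {
    s$is_donor <- donor
    s$is_acceptor <- acceptor
    s
  } else {
    atoms
  }
}

atom_ref_text <- function(atoms, idx) {
  sprintf("%s:%s %d:%s", trimws(atoms$chain_id[idx]), atoms$res_name[idx],
          atoms$res_seq[idx], atoms$name[idx])
}

#' Detect putative intermolecular hydrogen bonds
#'
#' Enumerates every cross-molecule donor/acceptor pair (in both role
#' assignments) whose heavy-atom separation is at most `cutoff`, the
#' conventional donor-acceptor distance criterion. Pairs duplicated with
#' swapped roles are reported once; bonds are sorted by length.
#'
#' @param receptor,ligand Structures or atom tables; donor/acceptor
#'   annotation is added automatically when missing.
#' @param cutoff Heavy-atom distance threshold in Angstrom (default 3.5).
#' @return A tibble of class `hbond_tbl`, one row per bond: donor and
#'   acceptor molecule/chain/residue/atom references and `length` (A).
#' @examples
#' rec <- parse_pdb(synth_pdb("diatomic", elements = c("N", "N")))
#' lig <- parse_pdb(synth_pdb("diatomic", elements = c("O", "O"),
#'                            hetero = TRUE))
#' detect_hbonds(rec, lig)
#' @export
detect_hbonds <- function(receptor, ligand, cutoff = 3.5) {
  rec <- as_atom_table(assign_donors_acceptors(receptor), "receptor")
  lig <- as_atom_table(assign_donors_acceptors(ligand), "ligand")
  empty <- tibble::tibble(
    donor_molecule = character(), donor_chain = character(),
    donor_res_name = character(), donor_res_seq = integer(),
    donor_atom = character(), donor_serial = integer(),
    acceptor_molecule = character(), acceptor_chain = character(),
    acceptor_res_name = character(), acceptor_res_seq = integer(),
    acceptor_atom = character(), acceptor_serial = integer(),
    length = double()
  )
  class(empty) <- c("hbond_tbl", class(empty))
  if (nrow(rec) == 0 || nrow(lig) == 0) return(empty)

  pair_up <- function(don, don_mol, acc, acc_mol) {
    di <- which(don$is_donor)
    ai <- which(acc$is_acceptor)
    if (length(di) == 0 || length(ai) == 0) return(NULL)
    dp <- cbind(don$x[di], don$y[di], don$z[di])
    ap <- cbind(acc$x[ai], acc$y[ai], acc$z[ai])
    dd <- outer(rowSums(dp^2), rowSums(ap^2), "+") - 2 * dp %*% t(ap)
    dd[dd < 0] <- 0
    hit <- which(sqrt(dd) <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    d_idx <- di[hit[, 1]]
    a_idx <- ai[hit[, 2]]
    tibble::tibble(
      donor_molecule = don_mol,
      donor_chain = trimws(don$chain_id[d_idx]),
      donor_res_name = don$res_name[d_idx],
      donor_res_seq = don$res_seq[d_idx],
      donor_atom = don$name[d_idx],
      donor_serial = don$serial[d_idx],
      acceptor_molecule = acc_mol,
      acceptor_chain = trimws(acc$chain_id[a_idx]),
      acceptor_res_name = acc$res_name[a_idx],
      acceptor_res_seq = acc$res_seq[a_idx],
      acceptor_atom = acc$name[a_idx],
      acceptor_serial = acc$serial[a_idx],
      length = sqrt(dd[hit])
    )
  }
  bonds <- dplyr::bind_rows(
    pair_up(rec, "receptor", lig, "ligand"),
    pair_up(lig, "ligand", rec, "receptor")
  )
  if (nrow(bonds) == 0) return(empty)
  # one row per unordered atom pair
  key <- purrr::map2_chr(
    paste(bonds$donor_molecule, bonds$donor_serial),
    paste(bonds$acceptor_molecule, bonds$acceptor_serial),
    ~ paste(sort(c(.x, .y)), collapse = "|")
  )
  bonds <- bonds[!duplicated(key), , drop = FALSE]
  bonds <- dplyr::arrange(bonds, .data$length)
  class(bonds) <- c("hbond_tbl", class(bonds))
  bonds
}

#' Labels for hydrogen-bonded atoms
#'
#' One label per distinct atom participating in at least one bond, with
#' text `"chain:resname resseq:atomname"` anchored at the atom position.
#'
#' @param bonds An `hbond_tbl` from [detect_hbonds()].
#' @param receptor,ligand The structures the bonds refer to (anchor
#'   positions are looked up by serial).
#' @return A tibble: `molecule`, `serial`, `text`, `x`, `y`, `z`.
#' @export
make_labels <- function(bonds, receptor, ligand) {
  if (nrow(bonds) == 0) {
    return(tibble::tibble(molecule = character(), serial = integer(),
                          text = character(), x = double(), y = double(),
                          z = double()))
  }
  ends <- dplyr::bind_rows(
    tibble::tibble(molecule = bonds$donor_molecule,
                   serial = bonds$donor_serial),
    tibble::tibble(molecule = bonds$acceptor_molecule,
                   serial = bonds$acceptor_serial)
  )
  ends <- dplyr::distinct(ends)
  rec <- as_atom_table(receptor, "receptor")
  lig <- as_atom_table(ligand, "ligand")
  purrr::pmap_dfr(ends, function(molecule, serial) {
    tab <- if (molecule == "receptor") rec else lig
    i <- which(tab$serial == serial)[1]
    tibble::tibble(molecule = molecule, serial = serial,
                   text = atom_ref_text(tab, i),
                   x = tab$x[i], y = tab$y[i], z = tab$z[i])
  })
}

#' @export
autoplot.hbond_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pair <- paste(df$donor_chain, df$donor_atom, "-",
                   df$acceptor_chain, df$acceptor_atom)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pair, .data$length),
                                   y = .data$length)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "donor-acceptor distance (Å)")
}
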