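# Cubic binding-site box determination: find the largest co-crystallized
# ligand, take the smallest cube covering it, expand by 50% (default) to
# reserve conformational sampling space; fall back to the protein's
# geometric center when no ligand exists.

# common monoatomic ions / crystallization additives excluded from
# largest-ligand detection (documented, overridable)
.ion_residues <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "CU",
                   "CO", "NI", "CD", "HG", "SO4", "PO4")
.water_residues <- c("HOH", "WAT", "DOD")

#' Find the largest co-crystallized ligand
#'
#' Among HETATM residue groups, excluding waters and a documented list of
#' monoatomic ions / common additives, returns the group with the most
#' atoms; ties break by first occurrence in the file.
#'
#' @param s A `mol_structure` or atom table.
#' @param exclude Residue names to exclude besides waters.
#' @return A tibble of the ligand's atoms, or `NULL` when no eligible
#'   group exists.
#' @export
find_largest_ligand <- function(s, exclude = .ion_residues) {
  atoms <- as_atom_table(s)
  het <- dplyr::filter(
    tibble::as_tibble(atoms), .data$is_hetero,
    !toupper(.data$res_name) %in% toupper(c(.water_residues, exclude))
  )
  if (nrow(het) == 0) return(NULL)
  het$first_row <- seq_len(nrow(het))
  grp <- dplyr::summarise(
    dplyr::group_by(het, .data$chain_id, .data$res_seq, .data$i_code,
                    .data$res_name),
    n_atoms = dplyr::n(), first = min(.data$first_row), .groups = "drop"
  )
  grp <- dplyr::arrange(grp, dplyr::desc(.data$n_atoms), .data$first)
  best <- grp[1, ]
  dplyr::select(
    dplyr::filter(het, .data$chain_id == best$chain_id,
                  .data$res_seq == best$res_seq,
                  .data$i_code == best$i_code,
                  .data$res_name == best$res_name),
    -"first_row"
  )
}

new_box <- function(center, edge) {
  stopifnot(all(edge > 0), length(edge) %in% c(1, 3))
  structure(list(center = center, edge = edge), class = "mol_box")
}

#' Automatic cubic docking box
#'
#' With a co-crystallized ligand: the center is the midpoint of the
#' ligand's per-axis coordinate extremes and the edge is
#' `(1 + expand_fraction)` times the largest per-axis extent (the smallest
#' covering cube expanded, default by 50%), floored at `min_edge`. Without
#' one: the center defaults to the unweighted geometric center of the
#' protein atoms with edge `default_edge`.
#'
#' `per_axis = TRUE` switches to the rectangular variant that expands each
#' axis independently before taking the cube over the expanded extents.
#'
#' @param s A `mol_structure` or atom table.
#' @param expand_fraction Fractional expansion (default 0.5 = 50%).
#' @param min_edge Minimum cube edge in Angstrom.
#' @param default_edge Edge used when no ligand exists.
#' @param ligand Optional pre-selected ligand atom table.
#' @param per_axis Expand each axis independently (rectangular variant
#'   behind a flag; the result is still reported as its covering cube).
#' @return A `mol_box`: list with `center` (A) and `edge` (A).
#' @export
auto_box <- function(s, expand_fraction = 0.5, min_edge = 10,
                     default_edge = 20, ligand = NULL, per_axis = FALSE) {
  atoms <- as_atom_table(s)
  lig <- ligand %||% find_largest_ligand(atoms)
  if (is.null(lig) || nrow(lig) == 0) {
    protein <- dplyr::filter(tibble::as_tibble(atoms), !.data$is_hetero)
    if (nrow(protein) == 0) protein <- tibble::as_tibble(atoms)
    center <- c(mean(protein$x), mean(protein$y), mean(protein$z))
    return(new_box(center, default_edge))
  }
  lo <- c(min(lig$x), min(lig$y), min(lig$z))
  hi <- c(max(lig$x), max(lig$y), max(lig$z))
  center <- (lo + hi) / 2
  extent <- hi - lo
  if (per_axis) {
    # rectangular variant: each axis expanded independently
    new_box(center, pmax(extent * (1 + expand_fraction), min_edge))
  } else {
    new_box(center, max((1 + expand_fraction) * max(extent), min_edge))
  }
}

#' Check ligand containment in a box
#'
#' An atom is inside iff every coordinate lies within
#' `[center - edge/2, center + edge/2]` (closed interval).
#'
#' @param b A `mol_box`.
#' @param m A `mol_structure`, atom table, or one model of an ensemble.
#' @return List with `all_inside` (logical) and `atoms_outside` (count).
#' @export
box_contains <- function(b, m) {
  atoms <- as_atom_table(m, "m")
  half <- rep(b$edge, length.out = 3) / 2
  inside <- abs(atoms$x - b$center[1]) <= half[1] &
    abs(atoms$y - b$center[2]) <= half[2] &
    abs(atoms$z - b$center[3]) <= half[3]
  list(all_inside = all(inside), atoms_outside = sum(!inside))
}

#' @export
print.mol_box <- function(x, ...) {
  cat(sprintf("<mol_box> center (%.2f, %.2f, %.2f) A, edge %s A\n",
              x$center[1], x$center[2], x$center[3],
              paste(sprintf("%.2f", x$edge), collapse = " x ")))
  invisible(x)
}

#' @export
tidy.mol_box <- function(x, ...) {
  e <- rep(x$edge, length.out = 3)
  tibble::tibble(center_x = x$center[1], center_y = x$center[2],
                 center_z = x$center[3],
                 edge_x = e[1], edge_y = e[2], edge_z = e[3])
}
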