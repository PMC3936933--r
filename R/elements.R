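# Element inference and the single van der Waals / covalent radius tables
# used throughout the package.

# Bondi-style van der Waals radii (Angstrom); one documented table used
# everywhere. Unknown elements fall back to `.vdw_default`.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)
.vdw_default <- 1.70

# single-bond covalent radii (Angstrom), used by the distance bond rule
.cov_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39
)
.cov_default <- 0.77

# AutoDock atom type -> chemical element
.pdbqt_type_element <- c(
  C = "C", A = "C", N = "N", NA_ = "N", NS = "N",
  O = "O", OA = "O", OS = "O", S = "S", SA = "S",
  H = "H", HD = "H", HS = "H", P = "P",
  F = "F", CL = "CL", BR = "BR", I = "I",
  MG = "MG", MN = "MN", ZN = "ZN", FE = "FE", CA = "CA"
)

.two_letter_elements <- c(
  "CL", "BR", "FE", "ZN", "MG", "MN", "CU", "CO", "NI", "CD",
  "HG", "SE", "NA", "CA", "K"
)

.hetero_safe_two_letter <- c("CL", "BR", "FE", "ZN", "MG", "MN")

pdbqt_type_to_element <- function(type) {
  key <- toupper(trimws(type))
  key[key == "NA"] <- "NA_"
  out <- unname(.pdbqt_type_element[key])
  ifelse(is.na(out), substr(key, 1, 1), out)
}

# element inference from the atom-name column; `res_name` disambiguates
# e.g. a " CA " alpha carbon from a calcium ion.
infer_element_from_name <- function(name, res_name, is_hetero) {
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  n <- length(stripped)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- stripped[i]
    if (nchar(s) == 0) { out[i] <- "" ; next }
    two <- substr(s, 1, 2)
    if (is_hetero[i] && two %in% .two_letter_elements &&
        toupper(trimws(res_name[i])) == two) {
      # monoatomic ion records name the element as the residue (e.g. CA, ZN)
      out[i] <- two
    } else if (is_hetero[i] && s %in% .hetero_safe_two_letter) {
      # two-letter symbols whose first letter is not itself a common organic
      # element, so a bare name like "ZN" or "CL1" is unambiguous in ligands
      out[i] <- s
    } else {
      first <- substr(s, 1, 1)
      # hydrogens may be written as 1HB etc.; gsub stripped the digit already
      out[i] <- first
    }
  }
  out
}

#' Assign chemical elements and van der Waals radii
#'
#' Infers the element of every atom (PDB element columns 77-78 preferred,
#' atom-name heuristic fallback, AutoDock PDBQT type map when present) and
#' attaches a van der Waals radius from the package's Bondi-style radius
#' table. Unknown elements receive the default radius (1.70 A) with a
#' warning. The operation is idempotent.
#'
#' @param s A `mol_structure` or a data frame of atom records.
#' @return The input with `element` and `vdw_radius` columns filled in.
#' @export
assign_elements_and_radii <- function(s) {
  atoms <- as_atom_table(s)
  n <- nrow(atoms)
  if (n == 0) return(s)

  element <- toupper(trimws(atoms$element %||% rep("", n)))
  element[is.na(element)] <- ""

  # PDBQT type map takes precedence where the element column is blank
  if (!is.null(atoms$pdbqt_type)) {
    has_type <- !is.na(atoms$pdbqt_type) & nzchar(trimws(atoms$pdbqt_type))
    fill <- element == "" & has_type
    element[fill] <- pdbqt_type_to_element(atoms$pdbqt_type[fill])
  }
  blank <- element == ""
  if (any(blank)) {
    element[blank] <- infer_element_from_name(
      atoms$name[blank], atoms$res_name[blank], atoms$is_hetero[blank]
    )
  }

  radius <- unname(.vdw_radii[element])
  unknown <- is.na(radius)
  if (any(unknown)) {
    msg_warn(sprintf(
      "%d atom(s) with element(s) %s not in the radius table; default %.2f A used",
      sum(unknown), paste(unique(element[unknown]), collapse = ", "), .vdw_default
    ), "unknown_element")
    radius[unknown] <- .vdw_default
  }

  if (inherits(s, "mol_structure")) {
    s$element <- element
    s$vdw_radius <- radius
    s
  } else {
    atoms$element <- element
    atoms$vdw_radius <- radius
    atoms
  }
}
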