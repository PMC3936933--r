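# PDB / PDBQT parsing into tidy atom tables.
#
# A mol_structure is a tibble of atom records (one row per ATOM/HETATM)
# carrying, as attributes, the structure id, the HELIX/SHEET ranges and any
# CONECT pairs found in the file. Column layout:
#   serial, name, alt_loc, res_name, chain_id, res_seq, i_code,
#   x, y, z, occupancy, b_factor, element, vdw_radius,
#   pdbqt_type, partial_charge, is_hetero, ss

new_mol_structure <- function(atoms, id = "", helix_ranges = NULL,
                              sheet_ranges = NULL, conect = NULL) {
  out <- tibble::as_tibble(atoms)
  class(out) <- c("mol_structure", class(out))
  attr(out, "id") <- id
  attr(out, "helix_ranges") <- helix_ranges
  attr(out, "sheet_ranges") <- sheet_ranges
  attr(out, "conect") <- conect
  out
}

fixed_num <- function(lines, from, to) {
  suppressWarnings(as.numeric(trimws(substr(lines, from, to))))
}
fixed_int <- function(lines, from, to) {
  suppressWarnings(as.integer(trimws(substr(lines, from, to))))
}

# parse a vector of ATOM/HETATM lines (wwPDB v3.3 columns); pdbqt adds
# partial charge (cols 67-76) and AutoDock atom type (cols 78-79)
parse_atom_lines <- function(lines, pdbqt = FALSE) {
  rec <- substr(lines, 1, 6)
  ok <- nchar(lines) >= 54
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    msg_warn(sprintf("skipped %d malformed atom record(s) shorter than the mandatory columns", n_bad),
             "malformed_record")
    lines <- lines[ok]
    rec <- rec[ok]
  }
  if (length(lines) == 0) {
    return(tibble::tibble(
      serial = integer(), name = character(), alt_loc = character(),
      res_name = character(), chain_id = character(), res_seq = integer(),
      i_code = character(), x = double(), y = double(), z = double(),
      occupancy = double(), b_factor = double(), element = character(),
      vdw_radius = double(), pdbqt_type = character(),
      partial_charge = double(), is_hetero = logical()
    ))
  }
  # pad so substr beyond the physical end yields blanks, not errors
  lines <- formatC(lines, width = -max(80, max(nchar(lines))))
  occ <- fixed_num(lines, 55, 60)
  bf <- fixed_num(lines, 61, 66)
  tibble::tibble(
    serial = fixed_int(lines, 7, 11),
    name = trimws(substr(lines, 13, 16)),
    alt_loc = substr(lines, 17, 17),
    res_name = trimws(substr(lines, 18, 20)),
    chain_id = substr(lines, 22, 22),
    res_seq = fixed_int(lines, 23, 26),
    i_code = substr(lines, 27, 27),
    x = fixed_num(lines, 31, 38),
    y = fixed_num(lines, 39, 46),
    z = fixed_num(lines, 47, 54),
    occupancy = ifelse(is.na(occ), 1, occ),
    b_factor = ifelse(is.na(bf), 0, bf),
    element = if (pdbqt) "" else trimws(substr(lines, 77, 78)),
    vdw_radius = NA_real_,
    pdbqt_type = if (pdbqt) trimws(substr(lines, 78, 79)) else NA_character_,
    partial_charge = if (pdbqt) fixed_num(lines, 67, 76) else NA_real_,
    is_hetero = trimws(rec) == "HETATM"
  )
}

parse_ss_records <- function(lines) {
  helix <- lines[startsWith(lines, "HELIX")]
  sheet <- lines[startsWith(lines, "SHEET")]
  hr <- NULL
  if (length(helix) > 0) {
    hr <- tibble::tibble(
      chain = substr(helix, 20, 20),
      from = fixed_int(helix, 22, 25),
      to = fixed_int(helix, 34, 37)
    )
  }
  sr <- NULL
  if (length(sheet) > 0) {
    sr <- tibble::tibble(
      chain = substr(sheet, 22, 22),
      from = fixed_int(sheet, 23, 26),
      to = fixed_int(sheet, 34, 37)
    )
  }
  list(helix = hr, sheet = sr)
}

parse_conect <- function(lines) {
  con <- lines[startsWith(lines, "CONECT")]
  if (length(con) == 0) return(NULL)
  pairs <- list()
  for (ln in con) {
    base <- fixed_int(ln, 7, 11)
    if (is.na(base)) next
    partners <- c(fixed_int(ln, 12, 16), fixed_int(ln, 17, 21),
                  fixed_int(ln, 22, 26), fixed_int(ln, 27, 31))
    partners <- partners[!is.na(partners)]
    if (length(partners) > 0) {
      pairs[[length(pairs) + 1]] <- cbind(base, partners)
    }
  }
  if (length(pairs) == 0) return(NULL)
  m <- do.call(rbind, pairs)
  colnames(m) <- c("serial_i", "serial_j")
  unique(t(apply(m, 1, sort)))
}

#' Parse PDB text into a structure
#'
#' Reads ATOM/HETATM records (wwPDB format v3.3 columns) into a tidy atom
#' table, keeping only the first MODEL of a multi-model (e.g. NMR) file and
#' alternate locations ' ' or 'A'. HELIX/SHEET records drive secondary
#' structure assignment; CONECT records are retained for bond derivation.
#' Elements and van der Waals radii are assigned on the way out.
#'
#' @param text A single string or character vector of PDB lines.
#' @param id Optional structure identifier.
#' @return A `mol_structure`: a tibble with one row per atom.
#' @examples
#' s <- parse_pdb(synth_pdb("diatomic", separation = 3.4))
#' nrow(s)
#' @export
parse_pdb <- function(text, id = "") {
  lines <- split_text(text)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    msg_abort("empty input: no PDB records", "empty_input")
  }
  # multi-model: keep MODEL 1 only
  model_idx <- which(startsWith(lines, "MODEL"))
  atom_region <- lines
  if (length(model_idx) > 0) {
    endmdl <- which(startsWith(lines, "ENDMDL"))
    stop_at <- if (length(endmdl) > 0) endmdl[1] else length(lines)
    keep <- lines[seq(model_idx[1], stop_at)]
    header <- lines[seq_len(model_idx[1] - 1)]
    atom_region <- c(header, keep)
  }
  is_atom <- startsWith(atom_region, "ATOM") | startsWith(atom_region, "HETATM")
  if (!any(is_atom)) {
    msg_abort("empty input: no ATOM/HETATM records", "empty_input")
  }
  atoms <- parse_atom_lines(atom_region[is_atom], pdbqt = FALSE)
  atoms <- dplyr::filter(atoms, .data$alt_loc %in% c(" ", "A", ""))
  if (nrow(atoms) == 0) {
    msg_abort("no atom records survived parsing", "malformed_record")
  }
  ss <- parse_ss_records(lines)
  s <- new_mol_structure(atoms, id = id,
                         helix_ranges = ss$helix, sheet_ranges = ss$sheet,
                         conect = parse_conect(lines))
  s <- assign_elements_and_radii(s)
  assign_secondary_structure(s)
}

#' Read a PDB file
#' @param path Path to a PDB file.
#' @param id Structure identifier; defaults to the file name.
#' @return A `mol_structure`.
#' @export
read_pdb <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  parse_pdb(readLines(path, warn = FALSE), id = id)
}

split_text <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
}

# first REMARK line carrying a recognizable energy token
extract_remark_energy <- function(lines) {
  remarks <- lines[startsWith(lines, "REMARK")]
  pat <- "(?i)(FREE ENERGY|BINDING AFFINITY|AFFINITY|RESULT|ENERGY|SCORE)[^-+0-9]*([-+]?[0-9]+\\.?[0-9]*)"
  for (ln in remarks) {
    m <- regmatches(ln, regexec(pat, ln, perl = TRUE))[[1]]
    if (length(m) == 3) {
      return(list(energy = as.numeric(m[3]), source = trimws(ln)))
    }
  }
  list(energy = NA_real_, source = NA_character_)
}

#' Parse PDBQT text into a docked ensemble
#'
#' Reads the AutoDock-family PDBQT dialect: one ligand conformation per
#' MODEL/ENDMDL block (the whole file is a single model when no MODEL lines
#' are present), partial charges (columns 67-76) and AutoDock atom types
#' (columns 78-79) from the extended columns, and a per-model energy from
#' the first REMARK line carrying a recognizable energy token (recorded in
#' the `energy_source` attribute). ROOT/BRANCH/TORSDOF torsion-tree lines
#' are tolerated and ignored.
#'
#' @param text A single string or character vector of PDBQT lines.
#' @param id Optional identifier.
#' @return A `docked_ensemble`: list with `models` (list of
#'   `mol_structure`) and `energies` (numeric, `NA` where absent).
#' @export
parse_pdbqt <- function(text, id = "") {
  lines <- split_text(text)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    msg_abort("empty input: no PDBQT records", "empty_input")
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  blocks <- if (length(model_starts) == 0) {
    list(lines)
  } else {
    ends <- which(startsWith(lines, "ENDMDL"))
    purrr::map(seq_along(model_starts), function(i) {
      stop_at <- ends[ends > model_starts[i]]
      stop_at <- if (length(stop_at) > 0) stop_at[1] else length(lines)
      lines[seq(model_starts[i], stop_at)]
    })
  }
  models <- list()
  energies <- numeric(0)
  sources <- character(0)
  for (b in blocks) {
    is_atom <- startsWith(b, "ATOM") | startsWith(b, "HETATM")
    if (!any(is_atom)) next
    atoms <- parse_atom_lines(b[is_atom], pdbqt = TRUE)
    if (nrow(atoms) == 0) next
    m <- new_mol_structure(atoms, id = id)
    m$ss <- rep("coil", nrow(m))
    m <- assign_elements_and_radii(m)
    e <- extract_remark_energy(b)
    models[[length(models) + 1]] <- m
    energies <- c(energies, e$energy)
    sources <- c(sources, e$source)
  }
  if (length(models) == 0) {
    msg_abort("empty input: no ATOM/HETATM records in any model", "empty_input")
  }
  ref_names <- models[[1]]$name
  for (m in models) {
    if (nrow(m) != length(ref_names) || !identical(m$name, ref_names)) {
      msg_abort("inconsistent models: atom count or atom order differs across MODEL blocks",
                "inconsistent_models")
    }
  }
  structure(
    list(models = models, energies = energies, id = id),
    energy_source = sources,
    class = "docked_ensemble"
  )
}

#' Read a PDBQT file
#' @param path Path to a PDBQT file.
#' @param id Identifier; defaults to the file name.
#' @return A `docked_ensemble`.
#' @export
read_pdbqt <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  parse_pdbqt(readLines(path, warn = FALSE), id = id)
}

#' Assign secondary structure from HELIX/SHEET records
#'
#' Residues covered by a HELIX record are flagged `helix`, by a SHEET
#' record `sheet`, all others `coil`. Records referencing residues absent
#' from the structure are ignored with a warning.
#'
#' @param s A `mol_structure`.
#' @param helix_ranges,sheet_ranges Optional tibbles with columns
#'   `chain`, `from`, `to`; default to the ranges parsed from the file.
#' @return `s` with an `ss` column in `{helix, sheet, coil}`.
#' @export
assign_secondary_structure <- function(s, helix_ranges = NULL,
                                       sheet_ranges = NULL) {
  helix_ranges <- helix_ranges %||% attr(s, "helix_ranges")
  sheet_ranges <- sheet_ranges %||% attr(s, "sheet_ranges")
  ss <- rep("coil", nrow(s))
  apply_ranges <- function(ranges, label) {
    if (is.null(ranges)) return(invisible())
    for (i in seq_len(nrow(ranges))) {
      hit <- s$chain_id == ranges$chain[i] &
        s$res_seq >= ranges$from[i] & s$res_seq <= ranges$to[i] &
        !s$is_hetero
      if (!any(hit)) {
        msg_warn(sprintf("%s record %s %d-%d matches no residues; ignored",
                         toupper(label), ranges$chain[i],
                         ranges$from[i], ranges$to[i]),
                 "ss_out_of_range")
      } else {
        ss[hit] <<- label
      }
    }
  }
  apply_ranges(helix_ranges, "helix")
  apply_ranges(sheet_ranges, "sheet")
  s$ss <- ss
  s
}

#' Count distinct polymer chains
#'
#' @param s A `mol_structure`.
#' @return Number of distinct chain identifiers carrying non-HETATM atoms.
#' @export
n_polymer_chains <- function(s) {
  atoms <- as_atom_table(s)
  length(unique(atoms$chain_id[!atoms$is_hetero]))
}

#' @export
print.mol_structure <- function(x, ...) {
  if (all(c("chain_id", "res_seq", "i_code") %in% names(x))) {
    cat(sprintf("<mol_structure> %s: %d atoms, %d chain(s), %d residue(s)\n",
                attr(x, "id") %||% "", nrow(x),
                length(unique(x$chain_id)),
                nrow(dplyr::distinct(tibble::as_tibble(x),
                                     .data$chain_id, .data$res_seq,
                                     .data$i_code))))
  }
  NextMethod()
}

#' @export
print.docked_ensemble <- function(x, ...) {
  cat(sprintf("<docked_ensemble> %s: %d model(s), %d atoms each\n",
              x$id, length(x$models), nrow(x$models[[1]])))
  if (any(!is.na(x$energies))) {
    cat("energies (kcal/mol):", paste(format(x$energies), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname parse_pdbqt
#' @param x A `docked_ensemble`.
#' @param ... Unused.
#' @export
glance.docked_ensemble <- function(x, ...) {
  tibble::tibble(
    model = seq_along(x$models),
    energy = x$energies,
    n_atoms = vapply(x$models, nrow, integer(1))
  )
}

#' @export
tidy.mol_structure <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "mol_structure")
  out
}

#' @export
tidy.docked_ensemble <- function(x, ...) {
  dplyr::bind_rows(
    purrr::imap(x$models, function(m, i) {
      dplyr::mutate(tibble::as_tibble(m), model = i, .before = 1)
    })
  )
}
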