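# Reading, writing and annotating protein structures (PDB format).
#
# Structures are plain S3 objects: a data frame of atoms plus an identifier.
# Coordinates are Angstroms throughout; no unit conversion anywhere.

#' Construct a protein structure object
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z`,
#'   `residue_name`, `residue_number`, `chain_id`, `is_hetero`; an
#'   `is_hydrophobic` column is added (all `NA`) when absent.
#' @param identifier free-text label, e.g. a PDB id.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, identifier = "") {
  required <- c("element", "x", "y", "z", "residue_name", "residue_number",
                "chain_id", "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (!"is_hydrophobic" %in% names(atoms)) atoms$is_hydrophobic <- NA
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, identifier = identifier),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure '%s': %d atoms, %d residues, %d chain(s)>\n",
              x$identifier, nrow(x$atoms),
              length(unique(residue_keys(x))),
              length(unique(x$atoms$chain_id))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `protein_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Residue keys (chain:number:name) for each atom
#' @param structure a `protein_structure`.
#' @return Character vector, one key per atom.
#' @export
residue_keys <- function(structure) {
  with(structure$atoms, paste(chain_id, residue_number, residue_name, sep = ":"))
}

# Element from PDB columns; fall back to the atom-name convention
# (first non-digit character of the left-justified name).
.guess_element <- function(element_field, atom_name) {
  el <- toupper(trimws(element_field))
  fallback <- toupper(sub("^[0-9 ]*([A-Za-z]).*$", "\\1", atom_name))
  el[el == ""] <- fallback[el == ""]
  el
}

#' Read a protein structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (wwPDB v3.3). Alternate locations
#' are resolved to the highest-occupancy conformer (ties broken by altLoc
#' label order); hydrogens are dropped; with `strip_cofactors = TRUE` all
#' HETATM records (waters included) are removed so the protein is isolated.
#'
#' @param path path to a PDB-format text file.
#' @param strip_cofactors drop HETATM records (default `TRUE`).
#' @param chains optional character vector restricting to these chain ids.
#' @param identifier label for the structure; defaults to the file name.
#' @return A `protein_structure` with hydrophobic flags already assigned
#'   (see [flag_hydrophobic_atoms()]).
#' @export
read_structure <- function(path, strip_cofactors = TRUE, chains = NULL,
                           identifier = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  rec <- rec[keep]
  if (length(lines) == 0) stop("no ATOM/HETATM records in ", path)

  atoms <- data.frame(
    record = trimws(rec),
    atom_name = substr(lines, 13, 16),
    altloc = substr(lines, 17, 17),
    residue_name = trimws(substr(lines, 18, 20)),
    chain_id = substr(lines, 22, 22),
    residue_number = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$element <- .guess_element(substr(lines, 77, 78), atoms$atom_name)
  atoms$is_hetero <- atoms$record == "HETATM"

  if (!is.null(chains)) atoms <- atoms[atoms$chain_id %in% chains, ]
  atoms <- atoms[atoms$element != "H", ]
  if (strip_cofactors) atoms <- atoms[!atoms$is_hetero, ]
  if (nrow(atoms) == 0) stop("structure is empty after stripping: ", path)

  # altloc resolution: within (chain, residue, atom name) keep the highest
  # occupancy; ties broken by altLoc label order (PDB convention).
  key <- with(atoms, paste(chain_id, residue_number, residue_name,
                           trimws(atom_name), sep = "|"))
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(key[ord]), ]
  atoms <- atoms[order(as.integer(rownames(atoms))), ]

  atoms$record <- NULL
  s <- protein_structure(
    atoms[, c("element", "x", "y", "z", "residue_name", "residue_number",
              "chain_id", "is_hetero", "atom_name", "altloc", "occupancy")],
    identifier = if (is.null(identifier)) basename(path) else identifier
  )
  flag_hydrophobic_atoms(s)
}

#' Write a structure to a PDB file
#'
#' Coordinates are written at PDB precision (3 decimals), so a write/read
#' round trip reproduces them to 0.001 Angstrom.
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  name <- if ("atom_name" %in% names(a)) a$atom_name else sprintf(" %-3s", a$element)
  rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
  lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)) %% 100000, substr(name, 1, 4), " ",
                   a$residue_name, a$chain_id, a$residue_number,
                   a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Flag hydrophobic atoms
#'
#' Coarse element rule: carbon and sulfur are hydrophobic; N, O, P, halogens
#' and metals are not. The flag depends only on element identity, so it is
#' deterministic and invariant under atom reordering.
#'
#' @param structure a `protein_structure`.
#' @return The structure with `is_hydrophobic` set on every atom.
#' @export
flag_hydrophobic_atoms <- function(structure) {
  structure$atoms$is_hydrophobic <- structure$atoms$element %in% c("C", "S")
  structure
}

#' Remove cofactor (HETATM) atoms from a structure
#'
#' Idempotent: stripping twice equals stripping once.
#'
#' @param structure a `protein_structure`.
#' @return The structure with hetero atoms removed.
#' @export
strip_cofactors <- function(structure) {
  structure$atoms <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  if (nrow(structure$atoms) == 0) stop("structure is empty after stripping")
  rownames(structure$atoms) <- NULL
  structure
}

# van der Waals radii (Angstrom) used for occupancy, SASA and ray casting.
# Bondi-style values; unknown elements fall back to carbon.
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
          F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

#' van der Waals radius lookup
#' @param element character vector of element symbols.
#' @return Numeric radii in Angstroms (carbon radius for unknown elements).
#' @export
vdw_radius <- function(element) {
  r <- .VDW[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# coordinate matrix helper used throughout
.coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}
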