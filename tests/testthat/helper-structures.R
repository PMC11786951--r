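# Small builders shared across test files.

toy_structure <- function(elements, coords, residue_number = seq_along(elements),
                          identifier = "toy") {
  flag_hydrophobic_atoms(protein_structure(
    data.frame(element = elements,
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               residue_name = "GLY", residue_number = residue_number,
               chain_id = "A", is_hetero = FALSE, stringsAsFactors = FALSE),
    identifier = identifier
  ))
}

# a bare pocket object with given surface points, for shell-geometry tests
fake_pocket <- function(surface_points) {
  p <- list(id = 1L, cells = seq_len(nrow(surface_points)),
            surface_points = surface_points, volume = 0,
            grid = list(origin = c(0, 0, 0), dim = c(1L, 1L, 1L), spacing = 1))
  class(p) <- "pocket"
  p
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, element, x, y, z, res = "GLY", resno = 1,
                          chain = "A", record = "ATOM  ", occ = 1,
                          altloc = " ", name = NULL) {
  if (is.null(name)) name <- sprintf(" %-3s", element)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, res, chain, resno, x, y, z, occ, 0,
          element)
}

# cached default engineered cavity + its pipeline products (expensive)
cavity_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- make_cavity_structure(inner_radius = 6, mouth_aperture = 0,
                                 lining_composition = 1, seed = 1)
      pockets <- find_pockets(s)
      shell <- assign_shell(pockets[[1]], s)
      cache <<- list(structure = s, pockets = pockets, shell = shell)
    }
    cache
  }
})
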