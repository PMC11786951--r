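# Seeded generators for every input the pipeline consumes: engineered-cavity
# pseudo-structures, per-target raw score tables, docking tables with planted
# structure, and the packaged study-table fixtures.
#
# Every generator is a pure function of its seed: the RNG state is set
# locally and restored, so callers' random streams are untouched.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Engineered hollow-cavity pseudo-structure
#'
#' Builds a hollow sphere of pseudo-atoms: concentric Fibonacci-lattice
#' layers from `inner_radius + r_atom` outward, so the enclosed cavity has
#' radius `inner_radius` up to packing gaps. A spherical cap subtending the
#' given solid-angle fraction around +z is removed to open a mouth. Lining
#' atoms are carbon (hydrophobic) with probability `lining_composition`,
#' oxygen otherwise, drawn from the seed; every atom is its own residue so
#' the pocket shell is exactly the lining.
#'
#' @param inner_radius cavity radius in Angstroms (> probe radius 1.4).
#' @param shell_thickness radial extent of the atom shell in Angstroms.
#' @param mouth_aperture solid-angle fraction in \[0, 1\] removed around +z
#'   (0 = fully closed).
#' @param lining_composition fraction of hydrophobic (carbon) atoms.
#' @param seed integer seed for the lining draw.
#' @param layer_step radial distance between atom layers (default 2).
#' @param atom_area surface area per atom on each layer, square Angstroms
#'   (default 3; smaller = denser packing).
#' @return A `protein_structure` with hydrophobic flags set. Deterministic
#'   given the seed.
#' @export
make_cavity_structure <- function(inner_radius = 6, shell_thickness = 4.5,
                                  mouth_aperture = 0, lining_composition = 1,
                                  seed = 1, layer_step = 2, atom_area = 3) {
  if (inner_radius <= 1.4) stop("inner_radius must exceed the 1.4 A probe")
  if (shell_thickness <= 0) stop("shell_thickness must be positive")
  if (mouth_aperture < 0 || mouth_aperture > 1) {
    stop("mouth_aperture must be a solid-angle fraction in [0, 1]")
  }
  if (lining_composition < 0 || lining_composition > 1) {
    stop("lining_composition must be in [0, 1]")
  }
  r_atom <- 1.7
  layer_r <- seq(inner_radius + r_atom,
                 inner_radius + r_atom + shell_thickness, by = layer_step)
  pts <- do.call(rbind, lapply(layer_r, function(r) {
    n <- max(12L, as.integer(ceiling(4 * pi * r^2 / atom_area)))
    .unit_sphere(n) * r
  }))
  # open the mouth: drop atoms inside the spherical cap around +z
  if (mouth_aperture > 0) {
    cos_cap <- 1 - 2 * mouth_aperture
    pts <- pts[pts[, 3] / sqrt(rowSums(pts^2)) < cos_cap, , drop = FALSE]
  }
  n <- nrow(pts)
  element <- .with_seed(seed, {
    ifelse(stats::runif(n) < lining_composition, "C", "O")
  })
  atoms <- data.frame(
    element = element, x = pts[, 1], y = pts[, 2], z = pts[, 3],
    residue_name = "CAV", residue_number = seq_len(n), chain_id = "A",
    is_hetero = FALSE, stringsAsFactors = FALSE
  )
  flag_hydrophobic_atoms(protein_structure(
    atoms,
    identifier = sprintf("cavity_r%.1f_ap%.3f_seed%d",
                         inner_radius, mouth_aperture, seed)
  ))
}

#' Ideal helix pseudo-structure (no cavity)
#'
#' An ideal alpha-helical backbone tube (2.3 A helix radius, 1.5 A rise and
#' 100 degrees per residue, with pseudo-atoms interpolated densely along the
#' backbone curve so the surface is smooth): an open surface with no
#' enclosed region, useful as a zero-pocket control.
#'
#' @param n_res number of residues (default 20).
#' @param atoms_per_res pseudo-atoms interpolated per residue (default 4).
#' @return A `protein_structure`.
#' @export
make_helix_structure <- function(n_res = 20, atoms_per_res = 4) {
  n <- n_res * atoms_per_res
  t <- seq_len(n) / atoms_per_res
  theta <- t * 100 * pi / 180
  # backbone tube, an axial core rod, and a side-chain ridge z-shifted into
  # the inter-turn groove: emulates the solid surface of a real helix, whose
  # backbone fills the core and whose side chains fill the groove (a bare
  # C-alpha tube would leave spurious spiral voids).
  zc <- seq(0, 1.5 * n_res + 2.7, by = 1.5)
  atoms <- data.frame(
    element = "C",
    x = c(2.3 * cos(theta), 3.6 * cos(theta), rep(0, length(zc))),
    y = c(2.3 * sin(theta), 3.6 * sin(theta), rep(0, length(zc))),
    z = c(1.5 * t, 1.5 * t + 2.7, zc),
    residue_name = "ALA",
    residue_number = c(ceiling(t), ceiling(t), n_res + seq_along(zc)),
    chain_id = "A", is_hetero = FALSE, stringsAsFactors = FALSE
  )
  flag_hydrophobic_atoms(protein_structure(atoms, identifier = "ideal_helix"))
}

#' Combine two structures into one
#'
#' Concatenates the atom tables, relabelling the second structure's chains
#' so residue keys stay disjoint.
#'
#' @param a,b `protein_structure` objects.
#' @param offset optional 3-vector added to `b`'s coordinates.
#' @return A `protein_structure`.
#' @export
combine_structures <- function(a, b, offset = c(0, 0, 0)) {
  bb <- b$atoms
  bb$x <- bb$x + offset[1]
  bb$y <- bb$y + offset[2]
  bb$z <- bb$z + offset[3]
  bb$chain_id <- paste0(bb$chain_id, "2")
  common <- intersect(names(a$atoms), names(bb))
  protein_structure(rbind(a$atoms[, common], bb[, common]),
                    identifier = paste(a$identifier, b$identifier, sep = "+"))
}

#' Synthetic per-target raw score table
#'
#' Raw scores drawn uniformly over the ranges the study observed: DLID in
#' \[-1.5, 2.1\], DScore in \[0.38, 1.24\], SPIDER possibility in
#' \[0.085, 0.089\]. Missing cells are planted at the stated rate (rounded
#' to a whole number of cells, sampled without replacement).
#'
#' @param n_targets number of targets (>= 2).
#' @param missing_fraction fraction of the `3 * n_targets` score cells set
#'   to `NA`.
#' @param seed integer seed.
#' @return Data frame with columns `target`, `dlid_raw`, `spider_raw`,
#'   `dscore_raw`.
#' @export
make_score_table <- function(n_targets, missing_fraction = 0, seed = 1) {
  if (n_targets < 2) stop("need at least two targets")
  .with_seed(seed, {
    out <- data.frame(
      target = sprintf("T%02d", seq_len(n_targets)),
      dlid_raw = stats::runif(n_targets, -1.5, 2.1),
      spider_raw = stats::runif(n_targets, 0.085, 0.089),
      dscore_raw = stats::runif(n_targets, 0.38, 1.24),
      stringsAsFactors = FALSE
    )
    n_missing <- round(missing_fraction * n_targets * 3)
    if (n_missing > 0) {
      cells <- sample(n_targets * 3, n_missing)
      for (cell in cells) {
        out[(cell - 1) %% n_targets + 1, (cell - 1) %/% n_targets + 2] <- NA
      }
    }
    out
  })
}

#' Synthetic docking tables with planted structure
#'
#' Each target gets its own decoy library (`<target>_m001`, ...), so no
#' background molecule ever appears on two targets. Background scores are
#' uniform in \[-19.5, -10.5\] (centered near -15, never reaching the -20
#' kcal/mol hit threshold); a `hit_fraction` of each target's molecules is
#' given a hit-tail score in \[-35, -20.05\]. `planted_shared` extra
#' molecules (ids `s01`, `s02`, ...) are inserted into exactly two targets
#' each with scores below -36, which puts them in both targets' top 10 — so
#' the shared-molecule list equals the planted set by construction.
#'
#' @param n_targets number of targets (>= 2 when planting shared molecules).
#' @param n_molecules library size per target.
#' @param planted_shared number of molecules shared across two targets'
#'   top-10 by construction.
#' @param hit_fraction fraction of library molecules per target scoring
#'   below the -20 threshold.
#' @param seed integer seed.
#' @return Data frame of docking records (`target`, `molecule`, `score`).
#' @export
make_docking_tables <- function(n_targets = 5, n_molecules = 50,
                                planted_shared = 0, hit_fraction = 0.2,
                                seed = 1) {
  if (planted_shared > n_molecules) stop("planted_shared exceeds library size")
  if (planted_shared > 0 && n_targets < 2) {
    stop("need at least two targets to plant shared molecules")
  }
  .with_seed(seed, {
    targets <- sprintf("TGT%02d", seq_len(n_targets))
    recs <- do.call(rbind, lapply(targets, function(t) {
      score <- stats::runif(n_molecules, -19.5, -10.5)
      n_hits <- round(hit_fraction * n_molecules)
      if (n_hits > 0) {
        hit_idx <- sample(n_molecules, n_hits)
        score[hit_idx] <- stats::runif(n_hits, -35, -20.05)
      }
      data.frame(target = t,
                 molecule = sprintf("%s_m%03d", t, seq_len(n_molecules)),
                 score = score, stringsAsFactors = FALSE)
    }))
    if (planted_shared > 0) {
      for (s in seq_len(planted_shared)) {
        pair <- sample(targets, 2)
        recs <- rbind(recs, data.frame(
          target = pair, molecule = sprintf("s%02d", s),
          score = stats::runif(2, -45, -36), stringsAsFactors = FALSE
        ))
      }
    }
    rownames(recs) <- NULL
    recs
  })
}

.FIXTURES <- paste0("table", 1:8)

#' Load a packaged study-table fixture
#'
#' Machine-readable copies of the study's printed tables: `table1` (pocket
#' counts and top DLID descriptors per target), `table2` (top SiteMap
#' DScore/SiteScore/volume/balance per target; the C5 row is missing),
#' `table3` (normalized DLID/SPIDER/SiteMap scores and composite for the 23
#' complete targets), `table4`..`table8` (top docking records for DRD2, C4b,
#' GABA-A-R, C9 and C5AR1). Values are verbatim from print; identifiers are
#' normalized to one canonical spelling per target/molecule.
#'
#' @param name one of `"table1"` ... `"table8"`.
#' @return Data frame.
#' @export
load_fixture <- function(name) {
  if (!name %in% .FIXTURES) {
    stop("unknown fixture '", name, "'; available: ",
         paste(.FIXTURES, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "pocketrank",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
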