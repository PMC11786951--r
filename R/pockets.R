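# Grid-based cavity detection and pocket descriptors.
#
# A pocket is a connected set of grid cells that lie outside every atom's van
# der Waals sphere but cannot be reached by a solvent probe rolling in from
# the box boundary. Surface points are centers of cavity cells adjacent to a
# protein-occupied cell; the shell is the residue lining within 3.5 A of any
# surface point.

# --- grid helpers ----------------------------------------------------------

.make_grid <- function(coords, radii, spacing, probe_radius) {
  pad <- max(radii) + probe_radius + 2 * spacing
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  dim <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  list(origin = lo, dim = dim, spacing = spacing)
}

# mark cells whose center lies within radius of any sphere center
.mark_spheres <- function(grid, centers, radii) {
  s <- grid$spacing
  o <- grid$origin
  d <- grid$dim
  occ <- array(FALSE, d)
  for (a in seq_len(nrow(centers))) {
    r <- radii[a]
    c3 <- centers[a, ]
    i0 <- pmax(1L, as.integer(ceiling((c3 - r - o) / s)) + 1L)
    i1 <- pmin(d, as.integer(floor((c3 + r - o) / s)) + 1L)
    if (any(i0 > i1)) next
    dx2 <- (o[1] + (i0[1]:i1[1] - 1) * s - c3[1])^2
    dy2 <- (o[2] + (i0[2]:i1[2] - 1) * s - c3[2])^2
    dz2 <- (o[3] + (i0[3]:i1[3] - 1) * s - c3[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    occ[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
      occ[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] | (d2 <= r^2)
  }
  occ
}

# breadth-first fill over `open` cells (6-neighborhood) from seed indices
.bfs_fill <- function(open, seeds) {
  d <- dim(open)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nxy <- nx * ny
  visited <- array(FALSE, d)
  frontier <- seeds[open[seeds] & !visited[seeds]]
  visited[frontier] <- TRUE
  while (length(frontier) > 0) {
    k0 <- frontier - 1L
    i <- k0 %% nx
    j <- (k0 %/% nx) %% ny
    k <- k0 %/% nxy
    nbrs <- c(frontier[i > 0L] - 1L, frontier[i < nx - 1L] + 1L,
              frontier[j > 0L] - nx, frontier[j < ny - 1L] + nx,
              frontier[k > 0L] - nxy, frontier[k < nz - 1L] + nxy)
    nbrs <- unique(nbrs)
    nbrs <- nbrs[open[nbrs] & !visited[nbrs]]
    visited[nbrs] <- TRUE
    frontier <- nbrs
  }
  visited
}

.boundary_indices <- function(d) {
  b <- array(FALSE, d)
  b[1, , ] <- TRUE; b[d[1], , ] <- TRUE
  b[, 1, ] <- TRUE; b[, d[2], ] <- TRUE
  b[, , 1] <- TRUE; b[, , d[3]] <- TRUE
  which(b)
}

# dilate a logical array by `radius` Angstroms (Euclidean, cell centers)
.dilate <- function(arr, radius, spacing) {
  m <- as.integer(floor(radius / spacing))
  if (m < 1L) return(arr)
  d <- dim(arr)
  out <- arr
  for (di in -m:m) for (dj in -m:m) for (dk in -m:m) {
    if (di == 0 && dj == 0 && dk == 0) next
    if ((di^2 + dj^2 + dk^2) * spacing^2 > radius^2) next
    src_i <- max(1, 1 - di):min(d[1], d[1] - di)
    src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
    src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
    out[src_i + di, src_j + dj, src_k + dk] <-
      out[src_i + di, src_j + dj, src_k + dk] | arr[src_i, src_j, src_k]
  }
  out
}

# connected components (6-neighborhood) of a logical array
.components <- function(mask) {
  remaining <- mask
  comps <- list()
  repeat {
    seed <- which(remaining)[1]
    if (is.na(seed)) break
    vis <- .bfs_fill(remaining, seed)
    comps[[length(comps) + 1L]] <- which(vis)
    remaining <- remaining & !vis
  }
  comps
}

.cell_centers <- function(grid, cells) {
  d <- grid$dim
  k0 <- cells - 1L
  i <- k0 %% d[1]
  j <- (k0 %/% d[1]) %% d[2]
  k <- k0 %/% (d[1] * d[2])
  cbind(grid$origin[1] + i * grid$spacing,
        grid$origin[2] + j * grid$spacing,
        grid$origin[3] + k * grid$spacing)
}

# squared Euclidean distances between two point matrices
.dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# --- pocket detection ------------------------------------------------------

#' Detect cavities on a protein structure
#'
#' Cavity criterion: grid cells outside all van der Waals spheres that a
#' solvent probe rolling in from the box boundary cannot reach. The probe
#' flood runs over cells with clearance `vdW + probe_radius` from every atom;
#' the reached region is then dilated by the probe radius so that the thin
#' free-space layer hugging the outer protein surface counts as bulk solvent.
#' What remains is split into 6-connected components; components smaller than
#' `min_volume` are discarded and the rest returned by decreasing volume.
#'
#' @param structure a `protein_structure` with at least 4 atoms.
#' @param grid_spacing grid cell edge in Angstroms (default 0.8).
#' @param probe_radius solvent probe radius in Angstroms (default 1.4).
#' @param min_volume smallest cavity volume kept, cubic Angstroms (default 100).
#' @return List of `pocket` objects ordered by decreasing volume. Each carries
#'   `cells` (grid indices), `surface_points` (n x 3 matrix), `volume`
#'   (`length(cells) * grid_spacing^3`, exactly) and the grid geometry.
#' @export
find_pockets <- function(structure, grid_spacing = 0.8, probe_radius = 1.4,
                         min_volume = 100) {
  if (n_atoms(structure) < 4) {
    stop("degenerate input: need at least 4 atoms to define a cavity")
  }
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  coords <- .coords(structure)
  radii <- vdw_radius(structure$atoms$element)
  grid <- .make_grid(coords, radii, grid_spacing, probe_radius)

  occ_vdw <- .mark_spheres(grid, coords, radii)
  occ_probe <- .mark_spheres(grid, coords, radii + probe_radius)
  reached <- .bfs_fill(!occ_probe, .boundary_indices(grid$dim))
  solvent <- .dilate(reached, probe_radius, grid_spacing)
  cavity <- !occ_vdw & !solvent

  comps <- .components(cavity)
  vols <- vapply(comps, function(cc) length(cc) * grid_spacing^3, numeric(1))
  keep <- vols >= min_volume
  comps <- comps[keep]
  vols <- vols[keep]
  ord <- order(-vols)

  # surface cells: cavity cells 6-adjacent to a vdW-occupied cell
  lapply(seq_along(ord), function(r) {
    cc <- comps[[ord[r]]]
    surf <- cc[.is_surface_cell(cc, occ_vdw, grid$dim)]
    p <- list(
      id = r,
      cells = cc,
      surface_points = .cell_centers(grid, surf),
      volume = vols[ord[r]],
      grid = grid
    )
    class(p) <- "pocket"
    p
  })
}

.is_surface_cell <- function(cells, occ_vdw, d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nxy <- nx * ny
  k0 <- cells - 1L
  i <- k0 %% nx
  j <- (k0 %/% nx) %% ny
  k <- k0 %/% nxy
  surf <- rep(FALSE, length(cells))
  probe <- function(sel, off) {
    surf[sel] <<- surf[sel] | occ_vdw[cells[sel] + off]
  }
  probe(i > 0L, -1L); probe(i < nx - 1L, +1L)
  probe(j > 0L, -nx); probe(j < ny - 1L, +nx)
  probe(k > 0L, -nxy); probe(k < nz - 1L, +nxy)
  surf
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket %d: volume %.1f A^3, %d cells, %d surface points>\n",
              x$id, x$volume, length(x$cells), nrow(x$surface_points)))
  invisible(x)
}

# --- shell and descriptors -------------------------------------------------

#' Assign the residue shell of a pocket
#'
#' The shell is exactly the set of residues having at least one atom within
#' `cutoff` of at least one pocket surface point.
#'
#' @param pocket a `pocket` from [find_pockets()].
#' @param structure the `protein_structure` the pocket was detected on.
#' @param cutoff shell distance in Angstroms (default 3.5).
#' @return Character vector of residue keys (`chain:number:name`).
#' @export
assign_shell <- function(pocket, structure, cutoff = 3.5) {
  if (nrow(pocket$surface_points) == 0) {
    warning("pocket has no surface points; shell is empty")
    return(character(0))
  }
  d2 <- .dist2(.coords(structure), pocket$surface_points)
  near <- apply(d2, 1, min) <= cutoff^2
  sort(unique(residue_keys(structure)[near]))
}

.shell_atom_idx <- function(structure, shell) {
  which(residue_keys(structure) %in% shell)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral point set on each atom's expanded sphere
#' (radius vdW + probe); a point is accessible when outside every other
#' atom's expanded sphere. Per-atom area is the accessible fraction of
#' `4*pi*(r+probe)^2`.
#'
#' @param structure a `protein_structure`.
#' @param probe_radius probe radius in Angstroms (default 1.4).
#' @param n_points sphere points per atom (default 960).
#' @param subset optional integer vector: report areas only for these atoms
#'   (occlusion still uses the whole structure).
#' @return Numeric vector of per-atom areas in square Angstroms.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960, subset = NULL) {
  coords <- .coords(structure)
  radii <- vdw_radius(structure$atoms$element)
  n <- nrow(coords)
  if (is.null(subset)) subset <- seq_len(n)
  pts <- .unit_sphere(n_points)
  ext <- radii + probe_radius
  d2all <- .dist2(coords, coords)
  areas <- numeric(length(subset))
  for (ii in seq_along(subset)) {
    i <- subset[ii]
    nbr <- which(d2all[i, ] < (ext[i] + ext)^2 & seq_len(n) != i)
    p <- sweep(pts * ext[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(acc)) break
      dj <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      acc <- acc & (dj > ext[j]^2)
    }
    areas[ii] <- 4 * pi * ext[i]^2 * sum(acc) / n_points
  }
  areas
}

.unit_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Pocket buriedness
#'
#' One minus the ratio of the shell atoms' solvent-accessible surface area in
#' the full structure to their area when extracted in isolation, clamped to
#' \[0, 1\]. A fully exposed shell scores 0, a fully occluded one 1.
#'
#' @param pocket a `pocket`.
#' @param structure the parent `protein_structure`.
#' @param probe_radius probe radius in Angstroms (default 1.4).
#' @param shell optional precomputed shell (residue keys); computed with the
#'   default 3.5 A cutoff when omitted.
#' @return Buriedness fraction in \[0, 1\].
#' @export
compute_buriedness <- function(pocket, structure, probe_radius = 1.4,
                               shell = NULL) {
  if (is.null(shell)) shell <- assign_shell(pocket, structure)
  idx <- .shell_atom_idx(structure, shell)
  if (length(idx) == 0) stop("undefined buriedness: empty shell")
  ctx <- sum(sasa(structure, probe_radius, subset = idx))
  iso_struct <- structure
  iso_struct$atoms <- structure$atoms[idx, , drop = FALSE]
  iso <- sum(sasa(iso_struct, probe_radius))
  if (iso <= 0) stop("undefined buriedness: isolated shell SASA is zero")
  min(1, max(0, 1 - ctx / iso))
}

#' Pocket hydrophobicity
#'
#' Fraction of pocket surface points whose nearest shell atom (within
#' `contact_cutoff`) is hydrophobic.
#'
#' @param pocket a `pocket`.
#' @param structure the parent `protein_structure` (hydrophobic flags set).
#' @param shell optional precomputed shell (residue keys).
#' @param contact_cutoff surface-point/atom contact distance in Angstroms.
#' @return Hydrophobic fraction in \[0, 1\].
#' @export
compute_hydrophobicity <- function(pocket, structure, shell = NULL,
                                   contact_cutoff = 4.5) {
  if (is.null(shell)) shell <- assign_shell(pocket, structure)
  idx <- .shell_atom_idx(structure, shell)
  if (length(idx) == 0 || nrow(pocket$surface_points) == 0) {
    stop("undefined hydrophobicity: no shell contacts")
  }
  d2 <- .dist2(pocket$surface_points, .coords(structure)[idx, , drop = FALSE])
  nearest <- max.col(-d2, ties.method = "first")
  mind <- d2[cbind(seq_len(nrow(d2)), nearest)]
  ok <- mind <= contact_cutoff^2
  if (!any(ok)) stop("undefined hydrophobicity: no shell contacts")
  mean(structure$atoms$is_hydrophobic[idx][nearest[ok]])
}

# Reference density for the hydrophilic/hydrophobic score normalization: the
# mean exponential-falloff (2 A length scale) shell-atom density at the site
# points of a fully polar-lined reference cavity (hollow sphere, 6 A inner
# radius, default construction). Frozen so that such a cavity scores ~1.
.DENSITY_REF <- 9.34

#' SiteMap-style pocket descriptors
#'
#' Computes the descriptors the SiteScore/Dscore formulas consume:
#' * `site_point_count` — pocket grid cells subsampled at `site_spacing`
#'   (uncapped here; the scoring formulas cap at 100);
#' * `enclosure` — mean over site points of the fraction of 64 fixed
#'   quasi-uniform ray directions blocked by a protein atom within
#'   `ray_cutoff`;
#' * `hydrophilic_score` / `hydrophobic_score` — mean exponential-falloff
#'   density (`exp(-d / length_scale)`) of polar / hydrophobic shell atoms
#'   around site points, scaled so a fully polar-lined reference cavity
#'   scores about 1;
#' * `balance` — hydrophobic over hydrophilic score (NA when the
#'   hydrophilic score is 0).
#'
#' All ingredients are deterministic: the ray directions and density sums
#' involve no random number generation, so repeated runs are bit-identical.
#'
#' @param pocket a `pocket`.
#' @param structure the parent `protein_structure`.
#' @param shell optional precomputed shell (residue keys).
#' @param site_spacing site-point lattice spacing in Angstroms (default 1.6).
#' @param n_rays ray directions per site point (default 64).
#' @param ray_cutoff maximum ray length in Angstroms (default 8).
#' @param length_scale density falloff length in Angstroms (default 2).
#' @param buriedness,hydrophobicity optionally precomputed values; computed
#'   from the pocket when `NULL`.
#' @return A list of class `pocket_descriptors` with fields `volume`,
#'   `buriedness`, `hydrophobicity`, `site_point_count`, `enclosure`,
#'   `hydrophilic_score`, `hydrophobic_score`, `balance`.
#' @export
compute_sitemap_descriptors <- function(pocket, structure, shell = NULL,
                                        site_spacing = 1.6, n_rays = 64,
                                        ray_cutoff = 8, length_scale = 2,
                                        buriedness = NULL,
                                        hydrophobicity = NULL) {
  if (length(pocket$cells) == 0) stop("empty pocket")
  if (is.null(shell)) shell <- assign_shell(pocket, structure)
  sp <- .site_points(pocket, site_spacing)
  coords <- .coords(structure)
  radii <- vdw_radius(structure$atoms$element)
  enc <- .enclosure(sp, coords, radii, n_rays, ray_cutoff)

  idx <- .shell_atom_idx(structure, shell)
  if (length(idx) > 0) {
    d <- sqrt(.dist2(sp, coords[idx, , drop = FALSE]))
    w <- exp(-d / length_scale)
    phob <- structure$atoms$is_hydrophobic[idx]
    phil_raw <- mean(rowSums(w[, !phob, drop = FALSE]))
    phob_raw <- mean(rowSums(w[, phob, drop = FALSE]))
  } else {
    phil_raw <- phob_raw <- 0
  }
  phil <- phil_raw / .DENSITY_REF
  phbs <- phob_raw / .DENSITY_REF

  if (is.null(buriedness)) {
    buriedness <- compute_buriedness(pocket, structure, shell = shell)
  }
  if (is.null(hydrophobicity)) {
    hydrophobicity <- compute_hydrophobicity(pocket, structure, shell = shell)
  }
  desc <- list(
    volume = pocket$volume,
    buriedness = buriedness,
    hydrophobicity = hydrophobicity,
    site_point_count = nrow(sp),
    enclosure = enc,
    hydrophilic_score = phil,
    hydrophobic_score = phbs,
    balance = if (phil > 0) phbs / phil else NA_real_
  )
  class(desc) <- "pocket_descriptors"
  desc
}

# site points: cavity cells on a coarser sublattice
.site_points <- function(pocket, site_spacing) {
  grid <- pocket$grid
  stride <- max(1L, as.integer(round(site_spacing / grid$spacing)))
  d <- grid$dim
  k0 <- pocket$cells - 1L
  i <- k0 %% d[1]
  j <- (k0 %/% d[1]) %% d[2]
  k <- k0 %/% (d[1] * d[2])
  keep <- (i %% stride == 0L) & (j %% stride == 0L) & (k %% stride == 0L)
  .cell_centers(grid, pocket$cells[keep])
}

# fraction of rays blocked, averaged over site points
.enclosure <- function(site_points, coords, radii, n_rays, ray_cutoff) {
  if (nrow(site_points) == 0) return(0)
  dirs <- .unit_sphere(n_rays)
  fracs <- numeric(nrow(site_points))
  maxr <- max(radii)
  for (s in seq_len(nrow(site_points))) {
    rel <- sweep(coords, 2, site_points[s, ], "-")
    d2 <- rowSums(rel^2)
    near <- which(d2 <= (ray_cutoff + maxr)^2)
    if (length(near) == 0) { fracs[s] <- 0; next }
    t_ca <- dirs %*% t(rel[near, , drop = FALSE])     # n_rays x n_near
    perp2 <- matrix(d2[near], nrow = n_rays, ncol = length(near),
                    byrow = TRUE) - t_ca^2
    hit <- t_ca > 0 & t_ca <= ray_cutoff &
      perp2 <= matrix(radii[near]^2, nrow = n_rays, ncol = length(near),
                      byrow = TRUE)
    fracs[s] <- mean(rowSums(hit) > 0)
  }
  mean(fracs)
}
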