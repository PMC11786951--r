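# Druggability scoring: drug-like density (DLID) in its regression and
# neighbor-density forms, and the SiteMap-style SiteScore / Dscore weighted
# sums, plus the druggability classifications.
#
# All logarithms here are base 10 (the convention of the DLID literature).

#' DLID, regression form
#'
#' `-8.70 + 1.71*log10(volume) + 3.94*buriedness + 2.27*hydrophobicity`.
#' Doubling the volume raises the score by exactly `1.71*log10(2)`.
#'
#' @param volume pocket volume in cubic Angstroms (> 0).
#' @param buriedness fraction in \[0, 1\].
#' @param hydrophobicity fraction in \[0, 1\].
#' @return DLID score (vectorized over inputs).
#' @export
dlid_regression <- function(volume, buriedness, hydrophobicity) {
  if (any(volume <= 0)) stop("volume must be positive")
  if (any(buriedness < 0 | buriedness > 1)) stop("buriedness must be in [0, 1]")
  if (any(hydrophobicity < 0 | hydrophobicity > 1)) {
    stop("hydrophobicity must be in [0, 1]")
  }
  -8.70 + 1.71 * log10(volume) + 3.94 * buriedness + 2.27 * hydrophobicity
}

#' Reference pocket set for density-form DLID
#'
#' @param volume,buriedness,hydrophobicity numeric vectors of descriptors for
#'   the reference pockets.
#' @param is_dllc logical: does the reference pocket contain a drug-like
#'   ligand (DLLC)?
#' @param neighborhood_radius neighbor radius in z-standardized
#'   `(log10 volume, buriedness, hydrophobicity)` space (default 1).
#' @return An object of class `reference_pocket_set`.
#' @export
reference_pocket_set <- function(volume, buriedness, hydrophobicity, is_dllc,
                                 neighborhood_radius = 1) {
  n <- length(volume)
  if (n < 1) stop("reference set needs at least one entry")
  if (neighborhood_radius <= 0) stop("neighborhood_radius must be positive")
  stopifnot(length(buriedness) == n, length(hydrophobicity) == n,
            length(is_dllc) == n)
  feat <- cbind(log10(volume), buriedness, hydrophobicity)
  mu <- colMeans(feat)
  sdv <- apply(feat, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1  # degenerate column: no scaling
  ref <- list(features = sweep(sweep(feat, 2, mu), 2, sdv, "/"),
              center = mu, scale = sdv,
              is_dllc = as.logical(is_dllc),
              neighborhood_radius = neighborhood_radius)
  class(ref) <- "reference_pocket_set"
  ref
}

#' DLID, density form
#'
#' `log10(DLLC neighbors / total neighbors) + 1.71`, where neighbors are
#' reference pockets within the set's neighborhood radius of the query in
#' z-standardized `(log10 volume, buriedness, hydrophobicity)` space.
#'
#' With zero neighbors a condition of class `pocketrank_no_neighbors` is
#' raised (callers may fall back to [dlid_regression()], see [dlid_score()]).
#' With neighbors but none DLLC, `-Inf` is returned with attribute
#' `flagged = TRUE` and a warning.
#'
#' @param volume,buriedness,hydrophobicity query pocket descriptors.
#' @param reference a [reference_pocket_set()].
#' @return DLID score (scalar).
#' @export
dlid_density <- function(volume, buriedness, hydrophobicity, reference) {
  q <- (c(log10(volume), buriedness, hydrophobicity) - reference$center) /
    reference$scale
  d2 <- colSums((t(reference$features) - q)^2)
  nbr <- d2 <= reference$neighborhood_radius^2
  total <- sum(nbr)
  if (total == 0) {
    stop(errorCondition("no reference pockets within the neighborhood radius",
                        class = c("pocketrank_no_neighbors", "error")))
  }
  dllc <- sum(reference$is_dllc[nbr])
  if (dllc == 0) {
    warning("no DLLC pockets among ", total, " neighbors; DLID is -Inf")
    return(structure(-Inf, flagged = TRUE))
  }
  log10(dllc / total) + 1.71
}

#' DLID with automatic fallback
#'
#' Density form when the reference set has neighbors of the query, otherwise
#' the regression form.
#'
#' @inheritParams dlid_density
#' @param reference a [reference_pocket_set()], or `NULL` to go straight to
#'   the regression form.
#' @return DLID score (scalar).
#' @export
dlid_score <- function(volume, buriedness, hydrophobicity, reference = NULL) {
  if (!is.null(reference)) {
    val <- tryCatch(
      dlid_density(volume, buriedness, hydrophobicity, reference),
      pocketrank_no_neighbors = function(e) NULL
    )
    if (!is.null(val)) return(val)
  }
  dlid_regression(volume, buriedness, hydrophobicity)
}

.check_site_inputs <- function(n, e, p) {
  if (any(n < 0) || any(p < 0)) stop("n and p must be non-negative")
  if (any(e < 0 | e > 1)) stop("enclosure must be in [0, 1]")
}

#' SiteScore
#'
#' Weighted sum of site-point count `n` (capped at 100), enclosure `e` and
#' hydrophilic score `p` (capped at 1). The default mode uses `sqrt(n)`,
#' consistent with the published calibration in which an average tight
#' binding site scores 1.0; `literal = TRUE` applies the weights to `n`
#' linearly as printed.
#'
#' @param n site-point count (>= 0).
#' @param e enclosure in \[0, 1\].
#' @param p hydrophilic score (>= 0; capped at 1 here).
#' @param literal use the literal linear `n` term (default `FALSE`).
#' @return SiteScore (vectorized).
#' @export
site_score <- function(n, e, p, literal = FALSE) {
  .check_site_inputs(n, e, p)
  nn <- pmin(n, 100)
  if (!literal) nn <- sqrt(nn)
  0.0733 * nn + 0.6688 * e - 0.20 * pmin(p, 1.0)
}

#' Dscore
#'
#' Same ingredients as [site_score()] with druggability-calibrated weights;
#' the hydrophilic score is deliberately not capped, which is what lets the
#' score mark highly polar sites as undruggable.
#'
#' @inheritParams site_score
#' @return Dscore (vectorized).
#' @export
dscore <- function(n, e, p, literal = FALSE) {
  .check_site_inputs(n, e, p)
  nn <- pmin(n, 100)
  if (!literal) nn <- sqrt(nn)
  0.094 * nn + 0.60 * e - 0.324 * p
}

#' Classify druggability
#'
#' DLID is druggable strictly above 0.5; SiteScore is druggable at or above
#' 0.80.
#'
#' @param dlid DLID score(s), or `NA`.
#' @param site_score SiteScore value(s), or `NA`.
#' @return Data frame with columns `dlid_druggable`, `site_druggable`.
#' @export
classify_druggability <- function(dlid = NA_real_, site_score = NA_real_) {
  data.frame(dlid_druggable = !is.na(dlid) & dlid > 0.5,
             site_druggable = !is.na(site_score) & site_score >= 0.80)
}

#' Score every pocket of a structure
#'
#' Pipeline glue: detects pockets, computes descriptors and appends the DLID
#' (regression form unless a reference set is supplied), SiteScore, Dscore
#' and druggability flags, one row per pocket.
#'
#' @param structure a `protein_structure`.
#' @param reference optional [reference_pocket_set()] for density-form DLID.
#' @param literal passed to [site_score()] / [dscore()].
#' @param ... passed to [find_pockets()].
#' @return Data frame with one row per detected pocket: `pocket`, `volume`,
#'   `buriedness`, `hydrophobicity`, `site_points`, `enclosure`,
#'   `hydrophilic`, `hydrophobic`, `balance`, `dlid`, `site_score`, `dscore`,
#'   `dlid_druggable`, `site_druggable`.
#' @export
score_pockets <- function(structure, reference = NULL, literal = FALSE, ...) {
  pockets <- find_pockets(structure, ...)
  rows <- lapply(pockets, function(p) {
    shell <- assign_shell(p, structure)
    d <- compute_sitemap_descriptors(p, structure, shell = shell)
    dl <- dlid_score(d$volume, d$buriedness, d$hydrophobicity, reference)
    ss <- site_score(d$site_point_count, d$enclosure, d$hydrophilic_score,
                     literal = literal)
    ds <- dscore(d$site_point_count, d$enclosure, d$hydrophilic_score,
                 literal = literal)
    data.frame(pocket = p$id, volume = d$volume, buriedness = d$buriedness,
               hydrophobicity = d$hydrophobicity,
               site_points = d$site_point_count, enclosure = d$enclosure,
               hydrophilic = d$hydrophilic_score,
               hydrophobic = d$hydrophobic_score, balance = d$balance,
               dlid = as.numeric(dl), site_score = ss, dscore = ds)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pocket = integer(0), volume = numeric(0),
                      buriedness = numeric(0), hydrophobicity = numeric(0),
                      site_points = integer(0), enclosure = numeric(0),
                      hydrophilic = numeric(0), hydrophobic = numeric(0),
                      balance = numeric(0), dlid = numeric(0),
                      site_score = numeric(0), dscore = numeric(0))
  }
  cbind(out, classify_druggability(out$dlid, out$site_score))
}
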