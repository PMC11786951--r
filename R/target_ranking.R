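# Fusing per-target raw method scores (DLID, SPIDER possibility, DScore)
# into a min-max-normalized composite ranking, and selecting docking
# candidates with a configurable exclusion list.

#' Canonicalize a target identifier
#'
#' Upper-cases and strips spaces, underscores and hyphens so typographic
#' variants of the same target label ("GABA-A R", "GABA-A-R", "GABAAR")
#' compare equal.
#'
#' @param x character vector of target labels.
#' @return Canonical labels.
#' @export
canonical_target_id <- function(x) {
  toupper(gsub("[ _-]", "", x))
}

#' Best score per target and method
#'
#' Collapses per-pocket score rows to one row per target carrying, for each
#' method column, the maximum over that target's pockets. Targets with no
#' finite value for a method (e.g. no detected pockets) get `NA`.
#'
#' @param pocket_scores data frame with a `target` column and one or more
#'   numeric method columns.
#' @param methods names of the method columns (default: every numeric column
#'   other than `target`).
#' @return Data frame, one row per target, `target` plus the method maxima.
#' @export
best_score_per_target <- function(pocket_scores,
                                  methods = setdiff(names(pocket_scores)[vapply(pocket_scores, is.numeric, logical(1))],
                                                    "target")) {
  if (nrow(pocket_scores) == 0) {
    out <- pocket_scores[0, c("target", methods), drop = FALSE]
    return(out)
  }
  targets <- unique(pocket_scores$target)
  out <- data.frame(target = targets, stringsAsFactors = FALSE)
  for (m in methods) {
    out[[m]] <- vapply(targets, function(t) {
      v <- pocket_scores[[m]][pocket_scores$target == t]
      v <- v[is.finite(v)]
      if (length(v) == 0) NA_real_ else max(v)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Drop targets with incomplete method scores
#'
#' Keeps exactly the rows where every method column is non-missing, the way
#' targets lacking a score from one method must be removed before min-max
#' fusion.
#'
#' @param rows data frame of per-target raw scores (`target` + method
#'   columns).
#' @param methods method column names (default: all numeric columns).
#' @return The complete rows.
#' @export
drop_incomplete <- function(rows,
                            methods = setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                                              "target")) {
  keep <- rowSums(is.na(rows[, methods, drop = FALSE])) == 0
  if (!any(keep) && nrow(rows) > 0) {
    warning("all rows incomplete; returning an empty table")
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Min-max normalization
#'
#' `(x - min) / (max - min)`: the column minimum maps to 0 and the maximum
#' to 1. Invariant under positive affine transforms of the input.
#'
#' @param x numeric vector with at least two values and `max > min`.
#' @return Normalized values in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2) stop("need at least two values to normalize")
  if (any(is.na(x))) stop("missing values; drop incomplete rows first")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate column: max equals min")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Normalize per-target raw scores and add the composite
#'
#' Applies [minmax_normalize()] to each method column of a complete score
#' table and sums the normalized columns into a composite in \[0, k\] for k
#' methods.
#'
#' @param rows complete per-target raw score table (`target` + method
#'   columns; see [drop_incomplete()]).
#' @param methods method column names (default: all numeric columns).
#' @return Data frame with `target`, one `<method>_norm` column per method,
#'   and `composite`.
#' @export
normalize_scores <- function(rows,
                             methods = setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                                               "target")) {
  out <- data.frame(target = rows$target, stringsAsFactors = FALSE)
  for (m in methods) out[[paste0(m, "_norm")]] <- minmax_normalize(rows[[m]])
  out$composite <- composite_score(out[, paste0(methods, "_norm"), drop = FALSE])
  out
}

#' Composite score
#'
#' Row sum of the normalized method columns. Errors on missing components.
#'
#' @param norm data frame (or matrix) of normalized scores, one column per
#'   method.
#' @return Numeric vector of composites.
#' @export
composite_score <- function(norm) {
  m <- as.matrix(norm)
  if (any(is.na(m))) stop("missing normalized component")
  rowSums(m)
}

#' Rank targets and select docking candidates
#'
#' Sorts by composite descending (ties broken alphabetically by target id),
#' removes the excluded targets, and returns the first `k`.
#'
#' @param rows data frame with `target` and `composite` columns (see
#'   [normalize_scores()]).
#' @param excluded character vector of target ids to remove before selection
#'   (compared after [canonical_target_id()]).
#' @param k number of targets to select.
#' @return The selected rows in rank order, with a `rank` column.
#' @export
rank_and_select <- function(rows, excluded = character(0), k) {
  pool <- rows[!canonical_target_id(rows$target) %in%
                 canonical_target_id(excluded), , drop = FALSE]
  if (k > nrow(pool)) {
    stop("k = ", k, " exceeds the ", nrow(pool), " non-excluded targets")
  }
  pool <- pool[order(-pool$composite, pool$target), , drop = FALSE]
  out <- pool[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}
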