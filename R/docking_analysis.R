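# Post-processing of docking score tables: threshold filtering at
# -20 kcal/mol, best-hit and top-N selection, and cross-target shared
# inhibitor analysis. Binding scores are kcal/mol; more negative is stronger.

#' Canonicalize a molecule identifier
#'
#' Strips whitespace and underscores and upper-cases, so typographically
#' inconsistent formula strings ("C_15_H_14_N_2_O_2_", "C15H14N2O2") compare
#' equal. Reported ids keep their original spelling (minus the separators).
#'
#' @param x character vector of molecule ids.
#' @return Canonical ids.
#' @export
canonical_molecule_id <- function(x) {
  toupper(gsub("[ _]", "", x))
}

#' Load a docking score table
#'
#' Reads a CSV or TSV with `target`, `molecule` and `score` columns (header
#' names matched case-insensitively; `binding_score` accepted for `score`).
#' Duplicate (target, molecule) pairs — compared after canonicalization — are
#' collapsed to the best (most negative) score with a warning.
#'
#' @param path path to the table.
#' @return Data frame of docking records: `target`, `molecule`, `score`.
#' @export
load_docking_table <- function(path) {
  if (!file.exists(path)) stop("cannot read docking table: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  if ("binding_score" %in% names(raw) && !"score" %in% names(raw)) {
    names(raw)[names(raw) == "binding_score"] <- "score"
  }
  need <- c("target", "molecule", "score")
  if (!all(need %in% names(raw))) {
    stop("docking table needs target, molecule and score columns: ", path)
  }
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score) | !nzchar(raw$molecule))
  if (length(bad) > 0) {
    stop("unparseable docking record at line ", bad[1] + 1, " of ", path)
  }
  rec <- data.frame(target = raw$target, molecule = raw$molecule,
                    score = score, stringsAsFactors = FALSE)
  key <- paste(canonical_target_id(rec$target),
               canonical_molecule_id(rec$molecule), sep = "|")
  if (anyDuplicated(key)) {
    warning("duplicate (target, molecule) pairs collapsed to best score")
    ord <- order(key, rec$score)
    rec <- rec[ord, ][!duplicated(key[ord]), ]
    rec <- rec[order(as.integer(rownames(rec))), ]
  }
  rownames(rec) <- NULL
  rec
}

#' Filter docking hits at a binding-score threshold
#'
#' Keeps records at or below the threshold (inclusive: a score of exactly
#' -20 kcal/mol counts as a hit). Order-preserving and idempotent.
#'
#' @param records docking record data frame (`target`, `molecule`, `score`).
#' @param threshold kcal/mol cutoff (default -20).
#' @return The passing records.
#' @export
filter_hits <- function(records, threshold = -20) {
  out <- records[records$score <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best docking hit for a target
#'
#' The record with the minimum (most negative) binding score; ties broken
#' alphabetically by molecule id.
#'
#' @param records docking record data frame.
#' @param target target id (canonicalized for comparison).
#' @return One-row data frame (`target`, `molecule`, `score`).
#' @export
best_hit <- function(records, target) {
  sel <- records[canonical_target_id(records$target) ==
                   canonical_target_id(target), , drop = FALSE]
  if (nrow(sel) == 0) stop("no docking records for target ", target)
  sel <- sel[order(sel$score, sel$molecule), , drop = FALSE]
  out <- sel[1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-N docking records for a target
#'
#' The `n` most negative scores for the target, ascending by score (best
#' first); ties broken alphabetically by molecule id. Returns everything
#' when fewer than `n` records exist.
#'
#' @param records docking record data frame.
#' @param target target id.
#' @param n number of records (default 10).
#' @return Ordered data frame of at most `n` records.
#' @export
top_hits <- function(records, target, n = 10) {
  sel <- records[canonical_target_id(records$target) ==
                   canonical_target_id(target), , drop = FALSE]
  sel <- sel[order(sel$score, sel$molecule), , drop = FALSE]
  out <- utils::head(sel, n)
  rownames(out) <- NULL
  out
}

#' Cross-target shared-inhibitor analysis
#'
#' Groups molecules by the set of targets whose selected set contains them —
#' the top `n` per target (`mode = "top_n"`) or every thresholded hit
#' (`mode = "all_hits"`) — and reports the molecules selected for two or
#' more targets.
#'
#' @param records docking record data frame covering at least two targets.
#' @param mode `"top_n"` or `"all_hits"`.
#' @param n top-N depth (default 10; `mode = "top_n"` only).
#' @param threshold kcal/mol cutoff for `mode = "all_hits"` (default -20).
#' @return A list of class `overlap_report`: `molecule_targets` (named list
#'   mapping each selected molecule to its target set), `counts_per_target`,
#'   and `shared` (character vector of molecules on >= 2 targets).
#' @export
cross_target_overlap <- function(records, mode = c("top_n", "all_hits"),
                                 n = 10, threshold = -20) {
  mode <- match.arg(mode)
  targets <- unique(records$target)
  if (length(targets) < 2) stop("need at least two targets for overlap")
  sets <- lapply(targets, function(t) {
    sel <- if (mode == "top_n") {
      top_hits(records, t, n)
    } else {
      filter_hits(records[canonical_target_id(records$target) ==
                            canonical_target_id(t), , drop = FALSE],
                  threshold)
    }
    unique(canonical_molecule_id(sel$molecule))
  })
  names(sets) <- targets
  mol_targets <- list()
  for (t in targets) {
    for (m in sets[[t]]) mol_targets[[m]] <- c(mol_targets[[m]], t)
  }
  shared <- names(mol_targets)[vapply(mol_targets, length, integer(1)) >= 2]
  rep <- list(molecule_targets = mol_targets,
              counts_per_target = vapply(sets, length, integer(1)),
              shared = sort(shared))
  class(rep) <- "overlap_report"
  rep
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report: %d targets, %d shared molecule(s)>\n",
              length(x$counts_per_target), length(x$shared)))
  for (m in x$shared) {
    cat(sprintf("  %s: %s\n", m, paste(x$molecule_targets[[m]], collapse = ", ")))
  }
  invisible(x)
}
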