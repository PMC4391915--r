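#' Normalize firefly readings to the renilla internal control
#'
#' First normalization step for dual-luciferase data: each well's reporter
#' (firefly) reading is divided by its renilla internal-control reading,
#' removing well-to-well transfection-efficiency differences. All metadata
#' columns are preserved.
#'
#' @param plate A plate table with numeric columns `firefly_rlu` and
#'   `renilla_rlu` (see [simulate_dose_response()] / [read_plate_csv()]).
#' @return The same table with `firefly_rlu`/`renilla_rlu` replaced by a
#'   `ratio` column.
#' @export
internal_normalize <- function(plate) {
  need <- c("firefly_rlu", "renilla_rlu")
  if (!all(need %in% names(plate))) {
    stop("plate table must have columns firefly_rlu and renilla_rlu",
         call. = FALSE)
  }
  bad <- which(!is.finite(plate$renilla_rlu) | plate$renilla_rlu <= 0)
  if (length(bad)) {
    w <- bad[1]
    lab <- if (all(c("construct", "dose_nM", "replicate") %in% names(plate))) {
      sprintf(" (construct %s, dose %g nM, replicate %s)",
              plate$construct[w], plate$dose_nM[w], plate$replicate[w])
    } else ""
    stop(sprintf("non-positive renilla reading in row %d%s", w, lab),
         call. = FALSE)
  }
  out <- plate
  out$ratio <- plate$firefly_rlu / plate$renilla_rlu
  out$firefly_rlu <- NULL
  out$renilla_rlu <- NULL
  out
}

# Resolve a reference selector to a logical row index.
# Accepted forms: "vehicle" (dose_nM == 0), "baseline" (no coregulators),
# a logical vector, or a predicate function on the table.
resolve_reference <- function(ratios, reference) {
  if (is.function(reference)) return(isTRUE_rows(reference(ratios), ratios))
  if (is.logical(reference)) return(isTRUE_rows(reference, ratios))
  if (is.character(reference) && length(reference) == 1L) {
    if (reference == "vehicle") {
      if (!"dose_nM" %in% names(ratios)) {
        stop("reference 'vehicle' needs a dose_nM column", call. = FALSE)
      }
      return(ratios$dose_nM == 0)
    }
    if (reference == "baseline") {
      if (!"coregulators" %in% names(ratios)) {
        stop("reference 'baseline' needs a coregulators column", call. = FALSE)
      }
      return(ratios$coregulators %in% c("", "none", NA))
    }
  }
  stop("'reference' must be \"vehicle\", \"baseline\", a logical vector, ",
       "or a predicate function", call. = FALSE)
}

isTRUE_rows <- function(sel, tab) {
  if (!is.logical(sel) || length(sel) != nrow(tab)) {
    stop("reference selector must yield one logical per row", call. = FALSE)
  }
  sel & !is.na(sel)
}

#' Convert internal-control ratios to fold activation
#'
#' Second (and, for coregulator studies, third) normalization step: every
#' ratio is divided by the arithmetic mean ratio of the reference rows.
#' With `reference = "vehicle"` this yields fold activation relative to the
#' ethanol control; re-applying with `reference = "baseline"` (receptor in
#' the absence of coregulator constructs) yields the coregulator-relative
#' scale used for co-transfection and 2-hybrid comparisons.
#'
#' Normalization is performed within each level of `group_by` (e.g. an
#' `experiment` column) so plates are scaled independently before pooling.
#'
#' @param ratios A ratio table from [internal_normalize()] (column `ratio`),
#'   or a fold table (column `fold`) for a second-stage normalization.
#' @param reference Condition selector: `"vehicle"`, `"baseline"`, a logical
#'   vector, or a function of the table returning a logical vector.
#' @param group_by Optional column name(s) defining independent
#'   normalization groups; `NULL` normalizes the whole table at once.
#' @return A fold table: the input with the value column replaced by `fold`.
#'   The mean fold of the reference rows is exactly 1 (per group).
#' @export
fold_normalize <- function(ratios, reference = "vehicle", group_by = NULL) {
  value_col <- if ("ratio" %in% names(ratios)) "ratio"
               else if ("fold" %in% names(ratios)) "fold"
               else stop("table must have a 'ratio' or 'fold' column",
                         call. = FALSE)
  sel <- resolve_reference(ratios, reference)
  if (!any(sel)) stop("reference selection matched no rows", call. = FALSE)
  grp <- if (is.null(group_by)) {
    rep(1L, nrow(ratios))
  } else {
    if (!all(group_by %in% names(ratios))) {
      stop("group_by columns not found in table", call. = FALSE)
    }
    interaction(ratios[group_by], drop = TRUE)
  }
  out <- ratios
  vals <- ratios[[value_col]]
  fold <- vals
  for (g in levels(factor(grp))) {
    in_g <- grp == g
    ref_g <- in_g & sel
    if (!any(ref_g)) {
      stop(sprintf("no reference rows in group '%s'", g), call. = FALSE)
    }
    m <- mean(vals[ref_g])
    if (!is.finite(m) || m == 0) {
      stop(sprintf("reference mean is zero or non-finite in group '%s'", g),
           call. = FALSE)
    }
    fold[in_g] <- vals[in_g] / m
  }
  out[[value_col]] <- NULL
  out$fold <- fold
  out
}
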