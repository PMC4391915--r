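#' Read and write plate, binding and assay-matrix tables
#'
#' Fixed plain-text dialects used throughout the pipeline:
#' * plate CSV: `construct, coregulators, dose_nM, replicate, firefly_rlu,
#'   renilla_rlu` (fold tables replace the last two with `fold`);
#' * binding CSV: `conc_nM, replicate, total_counts, nonspecific_counts`;
#' * assay-matrix TSV: `assay_id`, `assay_type` (`TT`/`M2H`), one 0/1 column
#'   per coregulator label, then one numeric column per species.
#'
#' @param x Table or [assay_matrix()] to write.
#' @param file Path.
#' @return Readers return the table / `assay_matrix`; writers return the
#'   path invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_plate_csv <- function(x, file) {
  write.csv(x, file, row.names = FALSE)
  invisible(file)
}

#' @rdname table_io
#' @export
read_plate_csv <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  if ("coregulators" %in% names(df)) {
    df$coregulators <- ifelse(is.na(df$coregulators), "", df$coregulators)
  }
  df
}

#' @rdname table_io
#' @export
write_binding_csv <- function(x, file) {
  write.csv(x, file, row.names = FALSE)
  invisible(file)
}

#' @rdname table_io
#' @export
read_binding_csv <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname table_io
#' @export
write_assay_matrix <- function(x, file) {
  if (!inherits(x, "assay_matrix")) {
    stop("'x' must be an assay_matrix", call. = FALSE)
  }
  labels <- sort(unique(unlist(x$coregulators, use.names = FALSE)))
  flags <- sapply(labels, function(l) {
    as.integer(vapply(x$coregulators, function(g) l %in% g, logical(1)))
  })
  df <- data.frame(assay_id = x$assay_ids, assay_type = x$assay_type,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (length(labels)) df <- cbind(df, as.data.frame(flags))
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname table_io
#' @export
read_assay_matrix <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("assay_id", "assay_type") %in% names(df))) {
    stop("assay-matrix TSV needs assay_id and assay_type columns",
         call. = FALSE)
  }
  meta <- c("assay_id", "assay_type")
  rest <- setdiff(names(df), meta)
  # dialect is positional: 0/1 coregulator flag columns come right after
  # assay_type, species columns follow — take the maximal 0/1 prefix
  zero_one <- vapply(rest, function(cn) is.numeric(df[[cn]]) &&
                       all(df[[cn]] %in% c(0, 1)), logical(1))
  n_flag <- if (all(zero_one)) 0L else match(FALSE, zero_one) - 1L
  flag_cols <- rest[seq_len(n_flag)]
  sp_cols <- setdiff(rest, flag_cols)
  vals <- as.matrix(df[sp_cols])
  rownames(vals) <- df$assay_id
  coreg <- lapply(seq_len(nrow(df)), function(i) {
    flag_cols[as.logical(unlist(df[i, flag_cols]))]
  })
  names(coreg) <- df$assay_id
  assay_matrix(vals, assay_type = df$assay_type, coregulators = coreg)
}

#' Export a standardized matrix with row annotations for heatmap rendering
#'
#' Writes the z-scored matrix together with assay type and coregulator
#' flags, ready for an external heatmap/Pickett-plot renderer.
#'
#' @param x An [assay_matrix()].
#' @param file Path (TSV).
#' @return The path, invisibly.
#' @export
export_standardized_matrix <- function(x, file) {
  write_assay_matrix(zscore_rows(x), file)
}
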