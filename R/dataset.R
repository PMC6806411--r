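#' Descriptor/activity dataset container
#'
#' A `qsar_dataset` bundles the three objects every pipeline stage exchanges:
#' a vector of unique compound identifiers, a numeric descriptor matrix
#' (compounds in rows, named descriptors in columns), and the activity
#' vector (typically pKi, in -log10 units). Compound order is significant
#' and defines all downstream indexing; nothing in the package sorts rows
#' implicitly.
#'
#' @param ids character vector of unique compound identifiers.
#' @param X numeric matrix of descriptor values, one row per compound;
#'   column names are the descriptor names and must be unique.
#' @param y numeric activity vector, one entry per compound.
#' @param activity_name label for the activity column (default `"pKi"`).
#' @return An object of class `qsar_dataset`: a list with elements `ids`,
#'   `X`, `y`, `activity_name`.
#' @examples
#' ds <- qsar_dataset(c("a", "b", "c"),
#'                    matrix(1:6, 3, dimnames = list(NULL, c("D1", "D2"))),
#'                    c(5.1, 6.2, 7.3))
#' ds
#' @export
qsar_dataset <- function(ids, X, y, activity_name = "pKi") {
  ids <- as.character(ids)
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(ids) == 0L) stop_named("empty dataset: no compounds")
  if (anyDuplicated(ids))
    stop_named("duplicate compound IDs: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (nrow(X) != length(ids))
    stop_named("descriptor matrix has %d rows but there are %d compound IDs",
               nrow(X), length(ids))
  if (length(y) != length(ids))
    stop_named("activity vector length %d != number of compounds %d",
               length(y), length(ids))
  if (is.null(colnames(X)) && ncol(X) > 0L)
    stop_named("descriptor matrix must have column names")
  if (anyDuplicated(colnames(X)))
    stop_named("duplicate descriptor names: %s",
               paste(unique(colnames(X)[duplicated(colnames(X))]),
                     collapse = ", "))
  if (ncol(X) > 0L && !all(is.finite(X)))
    stop_named("non-finite descriptor values remain after ingestion")
  if (!all(is.finite(y)))
    stop_named("non-finite activity values")
  rownames(X) <- ids
  structure(list(ids = ids, X = X, y = y, activity_name = activity_name),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("<qsar_dataset> %d compounds x %d descriptors; activity '%s'",
              length(x$ids), ncol(x$X), x$activity_name),
      sprintf("[%.3f, %.3f]\n", min(x$y), max(x$y)))
  invisible(x)
}

#' @export
format.qsar_dataset <- function(x, ...)
  sprintf("qsar_dataset(%d x %d)", length(x$ids), ncol(x$X))

#' Subset a dataset by compounds or descriptors
#'
#' @param dataset a [qsar_dataset()].
#' @param rows compound selector (indices, logical, or IDs).
#' @param cols descriptor selector (indices, logical, or names).
#' @return A `qsar_dataset` restricted to the selection, order preserved as
#'   given by the selector.
#' @export
ds_subset <- function(dataset, rows = NULL, cols = NULL) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  ri <- seq_along(dataset$ids)
  if (!is.null(rows)) {
    ri <- if (is.character(rows)) match(rows, dataset$ids) else ri[rows]
    if (anyNA(ri)) stop_named("unknown compound IDs in row selection")
  }
  ci <- seq_len(ncol(dataset$X))
  if (!is.null(cols)) {
    ci <- if (is.character(cols)) match(cols, colnames(dataset$X)) else ci[cols]
    if (anyNA(ci)) stop_named("unknown descriptor names in column selection")
  }
  qsar_dataset(dataset$ids[ri], dataset$X[ri, ci, drop = FALSE],
               dataset$y[ri], dataset$activity_name)
}

# Tokens treated as missing on ingestion (plus anything non-finite after
# numeric parsing, e.g. "-Inf").
MISSING_TOKENS <- c("", "NA", "NaN", "Inf")

#' Read a descriptor/activity table from CSV
#'
#' Reads the comma-separated dialect produced by descriptor-calculation
#' tools (PaDEL and kin): a header row, one compound per row, an identifier
#' column, an activity column, and numeric descriptor columns. Missing-value
#' tokens (`""`, `"NA"`, `"NaN"`, `"Inf"`, and anything that parses to a
#' non-finite number) are handled according to `missing_policy`.
#'
#' @param path path to a CSV file.
#' @param id_column name of the compound-identifier column.
#' @param activity_column name of the activity column.
#' @param missing_policy one of `"drop_column"` (default: descriptors with
#'   any missing value are dropped), `"drop_row"` (compounds with any
#'   missing descriptor are dropped), `"error"`.
#' @param activity_name label stored on the resulting dataset; defaults to
#'   `activity_column`.
#' @param quiet suppress the ingestion log messages.
#' @return A [qsar_dataset()]. The ingestion log (rows/columns kept and
#'   dropped) is attached as attribute `"ingestion_log"`.
#' @export
read_dataset <- function(path, id_column = "ID", activity_column = "pKi",
                         missing_policy = c("drop_column", "drop_row", "error"),
                         activity_name = activity_column, quiet = FALSE) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop_named("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  for (col in c(id_column, activity_column))
    if (!col %in% names(raw)) stop_named("column '%s' not present in %s", col, path)
  if (nrow(raw) == 0L) stop_named("empty table: %s", path)

  ids <- raw[[id_column]]
  if (anyDuplicated(ids))
    stop_named("duplicate compound IDs: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))

  parse_col <- function(v) {
    v[v %in% MISSING_TOKENS] <- NA_character_
    suppressWarnings(num <- as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    list(num = ifelse(is.finite(num), num, NA_real_), bad = bad)
  }

  act <- parse_col(raw[[activity_column]])
  if (any(act$bad))
    stop_named("activity column '%s' is not numeric (rows %s)",
               activity_column, paste(which(act$bad), collapse = ", "))
  if (anyNA(act$num))
    stop_named("missing activity values (rows %s)",
               paste(which(is.na(act$num)), collapse = ", "))

  desc_names <- setdiff(names(raw), c(id_column, activity_column))
  X <- matrix(NA_real_, nrow(raw), length(desc_names),
              dimnames = list(NULL, desc_names))
  for (nm in desc_names) {
    p <- parse_col(raw[[nm]])
    if (any(p$bad))
      stop_named("non-numeric descriptor column '%s' (e.g. value '%s')",
                 nm, raw[[nm]][which(p$bad)[1L]])
    X[, nm] <- p$num
  }

  dropped_cols <- character(0)
  dropped_rows <- character(0)
  if (anyNA(X)) {
    if (missing_policy == "error") {
      bad <- colnames(X)[colSums(is.na(X)) > 0L]
      stop_named("missing descriptor values in column(s): %s",
                 paste(bad, collapse = ", "))
    } else if (missing_policy == "drop_column") {
      keep <- colSums(is.na(X)) == 0L
      dropped_cols <- colnames(X)[!keep]
      X <- X[, keep, drop = FALSE]
    } else {
      keep <- rowSums(is.na(X)) == 0L
      dropped_rows <- ids[!keep]
      X <- X[keep, , drop = FALSE]
      ids <- ids[keep]
      act$num <- act$num[keep]
    }
  }

  log <- list(path = path, n_rows_read = nrow(raw),
              n_rows_kept = length(ids),
              n_cols_read = length(desc_names), n_cols_kept = ncol(X),
              dropped_columns = dropped_cols, dropped_rows = dropped_rows,
              missing_policy = missing_policy)
  if (!quiet)
    message(sprintf(
      "read_dataset: %d/%d compounds, %d/%d descriptors kept (policy %s)",
      log$n_rows_kept, log$n_rows_read, log$n_cols_kept, log$n_cols_read,
      missing_policy))
  ds <- qsar_dataset(ids, X, act$num, activity_name)
  attr(ds, "ingestion_log") <- log
  ds
}

#' Write a dataset to CSV
#'
#' Columns are written as identifier first, activity second, then the
#' descriptors in their stored order. Doubles are written with 17
#' significant digits so [read_dataset()] recovers them bit-exactly.
#'
#' @param dataset a [qsar_dataset()].
#' @param path output path.
#' @param id_column header used for the identifier column.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, id_column = "ID") {
  stopifnot(inherits(dataset, "qsar_dataset"))
  header <- c(id_column, dataset$activity_name, colnames(dataset$X))
  body <- cbind(dataset$ids, repr_double(dataset$y),
                if (ncol(dataset$X) > 0L)
                  apply(dataset$X, 2L, repr_double)
                else NULL)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_named("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}
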