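#' Inspection batches
#'
#' An inspection batch holds one row per tested sample: an identifier, an
#' inspection date and the numeric values of the m indicators, together with
#' the ordered indicator specification table that gives each column its legal
#' bound. The value matrix is the n x m data matrix consumed by the scorers.
#'
#' @param values Numeric n x m matrix of indicator values, columns in the
#'   order of `specs`. A data frame of numerics is accepted.
#' @param specs An [indicator_specs] table of length m.
#' @param sample_id Character vector of sample identifiers (default
#'   `"S1"..."Sn"`).
#' @param date Vector of inspection dates (`Date`; default today).
#' @return An object of class `"inspection_batch"`.
#' @seealso [read_batch()], [qualify()], [normalize_batch()]
#' @export
inspection_batch <- function(values, specs, sample_id = NULL, date = NULL) {
  specs <- if (inherits(specs, "indicator_specs")) specs else
    indicator_specs(specs)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); m <- ncol(values)
  if (n < 1 || m < 1) stop("batch must have at least one row and one column")
  if (m != nrow(specs))
    stop("batch has ", m, " columns but ", nrow(specs), " indicator specs")
  if (!is.null(colnames(values))) {
    if (!identical(colnames(values), specs$name))
      stop("column names of values do not match indicator spec order")
  } else {
    colnames(values) <- specs$name
  }
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  if (is.null(date)) date <- rep(Sys.Date(), n)
  date <- as.Date(date)
  if (length(sample_id) != n || length(date) != n)
    stop("sample_id and date must have one entry per row")
  structure(list(sample_id = as.character(sample_id), date = date,
                 values = values, specs = specs),
            class = "inspection_batch")
}

#' @export
print.inspection_batch <- function(x, ...) {
  cat("Inspection batch:", nrow(x$values), "samples x",
      ncol(x$values), "indicators\n")
  cat("Indicators:", paste(x$specs$name, collapse = ", "), "\n")
  cat("Dates:", format(min(x$date)), "to", format(max(x$date)), "\n")
  invisible(x)
}

#' @export
dim.inspection_batch <- function(x) dim(x$values)

#' @export
as.data.frame.inspection_batch <- function(x, ...) {
  data.frame(sample_id = x$sample_id, date = x$date,
             as.data.frame(x$values), check.names = FALSE)
}

#' Read and write inspection batch CSV files
#'
#' The CSV layout has a header `sample_id,date,<indicator columns>` with
#' ISO-8601 dates. Raw report exports may contain comparator-prefixed cells
#' (`"<0.2"`); with `clean = TRUE` these are stripped via [clean_values()]
#' before parsing.
#'
#' @param path CSV file path.
#' @param specs An [indicator_specs] table naming (and ordering) the
#'   indicator columns expected in the file.
#' @param clean Strip comparator symbols from value cells (default `TRUE`).
#' @return `read_batch()` returns an [inspection_batch];
#'   `write_batch()` invisibly returns `path`.
#' @export
read_batch <- function(path, specs, clean = TRUE) {
  specs <- if (inherits(specs, "indicator_specs")) specs else
    indicator_specs(specs)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "date", specs$name)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  raw <- as.matrix(df[, specs$name, drop = FALSE])
  vals <- if (clean) clean_values(raw) else {
    v <- suppressWarnings(apply(raw, 2, as.numeric)); dim(v) <- dim(raw); v
  }
  colnames(vals) <- specs$name
  inspection_batch(vals, specs, sample_id = df$sample_id,
                   date = as.Date(df$date))
}

#' @rdname read_batch
#' @param batch An [inspection_batch] to write.
#' @export
write_batch <- function(batch, path) {
  stopifnot(inherits(batch, "inspection_batch"))
  df <- as.data.frame(batch)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop indicator columns from a batch
#'
#' Items not detected in any sample (such as melamine in the motivating
#' milk data) carry no information for anomaly scoring and are removed
#' before analysis, together with their specification rows.
#'
#' @param batch An [inspection_batch].
#' @param drop Character vector of indicator names to remove (may be empty).
#' @return The batch without those columns; row count unchanged.
#' @export
drop_indicators <- function(batch, drop) {
  stopifnot(inherits(batch, "inspection_batch"))
  drop <- as.character(drop)
  if (!length(drop)) return(batch)
  unknown <- setdiff(drop, batch$specs$name)
  if (length(unknown))
    stop("indicator(s) not present in batch: ",
         paste(unknown, collapse = ", "))
  keep <- !(batch$specs$name %in% drop)
  if (!any(keep)) stop("cannot drop every indicator column")
  specs <- batch$specs[keep, , drop = FALSE]
  rownames(specs) <- NULL
  class(specs) <- c("indicator_specs", "data.frame")
  inspection_batch(batch$values[, keep, drop = FALSE], specs,
                   sample_id = batch$sample_id, date = batch$date)
}
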