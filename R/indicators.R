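#' Indicator specification tables
#'
#' An indicator specification describes one laboratory test item: its name,
#' measurement unit, the kind of legal bound it carries, the bound values and
#' the national standard that prescribes the analytical method. Three bound
#' kinds occur in practice:
#'
#' * `"min_limit"` -- a minimum content requirement (e.g. protein at least
#'   3.1 g/100 g): higher raw values mean lower risk;
#' * `"max_limit"` -- a maximum contaminant limit (e.g. aflatoxin M1 at
#'   most 0.5 ug/kg): higher raw values mean higher risk;
#' * `"interval"` -- the value must lie inside a closed interval
#'   (e.g. acidity 11--16 degrees T).
#'
#' `indicator_specs()` validates and classes a data frame of such records;
#' `milk_indicator_specs()` returns the built-in six-indicator table for
#' sterilized milk under GB 25190-2010; `read_indicator_specs()` loads a
#' YAML or JSON spec file with one record per indicator.
#'
#' @param specs A data frame with columns `name`, `unit`, `bound_kind`,
#'   `lo`, `hi`, `standard_ref`. `lo`/`hi` may be `NA` where the bound kind
#'   does not use them.
#' @return A data frame of class `"indicator_specs"`.
#' @examples
#' milk_indicator_specs()
#' @export
indicator_specs <- function(specs) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  required <- c("name", "unit", "bound_kind", "lo", "hi", "standard_ref")
  missing_cols <- setdiff(required, names(specs))
  if (length(missing_cols))
    stop("indicator spec table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(specs)) stop("indicator spec table is empty")
  if (anyDuplicated(specs$name))
    stop("duplicated indicator names in spec table")
  specs$lo <- as.numeric(specs$lo)
  specs$hi <- as.numeric(specs$hi)
  kinds <- c("min_limit", "max_limit", "interval")
  bad <- setdiff(unique(specs$bound_kind), kinds)
  if (length(bad))
    stop("unknown bound_kind: ", paste(bad, collapse = ", "))
  for (i in seq_len(nrow(specs))) {
    kind <- specs$bound_kind[i]
    lo <- specs$lo[i]; hi <- specs$hi[i]
    ok <- switch(kind,
      min_limit = is.finite(lo) && is.na(hi),
      max_limit = is.na(lo) && is.finite(hi),
      interval  = is.finite(lo) && is.finite(hi) && lo < hi)
    if (!ok)
      stop("indicator '", specs$name[i], "' (", kind,
           ") has inconsistent bounds lo=", lo, ", hi=", hi)
  }
  specs <- specs[, required]
  class(specs) <- c("indicator_specs", "data.frame")
  specs
}

#' @rdname indicator_specs
#' @export
milk_indicator_specs <- function() {
  path <- system.file("extdata", "gb25190_indicators.yaml", package = "asrws",
                      mustWork = TRUE)
  read_indicator_specs(path)
}

#' @rdname indicator_specs
#' @param path Path to a YAML or JSON file holding a list of indicator
#'   records (fields `name`, `unit`, `bound_kind`, `lo`, `hi`,
#'   `standard_ref`; omitted bounds are taken as absent).
#' @export
read_indicator_specs <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(recs$indicators)) recs <- recs$indicators
  rows <- lapply(recs, function(r) {
    data.frame(name = r$name,
               unit = if (is.null(r$unit)) "" else r$unit,
               bound_kind = r$bound_kind,
               lo = if (is.null(r$lo)) NA_real_ else as.numeric(r$lo),
               hi = if (is.null(r$hi)) NA_real_ else as.numeric(r$hi),
               standard_ref = if (is.null(r$standard_ref)) ""
                              else r$standard_ref,
               stringsAsFactors = FALSE)
  })
  indicator_specs(do.call(rbind, rows))
}

#' Strip comparator symbols from raw laboratory readings
#'
#' Test reports record values at or below the limit of quantification as
#' e.g. `"<0.2"`. Cleaning strips a leading `<` or `>` comparator
#' (surrounding whitespace tolerated) and parses the remaining literal as a
#' number; the censored reading is retained at its reported bound.
#'
#' @param raw_cells A character vector or matrix of raw cell contents.
#' @return A numeric vector or matrix of the same shape, dimnames preserved.
#'   Cells that do not parse after stripping raise an error naming the first
#'   offending position.
#' @examples
#' clean_values(c("<0.2", "3.42", " >1.5 "))
#' @export
clean_values <- function(raw_cells) {
  dims <- dim(raw_cells)
  dn <- dimnames(raw_cells)
  cells <- trimws(as.character(raw_cells))
  stripped <- trimws(sub("^[<>]", "", cells))
  out <- suppressWarnings(as.numeric(stripped))
  bad <- which(is.na(out) & !is.na(cells))
  if (length(bad)) {
    i <- bad[1]
    where <- if (is.null(dims)) paste0("position ", i) else
      paste0("row ", (i - 1) %% dims[1] + 1, ", column ",
             (i - 1) %/% dims[1] + 1)
    stop("unparseable cell '", cells[i], "' at ", where)
  }
  dim(out) <- dims
  dimnames(out) <- dn
  out
}

#' Qualify samples against legal indicator limits
#'
#' A sample is qualified when every indicator satisfies its legal bound:
#' min-limit indicators at or above `lo`, max-limit indicators at or below
#' `hi`, interval indicators inside the closed interval `[lo, hi]`.
#' Bounds are inclusive, matching the printed limits (>=, <=, a closed
#' interval). Any violation makes the sample unqualified; every violated
#' indicator is recorded.
#'
#' @param batch An [inspection_batch].
#' @return An object of class `"qualification"`: a list with
#'   `labels` (character, `"qualified"`/`"unqualified"` per sample) and
#'   `violated` (a list of character vectors of violated indicator names,
#'   empty for qualified samples).
#' @examples
#' b <- inspection_batch(
#'   values = matrix(c(1.74, 12, 8.79, 4.16, 3.42, 0.2), 1,
#'                   dimnames = list(NULL, milk_indicator_specs()$name)),
#'   specs = milk_indicator_specs(),
#'   sample_id = "20210913-761", date = as.Date("2021-09-13"))
#' qualify(b)$labels
#' @export
qualify <- function(batch) {
  stopifnot(inherits(batch, "inspection_batch"))
  x <- batch$values
  if (anyNA(x))
    stop("qualification needs complete rows; missing value found in batch")
  specs <- batch$specs
  viol <- matrix(FALSE, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    viol[, j] <- switch(specs$bound_kind[j],
      min_limit = x[, j] < specs$lo[j],
      max_limit = x[, j] > specs$hi[j],
      interval  = x[, j] < specs$lo[j] | x[, j] > specs$hi[j])
  }
  violated <- apply(viol, 1, function(v) specs$name[v], simplify = FALSE)
  labels <- ifelse(lengths(violated) > 0, "unqualified", "qualified")
  structure(list(labels = labels, violated = violated),
            class = "qualification")
}

#' @export
print.qualification <- function(x, ...) {
  n <- length(x$labels)
  u <- sum(x$labels == "unqualified")
  cat("Qualification of", n, "samples:", n - u, "qualified,",
      u, "unqualified\n")
  if (u) {
    tab <- sort(table(unlist(x$violated)), decreasing = TRUE)
    cat("Violated indicators:\n")
    print(tab)
  }
  invisible(x)
}
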