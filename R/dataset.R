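#' Specimen dataset for a single skeletal element
#'
#' A `specimen_dataset` holds one element's specimens as a numeric matrix
#' (specimens x measurement codes, `NA` = missing) plus specimen metadata.
#' Elements are analysed separately throughout the pipeline, so a dataset
#' never mixes femora with tibiotarsi or tarsometatarsi. Column order always
#' follows the element's measurement scheme.
#'
#' @param element Element name; see [measurement_scheme()].
#' @param measurements Numeric matrix or data frame with columns named by
#'   scheme codes. Codes absent from the input become all-`NA` columns.
#'   Observed values must be strictly positive (lengths in mm).
#' @param meta Data frame of per-specimen metadata with at least
#'   `specimen_id`. Optional columns: `collection`, `locality`, `type_taxon`,
#'   `type_year`, `type_month`, `type_role`. Extra columns are carried along.
#' @return An object of class `specimen_dataset` with components `element`,
#'   `measurements` (matrix, rownames = specimen ids) and `meta`.
#' @export
specimen_dataset <- function(element, measurements, meta = NULL) {
  element <- match_element(element)
  codes <- scheme_codes(element)
  measurements <- as.matrix(measurements)
  storage.mode(measurements) <- "double"
  if (is.null(colnames(measurements)))
    stop("measurement columns must be named by scheme codes")
  bad <- setdiff(colnames(measurements), codes)
  if (length(bad))
    stop(sprintf("unknown measurement code(s) for %s: %s",
                 element, paste(bad, collapse = ", ")))
  n <- nrow(measurements)
  if (is.null(meta)) {
    ids <- rownames(measurements)
    if (is.null(ids)) ids <- sprintf("spec%03d", seq_len(n))
    meta <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(meta))
    stop("meta must contain a specimen_id column")
  if (nrow(meta) != n)
    stop("meta and measurements disagree on the number of specimens")

  # expand to the full scheme, in scheme order
  M <- matrix(NA_real_, n, length(codes), dimnames = list(meta$specimen_id, codes))
  M[, colnames(measurements)] <- measurements

  neg <- which(!is.na(M) & M <= 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("non-positive measurement: specimen '%s', code %s (value %g)",
                 rownames(M)[neg[1, 1]], codes[neg[1, 2]], M[neg[1, 1], neg[1, 2]]))
  empty <- rowSums(!is.na(M)) == 0
  if (any(empty))
    stop(sprintf("specimen(s) with zero observed measurements rejected: %s",
                 paste(meta$specimen_id[empty], collapse = ", ")))

  structure(list(element = element, measurements = M, meta = meta),
            class = "specimen_dataset")
}

#' @export
print.specimen_dataset <- function(x, ...) {
  mf <- missing_fraction(x)
  cat(sprintf("specimen_dataset: %d %s specimens x %d codes; missingness %.1f%% (mean), %d specimens >= 25%% missing\n",
              nrow(x$measurements), x$element, ncol(x$measurements),
              100 * mean(is.na(x$measurements)), sum(mf >= 0.25)))
  invisible(x)
}

#' @export
dim.specimen_dataset <- function(x) dim(x$measurements)

#' Fraction of an element's measurements that are missing
#'
#' The denominator is always the element's full scheme length (20, 21 or 44),
#' regardless of which columns were present in the source table, so the value
#' is invariant to column order and to metadata columns.
#'
#' @param x A `specimen_dataset`.
#' @return Named numeric vector in `[0, 1]`, one entry per specimen.
#' @export
missing_fraction <- function(x) {
  stopifnot(inherits(x, "specimen_dataset"))
  rowMeans(is.na(x$measurements))
}

#' Read a wide-format specimen measurement table
#'
#' One row per specimen; measurement columns named by the element's scheme
#' codes; empty cells and the literal `"NA"` both mark missing values.
#' Non-measurement columns are kept as metadata. A column whose name looks
#' like a measurement code (`F\\d+`, `Tt\\d+`, `Tmt\\d+`) but does not belong
#' to the element's scheme is a schema error.
#'
#' @param path CSV file path.
#' @param element Element name.
#' @return A [specimen_dataset()].
#' @export
read_specimen_table <- function(path, element) {
  element <- match_element(element)
  codes <- scheme_codes(element)
  raw <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  code_like <- grepl("^(F|Tt|Tmt)[0-9]+$", names(raw))
  bad <- names(raw)[code_like & !(names(raw) %in% codes)]
  if (length(bad))
    stop(sprintf("unknown measurement code(s) for %s: %s",
                 element, paste(bad, collapse = ", ")))
  mcols <- intersect(codes, names(raw))
  if (!length(mcols)) stop("no measurement columns found for element ", element)
  meta <- raw[, setdiff(names(raw), mcols), drop = FALSE]
  if (!"specimen_id" %in% names(meta))
    stop("required column 'specimen_id' not found")
  M <- as.matrix(raw[, mcols, drop = FALSE])
  if (!is.numeric(M)) {
    # locate the offending cell for a useful error
    for (j in mcols) {
      v <- raw[[j]]
      suppressWarnings(num <- as.numeric(v))
      bad_row <- which(!is.na(v) & is.na(num))
      if (length(bad_row))
        stop(sprintf("non-numeric measurement: row %d (specimen '%s'), column %s (value '%s')",
                     bad_row[1], raw$specimen_id[bad_row[1]], j, v[bad_row[1]]))
    }
  }
  specimen_dataset(element, M, meta)
}

#' Write a specimen table
#'
#' Inverse of [read_specimen_table()]: missing cells are written as empty
#' strings, observed values with full precision, so that a write/read
#' round-trip reproduces the dataset exactly.
#'
#' @param x A `specimen_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(x, path) {
  stopifnot(inherits(x, "specimen_dataset"))
  M <- as.data.frame(x$measurements)
  out <- cbind(x$meta, M)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Subset a specimen dataset by row
#'
#' @param x A `specimen_dataset`.
#' @param i Row index (logical, integer or specimen ids).
#' @return A `specimen_dataset` with the selected specimens.
#' @export
subset_specimens <- function(x, i) {
  stopifnot(inherits(x, "specimen_dataset"))
  if (is.character(i)) i <- match(i, x$meta$specimen_id)
  structure(list(element = x$element,
                 measurements = x$measurements[i, , drop = FALSE],
                 meta = x$meta[i, , drop = FALSE]),
            class = "specimen_dataset")
}
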