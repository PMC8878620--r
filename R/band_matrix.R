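#' Construct a band-presence matrix
#'
#' A `band_matrix` holds binary (0/1) presence/absence calls of scored SSR
#' amplicons: rows are germplasm accessions, columns are bands. Each band id
#' embeds the primer that amplified it as `"PRIMER:index"` (e.g. `"3CM0506:2"`),
#' so the band-to-primer map is recoverable from the column header alone.
#'
#' @param values Numeric or integer matrix of 0/1 calls with accessions in rows
#'   and bands in columns.
#' @param accession_ids Row labels; defaults to `rownames(values)`.
#' @param band_ids Column labels of the form `"PRIMER:index"`; defaults to
#'   `colnames(values)`.
#' @return An object of class `band_matrix`: a list with elements `values`
#'   (integer matrix with dimnames), `accession_ids`, `band_ids`, and
#'   `primer_of_band` (character vector mapping each band to its primer code).
#' @export
#' @examples
#' m <- band_matrix(matrix(c(1, 0, 0, 1), 2, 2,
#'                  dimnames = list(c("a1", "a2"), c("P1:1", "P1:2"))))
#' n_accessions(m)
band_matrix <- function(values, accession_ids = rownames(values),
                        band_ids = colnames(values)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(accession_ids) || is.null(band_ids)) {
    stop("band matrix needs accession (row) and band (column) labels")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("band matrix needs at least one accession and one band")
  }
  if (anyDuplicated(accession_ids)) stop("duplicate accession ids")
  if (anyDuplicated(band_ids)) stop("duplicate band ids")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing band call at accession '%s', band '%s' (missing data unsupported)",
                 accession_ids[bad[1L]], band_ids[bad[2L]]))
  }
  if (!all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)))[1L]
    ai <- (bad - 1L) %% nrow(values) + 1L
    bi <- (bad - 1L) %/% nrow(values) + 1L
    stop(sprintf("non-binary cell %s at accession '%s', band '%s'",
                 format(values[ai, bi]), accession_ids[ai], band_ids[bi]))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(accession_ids, band_ids)
  structure(
    list(values = values,
         accession_ids = as.character(accession_ids),
         band_ids = as.character(band_ids),
         primer_of_band = primer_of_band(band_ids)),
    class = "band_matrix"
  )
}

#' Primer code of a band id
#'
#' Band ids are `"PRIMER:index"`; everything before the final colon is the
#' primer code.
#'
#' @param band_ids Character vector of band ids.
#' @return Character vector of primer codes, named by band id.
#' @export
primer_of_band <- function(band_ids) {
  if (!all(grepl(":", band_ids, fixed = TRUE))) {
    stop("band ids must have the form 'PRIMER:index'")
  }
  stats::setNames(sub(":[^:]*$", "", band_ids), band_ids)
}

#' @rdname band_matrix
#' @param m A `band_matrix`.
#' @export
n_accessions <- function(m) nrow(m$values)

#' @rdname band_matrix
#' @export
n_bands <- function(m) ncol(m$values)

#' @rdname band_matrix
#' @export
primer_codes <- function(m) unique(unname(m$primer_of_band))

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d accessions x %d bands from %d primers\n",
              n_accessions(x), n_bands(x), length(primer_codes(x))))
  invisible(x)
}

#' Read a band-presence matrix from CSV
#'
#' Expects a header row of band ids (`"PRIMER:index"`), a first column of
#' accession ids, and 0/1 cells. Any non-binary or missing cell is an error
#' naming the offending accession and band.
#'
#' @param path Path to a CSV file.
#' @return A [band_matrix()].
#' @export
read_band_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("band matrix file is empty")
  acc <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("band matrix cells must be numeric 0/1")
  rownames(vals) <- acc
  band_matrix(vals)
}

#' Write a band-presence matrix to CSV
#'
#' @param m A [band_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(m, path) {
  stopifnot(inherits(m, "band_matrix"))
  df <- data.frame(accession = m$accession_ids, m$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population assignment table from CSV
#'
#' @param path CSV with columns `accession` and `population`.
#' @return A data.frame with character columns `accession` and `population`.
#' @export
read_population_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "population") %in% names(df))) {
    stop("population map needs columns 'accession' and 'population'")
  }
  if (nrow(df) == 0L) stop("population map is empty")
  if (anyDuplicated(df$accession)) stop("duplicate accession in population map")
  if (anyNA(df$accession) || anyNA(df$population)) stop("population map has missing entries")
  df[c("accession", "population")]
}
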