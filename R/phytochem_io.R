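#' Read an essential-oil composition table from CSV
#'
#' The table carries, per accession, the three biomarker compounds of Java
#' citronella oil (citronellal, citronellol, geraniol) as percentages of the
#' oil. Optional `sd_*` columns carry the replicate standard deviations
#' printed alongside the means; they are kept as metadata and ignored by every
#' computation (clustering operates on the means).
#'
#' @param path CSV with columns `accession`, `citronellal`, `citronellol`,
#'   `geraniol` (and optionally `sd_citronellal` etc.).
#' @return A data.frame with one row per accession; compound values are
#'   percentages in \[0, 100\].
#' @export
read_phytochem_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("accession", oil_compounds())
  if (!all(req %in% names(df))) {
    stop("phytochemical table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("phytochemical table is empty")
  if (anyDuplicated(df$accession)) stop("duplicate accession in phytochemical table")
  vals <- as.matrix(df[oil_compounds()])
  if (anyNA(vals)) stop("missing compound value in phytochemical table")
  if (any(vals < 0) || any(vals > 100)) {
    stop("compound percentages must lie in [0, 100]")
  }
  df
}

#' The three oil biomarker compounds
#'
#' @return Character vector `c("citronellal", "citronellol", "geraniol")`.
#' @export
oil_compounds <- function() c("citronellal", "citronellol", "geraniol")

#' Packaged citronella core-collection fixtures
#'
#' Accessors for the plain-text data shipped with the package: the published
#' oil-composition table for the 72 accessions (`cw_phytochem()`), their
#' collection-state population assignments (`cw_populations()`), and the
#' published per-primer SSR summary for the 28 retained primers
#' (`cw_primer_table()`).
#'
#' @return `cw_phytochem()`: data.frame of 72 accessions x 3 compounds (+ SD
#'   metadata); `cw_populations()`: data.frame `accession`/`population`;
#'   `cw_primer_table()`: data.frame of 28 primers with columns
#'   `primer_code`, `total_alleles`, `polymorphic_alleles`,
#'   `pct_polymorphism`, `PIC`, `MI`, `Rp`.
#' @export
cw_phytochem <- function() {
  read_phytochem_table(system.file("extdata", "table1_phytochem.csv",
                                   package = "cymbodiv", mustWork = TRUE))
}

#' @rdname cw_phytochem
#' @export
cw_populations <- function() {
  read_population_map(system.file("extdata", "table1_populations.csv",
                                  package = "cymbodiv", mustWork = TRUE))
}

#' @rdname cw_phytochem
#' @export
cw_primer_table <- function() {
  df <- utils::read.csv(system.file("extdata", "table2_primers.csv",
                                    package = "cymbodiv", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 28L)
  df
}
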