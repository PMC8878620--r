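#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when mirroring printed tables;
#' base [round()] rounds half to even which differs at exact .5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.465, 2) # 0.47, where round() gives 0.46
round_half_up <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Coerce/validate a square symmetric dissimilarity matrix with zero diagonal.
# Accepts a "dist" object or a labelled matrix; returns a labelled matrix.
as_distance_matrix <- function(d, require_labels = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) {
    stop("distance input must be a numeric matrix or a 'dist' object")
  }
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  if (is.null(rownames(d))) {
    if (require_labels && !is.null(colnames(d))) {
      rownames(d) <- colnames(d)
    } else {
      rownames(d) <- colnames(d) <- paste0("item", seq_len(nrow(d)))
    }
  }
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Align a population map to a set of accession labels, returning a factor.
# `pops` is a data.frame with columns accession, population.
align_populations <- function(accessions, pops) {
  if (!is.data.frame(pops) || !all(c("accession", "population") %in% names(pops))) {
    stop("population map must be a data.frame with columns 'accession' and 'population'")
  }
  if (anyDuplicated(pops$accession)) {
    stop("population map assigns some accession more than once")
  }
  idx <- match(accessions, pops$accession)
  if (anyNA(idx)) {
    stop("no population assigned for accession(s): ",
         paste(utils::head(accessions[is.na(idx)], 5L), collapse = ", "))
  }
  factor(pops$population[idx])
}
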