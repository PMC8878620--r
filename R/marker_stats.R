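#' Per-band carrier frequencies
#'
#' For each scored band, the proportion `p` of accessions carrying it. This is
#' the quantity entering band informativeness and, in phenotypic mode, the
#' allele-frequency proxy used throughout the dominant-marker statistics.
#'
#' @param m A [band_matrix()].
#' @return data.frame with columns `band_id`, `primer`, `carrier_count`, `p`.
#' @export
band_frequencies <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  cc <- colSums(m$values)
  data.frame(band_id = m$band_ids,
             primer = unname(m$primer_of_band),
             carrier_count = as.integer(cc),
             p = cc / n_accessions(m),
             row.names = NULL)
}

#' Is a band polymorphic?
#'
#' Strict criterion: a band is polymorphic iff it is present in some but not
#' all accessions (0 < p < 1). No minimum-frequency cut is applied.
#'
#' @param p Carrier proportion(s) in \[0, 1\].
#' @return Logical vector.
#' @export
is_polymorphic <- function(p) p > 0 & p < 1

#' Polymorphism information content of a primer
#'
#' PIC = 1 - sum(pi^2) over the allele frequencies of the primer's locus. In
#' the default `"multiallelic"` mode the primer's bands are treated as the
#' alleles of a single multi-allelic locus, with pi the share of band i among
#' all carrier calls of that primer (this is the convention consistent with
#' reported dominant-marker PIC values above 0.5). The `"biallelic_mean"` mode
#' instead scores each band as a biallelic locus, 1 - (p^2 + (1-p)^2), and
#' averages over the primer's bands; it is bounded by 0.5.
#'
#' @param m A [band_matrix()].
#' @param primer A primer code present in `m`.
#' @param mode `"multiallelic"` (default) or `"biallelic_mean"`.
#' @return PIC in \[0, 1).
#' @export
pic_primer <- function(m, primer, mode = c("multiallelic", "biallelic_mean")) {
  mode <- match.arg(mode)
  f <- band_frequencies(m)
  f <- f[f$primer == primer, , drop = FALSE]
  if (nrow(f) == 0L) stop("unknown primer: ", primer)
  if (mode == "multiallelic") {
    tot <- sum(f$carrier_count)
    if (tot == 0L) stop("primer '", primer, "' has no carriers; allele frequencies undefined")
    pi <- f$carrier_count / tot
    1 - sum(pi^2)
  } else {
    mean(1 - (f$p^2 + (1 - f$p)^2))
  }
}

#' Effective multiplex ratio
#'
#' Operationally the polymorphic fraction of a primer's bands. Reported
#' marker-index values for this marker system are consistent only with
#' MI = PIC x (polymorphic/total), so EMR is the fraction, not the
#' count-times-fraction product.
#'
#' @param polymorphic Number of polymorphic bands of the primer.
#' @param total Total number of the primer's bands (>= 1).
#' @return EMR in \[0, 1\].
#' @export
emr <- function(polymorphic, total) {
  if (any(total < 1)) stop("total band count must be >= 1")
  if (any(polymorphic < 0) || any(polymorphic > total)) {
    stop("polymorphic count must lie in [0, total]")
  }
  polymorphic / total
}

#' Marker index
#'
#' MI = EMR x PIC, the combined informativeness of a primer. Returned at full
#' precision; use [round_half_up()] for table-style reporting.
#'
#' @param pic PIC value(s).
#' @param emr EMR value(s).
#' @return MI value(s).
#' @export
mi <- function(pic, emr) pic * emr

#' Band informativeness
#'
#' Ib = 1 - 2|0.5 - p|, maximal (1) for a band carried by half the
#' accessions and zero for a monomorphic band.
#'
#' @param p Carrier proportion(s) in \[0, 1\].
#' @return Ib in \[0, 1\].
#' @export
band_informativeness <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  1 - 2 * abs(0.5 - p)
}

#' Resolving power of a primer
#'
#' Rp = sum of band informativeness over the primer's bands; measures the
#' primer's ability to distinguish genotypes.
#'
#' @inheritParams pic_primer
#' @return Rp in \[0, band count\].
#' @export
rp <- function(m, primer) {
  f <- band_frequencies(m)
  f <- f[f$primer == primer, , drop = FALSE]
  if (nrow(f) == 0L) stop("unknown primer: ", primer)
  sum(band_informativeness(f$p))
}

#' Per-primer informativeness summary
#'
#' One row per primer with band counts, polymorphism percentage, PIC, EMR, MI
#' and Rp, followed by `Total` (column sums), `Average` (column means) and
#' `SD` (sample standard deviation, n-1) rows over the primers, mirroring the
#' layout of published SSR competency tables.
#'
#' @inheritParams pic_primer
#' @param mode PIC mode passed to [pic_primer()].
#' @param digits If non-NULL, round all statistics half-up to this many
#'   decimals for reporting; default `NULL` keeps full precision.
#' @return data.frame with columns `primer_code`, `total_alleles`,
#'   `polymorphic_alleles`, `pct_polymorphism`, `PIC`, `EMR`, `MI`, `Rp`.
#' @export
primer_summary <- function(m, mode = c("multiallelic", "biallelic_mean"),
                           digits = NULL) {
  mode <- match.arg(mode)
  f <- band_frequencies(m)
  primers <- unique(f$primer)
  rows <- lapply(primers, function(pr) {
    fp <- f[f$primer == pr, , drop = FALSE]
    tot <- nrow(fp)
    poly <- sum(is_polymorphic(fp$p))
    pic <- pic_primer(m, pr, mode)
    e <- emr(poly, tot)
    data.frame(primer_code = pr,
               total_alleles = tot,
               polymorphic_alleles = poly,
               pct_polymorphism = 100 * poly / tot,
               PIC = pic, EMR = e, MI = mi(pic, e),
               Rp = sum(band_informativeness(fp$p)))
  })
  out <- do.call(rbind, rows)
  num <- names(out)[-1L]
  tot_row <- c(list(primer_code = "Total"), as.list(colSums(out[num])))
  avg_row <- c(list(primer_code = "Average"), as.list(colMeans(out[num])))
  sd_row <- c(list(primer_code = "SD"), as.list(vapply(out[num], stats::sd, 0)))
  out <- rbind(out,
               as.data.frame(tot_row), as.data.frame(avg_row),
               as.data.frame(sd_row))
  if (!is.null(digits)) {
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  rownames(out) <- NULL
  out
}
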