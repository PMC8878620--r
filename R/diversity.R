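#' Per-band allele frequencies within a set of accessions
#'
#' Each binary band is treated as a two-allele locus (band present / band
#' absent). In the default `"phenotypic"` mode the band-allele frequency is
#' the carrier proportion itself — appropriate for vegetatively propagated
#' material where Hardy-Weinberg de-dominancing has no basis. The `"hwe"` mode
#' instead takes the null-allele frequency as the square root of the
#' non-carrier proportion (the classic dominant-data convention under random
#' mating).
#'
#' @param m A [band_matrix()].
#' @param subset Optional character vector of accession ids (default: all).
#' @param mode `"phenotypic"` (default) or `"hwe"`.
#' @return Matrix with one row per band and columns `p` (band allele) and `q`
#'   (null allele), rows named by band id; each row sums to 1.
#' @export
allele_freqs <- function(m, subset = NULL, mode = c("phenotypic", "hwe")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "band_matrix"))
  v <- m$values
  if (!is.null(subset)) {
    if (length(subset) == 0L) stop("empty accession subset")
    if (!all(subset %in% m$accession_ids)) stop("unknown accession in subset")
    v <- v[subset, , drop = FALSE]
  }
  carrier <- colMeans(v)
  if (mode == "phenotypic") {
    p <- carrier
  } else {
    q <- sqrt(1 - carrier)
    p <- 1 - q
  }
  cbind(p = p, q = 1 - p)
}

#' Diversity statistics of a locus
#'
#' Given the allele frequencies of one locus: observed allele count `na`
#' (alleles with nonzero frequency), effective allele count `ne = 1/sum(pi^2)`,
#' Nei gene diversity `h = 1 - sum(pi^2)`, and Shannon information index
#' `i = -sum(pi log pi)` (with 0 log 0 = 0).
#'
#' @param freqs Numeric vector of allele frequencies summing to 1, or a matrix
#'   with one locus per row.
#' @return data.frame with columns `na`, `ne`, `h`, `i` (one row per locus).
#' @export
locus_diversity <- function(freqs) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1L)
  if (any(abs(rowSums(freqs) - 1) > 1e-8)) {
    stop("allele frequencies of each locus must sum to 1")
  }
  sp2 <- rowSums(freqs^2)
  plogp <- freqs * log(freqs)
  plogp[freqs == 0] <- 0
  data.frame(na = rowSums(freqs > 0),
             ne = 1 / sp2,
             h = 1 - sp2,
             i = -rowSums(plogp),
             row.names = rownames(freqs))
}

#' Population diversity and differentiation summary
#'
#' Per population, the mean and SD over all loci of the observed (`na`) and
#' effective (`ne`) allele numbers, Nei gene diversity (`h`) and Shannon index
#' (`i`), plus the percentage of loci polymorphic within the population.
#' Pooled over populations, the total gene diversity `Ht` (per locus from the
#' unweighted mean of population allele frequencies, Nei 1973), the mean
#' within-population diversity `Hs`, the differentiation coefficient
#' `Gst = (Ht - Hs)/Ht` computed from the locus-averaged Ht and Hs, and the
#' gene-flow estimate `Nm` from [nm_from_gst()].
#'
#' @param m A [band_matrix()].
#' @param pops Population map: data.frame with columns `accession`,
#'   `population` covering every accession in `m`.
#' @param mode Allele-frequency mode, see [allele_freqs()].
#' @return An object of class `pop_diversity`: list with `per_population`
#'   (data.frame), `ht_mean`, `ht_sd`, `hs_mean`, `hs_sd`, `gst`, `nm`, and
#'   per-locus matrices in `locus` (`ht`, `hs`).
#' @export
population_summary <- function(m, pops, mode = c("phenotypic", "hwe")) {
  mode <- match.arg(mode)
  grp <- align_populations(m$accession_ids, pops)
  if (any(table(grp) < 1L)) stop("every population must contain at least one accession")
  pop_names <- levels(grp)
  k <- length(pop_names)

  # per-population band-allele frequency p (one column per population)
  pmat <- vapply(pop_names, function(g) {
    allele_freqs(m, subset = m$accession_ids[grp == g], mode = mode)[, "p"]
  }, numeric(n_bands(m)))
  pmat <- matrix(pmat, nrow = n_bands(m),
                 dimnames = list(m$band_ids, pop_names))

  per_pop <- do.call(rbind, lapply(pop_names, function(g) {
    ld <- locus_diversity(cbind(pmat[, g], 1 - pmat[, g]))
    data.frame(population = g,
               n = sum(grp == g),
               mean_na = mean(ld$na), sd_na = stats::sd(ld$na),
               mean_ne = mean(ld$ne), sd_ne = stats::sd(ld$ne),
               mean_h = mean(ld$h),  sd_h = stats::sd(ld$h),
               mean_i = mean(ld$i),  sd_i = stats::sd(ld$i),
               pct_polymorphic = 100 * mean(is_polymorphic(pmat[, g])))
  }))

  pbar <- rowMeans(pmat)
  ht_locus <- 1 - (pbar^2 + (1 - pbar)^2)
  hs_locus <- rowMeans(1 - (pmat^2 + (1 - pmat)^2))
  ht <- mean(ht_locus)
  hs <- mean(hs_locus)
  gst <- if (ht > 0) (ht - hs) / ht else 0
  structure(
    list(per_population = per_pop,
         ht_mean = ht, ht_sd = stats::sd(ht_locus),
         hs_mean = hs, hs_sd = stats::sd(hs_locus),
         gst = gst,
         nm = nm_from_gst(gst),
         locus = list(ht = ht_locus, hs = hs_locus, p = pmat),
         mode = mode),
    class = "pop_diversity"
  )
}

#' @export
print.pop_diversity <- function(x, ...) {
  cat("Population diversity summary (", x$mode, " frequencies)\n", sep = "")
  print(cbind(x$per_population[1L],
              round(x$per_population[-1L], 4L)), row.names = FALSE)
  cat(sprintf("Ht = %.4f +/- %.4f  Hs = %.4f +/- %.4f  Gst = %.4f  Nm = %.4f\n",
              x$ht_mean, x$ht_sd, x$hs_mean, x$hs_sd, x$gst, x$nm))
  invisible(x)
}

#' Gene flow from Gst
#'
#' The standard indirect estimate Nm = 0.5 (1 - Gst) / Gst of effective
#' migrants per generation. Undefined (no differentiation) when Gst <= 0, in
#' which case `Inf` is returned as a sentinel.
#'
#' @param gst Differentiation coefficient in \[0, 1\].
#' @return Nm (>= 0), or `Inf` when `gst <= 0`.
#' @export
nm_from_gst <- function(gst) {
  ifelse(gst > 0, 0.5 * (1 - gst) / gst, Inf)
}

#' Nei genetic identity and distance between populations
#'
#' For populations x and y with per-locus allele frequencies, the normalized
#' identity is `I = Jxy / sqrt(Jx Jy)` where `Jxy` is the mean over loci of
#' the cross-product of allele frequencies (and `Jx`, `Jy` the corresponding
#' within-population means of squared frequencies); the distance is
#' `D = -log(I)`. Identical frequency profiles give I = 1, D = 0.
#'
#' @inheritParams population_summary
#' @return List with symmetric matrices `identity` and `distance` (labelled by
#'   population). Zero identity yields an infinite distance sentinel.
#' @export
nei_identity_distance <- function(m, pops, mode = c("phenotypic", "hwe")) {
  mode <- match.arg(mode)
  grp <- align_populations(m$accession_ids, pops)
  pop_names <- levels(grp)
  if (length(pop_names) < 2L) stop("need at least two populations")
  pmat <- vapply(pop_names, function(g) {
    allele_freqs(m, subset = m$accession_ids[grp == g], mode = mode)[, "p"]
  }, numeric(n_bands(m)))
  pmat <- matrix(pmat, nrow = n_bands(m), dimnames = list(m$band_ids, pop_names))
  k <- length(pop_names)
  J <- matrix(0, k, k, dimnames = list(pop_names, pop_names))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      J[a, b] <- mean(pmat[, a] * pmat[, b] + (1 - pmat[, a]) * (1 - pmat[, b]))
    }
  }
  I <- J / sqrt(outer(diag(J), diag(J)))
  I <- pmin(I, 1)
  D <- -log(I)
  D[I == 0] <- Inf
  diag(D) <- 0
  list(identity = I, distance = D)
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage agglomerative clustering producing a rooted ultrametric
#' tree; used for the between-population dendrogram on Nei genetic distances.
#'
#' @param d Symmetric distance matrix with zero diagonal (or `dist`).
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma <- function(d) {
  d <- as_distance_matrix(d)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  ape::ladderize(tr)
}
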