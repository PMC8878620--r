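#' Simulate a band-presence matrix with population structure
#'
#' Stands in for the unpublished gel-band matrix of the citronella core
#' collection: a Balding-Nichols generator in which each band has an ancestral
#' carrier frequency drawn uniformly from `ancestral_freq_range`, and each
#' population draws its own frequency from
#' `Beta(p (1 - F)/F, (1 - p)(1 - F)/F)` at divergence level `fst`. Defaults
#' mirror the study: four collection-state populations of sizes 51/9/2/10 (72
#' accessions), 28 primers with the published per-primer band counts (92 bands
#' in all), and an among-population differentiation of 0.25.
#'
#' In `"phenotypic"` scoring an accession carries a band with probability
#' equal to the population band frequency (appropriate for clonally propagated
#' material); in `"dominant_diploid"` scoring the carrier probability is
#' `1 - (1 - q)^2` for band-allele frequency `q` under random mating.
#'
#' @param pop_sizes Named integer vector of population sizes (>= 1 each).
#' @param n_primers Number of primers (ignored when `bands_per_primer` has one
#'   entry per primer).
#' @param bands_per_primer Either a length-2 range (bands drawn uniformly per
#'   primer, default 2-5) or a vector of exact per-primer band counts.
#' @param fst Divergence parameter in (0, 1).
#' @param ancestral_freq_range Range of ancestral band frequencies.
#' @param scoring `"phenotypic"` (default) or `"dominant_diploid"`.
#' @param seed Optional integer seed; same seed gives identical output.
#' @return List with `bands` (a [band_matrix()]), `populations` (data.frame
#'   `accession`/`population`) and `truth` (ancestral and per-population band
#'   frequencies plus the configuration).
#' @export
simulate_bands <- function(pop_sizes = c(Assam = 51L, Manipur = 9L,
                                         Meghalaya = 2L,
                                         `Arunachal Pradesh` = 10L),
                           n_primers = 28L,
                           bands_per_primer = published_band_counts(),
                           fst = 0.25,
                           ancestral_freq_range = c(0.1, 0.9),
                           scoring = c("phenotypic", "dominant_diploid"),
                           seed = NULL) {
  scoring <- match.arg(scoring)
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1) {
    stop("fst must lie strictly between 0 and 1")
  }
  if (any(pop_sizes < 1L)) stop("population sizes must be >= 1")
  if (is.null(names(pop_sizes))) names(pop_sizes) <- paste0("Pop", seq_along(pop_sizes))
  if (!is.null(seed)) set.seed(seed)

  nb <- if (length(bands_per_primer) == 2L && n_primers != 2L) {
    sample(seq(bands_per_primer[1L], bands_per_primer[2L]), n_primers, replace = TRUE)
  } else {
    n_primers <- length(bands_per_primer)
    as.integer(bands_per_primer)
  }
  if (any(nb < 1L)) stop("each primer needs at least one band")
  primer_codes <- sprintf("SIM%02d", seq_len(n_primers))
  band_ids <- unlist(lapply(seq_len(n_primers), function(i) {
    paste0(primer_codes[i], ":", seq_len(nb[i]))
  }))
  n_band <- length(band_ids)
  k <- length(pop_sizes)
  N <- sum(pop_sizes)

  anc <- stats::runif(n_band, ancestral_freq_range[1L], ancestral_freq_range[2L])
  shape_scale <- (1 - fst) / fst
  pop_freq <- matrix(stats::rbeta(n_band * k,
                                  rep(anc, k) * shape_scale,
                                  rep(1 - anc, k) * shape_scale),
                     nrow = n_band,
                     dimnames = list(band_ids, names(pop_sizes)))

  grp <- rep(names(pop_sizes), pop_sizes)
  carrier_prob <- pop_freq[, grp, drop = FALSE]
  if (scoring == "dominant_diploid") {
    carrier_prob <- 1 - (1 - carrier_prob)^2
  }
  x <- matrix(stats::rbinom(n_band * N, 1L, carrier_prob), nrow = n_band)
  acc <- sprintf("ACC%03d", seq_len(N))
  values <- t(x)
  dimnames(values) <- list(acc, band_ids)
  list(bands = band_matrix(values),
       populations = data.frame(accession = acc, population = grp),
       truth = list(fst = fst, ancestral_freq = stats::setNames(anc, band_ids),
                    pop_freq = pop_freq, scoring = scoring,
                    bands_per_primer = stats::setNames(nb, primer_codes)))
}

#' Published per-primer band counts
#'
#' The numbers of scored bands of the 28 retained SSR primers (summing to 92),
#' used as the default band layout of [simulate_bands()].
#'
#' @return Named integer vector of length 28.
#' @export
published_band_counts <- function() {
  tab <- cw_primer_table()
  stats::setNames(as.integer(tab$total_alleles), tab$primer_code)
}

#' Simulate an oil-composition table with chemotype structure
#'
#' Gaussian draws about chemotype centroids, clipped to \[0, 100\]. Cluster
#' sizes come from `proportions` by deterministic largest-remainder rounding,
#' so `proportions = c(9, 58, 5)/72` with `n = 72` yields exactly 9/58/5.
#' Default centroids follow the chemotype pattern of the core collection:
#' a high-geraniol/high-citronellol group, a dominant high-citronellal group,
#' and a small low-everything group.
#'
#' @param n Number of accessions.
#' @param centroids k x 3 matrix of cluster centers (percent), columns
#'   citronellal, citronellol, geraniol.
#' @param proportions Cluster proportions summing to 1.
#' @param noise_sd Per-compound Gaussian noise SD (scalar or length 3).
#' @param seed Optional integer seed.
#' @return List with `table` (data.frame like [read_phytochem_table()] output)
#'   and `labels` (true cluster of each accession).
#' @export
simulate_phytochem <- function(n = 72L,
                               centroids = rbind(c(15, 15, 35),
                                                 c(43, 12, 20),
                                                 c(6, 5, 7)),
                               proportions = c(9, 58, 5) / 72,
                               noise_sd = 2,
                               seed = NULL) {
  k <- nrow(centroids)
  colnames(centroids) <- oil_compounds()
  if (length(proportions) != k) stop("one proportion per centroid required")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (any(centroids < 0 | centroids > 100)) stop("centroids must lie in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  # largest-remainder apportionment of n among clusters
  raw <- n * proportions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  labels <- rep(seq_len(k), sizes)
  sdv <- rep_len(noise_sd, 3L)
  vals <- centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * 3L, sd = rep(sdv, each = n)), n, 3L)
  vals <- pmin(pmax(vals, 0), 100)
  tab <- data.frame(accession = sprintf("SIM%03d", seq_len(n)), vals)
  names(tab)[-1L] <- oil_compounds()
  list(table = tab, labels = stats::setNames(labels, tab$accession),
       sizes = as.integer(sizes))
}
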