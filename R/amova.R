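#' Euclidean distance between accessions' band profiles
#'
#' For binary band vectors the squared Euclidean distance is the mismatch
#' count, the standard input to dominant-marker AMOVA.
#'
#' @param m A [band_matrix()].
#' @return Symmetric Euclidean distance matrix labelled by accession.
#' @export
band_distance <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  as.matrix(stats::dist(m$values))
}

# Within-population sum of squares from a squared-distance matrix and an
# integer grouping vector (1..k), with population sizes `sizes`.
ss_within_groups <- function(D2, groups, sizes) {
  ssw <- 0
  for (g in seq_along(sizes)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) ssw <- ssw + sum(D2[idx, idx]) / (2 * sizes[g])
  }
  ssw
}

amova_components <- function(D2, groups, sizes) {
  N <- length(groups)
  k <- length(sizes)
  ss_total <- sum(D2) / (2 * N)
  ss_within <- ss_within_groups(D2, groups, sizes)
  ss_among <- ss_total - ss_within
  df_among <- k - 1L
  df_within <- N - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  sigma_within <- ms_within
  sigma_among_raw <- (ms_among - ms_within) / n0
  sigma_among <- max(sigma_among_raw, 0)
  phi <- if (sigma_among + sigma_within > 0) {
    sigma_among / (sigma_among + sigma_within)
  } else 0
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       df_among = df_among, df_within = df_within, df_total = N - 1L,
       ms_among = ms_among, ms_within = ms_within, n0 = n0,
       sigma_among = sigma_among, sigma_among_raw = sigma_among_raw,
       sigma_within = sigma_within, phi_pt = phi)
}

#' Analysis of molecular variance (AMOVA) with permutation test
#'
#' Distance-based AMOVA partitioning the variance of squared pairwise
#' distances among and within populations, with the PhiPT statistic for
#' dominant marker data (among-population variance proportion). Significance
#' is assessed by permuting individuals among populations (sizes held fixed)
#' and counting permuted PhiPT values at least as large as the observed one,
#' with the +1 correction.
#'
#' Unequal population sizes are handled through the usual n0 coefficient; a
#' negative among-population variance component is truncated to zero before
#' percentages and PhiPT (the raw value is retained in `sigma_among_raw`).
#'
#' @param d Euclidean distance matrix among accessions (or `dist`); distances
#'   are squared internally. For band data use [band_distance()].
#' @param pops Population map data.frame (`accession`, `population`) covering
#'   every row label of `d`; at least two populations, and not all of size 1.
#' @param permutations Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return An object of class `amova_result`: list with `table` (data.frame of
#'   source, df, SS, MS, variance component and percent of total), `phi_pt`,
#'   `p_value`, `permutations`, `sigma_among_raw`, and the permuted PhiPT
#'   samples in `null_phi`.
#' @export
amova <- function(d, pops, permutations = 999L, seed = NULL) {
  d <- as_distance_matrix(d)
  grp <- align_populations(rownames(d), pops)
  k <- nlevels(grp)
  if (k < 2L) stop("AMOVA needs at least two populations")
  sizes <- as.integer(table(grp))
  N <- length(grp)
  if (N - k < 1L) stop("all populations of size 1: no within-population degrees of freedom")
  D2 <- d^2
  groups <- as.integer(grp)
  obs <- amova_components(D2, groups, sizes)

  null_phi <- numeric(0)
  p_value <- NA_real_
  if (permutations >= 1L) {
    if (!is.null(seed)) set.seed(seed)
    null_phi <- vapply(seq_len(permutations), function(b) {
      amova_components(D2, sample(groups), sizes)$phi_pt
    }, 0)
    p_value <- (1 + sum(null_phi >= obs$phi_pt)) / (permutations + 1)
  }

  sig <- c(obs$sigma_among, obs$sigma_within)
  pct <- if (sum(sig) > 0) 100 * sig / sum(sig) else c(0, 100)
  tab <- data.frame(
    source = c("Among populations", "Within populations", "Total"),
    df = c(obs$df_among, obs$df_within, obs$df_total),
    SS = c(obs$ss_among, obs$ss_within, obs$ss_total),
    MS = c(obs$ms_among, obs$ms_within, NA),
    variance = c(sig, sum(sig)),
    pct_of_total = c(pct, 100)
  )
  structure(
    list(table = tab, phi_pt = obs$phi_pt, p_value = p_value,
         permutations = permutations, sigma_among_raw = obs$sigma_among_raw,
         n0 = obs$n0, null_phi = null_phi),
    class = "amova_result"
  )
}

#' Permutation null distribution of PhiPT
#'
#' Convenience wrapper returning the permuted PhiPT samples together with the
#' observed statistic and the (+1-corrected) p-value; reproducible under a
#' fixed seed.
#'
#' @inheritParams amova
#' @return List with `observed`, `samples`, `p_value`.
#' @export
permutation_null <- function(d, pops, permutations = 999L, seed = NULL) {
  stopifnot(permutations >= 1L)
  res <- amova(d, pops, permutations = permutations, seed = seed)
  list(observed = res$phi_pt, samples = res$null_phi, p_value = res$p_value)
}

#' @export
print.amova_result <- function(x, ...) {
  tab <- x$table
  tab[-1L] <- round(tab[-1L], 4L)
  print(tab, row.names = FALSE)
  cat(sprintf("PhiPT = %.4f, p = %.4g (%d permutations)\n",
              x$phi_pt, x$p_value, x$permutations))
  invisible(x)
}
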