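#' Euclidean distance over oil-compound percentages
#'
#' Pairwise Euclidean distances among accessions over the three biomarker
#' compounds. All three variables share the percent scale, so the default
#' operates on raw values; `standardize = TRUE` z-scores each compound first
#' (a constant compound is centered but left unscaled).
#'
#' @param t Phytochemical table (data.frame from [read_phytochem_table()] with
#'   an `accession` column, or a plain numeric matrix with row labels).
#' @param standardize Z-standardize each compound before computing distances.
#' @return Symmetric distance matrix labelled by accession.
#' @export
euclidean_matrix <- function(t, standardize = FALSE) {
  if (is.data.frame(t)) {
    x <- as.matrix(t[oil_compounds()])
    rownames(x) <- t$accession
  } else {
    x <- as.matrix(t)
  }
  if (anyNA(x)) stop("missing values in phytochemical data")
  if (standardize) {
    s <- apply(x, 2L, stats::sd)
    s[s == 0] <- 1
    x <- scale(x, center = TRUE, scale = s)
  }
  as.matrix(stats::dist(x))
}

#' Complete-linkage agglomerative clustering
#'
#' Greedy agglomeration minimizing the maximum inter-cluster distance at each
#' step. Ties are broken by the smallest pair of cluster representatives
#' (each cluster represented by its smallest original index), making the merge
#' history deterministic. Merge heights are also reported on the similarity
#' scale `100 (1 - d / d_max)` used by similarity-scaled dendrograms, with
#' `d_max` the largest observed pairwise distance.
#'
#' @param d Symmetric distance matrix with zero diagonal (or `dist`).
#' @return An object of class `chem_clust`: list with `merge` (hclust-style
#'   (n-1) x 2 matrix: negative entries are singleton indices, positive entries
#'   prior merge steps), `height`, `similarity`, `labels`, `d_max`.
#' @export
complete_linkage <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  labs <- rownames(d)
  if (n == 1L) {
    return(structure(list(merge = matrix(integer(0), 0L, 2L),
                          height = numeric(0), similarity = numeric(0),
                          labels = labs, d_max = 0),
                     class = "chem_clust"))
  }
  d_max <- max(d)
  # active clusters: member index sets, hclust-style id, representative (min member)
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  reps <- seq_len(n)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    nn <- nrow(D)
    DD <- D
    DD[lower.tri(DD, diag = TRUE)] <- Inf
    hmin <- min(DD)
    cand <- which(DD <= hmin + 1e-12 * max(1, hmin), arr.ind = TRUE)
    # tie-break: smallest (representative_i, representative_j) pair
    rp <- cbind(pmin(reps[cand[, 1L]], reps[cand[, 2L]]),
                pmax(reps[cand[, 1L]], reps[cand[, 2L]]))
    o <- order(rp[, 1L], rp[, 2L])[1L]
    i <- cand[o, 1L]; j <- cand[o, 2L]
    height[s] <- D[i, j]
    merge[s, ] <- sort(c(ids[i], ids[j]))
    newd <- pmax(D[i, ], D[j, ])
    keep <- setdiff(seq_len(nn), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]), c(newd[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    reps <- c(reps[keep], min(reps[i], reps[j]))
    ids <- c(ids[keep], s)
  }
  structure(
    list(merge = merge, height = height,
         similarity = if (d_max > 0) 100 * (1 - height / d_max) else rep(100, n - 1L),
         labels = labs, d_max = d_max),
    class = "chem_clust"
  )
}

#' @export
print.chem_clust <- function(x, ...) {
  cat(sprintf("complete-linkage clustering of %d items (%d merges)\n",
              length(x$labels), nrow(x$merge)))
  invisible(x)
}

#' Cut a complete-linkage clustering into k clusters
#'
#' Withholds the last k-1 merges of the history. Cluster ids are numbered by
#' the smallest original index they contain. When the underlying data table is
#' supplied, per-cluster compound means are computed for boxplot-style
#' reporting.
#'
#' @param result A [complete_linkage()] result.
#' @param k Number of clusters, 1 <= k <= n.
#' @param data Optional phytochemical table (same rows/order as the distance
#'   matrix) for cluster means.
#' @return List with `labels` (named integer vector), `sizes`, and (if `data`
#'   given) `means` (cluster x compound matrix).
#' @export
cut_k <- function(result, k, data = NULL) {
  stopifnot(inherits(result, "chem_clust"))
  n <- length(result$labels)
  if (k < 1L || k > n) stop("k must lie in [1, n]")
  assign <- seq_len(n)
  if (n - k >= 1L) {
    cluster_of_step <- integer(n - 1L)
    for (s in seq_len(n - k)) {
      mem_ids <- result$merge[s, ]
      grp <- integer(0)
      for (v in seq_len(2L)) {
        grp <- c(grp, if (mem_ids[v] < 0L) -mem_ids[v] else
          which(assign == cluster_of_step[mem_ids[v]]))
      }
      newid <- min(assign[grp])
      assign[grp] <- newid
      cluster_of_step[s] <- newid
    }
  }
  # renumber clusters 1..k by smallest member index
  uq <- sort(unique(assign))
  labels <- match(assign, uq)
  names(labels) <- result$labels
  sizes <- as.integer(table(labels))
  out <- list(labels = labels, sizes = sizes)
  if (!is.null(data)) {
    x <- if (is.data.frame(data)) {
      xm <- as.matrix(data[oil_compounds()]); rownames(xm) <- data$accession; xm
    } else as.matrix(data)
    stopifnot(nrow(x) == n)
    out$means <- do.call(rbind, lapply(seq_len(k), function(g) {
      colMeans(x[labels == g, , drop = FALSE])
    }))
    rownames(out$means) <- paste0("cluster", seq_len(k))
  }
  out
}

#' Descriptive summaries of oil compounds
#'
#' Per compound: minimum, maximum, range, mean, boxplot quartiles, and the
#' accession attaining the maximum.
#'
#' @param t Phytochemical table (see [euclidean_matrix()]).
#' @return data.frame with one row per compound.
#' @export
compound_ranges <- function(t) {
  if (is.data.frame(t)) {
    x <- as.matrix(t[oil_compounds()])
    rownames(x) <- t$accession
  } else {
    x <- as.matrix(t)
  }
  if (nrow(x) == 0L) stop("empty phytochemical table")
  do.call(rbind, lapply(colnames(x), function(cp) {
    v <- x[, cp]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(compound = cp, min = min(v), q1 = q[1L], median = q[2L],
               q3 = q[3L], max = max(v), range = max(v) - min(v),
               mean = mean(v),
               argmax_accession = rownames(x)[which.max(v)])
  }))
}
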