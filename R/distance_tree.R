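#' Jaccard similarity and dissimilarity among accessions
#'
#' For each pair of accessions, `s = a / (a + b + c)` over band columns, where
#' `a` counts shared band presences and `b`, `c` the one-sided mismatches;
#' shared absences are ignored. The dissimilarity is `1 - s`. A pair with no
#' presences at all (`a + b + c = 0`) is assigned similarity 1 with a warning
#' rather than NaN.
#'
#' @param m A [band_matrix()].
#' @return List with symmetric matrices `similarity` and `dissimilarity`
#'   labelled by accession id.
#' @export
jaccard <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  if (n_accessions(m) < 2L) stop("need at least two accessions")
  x <- m$values
  a <- tcrossprod(x)
  rs <- rowSums(x)
  union <- outer(rs, rs, "+") - a
  s <- a / union
  if (any(union == 0)) {
    warning("accession pair(s) with no scored presences; similarity set to 1")
    s[union == 0] <- 1
  }
  diag(s) <- 1
  dimnames(s) <- list(m$accession_ids, m$accession_ids)
  list(similarity = s, dissimilarity = 1 - s)
}

#' Neighbour-joining tree
#'
#' The Saitou-Nei agglomeration on a pairwise distance matrix, producing an
#' unrooted tree. Ties in the Q-criterion are broken by the smallest (row,
#' column) index pair, making the output deterministic. Negative branch
#' lengths arising at a join are clamped to zero with the deficit transferred
#' to the sibling edge (preserving the distance through the new node); the
#' number of clamped edges is recorded in the `"negative_branches"` attribute.
#'
#' @param d Symmetric distance matrix with zero diagonal (or `dist`), n >= 2.
#' @return An unrooted `phylo` tree whose tips are the row labels of `d`.
#' @export
neighbor_joining <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  labs <- rownames(d)
  if (n < 2L) stop("need at least two taxa")
  neg <- 0L
  if (n == 2L) {
    half <- d[1L, 2L] / 2
    txt <- sprintf("(%s:%.12g,%s:%.12g);",
                   newick_quote(labs[1L]), half, newick_quote(labs[2L]), half)
    tr <- parse_newick(txt)
    attr(tr, "negative_branches") <- 0L
    return(tr)
  }
  sub <- newick_quote(labs)
  D <- d
  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0; neg <- neg + 1L }
    if (vj < 0) { vi <- vi + vj; vj <- 0; neg <- neg + 1L }
    newsub <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], vi, sub[j], vj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    Dn <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], newsub)
    D <- Dn
  }
  v1 <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  v2 <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  v3 <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  v <- c(v1, v2, v3)
  neg <- neg + sum(v < 0)
  v <- pmax(v, 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 sub[1L], v[1L], sub[2L], v[2L], sub[3L], v[3L])
  tr <- parse_newick(txt)
  attr(tr, "negative_branches") <- neg
  tr
}

#' Principal coordinate analysis
#'
#' Metric multidimensional scaling: Gower double-centering of `-d^2/2`
#' followed by an eigendecomposition. Negative eigenvalues (non-Euclidean
#' input) are reported but excluded from the percent-variance denominator, and
#' coordinates are returned for the positive axes only.
#'
#' @param d Symmetric distance matrix with zero diagonal (or `dist`).
#' @return An object of class `pcoa_result`: list with `eigenvalues` (all, in
#'   descending order), `table` (data.frame of `axis`, `eigenvalue`,
#'   `pct_variance`, `cumulative` over the positive axes) and `coordinates`
#'   (accessions x positive axes).
#' @export
pcoa <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  G <- -0.5 * d^2
  rm_ <- rowMeans(G)
  B <- G - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(G)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values
  tol <- 1e-9 * max(abs(lam), 1)
  pos <- which(lam > tol)
  denom <- sum(lam[pos])
  pct <- if (denom > 0) 100 * lam[pos] / denom else numeric(0)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam[pos]), length(pos))
  dimnames(coords) <- list(rownames(d),
                           if (length(pos)) paste0("Axis", seq_along(pos)))
  structure(
    list(eigenvalues = lam,
         table = data.frame(axis = seq_along(pos),
                            eigenvalue = lam[pos],
                            pct_variance = pct,
                            cumulative = cumsum(pct)),
         coordinates = coords),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("Principal coordinate analysis:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "positive axes\n")
  print(utils::head(cbind(x$table[1L], round(x$table[-1L], 4L)), 10L),
        row.names = FALSE)
  invisible(x)
}
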