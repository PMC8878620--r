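test_that("Euclidean distances over compounds behave as expected", {
  t <- data.frame(accession = c("u", "v"),
                  citronellal = c(0, 3), citronellol = c(0, 4), geraniol = c(0, 0))
  d <- euclidean_matrix(t)
  expect_equal(unname(d["u", "v"]), 5)            # 3-4-5 triangle
  t2 <- rbind(t, t[1, ]); t2$accession[3] <- "w"
  d2 <- euclidean_matrix(t2)
  expect_equal(unname(d2["u", "w"]), 0)           # identical rows

  # standardized distances invariant to per-compound affine rescaling
  set.seed(2)
  x <- data.frame(accession = paste0("a", 1:8),
                  citronellal = runif(8, 0, 50), citronellol = runif(8, 0, 30),
                  geraniol = runif(8, 0, 40))
  y <- x
  y$citronellal <- 3 * x$citronellal + 10
  y$geraniol <- 0.5 * x$geraniol - 2
  expect_equal(euclidean_matrix(y, standardize = TRUE),
               euclidean_matrix(x, standardize = TRUE), tolerance = 1e-9)
})

test_that("complete linkage follows the hand trace and stays monotone", {
  lab <- c("A", "B", "C")
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3, dimnames = list(lab, lab))
  cl <- complete_linkage(d)
  expect_equal(cl$height, c(1, 2))
  expect_equal(cl$merge[1, ], c(-2L, -1L))  # pair at distance 1, smallest labels
  expect_equal(cl$similarity, c(50, 0))

  # single point: empty history
  cl1 <- complete_linkage(matrix(0, 1, 1, dimnames = list("A", "A")))
  expect_equal(nrow(cl1$merge), 0L)

  set.seed(19)
  for (rep in 1:10) {
    x <- matrix(rnorm(14), 7, 2, dimnames = list(paste0("p", 1:7), NULL))
    cl <- complete_linkage(as.matrix(dist(x)))
    expect_true(all(diff(cl$height) >= -1e-12))
  }
})

test_that("merge history equals brute-force agglomeration on random 7-point sets", {
  # brute force: recompute every inter-cluster maximum from the original
  # matrix at each step (no Lance-Williams update)
  brute <- function(d) {
    n <- nrow(d)
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    parts <- list()
    while (length(clusters) > 1L) {
      best <- NULL; bh <- Inf
      for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
      }
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
      heights <- c(heights, bh)
      parts[[length(parts) + 1L]] <-
        vapply(seq_len(n), function(v) {
          which(vapply(clusters, function(cl) v %in% cl, TRUE))
        }, 0L)
    }
    list(heights = heights, partitions = parts)
  }
  set.seed(23)
  for (rep in 1:8) {
    x <- matrix(rnorm(21), 7, 3, dimnames = list(paste0("p", 1:7), NULL))
    d <- as.matrix(dist(x))
    cl <- complete_linkage(d)
    bf <- brute(d)
    expect_equal(cl$height, bf$heights, tolerance = 1e-9)
    for (k in 6:2) {
      got <- cut_k(cl, k)$labels
      want <- bf$partitions[[7 - k]]
      expect_equal(adjusted_rand(got, want), 1)  # same partition at every k
    }
    # and the heights agree with the standard library implementation
    expect_equal(cl$height, stats::hclust(as.dist(d), "complete")$height,
                 tolerance = 1e-9)
  }
})

test_that("cut_k nests, covers all sizes, and reconstructs the grand mean", {
  t1 <- cw_phytochem()
  cl <- complete_linkage(euclidean_matrix(t1))
  n <- nrow(t1)
  expect_error(cut_k(cl, 0), "\\[1, n\\]")
  expect_equal(cut_k(cl, n)$sizes, rep(1L, n))       # all singletons
  expect_equal(cut_k(cl, 1)$sizes, n)
  prev <- cut_k(cl, 5)$labels
  nxt <- cut_k(cl, 4)$labels
  # nesting: the k=4 partition merges exactly two clusters of the k=5 one
  tab <- table(prev, nxt)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(sum(colSums(tab > 0) > 1), 1L)

  ck <- cut_k(cl, 3, data = t1)
  expect_equal(sum(ck$sizes), n)
  grand <- colMeans(as.matrix(t1[oil_compounds()]))
  recon <- colSums(ck$means * ck$sizes) / n
  expect_equal(recon, grand, tolerance = 1e-9)
})

test_that("well-separated simulated chemotypes are recovered perfectly", {
  sim <- simulate_phytochem(n = 60, noise_sd = 1.5, seed = 31)
  cl <- complete_linkage(euclidean_matrix(sim$table))
  ck <- cut_k(cl, 3)
  expect_equal(adjusted_rand(ck$labels, sim$labels), 1)
})

test_that("compound descriptives match the published extremes", {
  t1 <- cw_phytochem()
  cr <- compound_ranges(t1)
  expect_equal(cr$max[cr$compound == "citronellal"], 51.450)
  expect_equal(cr$argmax_accession[cr$compound == "citronellal"], "IC-0626993")
  expect_equal(cr$max[cr$compound == "citronellol"], 26.389)
  expect_equal(cr$argmax_accession[cr$compound == "citronellol"], "IC-0627002")
  expect_equal(cr$max[cr$compound == "geraniol"], 41.146)
  expect_equal(cr$argmax_accession[cr$compound == "geraniol"], "IC-0627004")
  expect_true(all(cr$min <= cr$q1 & cr$q1 <= cr$median &
                    cr$median <= cr$q3 & cr$q3 <= cr$max))

  cst <- compound_ranges(data.frame(accession = c("a", "b"),
                                    citronellal = c(1, 1),
                                    citronellol = c(2, 3), geraniol = c(0, 0)))
  expect_equal(cst$range[cst$compound == "citronellal"], 0)
})
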