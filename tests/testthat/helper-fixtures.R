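# Small in-code fixtures shared across test files.

# 6 accessions x 4 bands (2 primers), 2 populations of 3; used with frozen
# hand-computed diversity values.
toy_bands <- function() {
  v <- rbind(a1 = c(1, 0, 1, 1), a2 = c(1, 1, 0, 1), a3 = c(1, 0, 1, 1),
             b1 = c(0, 1, 0, 1), b2 = c(0, 1, 1, 1), b3 = c(1, 1, 0, 1))
  colnames(v) <- c("P1:1", "P1:2", "P2:1", "P2:2")
  band_matrix(v)
}

toy_pops <- function() {
  data.frame(accession = c("a1", "a2", "a3", "b1", "b2", "b3"),
             population = rep(c("A", "B"), each = 3))
}

# random binary band matrix with simple "P<i>:<j>" ids
random_bands <- function(n_acc, n_band, prob = 0.5, primer_size = 2L) {
  v <- matrix(rbinom(n_acc * n_band, 1L, prob), n_acc, n_band)
  primer <- rep(seq_len(ceiling(n_band / primer_size)), each = primer_size)[seq_len(n_band)]
  idx <- stats::ave(primer, primer, FUN = seq_along)
  colnames(v) <- paste0("P", primer, ":", idx)
  rownames(v) <- paste0("acc", seq_len(n_acc))
  # guard against an all-zero accession pair wrinkle in Jaccard tests
  v[, 1] <- 1L
  band_matrix(v)
}

# adjusted Rand index between two labelings (independent of any package)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(m) sum(choose(m, 2))
  a <- comb2(tab)
  b <- comb2(rowSums(tab))
  c_ <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- b * c_ / n2
  (a - expected) / ((b + c_) / 2 - expected)
}
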