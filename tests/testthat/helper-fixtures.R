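# Small builders shared across test files.  Everything is generated in
# code; no stored fixtures.

# a tiny two-standard library with well-separated peaks
tiny_library <- function(axis = seq(-0.2, 9.6, by = 0.002), width = 0.002) {
  make_standard_library(list(
    standard_spec("alanine", data.frame(center = 1.48, height = 1,
                                        width = width)),
    standard_spec("glucose", data.frame(center = 3.40, height = 1,
                                        width = width))), axis)
}

# k standards with evenly spaced single peaks across 0.7..9.3 ppm
spread_library <- function(k, axis = seq(-0.2, 9.6, by = 0.002),
                           width = 0.002) {
  centers <- seq(0.7, 9.3, length.out = k)
  make_standard_library(lapply(seq_len(k), function(i)
    standard_spec(sprintf("m%02d", i),
                  data.frame(center = centers[i], height = 1,
                             width = width))), axis)
}

# brute-force two-sided Spearman permutation p-value, independent of the
# package internals: lexicographic next-permutation enumeration and
# per-permutation correlation of ranks
brute_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  obs <- abs(cor(rx, ry))
  perm <- seq_len(n)
  count <- 0L
  total <- 0L
  repeat {
    total <- total + 1L
    if (abs(cor(rx[perm], ry)) >= obs - 1e-12) count <- count + 1L
    # next permutation in lexicographic order
    i <- n - 1L
    while (i >= 1L && perm[i] >= perm[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (perm[j] <= perm[i]) j <- j - 1L
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    perm[(i + 1L):n] <- rev(perm[(i + 1L):n])
  }
  count / total
}

# matched blood/csf tables from raw matrices (minimal metadata)
tables_from_matrices <- function(X, Y, genotype = "WT") {
  n <- nrow(X)
  meta <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                     sex = "female", genotype = genotype,
                     age_point = "early", stringsAsFactors = FALSE)
  list(blood = conc_table(cbind(meta, fluid = "blood", as.data.frame(X))),
       csf = conc_table(cbind(meta, fluid = "csf", as.data.frame(Y))))
}
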