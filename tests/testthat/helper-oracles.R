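# Independent brute-force oracles used to pin expected values.

# assign each value to an equal-width bin by explicit scan; last bin
# right-inclusive
oracle_bin_counts <- function(values, nbins) {
  lo <- min(values); hi <- max(values)
  edges <- seq(lo, hi, length.out = nbins + 1)
  counts <- integer(nbins)
  for (v in values) {
    placed <- FALSE
    for (j in seq_len(nbins)) {
      if (j < nbins) {
        if (v >= edges[j] && v < edges[j + 1]) { placed <- TRUE }
      } else {
        if (v >= edges[j] && v <= edges[j + 1]) { placed <- TRUE }
      }
      if (placed) { counts[j] <- counts[j] + 1L; break }
    }
  }
  list(edges = edges, counts = counts)
}

# first empty bin scanning from the dark end; threshold is its upper edge
oracle_first_empty_bin <- function(counts, edges) {
  for (i in seq_along(counts)) {
    if (counts[i] == 0L) return(edges[i + 1])
  }
  Inf
}

# separable sampled-Gaussian impulse response, truncated at 4 sigma like
# the implementation, computed independently as an outer product
oracle_gaussian_impulse <- function(n, sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- (-r):r
  w <- exp(-0.5 * (x / sigma_vox)^2)
  w <- w / sum(w)
  full <- numeric(n)
  centre <- (n + 1) %/% 2
  full[centre + x] <- w
  outer(outer(full, full), full)
}

# a compact phantom for unit tests (64^3 keeps each pipeline stage fast)
small_spec <- function(...) {
  phantom_spec(shape = c(64L, 64L, 64L),
               brain_semi_axes = c(26, 30, 24),
               ventricle_offset_mm = c(8, 4, 1),
               ventricle_semi_axes = c(4.5, 10, 7),
               ...)
}

small_lesions <- function() {
  list(list(center = c(-13, -6, 0), radius = 4),
       list(center = c(12, 6, -3), radius = 4))
}
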