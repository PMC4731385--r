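test_that("histogram bins conserve counts and match a brute-force oracle", {
  set.seed(21)
  for (nbins in c(7L, 32L, 100L)) {
    x <- c(runif(500, 0, 100), 0, 100)  # include both extremes
    h <- build_histogram(x, nbins)
    o <- oracle_bin_counts(x, nbins)
    expect_identical(h$counts, o$counts)
    expect_equal(h$bin_edges, o$edges)
    expect_identical(sum(h$counts), length(x))
    expect_identical(h$status, "ok")
  }
})

test_that("the rightmost bin is right-inclusive so the maximum is never dropped", {
  h <- build_histogram(c(0, 1, 2, 3, 4), nbins = 4L)
  expect_identical(h$counts, c(1L, 1L, 1L, 2L))
})

test_that("constant input degenerates to a flagged single bin", {
  h <- build_histogram(rep(42, 10), nbins = 64L)
  expect_identical(h$status, "constant")
  expect_equal(h$bin_edges, c(41.5, 42.5))
  expect_identical(h$counts, 10L)
  expect_error(build_histogram(numeric(0)), "empty")
  expect_error(build_histogram(c(1, NA)), "finite")
})

test_that("gap threshold is the upper edge of the first empty bin from the dark end", {
  # counts (5,3,1,0,0,7,9) over unit bins starting at 0: first empty is
  # bin 4, upper edge 4.0
  x <- c(0, rep(0.5, 4), rep(1.5, 3), 2.5, rep(5.5, 7), rep(6.3, 8), 7.0)
  h <- build_histogram(x, nbins = 7L)
  expect_identical(h$counts, c(5L, 3L, 1L, 0L, 0L, 7L, 9L))
  g <- find_gap_threshold(h)
  expect_identical(g$status, "ok")
  expect_equal(g$threshold, 4.0)
  expect_identical(g$gap_bin, 4L)
  expect_equal(g$threshold, oracle_first_empty_bin(h$counts, h$bin_edges))
})

test_that("a leading empty bin and a gapless histogram are both handled", {
  # value range [0,3], 3 bins; nothing in [0,1): threshold is that bin's
  # upper edge even though it precedes all mass... construct via explicit
  # histogram object to pin the semantics
  h <- structure(list(bin_edges = c(0, 1, 2, 3),
                      counts = c(0L, 4L, 4L), status = "ok"),
                 class = "intensity_histogram")
  g <- find_gap_threshold(h)
  expect_equal(g$threshold, 1)
  expect_identical(g$gap_bin, 1L)

  hfull <- build_histogram(c(0.5, 1.5, 2.5), nbins = 3L)
  gfull <- find_gap_threshold(hfull)
  expect_identical(gfull$status, "no_gap_found")
  expect_identical(gfull$threshold, Inf)
  expect_true(is.na(gfull$gap_bin))
})

test_that("random histograms agree with the first-empty-bin oracle", {
  set.seed(22)
  for (i in 1:50) {
    counts <- as.integer(rpois(20, lambda = runif(1, 0.3, 3)))
    h <- structure(list(bin_edges = seq(0, 20), counts = counts,
                        status = "ok"),
                   class = "intensity_histogram")
    g <- find_gap_threshold(h)
    expect_equal(g$threshold, oracle_first_empty_bin(counts, h$bin_edges))
  }
})

test_that("candidate extraction keeps strictly-above-threshold voxels and labels components", {
  a <- array(0, c(12, 12, 12))
  a[2:4, 2:4, 2:4] <- 100      # cube 1: 27 voxels
  a[8:10, 8:10, 8:10] <- 100   # cube 2: 27 voxels, disjoint
  a[6, 6, 6] <- 50             # exactly at threshold: excluded
  v <- flair_volume(a)
  nb <- flair_mask(a > 0, parent = v)
  cs <- extract_candidates(v, nb, threshold = 50)
  expect_identical(nrow(cs$components), 2L)
  expect_identical(sort(cs$components$n_voxels), c(27L, 27L))
  expect_equal(cs$components$volume_mm3, cs$components$n_voxels * 1.0)
  expect_true(all(cs$label_map[a <= 50] == 0L))

  # Inf threshold (no gap) gives an empty set
  cs0 <- extract_candidates(v, nb, threshold = Inf, status = "no_gap_found")
  expect_identical(nrow(cs0$components), 0L)
  expect_true(all(cs0$label_map == 0L))
  expect_identical(cs0$status, "no_gap_found")
})

test_that("connectivity controls whether diagonal voxels join", {
  a <- array(0, c(5, 5, 5))
  a[2, 2, 2] <- 10
  a[3, 3, 3] <- 10  # corner-adjacent
  v <- flair_volume(a)
  nb <- flair_mask(a > 0, parent = v)
  expect_identical(nrow(extract_candidates(v, nb, 1, connectivity = 26L)$components), 1L)
  expect_identical(nrow(extract_candidates(v, nb, 1, connectivity = 6L)$components), 2L)
  # 18-connectivity: corner (3-axis offset) still separate, edge joins
  expect_identical(nrow(extract_candidates(v, nb, 1, connectivity = 18L)$components), 2L)
  a2 <- array(0, c(5, 5, 5)); a2[2, 2, 2] <- 10; a2[3, 3, 2] <- 10
  v2 <- flair_volume(a2)
  expect_identical(
    nrow(extract_candidates(v2, flair_mask(a2 > 0, parent = v2), 1,
                            connectivity = 18L)$components), 1L)
})

test_that("component labels exactly partition the candidate voxels", {
  set.seed(23)
  a <- array(rbinom(17^3, 1, 0.2) * 10, c(17, 17, 17))
  v <- flair_volume(a)
  nb <- flair_mask(a > 0, parent = v)
  cs <- extract_candidates(v, nb, threshold = 5)
  expect_identical(sum(cs$components$n_voxels), sum(a > 5))
  # ids are dense 1..C and sizes match the label map
  expect_identical(cs$components$id, seq_len(nrow(cs$components)))
  tab <- tabulate(cs$label_map[cs$label_map > 0L], nbins = nrow(cs$components))
  expect_identical(tab, cs$components$n_voxels)
  # every component is internally connected: relabeling it alone yields 1
  for (id in sample(cs$components$id, min(5, nrow(cs$components))))
    expect_identical(flairlv:::label_components(cs$label_map == id, 26L)$n, 1L)
})
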