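# build a lesion_components object from a plain intensity array
cset_from_array <- function(a, threshold = 0, voxel_dims = c(1, 1, 1)) {
  v <- flair_volume(a, voxel_dims = voxel_dims)
  extract_candidates(v, flair_mask(a > threshold, parent = v), threshold)
}

test_that("registering a mask to itself returns the identity transform", {
  ph <- generate_phantom(small_spec())
  m <- ph$truth$brain_mask
  t <- register_affine(m, m)
  expect_lt(max(abs(t$matrix - diag(4))), 1e-6)
})

test_that("registration recovers a pure translation between masks", {
  ph <- generate_phantom(small_spec())
  m <- ph$truth$brain_mask
  shifted <- m
  shifted$affine <- m$affine
  shifted$affine[1:3, 4] <- m$affine[1:3, 4] + c(5, -3, 2)
  t <- register_affine(shifted, m)
  expect_lt(max(abs(t$matrix[1:3, 1:3] - diag(3))), 1e-6)
  expect_lt(max(abs(t$matrix[1:3, 4] - c(5, -3, 2))), 0.5)
})

test_that("registration recovers an isotropic scale difference", {
  ph <- generate_phantom(small_spec())
  m <- ph$truth$brain_mask
  grown <- m
  grown$affine <- m$affine %*% diag(c(1.1, 1.1, 1.1, 1))
  grown$voxel_dims <- m$voxel_dims * 1.1
  t <- register_affine(grown, m)
  sc <- diag(t$matrix[1:3, 1:3])
  expect_lt(max(abs(sc - 1.1)) / 1.1, 0.02)
})

test_that("identity resampling reproduces the volume away from the border", {
  set.seed(31)
  v <- flair_volume(array(runif(14^3), c(14, 14, 14)))
  r <- resample_to_subject(v, diag(4), v)
  expect_lt(max(abs(r$data - v$data)), 1e-10)
  # constant volume resamples to the constant under a small translation
  cv <- flair_volume(array(2, c(14, 14, 14)))
  tr <- diag(4); tr[1:3, 4] <- c(0.3, -0.2, 0.4)
  rc <- resample_to_subject(cv, tr, cv)
  interior <- array(FALSE, c(14, 14, 14))
  interior[3:12, 3:12, 3:12] <- TRUE
  expect_lt(max(abs(rc$data[interior] - 2)), 1e-10)
})

test_that("trilinear resampling of a step edge gives 0.5 at half-voxel shift", {
  a <- array(0, c(10, 10, 10)); a[6:10, , ] <- 1
  v <- flair_volume(a)
  tr <- diag(4); tr[1, 4] <- 0.5   # shift atlas +x by half a voxel
  r <- resample_to_subject(v, tr, v)
  expect_equal(r$data[6, 5, 5], 0.5, tolerance = 1e-10)
  expect_equal(r$data[8, 5, 5], 1, tolerance = 1e-10)
  expect_equal(r$data[3, 5, 5], 0, tolerance = 1e-10)
})

test_that("WM mask threshold is strict and rejects out-of-range probabilities", {
  p <- array(0, c(3, 3, 3))
  p[1, 1, 1] <- 0.70
  p[2, 1, 1] <- 0.71
  wm <- make_wm_mask(flair_volume(p), threshold = 0.7)
  expect_false(wm$data[1, 1, 1])
  expect_true(wm$data[2, 1, 1])
  expect_error(make_wm_mask(flair_volume(array(1.5, c(3, 3, 3)))),
               "outside")
})

test_that("one WM voxel retains the whole component; zero removes it whole", {
  a <- array(0, c(12, 12, 12))
  a[2:6, 2:3, 2:6] <- 10   # 50-voxel slab, component A
  a[9:11, 9:11, 9:11] <- 10  # 27-voxel cube, component B
  cs <- cset_from_array(a)
  wm_arr <- array(FALSE, c(12, 12, 12))
  wm_arr[2, 2, 2] <- TRUE  # exactly one voxel of A; none of B
  wm <- flair_mask(wm_arr, voxel_dims = c(1, 1, 1), affine = cs$affine)
  out <- filter_by_wm_overlap(cs, wm)
  expect_identical(nrow(out$components), 1L)
  expect_identical(out$components$n_voxels, 50L)   # retained whole
  expect_identical(out$components$wm_overlap, 1)
  expect_true(all(out$label_map[a == 0] == 0L))
  # empty WM mask removes everything
  none <- flair_mask(array(FALSE, c(12, 12, 12)), voxel_dims = c(1, 1, 1),
                     affine = cs$affine)
  expect_identical(nrow(filter_by_wm_overlap(cs, none)$components), 0L)
})

test_that("a midline sheet is removed entirely", {
  a <- array(0, c(20, 20, 20))
  a[10:11, 5:15, 5:15] <- 10  # thin sheet straddling x = 10 (0-based 9-10)
  cs <- cset_from_array(a)
  plane <- list(point = c(9.5, 0, 0), normal = c(1, 0, 0))
  out <- midline_filter(cs, plane, touch_mm = 4, truncate_mm = 9)
  expect_identical(nrow(out$components), 0L)
  expect_true(all(out$label_map == 0L))
})

test_that("a component spanning past the truncation distance is cut, not deleted", {
  a <- array(0, c(30, 20, 20))
  a[11:25, 8:12, 8:12] <- 10  # touches x=10 (0-based 10..24): spans 0..14 mm
  cs <- cset_from_array(a)
  plane <- list(point = c(10, 0, 0), normal = c(1, 0, 0))
  out <- midline_filter(cs, plane, touch_mm = 4, truncate_mm = 9)
  expect_identical(nrow(out$components), 1L)
  # removal is inclusive at 9 mm: voxels at 0-based x in [10, 19] go,
  # x in [20, 24] survive -> 5 x 5 x 5
  expect_identical(out$components$n_voxels, 125L)
  lin <- which(out$label_map > 0L)
  ijk <- flairlv:::linear_to_ijk(lin, dim(out$label_map))
  expect_true(all(ijk[, 1] >= 20))
})

test_that("a component clear of the touch distance is untouched even inside truncate range", {
  a <- array(0, c(30, 20, 20))
  a[16:18, 8:12, 8:12] <- 10  # 0-based x 15..17: min distance 5 mm > 4
  cs <- cset_from_array(a)
  plane <- list(point = c(10, 0, 0), normal = c(1, 0, 0))
  out <- midline_filter(cs, plane, touch_mm = 4, truncate_mm = 9)
  expect_identical(out$components$n_voxels, cs$components$n_voxels)
  expect_identical(out$label_map, cs$label_map)
})

test_that("both filters are idempotent", {
  ph <- generate_phantom(small_spec(lesions = small_lesions(),
                                    noise_sd = 0))
  a <- ph$volume$data
  v <- ph$volume
  cs <- extract_candidates(v, flair_mask(a > 100, parent = v), 100)
  wm <- flair_mask(ph$truth$wm_mask$data, parent = v)
  f1 <- filter_by_wm_overlap(cs, wm)
  f2 <- filter_by_wm_overlap(f1, wm)
  expect_identical(f1$label_map, f2$label_map)
  plane <- ph$truth$midline_plane
  m1 <- midline_filter(f1, plane)
  m2 <- midline_filter(m1, plane)
  expect_identical(m1$label_map, m2$label_map)
})

test_that("midline removal never reaches beyond the truncation distance", {
  set.seed(32)
  for (rep in 1:5) {
    a <- array(rbinom(16^3, 1, 0.3) * 10, c(16, 16, 16))
    cs <- cset_from_array(a)
    plane <- list(point = c(8, 0, 0), normal = c(1, 0, 0))
    out <- midline_filter(cs, plane, touch_mm = 4, truncate_mm = 9)
    removed <- cs$label_map > 0L & out$label_map == 0L
    if (!any(removed)) next
    ijk <- flairlv:::linear_to_ijk(which(removed), dim(a))
    d <- abs(ijk[, 1] - 8)
    expect_true(all(d <= 9))
  }
})

test_that("the synthetic atlas bundle is internally consistent", {
  at <- synthetic_atlas(shape = c(64L, 64L, 64L))
  expect_s3_class(at, "atlas_bundle")
  expect_true(all(at$wm_prob$data >= 0 & at$wm_prob$data <= 1))
  expect_equal(at$standard_icv, sum(at$brain_mask$data))
  # high-confidence WM stays clear of the ventricles and the midline septum
  wm <- make_wm_mask(at$wm_prob)
  expect_gt(sum(wm$data), 0)
  expect_true(all(!wm$data[at$brain_mask$data == 0]))
})
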