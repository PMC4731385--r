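#' Moments-based affine registration of two binary masks
#'
#' Estimates an atlas-to-subject world-coordinate affine from mask moments:
#' centre-of-mass translation, principal-axes rotation and per-axis scale
#' from the square roots of the second-moment eigenvalues. This is a
#' deliberately simple stand-in for full nonlinear registration — adequate
#' for propagating an atlas WM probability map and midline plane when no
#' externally computed transform or subject-space map is supplied.
#'
#' @param subject_mask,atlas_mask nonempty [flair_mask()] objects.
#' @return Object of class `affine_transform`: `matrix` (4x4 world-mm
#'   atlas-to-subject map).
#' @export
register_affine <- function(subject_mask, atlas_mask) {
  mom <- function(m) {
    lin <- which(m$data)
    if (length(lin) == 0) stop("empty mask")
    ijk <- linear_to_ijk(lin, dim(m$data))
    xyz <- voxel_to_world(m$affine, ijk)
    mu <- colMeans(xyz)
    C <- stats::cov(xyz)
    e <- eigen(C, symmetric = TRUE)
    if (any(e$values < 1e-8 * max(e$values)))
      stop("degenerate mask: second moments are rank deficient")
    V <- e$vectors
    # deterministic sign: each axis points along its dominant world direction
    for (j in 1:3) {
      s <- V[which.max(abs(V[, j])), j]
      if (s < 0) V[, j] <- -V[, j]
    }
    if (det(V) < 0) V[, 3] <- -V[, 3]
    list(mu = mu, V = V, l = e$values)
  }
  s <- mom(subject_mask)
  a <- mom(atlas_mask)
  A <- s$V %*% diag(sqrt(s$l / a$l)) %*% t(a$V)
  t4 <- diag(4)
  t4[1:3, 1:3] <- A
  t4[1:3, 4] <- s$mu - A %*% a$mu
  structure(list(matrix = t4), class = "affine_transform")
}

#' Resample a volume onto a subject grid through an affine
#'
#' Trilinear interpolation of `map` onto the grid of `target`, mapping each
#' target voxel centre to world mm, through the inverse of the
#' atlas-to-subject transform, into the map's voxel coordinates. Points
#' outside the map's field of view get 0.
#'
#' @param map a [flair_volume()] in atlas space.
#' @param t an [register_affine()] transform (atlas world to subject world),
#'   or a 4x4 matrix.
#' @param target a [flair_volume()] or [flair_mask()] defining the output
#'   grid.
#' @return A [flair_volume()] on the target grid.
#' @export
resample_to_subject <- function(map, t, target) {
  tm <- if (inherits(t, "affine_transform")) t$matrix else as.matrix(t)
  if (abs(det(tm)) < 1e-12) stop("non-invertible transform")
  d <- dim(target$data)
  n <- prod(d)
  ijk <- linear_to_ijk(seq_len(n), d)
  # subject voxel -> subject world -> atlas world -> atlas voxel
  M <- solve(map$affine) %*% solve(tm) %*% target$affine
  src <- t(M %*% t(cbind(ijk, 1)))[, 1:3, drop = FALSE]
  md <- dim(map$data)
  x <- src[, 1]; y <- src[, 2]; z <- src[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(n)
  # corner gather with zero outside the field of view
  corner <- function(cx, cy, cz) {
    ok <- cx >= 0 & cx <= md[1] - 1 & cy >= 0 & cy <= md[2] - 1 &
      cz >= 0 & cz <= md[3] - 1
    val <- numeric(n)
    lin <- cx[ok] + md[1] * (cy[ok] + md[2] * cz[ok]) + 1
    val[ok] <- map$data[lin]
    val
  }
  out <- corner(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    corner(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    corner(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    corner(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    corner(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    corner(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    corner(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    corner(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  flair_volume(array(out, d), voxel_dims = target$voxel_dims,
               affine = target$affine)
}

#' Threshold a WM probability map into a mask
#'
#' Voxels with WM probability strictly above the threshold are included.
#'
#' @param wm_prob_subject [flair_volume()] with values in `[0, 1]`.
#' @param threshold probability cut (default 0.7, strict `>`).
#' @return A [flair_mask()].
#' @export
make_wm_mask <- function(wm_prob_subject, threshold = 0.7) {
  x <- wm_prob_subject$data
  if (min(x) < -1e-6 || max(x) > 1 + 1e-6)
    stop("WM probability values outside [0, 1]")
  flair_mask(x > threshold, parent = wm_prob_subject)
}

#' Keep lesion components overlapping the white-matter mask
#'
#' A component with at least one voxel inside the WM mask is retained
#' whole; components entirely outside are removed whole. This eliminates
#' false positives outside the white matter (peripheral and midbrain gray
#' matter structures that are consistently bright).
#'
#' @param cset a [extract_candidates()] result.
#' @param wm a WM [flair_mask()] on the same grid.
#' @return A filtered `lesion_components` object with dense ids; component
#'   table gains a `wm_overlap` voxel count.
#' @export
filter_by_wm_overlap <- function(cset, wm) {
  stopifnot(inherits(cset, "lesion_components"))
  if (!all(dim(cset$label_map) == dim(wm$data)))
    stop("shape mismatch between components and WM mask")
  nc <- nrow(cset$components)
  if (nc == 0L) return(cset)
  ids <- cset$label_map[cset$label_map > 0L]
  inwm <- wm$data[cset$label_map > 0L]
  overlap <- vapply(seq_len(nc), function(i) sum(inwm[ids == i]), numeric(1))
  keep_ids <- which(overlap >= 1)
  keep_mask <- array(cset$label_map %in% keep_ids & cset$label_map > 0L,
                     dim(cset$label_map))
  out <- relabel_components(cset, keep_mask)
  # components survive whole, so sizes map 1:1 onto kept ids
  if (nrow(out$components) > 0)
    out$components$wm_overlap <- vapply(seq_len(nrow(out$components)),
      function(i) sum(wm$data[out$label_map == i]), numeric(1))
  out
}

#' Remove midline false positives
#'
#' Bright midline structures (septum pellucidum, midbrain) mimic lesions.
#' Any component whose minimum unsigned perpendicular distance to the
#' mid-sagittal plane is within `touch_mm` (inclusive) is flagged; its
#' voxels at distance `<= truncate_mm` from the plane are removed, while
#' voxels farther out are kept — so periventricular lesions contiguous with
#' the septum survive beyond the truncation distance. Surviving voxels are
#' relabeled into components.
#'
#' @param cset a `lesion_components` object.
#' @param midline_plane list with `point` (length-3 world mm) and `normal`
#'   (length-3, will be normalized).
#' @param touch_mm distance within which a component counts as touching the
#'   midline (default 4, inclusive).
#' @param truncate_mm maximum distance from the midline at which removal is
#'   applied (default 9, inclusive); must be >= `touch_mm`.
#' @return A filtered `lesion_components` object.
#' @export
midline_filter <- function(cset, midline_plane, touch_mm = 4,
                           truncate_mm = 9) {
  stopifnot(inherits(cset, "lesion_components"), touch_mm <= truncate_mm)
  nc <- nrow(cset$components)
  if (nc == 0L) return(cset)
  nrm <- midline_plane$normal / sqrt(sum(midline_plane$normal^2))
  lin <- which(cset$label_map > 0L)
  ijk <- linear_to_ijk(lin, dim(cset$label_map))
  xyz <- voxel_to_world(cset$affine, ijk)
  dist <- abs((xyz[, 1] - midline_plane$point[1]) * nrm[1] +
              (xyz[, 2] - midline_plane$point[2]) * nrm[2] +
              (xyz[, 3] - midline_plane$point[3]) * nrm[3])
  ids <- cset$label_map[lin]
  min_dist <- vapply(seq_len(nc), function(i) min(dist[ids == i]),
                     numeric(1))
  flagged <- min_dist <= touch_mm
  drop <- flagged[ids] & dist <= truncate_mm
  keep_mask <- array(FALSE, dim(cset$label_map))
  keep_mask[lin[!drop]] <- TRUE
  relabel_components(cset, keep_mask)
}

#' FLAIR-like reference from standard-space T2 and CSF masks
#'
#' Subtracts the CSF mask/probability from the T2 standard image and clips
#' at zero, giving a reference whose fluid signal is suppressed like FLAIR.
#'
#' @param t2_standard,csf_mask [flair_volume()] objects on the same grid
#'   (`csf_mask` may be a [flair_mask()]).
#' @return A [flair_volume()].
#' @export
make_flair_like_reference <- function(t2_standard, csf_mask) {
  stopifnot_same_grid(t2_standard, csf_mask)
  csf <- if (is.logical(csf_mask$data))
    array(as.numeric(csf_mask$data) * max(t2_standard$data), dim(csf_mask$data))
  else csf_mask$data
  out <- t2_standard
  out$data <- pmax(t2_standard$data - csf, 0)
  out
}

#' Synthetic standard-space atlas
#'
#' A self-contained, synthetic substitute for a standard-space atlas bundle:
#' built from the lesion-free default phantom, it provides a brain mask, a
#' smoothed WM probability map, a FLAIR-like reference, the mid-sagittal
#' plane and a standard intracranial volume. It exists so the pipeline and
#' its tests run without any external atlas download; users with real
#' standard-space maps should supply those instead.
#'
#' @param shape grid shape (default `c(96, 96, 96)`).
#' @param voxel_dims voxel size mm (default 1 mm isotropic).
#' @return List of class `atlas_bundle`: `brain_mask`, `wm_prob`
#'   ([flair_volume()], values in `[0, 1]`), `flair_like`
#'   ([flair_volume()]), `midline_plane` (`point`, `normal`, world mm),
#'   `standard_icv` (mm^3).
#' @export
synthetic_atlas <- function(shape = c(96L, 96L, 96L),
                            voxel_dims = c(1, 1, 1)) {
  spec <- phantom_spec(shape = shape, voxel_dims = voxel_dims,
                       lesions = list(), noise_sd = 0, seed = 1L)
  ph <- generate_phantom(spec)
  # the high-confidence (> 0.7) region of a standard-space WM probability
  # map sits well inside the anatomical WM boundary; erode before
  # smoothing so the synthetic map has the same interior margin
  wmm <- ph$truth$wm_mask$data
  wmm <- binary_erode(binary_erode(wmm, connectivity = 6),
                      connectivity = 6)
  wm <- flair_volume(array(as.numeric(wmm), shape),
                     voxel_dims = voxel_dims, affine = ph$volume$affine)
  wm <- gaussian_smooth(wm, sigma_mm = 1)
  wm$data <- pmin(pmax(wm$data, 0), 1)
  icv <- sum(ph$truth$brain_mask$data) * prod(voxel_dims)
  structure(list(brain_mask = ph$truth$brain_mask,
                 wm_prob = wm,
                 flair_like = ph$volume,
                 midline_plane = ph$truth$midline_plane,
                 standard_icv = icv),
            class = "atlas_bundle")
}

# map a plane (point, normal) in atlas world coordinates through an
# atlas->subject affine
transform_plane <- function(plane, t) {
  tm <- if (inherits(t, "affine_transform")) t$matrix else as.matrix(t)
  A <- tm[1:3, 1:3]
  p <- as.numeric(A %*% plane$point + tm[1:3, 4])
  n <- as.numeric(solve(t(A)) %*% plane$normal)
  list(point = p, normal = n / sqrt(sum(n^2)))
}
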