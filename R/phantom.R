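#' Synthetic FLAIR phantom specification
#'
#' Describes a brain-extracted FLAIR-like test volume: an ellipsoidal brain
#' with a gray-matter shell over a white-matter core, two mirrored
#' ventricles of dark CSF, a bright septum-like mid-sagittal sheet between
#' them, optional hyperintense lesions, and additive Gaussian noise. The
#' default intensity palette (CSF 20, WM 55, GM 70, septum 120, lesion 130)
#' keeps the FLAIR ordering CSF < WM < GM << lesion and leaves an empty-bin
#' gap between CSF and hyperintensities in the nonbrain histogram at the
#' default binning and noise level.
#'
#' Lesions are given as offsets from the brain centre in mm: spheres as
#' `list(center = c(x, y, z), radius = r)`, boxes as
#' `list(box = rbind(lo, hi))` with `lo`/`hi` mm offsets. The mid-sagittal
#' plane of the phantom is exactly the world plane through the brain centre
#' with normal along +x, so midline-filter geometry is analytically known.
#'
#' @param shape grid shape (default `c(96, 96, 96)`).
#' @param voxel_dims voxel size in mm (default 1 mm isotropic).
#' @param brain_semi_axes ellipsoid semi-axes in mm (default
#'   `c(38, 44, 36)`).
#' @param csf_rim_thickness_mm thickness of the sulcal-CSF layer at the
#'   brain surface (default 2); brain-extracted FLAIR retains this dark
#'   fluid rim, which together with the ventricles gives the CSF class the
#'   share of voxels a real extraction produces.
#' @param gm_shell_thickness_mm cortical shell thickness (default 3).
#' @param ventricle_offset_mm centre offset of the right ventricle from the
#'   brain centre (mirrored in x for the left; default `c(10, 6, 2)`).
#' @param ventricle_semi_axes ventricle semi-axes mm (default
#'   `c(5.5, 14, 9)`).
#' @param septum_half_thickness_mm half-thickness of the midline sheet
#'   (default 1.5); `0` removes the septum.
#' @param septum_offset_mm lateral (x) displacement of the septum sheet from
#'   the midline (default 0); positive values emulate ventricular
#'   enlargement pushing midline structures away from the plane.
#' @param lesions list of sphere/box descriptors (see above); default none.
#' @param palette named intensities `csf`, `wm`, `gm`, `septum`, `lesion`.
#' @param noise_sd additive Gaussian noise sd inside the brain (default 4).
#' @param seed integer RNG seed (default 1).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L),
                         voxel_dims = c(1, 1, 1),
                         brain_semi_axes = c(38, 44, 36),
                         csf_rim_thickness_mm = 2,
                         gm_shell_thickness_mm = 3,
                         ventricle_offset_mm = c(10, 6, 2),
                         ventricle_semi_axes = c(5.5, 14, 9),
                         septum_half_thickness_mm = 1.5,
                         septum_offset_mm = 0,
                         lesions = list(),
                         palette = c(csf = 20, wm = 55, gm = 70,
                                     septum = 120, lesion = 130),
                         noise_sd = 4,
                         seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 16),
            all(voxel_dims > 0), all(brain_semi_axes > 0),
            gm_shell_thickness_mm > 0, csf_rim_thickness_mm >= 0,
            all(brain_semi_axes > gm_shell_thickness_mm +
                  csf_rim_thickness_mm),
            all(ventricle_semi_axes > 0),
            septum_half_thickness_mm >= 0, noise_sd >= 0)
  pal <- palette
  if (!(pal["csf"] < pal["wm"] && pal["wm"] < pal["gm"] &&
        pal["gm"] < pal["lesion"]))
    stop("palette must satisfy csf < wm < gm < lesion")
  structure(list(shape = as.integer(shape), voxel_dims = voxel_dims,
                 brain_semi_axes = brain_semi_axes,
                 csf_rim_thickness_mm = csf_rim_thickness_mm,
                 gm_shell_thickness_mm = gm_shell_thickness_mm,
                 ventricle_offset_mm = ventricle_offset_mm,
                 ventricle_semi_axes = ventricle_semi_axes,
                 septum_half_thickness_mm = septum_half_thickness_mm,
                 septum_offset_mm = septum_offset_mm,
                 lesions = lesions, palette = pal,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default deep-white-matter lesion set
#'
#' Four spheres of radius 5.3 mm in deep white matter, all well clear of
#' the midline band, totalling close to 1% of brain tissue volume on the
#' default phantom geometry.
#'
#' @return A list of lesion descriptors for [phantom_spec()].
#' @export
default_lesion_set <- function() {
  list(list(center = c(-20, -10, 0), radius = 5.3),
       list(center = c(19, -14, 3), radius = 5.3),
       list(center = c(-17, 16, -9), radius = 5.3),
       list(center = c(21, 12, -4), radius = 5.3))
}

#' Generate a synthetic FLAIR phantom
#'
#' Deterministic given the spec's seed (bit-identical regeneration).
#' Intensities are the palette value of each region plus Gaussian noise
#' inside the brain; background is exactly 0.
#'
#' @param spec a [phantom_spec()].
#' @return List: `volume` ([flair_volume()]), `truth` (list with
#'   `brain_mask`, `wm_mask`, `gm_mask`, `csf_mask`, `lesion_mask`,
#'   `septum_mask`, `midline_plane`, `true_lesion_volume_mm3`,
#'   `true_t2lv_percent`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  vd <- spec$voxel_dims
  affine <- diag(c(vd, 1))
  cx <- (d - 1) * vd / 2  # brain centre, world mm
  xs <- (seq_len(d[1]) - 1) * vd[1]
  ys <- (seq_len(d[2]) - 1) * vd[2]
  zs <- (seq_len(d[3]) - 1) * vd[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  inside_ellipsoid <- function(centre, semi) {
    ((X - centre[1]) / semi[1])^2 + ((Y - centre[2]) / semi[2])^2 +
      ((Z - centre[3]) / semi[3])^2 <= 1
  }
  brain <- inside_ellipsoid(cx, spec$brain_semi_axes)
  below_rim <- inside_ellipsoid(cx, spec$brain_semi_axes -
                                  spec$csf_rim_thickness_mm)
  inner <- inside_ellipsoid(cx, spec$brain_semi_axes -
                              spec$csf_rim_thickness_mm -
                              spec$gm_shell_thickness_mm)
  vent_r <- inside_ellipsoid(cx + spec$ventricle_offset_mm,
                             spec$ventricle_semi_axes)
  vent_l <- inside_ellipsoid(cx + spec$ventricle_offset_mm * c(-1, 1, 1),
                             spec$ventricle_semi_axes)
  vent <- (vent_r | vent_l) & inner

  septum <- array(FALSE, d)
  if (spec$septum_half_thickness_mm > 0) {
    vo <- spec$ventricle_offset_mm
    vs <- spec$ventricle_semi_axes
    septum <- abs(X - cx[1] - spec$septum_offset_mm) <=
      spec$septum_half_thickness_mm &
      abs(Y - cx[2] - vo[2]) <= vs[2] - 2 &
      abs(Z - cx[3] - vo[3]) <= vs[3] - 2 &
      inner
  }

  lesion <- array(FALSE, d)
  for (L in spec$lesions) {
    if (!is.null(L$center)) {
      reg <- ((X - cx[1] - L$center[1])^2 + (Y - cx[2] - L$center[2])^2 +
                (Z - cx[3] - L$center[3])^2) <= L$radius^2
    } else if (!is.null(L$box)) {
      lo <- L$box[1, ]; hi <- L$box[2, ]
      reg <- X >= cx[1] + lo[1] & X <= cx[1] + hi[1] &
        Y >= cx[2] + lo[2] & Y <= cx[2] + hi[2] &
        Z >= cx[3] + lo[3] & Z <= cx[3] + hi[3]
    } else stop("lesion descriptor needs 'center' or 'box'")
    if (any(reg & !brain))
      stop("lesion extends outside the brain ellipsoid")
    lesion <- lesion | reg
  }

  # class priority: lesion > septum > CSF (rim + ventricles) > WM > GM
  gm <- below_rim & !inner
  wm <- inner & !vent
  csf <- vent | (brain & !below_rim)
  septum <- septum & !lesion
  csf <- csf & !septum & !lesion
  wm <- wm & !septum & !lesion
  gm <- gm & !lesion

  pal <- spec$palette
  img <- array(0, d)
  img[gm] <- pal["gm"]
  img[wm] <- pal["wm"]
  img[csf] <- pal["csf"]
  img[septum] <- pal["septum"]
  img[lesion] <- pal["lesion"]

  if (spec$noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(spec$seed)
    img[brain] <- img[brain] + stats::rnorm(sum(brain), 0, spec$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  vol <- flair_volume(img, voxel_dims = vd, affine = affine)
  vv <- prod(vd)
  n_tissue <- sum(wm) + sum(gm) + sum(lesion)
  truth <- list(
    brain_mask = flair_mask(brain, parent = vol),
    wm_mask = flair_mask(wm, parent = vol),
    gm_mask = flair_mask(gm, parent = vol),
    csf_mask = flair_mask(csf, parent = vol),
    lesion_mask = flair_mask(lesion, parent = vol),
    septum_mask = flair_mask(septum, parent = vol),
    midline_plane = list(point = cx, normal = c(1, 0, 0)),
    true_lesion_volume_mm3 = sum(lesion) * vv,
    true_t2lv_percent = if (n_tissue > 0) 100 * sum(lesion) / n_tissue else 0
  )
  list(volume = vol, truth = truth)
}

#' Named phantom scenarios used by the validation tests
#'
#' Each scenario pairs a [phantom_spec()] with the qualitative outcome the
#' pipeline is expected to produce on it, including the documented failure
#' mode where a laterally displaced septum (emulating severe ventricular
#' enlargement) escapes the midline filter.
#'
#' @param noise_sd noise level applied to every scenario (default 4).
#' @param seed base RNG seed (default 1).
#' @return Named list of scenarios, each
#'   `list(name, spec, expect = list(...))`.
#' @export
default_validation_suite <- function(noise_sd = 4, seed = 1L) {
  base <- function(...) phantom_spec(noise_sd = noise_sd, seed = seed, ...)
  list(
    lesion_free = list(
      name = "lesion_free",
      spec = base(lesions = list()),
      expect = list(t2lv_percent = 0, n_final = 0)),
    deep_wm = list(
      name = "deep_wm",
      spec = base(lesions = default_lesion_set()[1]),
      expect = list(n_final = 1, t2lv_positive = TRUE)),
    periventricular = list(
      name = "periventricular",
      spec = base(lesions = list(list(
        box = rbind(c(1, -10, -4), c(12, 8, 4))))),
      expect = list(surviving_beyond_mm = 9)),
    septum_only = list(
      name = "septum_only",
      spec = base(lesions = list(), septum_half_thickness_mm = 2),
      expect = list(n_final = 0)),
    enlarged_ventricles = list(
      name = "enlarged_ventricles",
      spec = base(lesions = list(), septum_offset_mm = 6.5,
                  ventricle_semi_axes = c(7.5, 16, 10)),
      expect = list(midline_filter_escapes = TRUE)),
    default_load = list(
      name = "default_load",
      spec = base(lesions = default_lesion_set()),
      expect = list(t2lv_near_percent = 1.0))
  )
}
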