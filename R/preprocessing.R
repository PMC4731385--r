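#' Pipeline configuration
#'
#' Collects every tunable parameter of the lesion-mapping pipeline. Distance
#' parameters are in mm and are converted to voxels per axis using the
#' image's voxel dimensions, so defaults behave identically on anisotropic
#' grids.
#'
#' @param smoothing_sigma_mm Gaussian blur applied to the brain-extracted
#'   image before segmentation, in mm (default 0.5); 0 disables smoothing.
#' @param wm_prob_threshold white-matter probability above which a voxel
#'   joins the WM mask (strict `>`, default 0.7).
#' @param midline_touch_mm a lesion component whose nearest voxel lies
#'   within this distance of the mid-sagittal plane is treated as a midline
#'   false positive (inclusive, default 4 mm).
#' @param midline_max_removal_mm removal of a flagged component is truncated
#'   at this distance from the midline; voxels farther out are kept
#'   (inclusive removal band, default 9 mm). Must be >= `midline_touch_mm`.
#' @param histogram_bins number of equal-width bins for the nonbrain
#'   intensity histogram used by the gap-threshold search (default 32).
#'   The bin width must be comparable to the noise sd of the dark (CSF)
#'   class: much finer binning lets the sparse lower tail of the CSF
#'   distribution produce a spurious empty bin below the CSF mode, which
#'   stops the darkest-bin scan before any CSF has been removed.
#' @param connectivity 3D connectivity for lesion components: 6, 18 or 26
#'   (default 26).
#' @param bright_outlier_z voxels brighter than
#'   `mean_GM + bright_outlier_z * sd_GM` are captured into the nonbrain
#'   class (default 3.5).
#' @param outlier_sd standard-deviation multiple for the statistical outlier
#'   rule (default 3).
#' @param brain_mask_factor fallback brain-mask threshold as a fraction of
#'   the median nonzero intensity (default 0.3).
#' @param gmm_tol relative log-likelihood convergence tolerance for the EM
#'   fit (default 1e-6).
#' @param gmm_max_iter maximum EM iterations (default 500).
#' @param gmm_max_samples intensities are subsampled (seeded) to at most
#'   this many voxels before the EM fit (default 200000).
#' @param rng_seed integer seed controlling every stochastic step
#'   (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(smoothing_sigma_mm = 0.5,
                            wm_prob_threshold = 0.7,
                            midline_touch_mm = 4,
                            midline_max_removal_mm = 9,
                            histogram_bins = 32L,
                            connectivity = 26L,
                            bright_outlier_z = 3.5,
                            outlier_sd = 3,
                            brain_mask_factor = 0.3,
                            gmm_tol = 1e-6,
                            gmm_max_iter = 500L,
                            gmm_max_samples = 200000L,
                            rng_seed = 1L) {
  stopifnot(smoothing_sigma_mm >= 0,
            wm_prob_threshold > 0, wm_prob_threshold < 1,
            midline_touch_mm >= 0,
            midline_max_removal_mm >= midline_touch_mm,
            histogram_bins >= 16,
            connectivity %in% c(6, 18, 26),
            bright_outlier_z > 0, outlier_sd > 0,
            brain_mask_factor > 0)
  structure(list(
    smoothing_sigma_mm = smoothing_sigma_mm,
    wm_prob_threshold = wm_prob_threshold,
    midline_touch_mm = midline_touch_mm,
    midline_max_removal_mm = midline_max_removal_mm,
    histogram_bins = as.integer(histogram_bins),
    connectivity = as.integer(connectivity),
    bright_outlier_z = bright_outlier_z,
    outlier_sd = outlier_sd,
    brain_mask_factor = brain_mask_factor,
    gmm_tol = gmm_tol,
    gmm_max_iter = as.integer(gmm_max_iter),
    gmm_max_samples = as.integer(gmm_max_samples),
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

#' Estimate a brain mask from a FLAIR image
#'
#' A simple intensity-based stand-in for dedicated brain extraction: voxels
#' above `factor` times the median nonzero intensity are kept, the mask is
#' closed morphologically, reduced to its largest 26-connected component,
#' and interior cavities are filled. Intended for images whose background is
#' already near zero (e.g. already brain-extracted input, or phantoms); for
#' raw clinical scans, supply a mask from a dedicated extraction tool
#' instead.
#'
#' @param v a [flair_volume()].
#' @param factor threshold as a fraction of the median nonzero intensity
#'   (default 0.3).
#' @return A [flair_mask()].
#' @export
estimate_brain_mask <- function(v, factor = 0.3) {
  stopifnot(inherits(v, "flair_volume"))
  nz <- v$data[v$data > 0]
  if (length(nz) == 0) stop("no brain found: image is all zero")
  thr <- factor * stats::median(nz)
  m <- v$data > thr
  if (!any(m)) stop("no brain found: no voxels above threshold")
  m <- binary_close(m, connectivity = 26)
  lab <- label_components(m, connectivity = 26)
  keep <- which.max(lab$sizes)
  m <- lab$labels == keep
  m <- fill_holes(m)
  flair_mask(m, parent = v)
}

#' Apply a brain mask to a volume
#'
#' Voxels outside the mask are set to 0; voxels inside are unchanged.
#'
#' @param v a [flair_volume()].
#' @param m a [flair_mask()] on the same grid.
#' @return A masked [flair_volume()].
#' @export
apply_brain_mask <- function(v, m) {
  stopifnot_same_grid(v, m)
  out <- v
  out$data[!m$data] <- 0
  out
}

#' Gaussian smoothing in millimetres
#'
#' Separable Gaussian convolution with the sigma given in mm, converted to
#' voxels per axis. Boundary handling is reflect (edge-repeating) padding,
#' which preserves intensity near the volume faces. `sigma_mm = 0` returns
#' the input unchanged.
#'
#' @param v a [flair_volume()].
#' @param sigma_mm Gaussian standard deviation in mm (>= 0).
#' @return A smoothed [flair_volume()].
#' @export
gaussian_smooth <- function(v, sigma_mm = 0.5) {
  stopifnot(inherits(v, "flair_volume"))
  if (!is.finite(sigma_mm) || sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(v)
  a <- v$data
  sig_vox <- sigma_mm / v$voxel_dims
  a <- conv_axis1(a, gaussian_kernel_1d(sig_vox[1]))
  a <- aperm(conv_axis1(aperm(a, c(2, 1, 3)),
                        gaussian_kernel_1d(sig_vox[2])), c(2, 1, 3))
  a <- aperm(conv_axis1(aperm(a, c(3, 2, 1)),
                        gaussian_kernel_1d(sig_vox[3])), c(3, 2, 1))
  out <- v
  out$data <- a
  out
}
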