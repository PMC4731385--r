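#' Equal-width intensity histogram
#'
#' Bins span `[min, max]` of the values with the rightmost edge inclusive.
#' Constant input yields a degenerate single bin of width 1 centred on the
#' value, flagged in `status`.
#'
#' @param values nonempty numeric vector.
#' @param nbins number of bins (>= 16 for pipeline use; any >= 1 accepted).
#' @return List of class `intensity_histogram`: `bin_edges` (length
#'   `nbins + 1`), `counts` (length `nbins`), `status` (`"ok"` or
#'   `"constant"`).
#' @export
build_histogram <- function(values, nbins = 256L) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty values")
  if (anyNA(values)) stop("values must be finite")
  nbins <- as.integer(nbins)
  if (nbins < 1L) stop("nbins must be >= 1")
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    return(structure(list(bin_edges = c(lo - 0.5, lo + 0.5),
                          counts = length(values), status = "constant"),
                     class = "intensity_histogram"))
  }
  edges <- seq(lo, hi, length.out = nbins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  structure(list(bin_edges = edges,
                 counts = tabulate(bin, nbins = nbins),
                 status = "ok"),
            class = "intensity_histogram")
}

#' Histogram gap threshold separating CSF from hyperintensities
#'
#' Implements the iterative darkest-bin removal: bins are scanned in
#' ascending intensity order and the first empty bin ends the scan; the
#' threshold is the upper edge of that empty bin, so the empty bin and
#' everything darker is removed and retention is strictly above the
#' threshold. On a nonbrain-class histogram this separates dark CSF from
#' bright lesions, which sit across an empty intensity gap. If every bin is
#' occupied there is no gap: the threshold is `+Inf` (zero lesions
#' downstream) and `status` is `"no_gap_found"`.
#'
#' @param h an [build_histogram()] result.
#' @return List: `threshold` (scalar), `status` (`"ok"` or
#'   `"no_gap_found"`), `gap_bin` (index of the empty bin, `NA` if none).
#' @export
find_gap_threshold <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  empty <- which(h$counts == 0L)
  if (length(empty) == 0L)
    return(list(threshold = Inf, status = "no_gap_found", gap_bin = NA_integer_))
  i <- empty[1L]
  list(threshold = h$bin_edges[i + 1L], status = "ok", gap_bin = i)
}

#' Extract connected lesion candidates
#'
#' Candidate voxels are nonbrain-class voxels with intensity strictly above
#' the gap threshold; they are grouped into connected components at the
#' configured 3D connectivity.
#'
#' @param v brain-masked [flair_volume()] (same image the histogram came
#'   from).
#' @param nonbrain nonbrain-class [flair_mask()].
#' @param threshold gap threshold from [find_gap_threshold()] (`Inf` yields
#'   an empty set).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param status status string carried into the result.
#' @return Object of class `lesion_components`: `label_map` (integer array,
#'   0 = none, ids dense 1..C), `components` (data.frame: `id`, `n_voxels`,
#'   `volume_mm3`), `threshold_used`, `status`, `connectivity`,
#'   `voxel_dims`, `affine`.
#' @export
extract_candidates <- function(v, nonbrain, threshold, connectivity = 26L,
                               status = "ok") {
  stopifnot_same_grid(v, nonbrain)
  cand <- nonbrain$data & (v$data > threshold)
  lab <- label_components(cand, connectivity = connectivity)
  vv <- voxel_volume_mm3(v)
  comps <- data.frame(id = seq_len(lab$n),
                      n_voxels = lab$sizes,
                      volume_mm3 = lab$sizes * vv)
  structure(list(label_map = lab$labels, components = comps,
                 threshold_used = threshold, status = status,
                 connectivity = as.integer(connectivity),
                 voxel_dims = v$voxel_dims, affine = v$affine),
            class = "lesion_components")
}

#' @export
print.lesion_components <- function(x, ...) {
  cat(sprintf("<lesion_components> %d component(s), %d voxel(s), threshold %.4g (%s)\n",
              nrow(x$components), sum(x$components$n_voxels),
              x$threshold_used, x$status))
  invisible(x)
}

# rebuild a lesion_components object from a surviving-voxel mask,
# relabeling components densely
relabel_components <- function(cset, keep_mask) {
  lab <- label_components(keep_mask, connectivity = cset$connectivity)
  vv <- prod(cset$voxel_dims)
  comps <- data.frame(id = seq_len(lab$n),
                      n_voxels = lab$sizes,
                      volume_mm3 = lab$sizes * vv)
  out <- cset
  out$label_map <- lab$labels
  out$components <- comps
  out
}

#' Binary lesion mask from a component set
#'
#' @param cset a [extract_candidates()] (or filtered) result.
#' @return A [flair_mask()] of all labeled voxels.
#' @export
lesion_mask <- function(cset) {
  stopifnot(inherits(cset, "lesion_components"))
  flair_mask(cset$label_map > 0L, voxel_dims = cset$voxel_dims,
             affine = cset$affine)
}
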