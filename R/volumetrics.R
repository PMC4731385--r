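#' T2 lesion volume as a percentage of brain volume
#'
#' Lesion volume is the final filtered lesion voxel count times the voxel
#' volume. Brain volume is the union of WM- and GM-labeled voxels with the
#' final lesion voxels (lesion voxels are brain tissue that the
#' segmentation pushed into the nonbrain class); CSF is excluded.
#'
#' @param final final filtered `lesion_components` object.
#' @param seg the [classify_tissues()] segmentation on the same grid.
#' @param voxel_vol voxel volume in mm^3.
#' @param stage_counts optional named integer vector of component counts per
#'   pipeline stage, recorded in the result.
#' @param status optional status flags carried through.
#' @return Object of class `t2lv_result`: `lesion_volume_mm3`,
#'   `brain_volume_mm3`, `t2lv_percent`, `n_components_final`,
#'   `stage_counts`, `status`.
#' @export
compute_t2lv <- function(final, seg, voxel_vol, stage_counts = NULL,
                         status = character(0)) {
  stopifnot(inherits(final, "lesion_components"),
            inherits(seg, "tissue_segmentation"))
  if (!all(dim(final$label_map) == dim(seg$labels)))
    stop("shape mismatch between lesion set and segmentation")
  les <- final$label_map > 0L
  brain <- seg$labels == 2L | seg$labels == 3L | les
  bv <- sum(brain) * voxel_vol
  if (bv <= 0) stop("zero brain volume")
  lv <- sum(les) * voxel_vol
  structure(list(lesion_volume_mm3 = lv,
                 brain_volume_mm3 = bv,
                 t2lv_percent = 100 * lv / bv,
                 n_components_final = nrow(final$components),
                 stage_counts = stage_counts,
                 status = status),
            class = "t2lv_result")
}

#' @export
print.t2lv_result <- function(x, ...) {
  cat(sprintf("<t2lv_result> T2LV %.3f%% of brain volume\n", x$t2lv_percent))
  cat(sprintf("  lesion %.1f mm^3 in %d component(s); brain %.1f mm^3\n",
              x$lesion_volume_mm3, x$n_components_final,
              x$brain_volume_mm3))
  if (!is.null(x$stage_counts))
    cat("  components per stage:",
        paste(names(x$stage_counts), x$stage_counts, sep = "=",
              collapse = ", "), "\n")
  if (length(x$status)) cat("  status:", paste(x$status, collapse = ", "), "\n")
  invisible(x)
}

#' Fill lesions into the white-matter class
#'
#' Relabels every final lesion voxel as WM (posterior set to (0, 1, 0)),
#' restoring volume to white matter that the lesion signal displaced into
#' the nonbrain class — required for unbiased WM/GM volumes in lesioned
#' brains.
#'
#' @param seg a [classify_tissues()] segmentation.
#' @param final the final filtered `lesion_components` object on the same
#'   grid.
#' @return The modified `tissue_segmentation`.
#' @export
fill_lesions <- function(seg, final) {
  stopifnot(inherits(seg, "tissue_segmentation"),
            inherits(final, "lesion_components"))
  if (!all(dim(final$label_map) == dim(seg$labels)))
    stop("shape mismatch between lesion set and segmentation")
  les <- final$label_map > 0L
  if (!any(les)) return(seg)
  seg$labels[les] <- 2L
  for (j in 1:3) {
    pj <- seg$posteriors[, , , j]
    pj[les] <- if (j == 2L) 1 else 0
    seg$posteriors[, , , j] <- pj
  }
  nb <- seg$nonbrain_mask$data
  nb[les] <- FALSE
  seg$nonbrain_mask$data <- nb
  seg
}

#' Normalize a tissue volume to a standard intracranial volume
#'
#' Multiplies the raw volume by `standard_icv / subject_icv`, expressing it
#' in standard space ("normalized mm^3") so that smaller values reflect
#' greater atrophy independent of head size.
#'
#' @param raw_mm3 raw tissue volume, mm^3.
#' @param subject_icv_mm3 subject intracranial volume, mm^3 (> 0).
#' @param standard_icv_mm3 standard-space intracranial volume, mm^3 (> 0).
#' @return Normalized volume in mm^3.
#' @export
normalize_volume <- function(raw_mm3, subject_icv_mm3, standard_icv_mm3) {
  if (!is.finite(subject_icv_mm3) || subject_icv_mm3 <= 0)
    stop("subject ICV must be positive")
  if (!is.finite(standard_icv_mm3) || standard_icv_mm3 <= 0)
    stop("standard ICV must be positive")
  raw_mm3 * standard_icv_mm3 / subject_icv_mm3
}
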