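#' Run the full lesion-mapping pipeline
#'
#' Executes, on a single T2-FLAIR volume: brain masking, Gaussian
#' smoothing, 3-class Gaussian-mixture tissue segmentation with
#' bright-outlier capture, the histogram gap threshold separating CSF from
#' hyperintensities, connected-component candidate extraction, the
#' white-matter overlap filter, the midline false-positive filter, and
#' volumetrics (T2LV as % brain volume, lesion-filled WM/GM volumes,
#' ICV-normalized volumes).
#'
#' The WM mask and mid-sagittal plane come from, in order of precedence: a
#' user-supplied subject-space WM probability map (`wm_prob`), or an atlas
#' bundle registered by image moments (`atlas`, default the built-in
#' [synthetic_atlas()]). With a user WM map and no atlas, the midline
#' plane falls back to the plane through the brain-mask centroid with
#' normal along the voxel x-axis mapped to world coordinates.
#'
#' @param flair a [flair_volume()] or path to a NIfTI file.
#' @param config a [pipeline_config()].
#' @param brain_mask optional [flair_mask()] or NIfTI path; when absent a
#'   mask is estimated with [estimate_brain_mask()].
#' @param wm_prob optional subject-space WM probability [flair_volume()] or
#'   NIfTI path (bypasses atlas registration).
#' @param atlas optional [synthetic_atlas()]-style bundle; default the
#'   built-in synthetic atlas matched to the subject grid.
#' @param out_dir optional output directory; when given, writes
#'   `lesion_mask.nii.gz`, `tissue_labels.nii.gz`, `candidates.nii.gz`,
#'   `summary.tsv` and `report.json`.
#' @param subject_id identifier used in the summary row (default
#'   `"subject"`).
#' @return A `run_report` list: `config`, `gmm`, `gap`, `stage_counts`,
#'   `t2lv` ([compute_t2lv()] result), `volumes` (raw and normalized WM/GM
#'   after lesion filling), `icv`, `final` (the final `lesion_components`),
#'   `seg`, `version`.
#' @export
run_pipeline <- function(flair, config = pipeline_config(),
                         brain_mask = NULL, wm_prob = NULL, atlas = NULL,
                         out_dir = NULL, subject_id = "subject") {
  stopifnot(inherits(config, "pipeline_config"))
  v <- if (is.character(flair)) read_volume(flair) else flair
  stopifnot(inherits(v, "flair_volume"))
  status <- character(0)

  # --- preprocessing ---------------------------------------------------
  m <- if (is.null(brain_mask)) {
    estimate_brain_mask(v, factor = config$brain_mask_factor)
  } else if (is.character(brain_mask)) read_mask(brain_mask) else brain_mask
  stopifnot(inherits(m, "flair_mask"))
  vm <- apply_brain_mask(v, m)
  vs <- gaussian_smooth(vm, config$smoothing_sigma_mm)

  # --- tissue segmentation --------------------------------------------
  intens <- vs$data[m$data]
  if (length(intens) > config$gmm_max_samples) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(config$rng_seed)
    intens <- sample(intens, config$gmm_max_samples)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  # fit, then refit with the hyperintense tail excluded: lesions inflate
  # the GM component's sd on the first pass, which would push the
  # bright-outlier capture threshold too high
  fit <- fit_gmm(intens, k = 3L, tol = config$gmm_tol,
                 max_iter = config$gmm_max_iter, seed = config$rng_seed)
  for (pass in 1:2) {
    cut <- fit$means[3] + config$bright_outlier_z * fit$sds[3]
    keep <- intens <= cut
    if (all(keep) || sum(keep) < 30L) break
    fit <- fit_gmm(intens[keep], k = 3L, tol = config$gmm_tol,
                   max_iter = config$gmm_max_iter, seed = config$rng_seed)
  }
  seg <- classify_tissues(vs, m, fit,
                          bright_outlier_z = config$bright_outlier_z)

  # --- gap threshold and candidates -----------------------------------
  nb_int <- vs$data[seg$nonbrain_mask$data]
  if (length(nb_int) == 0) {
    gap <- list(threshold = Inf, status = "no_gap_found",
                gap_bin = NA_integer_)
    status <- c(status, "empty_nonbrain_class")
  } else {
    h <- build_histogram(nb_int, nbins = config$histogram_bins)
    gap <- find_gap_threshold(h)
  }
  if (gap$status == "no_gap_found") {
    warning("no empty histogram bin found; reporting zero lesions")
    status <- c(status, "no_gap_found")
  }
  cand <- extract_candidates(vs, seg$nonbrain_mask, gap$threshold,
                             connectivity = config$connectivity,
                             status = gap$status)

  # --- WM mask and midline plane --------------------------------------
  if (!is.null(wm_prob)) {
    wp <- if (is.character(wm_prob)) read_volume(wm_prob) else wm_prob
    wm <- make_wm_mask(wp, threshold = config$wm_prob_threshold)
    if (!is.null(atlas)) {
      tr <- register_affine(m, atlas$brain_mask)
      plane <- transform_plane(atlas$midline_plane, tr)
    } else {
      lin <- which(m$data)
      ctr <- colMeans(voxel_to_world(m$affine,
                                     linear_to_ijk(lin, dim(m$data))))
      nrm <- m$affine[1:3, 1]
      plane <- list(point = ctr, normal = nrm / sqrt(sum(nrm^2)))
      status <- c(status, "midline_fallback_plane")
    }
  } else {
    if (is.null(atlas))
      atlas <- synthetic_atlas(shape = dim(v$data),
                               voxel_dims = v$voxel_dims)
    tr <- register_affine(m, atlas$brain_mask)
    wp <- resample_to_subject(atlas$wm_prob, tr, v)
    wp$data <- pmin(pmax(wp$data, 0), 1)
    wm <- make_wm_mask(wp, threshold = config$wm_prob_threshold)
    plane <- transform_plane(atlas$midline_plane, tr)
  }

  # --- false-positive filters (WM overlap, then midline) --------------
  after_wm <- filter_by_wm_overlap(cand, wm)
  final <- midline_filter(after_wm, plane,
                          touch_mm = config$midline_touch_mm,
                          truncate_mm = config$midline_max_removal_mm)
  stage_counts <- c(candidates = nrow(cand$components),
                    after_wm_filter = nrow(after_wm$components),
                    after_midline_filter = nrow(final$components))

  # --- volumetrics ----------------------------------------------------
  vv <- voxel_volume_mm3(v)
  t2lv <- compute_t2lv(final, seg, vv, stage_counts = stage_counts,
                       status = status)
  filled <- fill_lesions(seg, final)
  vols <- tissue_volumes(filled, vv)
  icv <- sum(m$data) * vv  # brain mask (tissue + CSF) as ICV proxy
  std_icv <- if (!is.null(atlas)) atlas$standard_icv else icv
  volumes <- list(
    wm_mm3 = unname(vols["wm_mm3"]), gm_mm3 = unname(vols["gm_mm3"]),
    wm_normalized_mm3 = normalize_volume(unname(vols["wm_mm3"]), icv, std_icv),
    gm_normalized_mm3 = normalize_volume(unname(vols["gm_mm3"]), icv, std_icv))

  report <- list(subject_id = subject_id,
                 config = unclass(config),
                 gmm = list(means = fit$means, sds = fit$sds,
                            weights = fit$weights,
                            converged = fit$converged, n_iter = fit$n_iter),
                 gap = gap,
                 stage_counts = as.list(stage_counts),
                 t2lv = unclass(t2lv)[c("lesion_volume_mm3",
                                        "brain_volume_mm3", "t2lv_percent",
                                        "n_components_final")],
                 volumes = volumes, icv_mm3 = icv,
                 standard_icv_mm3 = std_icv,
                 status = status,
                 version = as.character(utils::packageVersion("flairlv")))
  out <- list(config = config, gmm = fit, gap = gap,
              stage_counts = stage_counts, t2lv = t2lv, volumes = volumes,
              icv_mm3 = icv, final = final, candidates = cand, seg = seg,
              brain_mask = m, wm_mask = wm, midline_plane = plane,
              report = report, version = report$version)
  class(out) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(lesion_mask(final), file.path(out_dir, "lesion_mask.nii.gz"))
    lab <- flair_volume(array(as.double(seg$labels), dim(seg$labels)),
                        voxel_dims = v$voxel_dims, affine = v$affine)
    write_volume(lab, file.path(out_dir, "tissue_labels.nii.gz"))
    candv <- flair_volume(array(as.double(cand$label_map),
                                dim(cand$label_map)),
                          voxel_dims = v$voxel_dims, affine = v$affine)
    write_volume(candv, file.path(out_dir, "candidates.nii.gz"))
    summ <- data.frame(subject_id = subject_id,
                       t2lv_percent = t2lv$t2lv_percent,
                       lesion_mm3 = t2lv$lesion_volume_mm3,
                       brain_mm3 = t2lv$brain_volume_mm3,
                       wm_mm3 = volumes$wm_mm3, gm_mm3 = volumes$gm_mm3,
                       wm_normalized_mm3 = volumes$wm_normalized_mm3,
                       gm_normalized_mm3 = volumes$gm_normalized_mm3,
                       n_components_final = t2lv$n_components_final,
                       candidates = stage_counts["candidates"],
                       after_wm_filter = stage_counts["after_wm_filter"],
                       status = paste(status, collapse = ";"))
    utils::write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$t2lv)
  cat(sprintf("  gap threshold %.4g (%s)\n", x$gap$threshold,
              x$gap$status))
  invisible(x)
}

#' Run correlation and regression analyses on a subject table
#'
#' Computes, over a subject table of MRI and clinical measures: per-variable
#' outlier flags (standard-deviation rule), the Pearson correlation matrix
#' with two-tailed p-values, the partial correlation matrix controlled for
#' a nuisance covariate, and hierarchical multiple regressions for the
#' requested dependent variables.
#'
#' @param table a data.frame or path to a TSV/CSV file with a header row.
#' @param analyses list of HMR analyses: each
#'   `list(dv = "colname", blocks = list(c(...), ...))`.
#' @param variables columns entering the correlation matrices (default all
#'   numeric columns).
#' @param control covariate column controlled for in the partial
#'   correlations (default `"age"` when present, else none).
#' @param outlier_sd standard-deviation multiple for the outlier log
#'   (default 3); flagged values are reported, not removed — exclusion is
#'   the caller's choice.
#' @param out_dir optional directory for TSV/JSON output.
#' @return List of class `stats_report`: `pearson` (`r`, `p`, `n`
#'   matrices), `partial` (or NULL), `hmr` (named list of [hmr()] results),
#'   `outliers` (named list of flagged row indices).
#' @export
run_stats <- function(table, analyses = list(), variables = NULL,
                      control = "age", outlier_sd = 3, out_dir = NULL) {
  df <- if (is.character(table)) {
    sep <- if (grepl("\\.csv$", table, ignore.case = TRUE)) "," else "\t"
    utils::read.table(table, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else as.data.frame(table)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  if (is.null(variables)) variables <- num_cols
  missing <- setdiff(variables, names(df))
  if (length(missing))
    stop("unknown column(s): ", paste(missing, collapse = ", "))

  outliers <- lapply(df[variables], function(x)
    if (sum(!is.na(x)) >= 3) detect_outliers(x, k = outlier_sd) else integer(0))
  outliers <- outliers[vapply(outliers, length, integer(1)) > 0]

  nv <- length(variables)
  rmat <- pmat <- nmat <- matrix(NA_real_, nv, nv,
                                 dimnames = list(variables, variables))
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    if (i == j) { rmat[i, j] <- 1; next }
    pc <- tryCatch(pearson(df[[variables[i]]], df[[variables[j]]]),
                   error = function(e) NULL)
    if (!is.null(pc)) {
      rmat[i, j] <- pc$r; pmat[i, j] <- pc$p; nmat[i, j] <- pc$n
    }
  }

  partial <- NULL
  if (!is.null(control) && control %in% names(df)) {
    pv <- setdiff(variables, control)
    np <- length(pv)
    pr <- pp <- matrix(NA_real_, np, np, dimnames = list(pv, pv))
    for (i in seq_len(np)) for (j in seq_len(np)) {
      if (i == j) { pr[i, j] <- 1; next }
      pc <- tryCatch(partial_corr(df[[pv[i]]], df[[pv[j]]],
                                  df[[control]]),
                     error = function(e) NULL)
      if (!is.null(pc)) { pr[i, j] <- pc$r; pp[i, j] <- pc$p }
    }
    partial <- list(r = pr, p = pp, control = control)
  }

  hmr_results <- list()
  for (an in analyses) {
    hmr_results[[an$dv]] <- hmr(an$dv, an$blocks, data = df)
  }

  out <- structure(list(pearson = list(r = rmat, p = pmat, n = nmat),
                        partial = partial, hmr = hmr_results,
                        outliers = outliers),
                   class = "stats_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(round(rmat, 3),
                       file.path(out_dir, "pearson_r.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(round(pmat, 3),
                       file.path(out_dir, "pearson_p.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(partial)) {
      utils::write.table(round(partial$r, 3),
                         file.path(out_dir, "partial_r.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(round(partial$p, 3),
                         file.path(out_dir, "partial_p.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    for (dv in names(hmr_results)) {
      utils::write.table(hmr_results[[dv]]$stages,
                         file.path(out_dir, paste0("hmr_", dv, "_stages.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(hmr_results[[dv]]$final,
                         file.path(out_dir, paste0("hmr_", dv, "_final.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    json <- list(outliers = outliers,
                 hmr = lapply(hmr_results, function(h)
                   list(stages = h$stages, final = h$final,
                        overall_p = h$overall_p, n = h$n)))
    jsonlite::write_json(json, file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
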