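#' Fit a Gaussian mixture to brain intensities by EM
#'
#' Expectation-maximization fit of a k-component univariate Gaussian mixture
#' to the in-mask intensity sample, emulating histogram-based tissue
#' classification of a brain-extracted FLAIR image into nonbrain/CSF, white
#' matter and gray matter (FLAIR ordering: CSF darkest, GM the brightest
#' tissue). Initialization is a deterministic quantile split (10th/50th/85th
#' percentiles for k = 3, evenly spaced quantiles otherwise) with equal
#' weights and a common standard deviation equal to the sample sd.
#' Components are reported in ascending mean order.
#'
#' Component sds are floored at `1e-3` times the data range so that
#' quantized (noise-free) data cannot drive the likelihood to infinity. A
#' starved component (weight collapsing to zero) triggers a restart with
#' jittered initial means (seeded); after 5 restarts an error is raised.
#'
#' @param intensities numeric vector of voxel intensities (>= 10 k values).
#' @param k number of components (default 3).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param seed integer seed used only for degenerate-fit restarts.
#' @return An object of class `gmm_fit`: `means`, `sds`, `weights` (each
#'   length k, ascending mean order), `log_likelihood`, `n_iter`,
#'   `converged`, `n`.
#' @export
fit_gmm <- function(intensities, k = 3L, tol = 1e-6, max_iter = 500L,
                    seed = 1L) {
  x <- as.numeric(intensities)
  if (anyNA(x) || any(!is.finite(x))) stop("intensities must be finite")
  n <- length(x)
  k <- as.integer(k)
  if (n < 10L * k)
    stop("too few samples: need at least ", 10L * k, " values for k = ", k)
  rng <- diff(range(x))
  if (rng <= 0) stop("intensities are constant; cannot fit a mixture")
  sd_floor <- 1e-3 * rng
  probs <- if (k == 3L) c(0.10, 0.50, 0.85) else
    seq(0.1, 0.9, length.out = k)
  mu0 <- as.numeric(stats::quantile(x, probs, names = FALSE))
  s0 <- stats::sd(x)

  run_em <- function(mu) {
    sds <- rep(s0, k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(max_iter)) {
      dens <- vapply(seq_len(k),
                     function(j) w[j] * stats::dnorm(x, mu[j], sds[j]),
                     numeric(n))
      rs <- rowSums(dens)
      rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
      ll <- sum(log(rs))
      resp <- dens / rs
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sds <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
      if (any(!is.finite(mu)) || any(!is.finite(sds)) || any(nk < 1e-8))
        return(list(degenerate = TRUE))
      # variance floor: quantized (e.g. noiseless) data drives component
      # sds to zero and the likelihood to infinity; clamp instead
      sds <- pmax(sds, sd_floor)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * abs(ll_old)) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    list(degenerate = FALSE, means = mu, sds = sds, weights = w,
         ll = ll_old, n_iter = iter, converged = converged)
  }

  fit <- run_em(mu0)
  tries <- 0L
  while (isTRUE(fit$degenerate) && tries < 5L) {
    tries <- tries + 1L
    jit <- local({
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed + tries)
      stats::rnorm(k, 0, 0.05 * rng)
    })
    fit <- run_em(mu0 + jit)
  }
  if (isTRUE(fit$degenerate))
    stop("degenerate mixture fit after 5 restarts")
  ord <- order(fit$means)
  structure(list(means = fit$means[ord], sds = fit$sds[ord],
                 weights = fit$weights[ord],
                 log_likelihood = fit$ll, n_iter = fit$n_iter,
                 converged = fit$converged, n = n, k = k),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> k = %d, n = %d, logLik = %.2f (%s, %d iter)\n",
              x$k, x$n, x$log_likelihood,
              if (x$converged) "converged" else "not converged", x$n_iter))
  cls <- if (x$k == 3L) c("CSF/nonbrain", "WM", "GM") else
    paste0("class", seq_len(x$k))
  for (j in seq_len(x$k))
    cat(sprintf("  %-12s mean %8.3f  sd %7.3f  weight %.3f\n",
                cls[j], x$means[j], x$sds[j], x$weights[j]))
  invisible(x)
}

#' Classify brain voxels into tissue classes
#'
#' Posterior probabilities by Bayes' rule from a fitted 3-class mixture,
#' hard labels by argmax (ties to the lower class index). FLAIR
#' hyperintensities are much brighter than any tissue mode and would
#' otherwise be split between the GM tail and the nonbrain class, so an
#' explicit capture rule assigns every voxel brighter than
#' `mean_GM + bright_outlier_z * sd_GM` to the nonbrain class, reproducing
#' the behaviour that makes the downstream CSF/lesion gap threshold work.
#'
#' @param v brain-masked, smoothed [flair_volume()].
#' @param m brain [flair_mask()].
#' @param fit a 3-class [fit_gmm()] result from the same intensity
#'   population.
#' @param bright_outlier_z z-score above the GM mean beyond which voxels are
#'   captured into the nonbrain class (default 3.5).
#' @return Object of class `tissue_segmentation`: `posteriors` (4D array
#'   `c(dim, 3)`, zero outside the mask), `labels` (integer array: 0
#'   background, 1 CSF/nonbrain, 2 WM, 3 GM), `nonbrain_mask`
#'   ([flair_mask()]), `brain_mask`, `fit`.
#' @export
classify_tissues <- function(v, m, fit, bright_outlier_z = 3.5) {
  stopifnot(inherits(fit, "gmm_fit"), fit$k == 3L)
  stopifnot_same_grid(v, m)
  if (!any(m$data)) stop("empty brain mask")
  d <- dim(v$data)
  x <- v$data[m$data]
  dens <- vapply(1:3, function(j)
    fit$weights[j] * stats::dnorm(x, fit$means[j], fit$sds[j]),
    numeric(length(x)))
  rs <- rowSums(dens)
  rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
  post <- dens / rs
  # argmax with ties to the lower class index
  lab <- max.col(post, ties.method = "first")
  bright <- x > fit$means[3] + bright_outlier_z * fit$sds[3]
  lab[bright] <- 1L
  labels <- array(0L, d)
  labels[m$data] <- lab
  posteriors <- array(0, c(d, 3L))
  for (j in 1:3) {
    pj <- array(0, d)
    pj[m$data] <- post[, j]
    posteriors[, , , j] <- pj
  }
  nonbrain <- array(FALSE, d)
  nonbrain[m$data] <- lab == 1L
  structure(list(posteriors = posteriors,
                 labels = labels,
                 nonbrain_mask = flair_mask(nonbrain, parent = v),
                 brain_mask = m,
                 fit = fit),
            class = "tissue_segmentation")
}

#' Tissue volumes from a segmentation
#'
#' Hard-label voxel counts times the voxel volume. Brain volume is
#' WM + GM; the nonbrain/CSF class is excluded (final lesion voxels re-enter
#' the brain volume in [compute_t2lv()] after filtering).
#'
#' @param seg a [classify_tissues()] result.
#' @param voxel_vol voxel volume in mm^3 (see [voxel_volume_mm3()]).
#' @return Named numeric: `csf_mm3`, `wm_mm3`, `gm_mm3`, `brain_mm3`.
#' @export
tissue_volumes <- function(seg, voxel_vol) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  counts <- tabulate(seg$labels[seg$labels > 0L], nbins = 3L)
  vols <- counts * voxel_vol
  c(csf_mm3 = vols[1], wm_mm3 = vols[2], gm_mm3 = vols[3],
    brain_mm3 = vols[2] + vols[3])
}
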