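#' Standard-deviation outlier rule
#'
#' Flags observations at least `k` standard deviations from the mean, with
#' mean and sd computed once on the full sample (n - 1 denominator); the
#' boundary is inclusive. A zero-variance sample has no outliers.
#'
#' @param x numeric sample, `n >= 3` (NAs are never flagged).
#' @param k standard-deviation multiple (default 3).
#' @return Integer indices of the flagged observations.
#' @export
detect_outliers <- function(x, k = 3) {
  xx <- x[!is.na(x)]
  if (length(xx) < 3) stop("need at least 3 observations")
  m <- mean(xx)
  s <- stats::sd(xx)
  if (!is.finite(s) || s == 0) return(integer(0))
  which(!is.na(x) & abs(x - m) >= k * s)
}

#' Base-10 logarithm transform
#'
#' @param x strictly positive numeric vector.
#' @return `log10(x)`.
#' @export
apply_transform_log10 <- function(x) {
  if (any(x[!is.na(x)] <= 0)) stop("log10 requires strictly positive values")
  log10(x)
}

#' Choose a normalizing transform
#'
#' Tries the identity, square-root, log10 and inverse (1/x) transforms
#' (each only on its domain: sqrt needs nonnegative, log10/inverse strictly
#' positive values), scores each by the Shapiro-Wilk W statistic, and
#' returns the best. The identity is preferred when its W is within
#' `identity_margin` of the best, so already-normal data is left alone.
#' The inverse transform reverses monotonic ordering; this is flagged in
#' the returned label so downstream sign interpretation is explicit.
#'
#' @param x numeric sample (3 <= n <= 5000 after NA removal).
#' @param identity_margin tolerance within which identity wins (default
#'   0.005).
#' @return List: `x` (transformed values, NAs preserved), `label` (one of
#'   `"identity"`, `"sqrt"`, `"log10"`, `"inverse"`), `w` (named W
#'   statistics of the candidates), `reverses_order` (TRUE for inverse).
#' @export
select_transform <- function(x, identity_margin = 0.005) {
  xx <- x[!is.na(x)]
  if (length(xx) < 3) stop("need at least 3 observations")
  cands <- list(identity = function(v) v)
  if (all(xx >= 0)) cands$sqrt <- sqrt
  if (all(xx > 0)) {
    cands$log10 <- log10
    cands$inverse <- function(v) 1 / v
  }
  w <- vapply(cands, function(f) {
    tx <- f(xx)
    if (stats::sd(tx) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(tx)$statistic, error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(w))) {
    warning("no admissible transform; returning identity")
    return(list(x = x, label = "identity", w = w, reverses_order = FALSE))
  }
  best <- names(which.max(w))
  if (!is.na(w["identity"]) && w["identity"] >= max(w, na.rm = TRUE) -
      identity_margin)
    best <- "identity"
  list(x = cands[[best]](x), label = best, w = w,
       reverses_order = identical(best, "inverse"))
}

#' Pearson correlation with two-tailed significance
#'
#' Product-moment correlation on pairwise-complete observations; the
#' two-tailed p-value comes from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric samples.
#' @return List: `r`, `p`, `n`, `df`.
#' @export
pearson <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       df = unname(ct$parameter))
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the least-squares residuals of `x` and `y` after
#' regressing each on the covariates (with intercept). With k covariates
#' the degrees of freedom are `n - 2 - k` and the two-tailed p-value comes
#' from `t = r * sqrt(df / (1 - r^2))`. With no covariates this reduces
#' exactly to [pearson()].
#'
#' @param x,y paired numeric samples.
#' @param covariates numeric vector, matrix or data.frame of covariates
#'   (`NULL` for none). Observations are complete-case filtered jointly.
#' @return List: `r`, `p`, `n`, `df`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0))
    return(pearson(x, y))
  cv <- as.matrix(covariates)
  ok <- stats::complete.cases(x, y, cv)
  x <- x[ok]; y <- y[ok]; cv <- cv[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(cv)
  if (n < k + 3) stop("need at least k + 3 complete observations")
  X <- cbind(1, cv)
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero residual variance")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), n = n, df = df)
}

#' Hierarchical multiple regression
#'
#' Fits nested ordinary-least-squares models, adding the predictor blocks
#' in order, and reports per stage the R-squared, adjusted R-squared,
#' R-squared change over the previous stage, and the F test of that change
#' `F = (dR2 / q) / ((1 - R2) / (n - p - 1))` with `q` predictors added at
#' the stage and `p` cumulative predictors. The final model's standardized
#' beta coefficients (fit on z-scored response and predictors) are reported
#' with two-tailed t tests, along with the overall model F p-value.
#'
#' @param y response vector, or a column name when `data` is given.
#' @param blocks list of predictor blocks: each a character vector of
#'   column names in `data`, or a numeric matrix/vector.
#' @param data optional data.frame providing named columns.
#' @return Object of class `hmr_result`: `stages` (data.frame: `model`,
#'   `predictors`, `r`, `r_squared`, `adj_r_squared`, `r_squared_change`,
#'   `f_change`, `p_f_change`, `df1`, `df2`), `final` (data.frame:
#'   `predictor`, `beta_std`, `p`), `overall_p`, `n`.
#' @export
hmr <- function(y, blocks, data = NULL) {
  get_block <- function(b, nm) {
    if (is.character(b)) {
      if (is.null(data)) stop("character blocks require 'data'")
      missing <- setdiff(b, names(data))
      if (length(missing))
        stop("unknown column(s): ", paste(missing, collapse = ", "))
      as.matrix(data[b])
    } else {
      m <- as.matrix(b)
      if (is.null(colnames(m)))
        colnames(m) <- paste0(nm, "_", seq_len(ncol(m)))
      m
    }
  }
  if (is.character(y)) {
    if (is.null(data)) stop("character response requires 'data'")
    yv <- data[[y]]
    if (is.null(yv)) stop("unknown column: ", y)
  } else yv <- as.numeric(y)
  bl <- lapply(seq_along(blocks), function(i)
    get_block(blocks[[i]], paste0("block", i)))
  Xall <- do.call(cbind, bl)
  ok <- stats::complete.cases(yv, Xall)
  yv <- yv[ok]
  Xall <- Xall[ok, , drop = FALSE]
  n <- length(yv)
  if (n <= ncol(Xall) + 1) stop("too few observations for the predictors")
  sizes <- vapply(bl, ncol, integer(1))
  ends <- cumsum(sizes)

  stages <- vector("list", length(bl))
  r2_prev <- 0
  for (m in seq_along(bl)) {
    p_m <- ends[m]
    Xm <- Xall[, seq_len(p_m), drop = FALSE]
    if (qr(cbind(1, Xm))$rank < p_m + 1)
      stop("rank deficiency at stage ", m)
    fit <- stats::lm(yv ~ Xm)
    r2 <- summary(fit)$r.squared
    adj <- 1 - (1 - r2) * (n - 1) / (n - p_m - 1)
    dr2 <- r2 - r2_prev
    q <- sizes[m]
    fch <- (dr2 / q) / ((1 - r2) / (n - p_m - 1))
    pch <- stats::pf(fch, q, n - p_m - 1, lower.tail = FALSE)
    stages[[m]] <- data.frame(
      model = m,
      predictors = paste(colnames(Xall)[seq_len(p_m)], collapse = " + "),
      r = sqrt(r2), r_squared = r2, adj_r_squared = adj,
      r_squared_change = dr2, f_change = fch, p_f_change = pch,
      df1 = q, df2 = n - p_m - 1)
    r2_prev <- r2
  }
  stages <- do.call(rbind, stages)

  Z <- scale(Xall)
  yz <- as.numeric(scale(yv))
  zfit <- stats::lm(yz ~ Z)
  sm <- summary(zfit)
  coefs <- sm$coefficients[-1, , drop = FALSE]
  final <- data.frame(predictor = colnames(Xall),
                      beta_std = unname(coefs[, 1]),
                      p = unname(coefs[, 4]))
  fstat <- sm$fstatistic
  overall_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(stages = stages, final = final,
                 overall_p = unname(overall_p), n = n),
            class = "hmr_result")
}

#' @export
print.hmr_result <- function(x, ...) {
  cat(sprintf("<hmr_result> n = %d, overall model p = %.4g\n", x$n,
              x$overall_p))
  st <- x$stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  model %d [%s]: R2 %.3f (adj %.3f), dR2 %.3f, F(%d,%d) = %.3f, p = %.3f\n",
                st$model[i], st$predictors[i], st$r_squared[i],
                st$adj_r_squared[i], st$r_squared_change[i], st$df1[i],
                st$df2[i], st$f_change[i], st$p_f_change[i]))
  cat("  final standardized betas:\n")
  for (i in seq_len(nrow(x$final)))
    cat(sprintf("    %-12s beta %7.3f  p %.3f\n", x$final$predictor[i],
                x$final$beta_std[i], x$final$p[i]))
  invisible(x)
}
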