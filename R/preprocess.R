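#' Subtract per-sample background
#'
#' Subtracts a per-sample background estimate from every probe intensity.
#' Negative results are allowed: the glog transform's `alpha` shift absorbs
#' them (with `lambda > 0`).
#'
#' @param x Probe x sample intensity matrix.
#' @param background Numeric vector, one value per sample (column).
#' @return The matrix with `background[j]` subtracted from column j.
#' @export
subtract_background <- function(x, background) {
  if (length(background) != ncol(x))
    stop("`background` must have one value per sample (", ncol(x), ")")
  sweep(x, 2L, background)
}

#' Generalized-log (glog) transform
#'
#' Computes `g(y) = ln((y - alpha) + sqrt((y - alpha)^2 + lambda))`
#' elementwise. For `lambda > 0` the transform is defined for all real `y`
#' and strictly increasing; for large signal it behaves like
#' `ln(2 (y - alpha))` and near background it is approximately linear, which
#' stabilizes the variance of two-component (additive + multiplicative)
#' intensity noise. At `lambda = 0` it degenerates to `ln(2 (y - alpha))`
#' and requires `y > alpha`.
#'
#' @param y Numeric vector or matrix of intensities.
#' @param lambda Glog offset, intensity-squared units, >= 0.
#' @param alpha Additive background shift subtracted before transforming.
#' @return Transformed values with the shape of `y`.
#' @examples
#' glog(0, lambda = 1)               # 0
#' glog(3, lambda = 4, alpha = 1)    # log(2 + sqrt(8))
#' @export
glog <- function(y, lambda, alpha = 0) {
  if (lambda < 0) stop("`lambda` must be >= 0")
  s <- y - alpha
  if (lambda == 0 && any(s <= 0))
    stop("lambda = 0 requires all intensities > alpha")
  log(s + sqrt(s^2 + lambda))
}

#' Estimate glog parameters by profile maximum likelihood
#'
#' Estimates the pair `(lambda, alpha)` under the model in which the
#' transformed values are Normal with a free mean per (gene, dose x time
#' cell) and a common variance. The profile log-likelihood, including the
#' log-Jacobian of the transform, is
#'
#'   l(lambda, alpha) = -N/2 log(RSS/N) - 1/2 sum(log((y - alpha)^2 + lambda))
#'
#' where RSS pools within-cell residuals over all genes and N is the number
#' of observations. It is maximized over a deterministic log-spaced lambda
#' grid crossed with an alpha grid spanning the low-intensity range,
#' followed by Nelder-Mead refinement of `(alpha, log lambda)` — no
#' randomness is involved, so the estimate is reproducible by construction.
#'
#' @param x Probe x sample raw intensity matrix.
#' @param design Matching `study_design`; replicate grouping comes from its
#'   dose x time cells, at least one of which must hold >= 2 samples.
#' @param n_lambda,n_alpha Grid resolutions.
#' @param refine Run Nelder-Mead refinement from the best grid point.
#' @return A list of class `glog_params`: `lambda`, `alpha`, `loglik`.
#' @export
estimate_glog <- function(x, design, n_lambda = 13, n_alpha = 9,
                          refine = TRUE) {
  .check_design_matrix(x, design)
  cells <- interaction(design$dose_cGy, design$time_h, drop = TRUE)
  counts <- as.vector(table(cells))
  if (!any(counts >= 2))
    stop("glog estimation needs at least one dose x time cell with >= 2 replicates")
  G <- stats::model.matrix(~ cells - 1)  # sample x cell indicator
  Gn <- sweep(G, 2L, counts, `/`)
  N <- length(x)

  nll <- function(alpha, lambda) {
    if (lambda <= 0) return(Inf)
    z <- glog(x, lambda, alpha)
    # tiny lambda with y < alpha underflows the log argument to 0
    if (!all(is.finite(z))) return(Inf)
    M <- z %*% Gn                       # cell means per gene
    rss <- sum(z^2) - sum(sweep(M^2, 2L, counts, `*`))
    if (rss <= 0) rss <- .Machine$double.eps
    N / 2 * log(rss / N) + 0.5 * sum(log((x - alpha)^2 + lambda))
  }

  ymin <- min(x)
  ymed <- stats::median(x)
  alpha_grid <- seq(ymin - 0.5 * (ymed - ymin), ymed, length.out = n_alpha)
  lmax <- max((x - ymin)^2)
  lambda_grid <- 10^seq(log10(lmax) - 12, log10(lmax), length.out = n_lambda)

  grid <- expand.grid(alpha = alpha_grid, lambda = lambda_grid)
  vals <- mapply(nll, grid$alpha, grid$lambda)
  best <- grid[which.min(vals), ]

  lambda <- best$lambda
  alpha <- best$alpha
  if (refine) {
    opt <- stats::optim(c(alpha, log(lambda)),
                        function(p) nll(p[1], exp(p[2])),
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    alpha <- opt$par[1]
    lambda <- exp(opt$par[2])
  }
  structure(list(lambda = lambda, alpha = alpha,
                 loglik = -nll(alpha, lambda)),
            class = "glog_params")
}

#' @export
print.glog_params <- function(x, ...) {
  cat(sprintf("glog parameters: lambda = %.6g, alpha = %.6g (loglik %.4g)\n",
              x$lambda, x$alpha, x$loglik))
  invisible(x)
}

#' Apply the glog transform with estimated parameters
#'
#' @param x Probe x sample matrix.
#' @param params A `glog_params` (or list with `lambda`, `alpha`).
#' @return Transformed matrix.
#' @export
glog_transform <- function(x, params) {
  glog(x, params$lambda, params$alpha)
}

#' Quantile normalization
#'
#' Forces every sample (column) to the same distribution: the across-sample
#' mean of order statistics. Ties within a column receive the mean of the
#' reference values they span. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param x Probe x sample matrix with >= 2 samples.
#' @return Normalized matrix with unchanged dimnames.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Filter probes never reliably detected
#'
#' Keeps exactly the probes whose detection p-value is below `alpha` in at
#' least one sample; a probe with detection p > `alpha` across all samples
#' is considered indistinguishable from background and removed. Probe order
#' is preserved.
#'
#' @param x Probe x sample expression matrix.
#' @param detection Matching matrix of detection p-values in `[0, 1]`.
#' @param alpha Detection threshold, default 0.05.
#' @return The filtered expression matrix (a subset of rows of `x`).
#' @export
filter_detection <- function(x, detection, alpha = 0.05) {
  if (!identical(dim(x), dim(detection)) ||
      !identical(rownames(x), rownames(detection)))
    stop("expression and detection matrices are not aligned")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  keep <- rowSums(detection < alpha) > 0
  x[keep, , drop = FALSE]
}

#' Per-probe mean/SD diagnostic of variance stabilization
#'
#' Computes each probe's mean and standard deviation across samples and
#' ranks probes by mean — the ranked mean-versus-SD profile used to judge
#' whether the glog + quantile pipeline has flattened the strong
#' mean-variance dependence of raw intensities.
#'
#' @param x Probe x sample matrix with >= 2 samples.
#' @return Data frame (`probe`, `mean`, `sd`, `mean_rank`), ordered by mean
#'   rank, with attribute `sd_range = c(min, max)`.
#' @export
rank_mean_sd <- function(x) {
  if (ncol(x) < 2) stop("need >= 2 samples")
  mu <- rowMeans(x)
  sds <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  out <- data.frame(probe = rownames(x), mean = mu, sd = sds,
                    mean_rank = rank(mu, ties.method = "first"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$mean_rank), ]
  rownames(out) <- NULL
  attr(out, "sd_range") <- c(min(sds), max(sds))
  out
}
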