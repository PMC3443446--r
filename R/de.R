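#' Fit the saturated cell-means ANOVA per gene
#'
#' For every gene, fits the model in which each dose x time cell has its
#' own mean and all cells share a gene-specific error variance. The
#' residual mean square (MSE) pools within-cell variation with
#' `df = n_samples - n_cells` degrees of freedom — 12 for the full
#' 3 dose x 4 time x 2 replicate design. The gene-specific MSE (not an
#' empirical-Bayes posterior) is carried into every downstream contrast.
#'
#' @param x Gene x sample matrix of normalized expression.
#' @param design Matching `study_design`.
#' @return A list of class `cell_means_fit`: `means` (gene x cell),
#'   `mse` (per gene), `df` (scalar residual df), `cells` (data frame of
#'   cell dose/time/n) and `genes`.
#' @export
fit_cell_means <- function(x, design) {
  .check_design_matrix(x, design)
  cells <- interaction(design$dose_cGy, design$time_h, drop = TRUE, sep = "@")
  counts <- as.vector(table(cells))
  df <- ncol(x) - nlevels(cells)
  if (df <= 0)
    stop("zero residual degrees of freedom: every cell needs replication overall")
  G <- stats::model.matrix(~ cells - 1)
  means <- x %*% sweep(G, 2L, counts, `/`)
  rss <- rowSums(x^2) - rowSums(sweep(means^2, 2L, counts, `*`))
  rss[rss < 0] <- 0  # numerical guard
  info <- data.frame(do.call(rbind, strsplit(levels(cells), "@", fixed = TRUE)),
                     stringsAsFactors = FALSE)
  names(info) <- c("dose_cGy", "time_h")
  info$dose_cGy <- as.numeric(info$dose_cGy)
  info$time_h <- as.numeric(info$time_h)
  info$n <- counts
  colnames(means) <- levels(cells)
  structure(list(means = means, mse = rss / df, df = df, cells = info,
                 genes = rownames(x)),
            class = "cell_means_fit")
}

#' Dose-versus-control t contrast at one time point
#'
#' Tests, per gene, the difference between the `dose` and `control` cell
#' means at time `time`, using the gene's pooled MSE:
#' `t = (mean_dose - mean_control) / sqrt(MSE (1/n1 + 1/n0))`, with a
#' two-sided p-value from the t distribution at the fit's residual df.
#' A gene with MSE = 0 and a non-zero difference gets p = 0 by convention
#' and is flagged in the `degenerate` column.
#'
#' @param fit A `cell_means_fit`.
#' @param dose Treated dose (cGy).
#' @param time Time point (hours).
#' @param control Control dose, default 0.
#' @return Data frame (`gene`, `estimate`, `t`, `p`, `degenerate`) with
#'   attributes `dose`, `time`, `df`.
#' @export
dose_contrast <- function(fit, dose, time, control = 0) {
  stopifnot(inherits(fit, "cell_means_fit"))
  c1 <- which(fit$cells$dose_cGy == dose & fit$cells$time_h == time)
  c0 <- which(fit$cells$dose_cGy == control & fit$cells$time_h == time)
  if (length(c1) != 1L || length(c0) != 1L)
    stop("dose/time cell not present in the fit")
  d <- fit$means[, c1] - fit$means[, c0]
  se <- sqrt(fit$mse * (1 / fit$cells$n[c1] + 1 / fit$cells$n[c0]))
  tstat <- d / se
  p <- 2 * stats::pt(-abs(tstat), fit$df)
  degenerate <- se == 0
  tstat[degenerate & d == 0] <- 0
  p[degenerate] <- ifelse(d[degenerate] == 0, 1, 0)
  out <- data.frame(gene = fit$genes, estimate = unname(d),
                    t = unname(tstat), p = unname(p),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  attr(out, "dose") <- dose
  attr(out, "time") <- time
  attr(out, "df") <- fit$df
  out
}

#' Benjamini-Hochberg FDR adjustment with discovery flags
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level; default 0.10.
#' @return List with `adjusted` (step-up adjusted values) and `flag`
#'   (`adjusted <= q`).
#' @export
bh_fdr <- function(p, q = 0.10) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, flag = adjusted <= q)
}

#' One full dose-versus-control DE comparison
#'
#' Runs [dose_contrast()] and applies BH FDR within the comparison,
#' flagging genes at `q`.
#'
#' @inheritParams dose_contrast
#' @param q FDR level, default 0.10.
#' @return Data frame of class `de_comparison` (`gene`, `estimate`, `t`,
#'   `p`, `q_value`, `de`) with attributes `dose`, `time`, `de_set`.
#' @export
de_comparison <- function(fit, dose, time, q = 0.10, control = 0) {
  cmp <- dose_contrast(fit, dose, time, control)
  fdr <- bh_fdr(cmp$p, q)
  cmp$q_value <- fdr$adjusted
  cmp$de <- fdr$flag
  attr(cmp, "q") <- q
  attr(cmp, "de_set") <- cmp$gene[cmp$de]
  class(cmp) <- c("de_comparison", "data.frame")
  cmp
}

#' Overlap of the low- and high-dose DE sets at one time point
#'
#' Intersects the two comparisons' DE sets and reports the percentage of
#' common genes relative to the union,
#' `100 |low ∩ high| / |low ∪ high|`, rounded to one decimal.
#'
#' @param cmp_low,cmp_high `de_comparison` objects at the same time point
#'   over the same gene universe.
#' @return List with `summary` (one-row data frame: `time_h`, `n_de_low`,
#'   `n_de_high`, `n_common`, `pct_common`) and `genes` (the common set).
#' @export
common_sets <- function(cmp_low, cmp_high) {
  if (!identical(attr(cmp_low, "time"), attr(cmp_high, "time")))
    stop("comparisons are at different time points")
  if (!setequal(cmp_low$gene, cmp_high$gene))
    stop("comparisons use different gene universes")
  a <- attr(cmp_low, "de_set")
  b <- attr(cmp_high, "de_set")
  common <- intersect(a, b)
  list(summary = data.frame(time_h = attr(cmp_low, "time"),
                            n_de_low = length(a), n_de_high = length(b),
                            n_common = length(common),
                            pct_common = common_pct(length(a), length(b),
                                                    length(common))),
       genes = common)
}

#' Percentage of common DE genes from printed counts
#'
#' The denominator is the union of the two DE sets:
#' `100 n_common / (n_low + n_high - n_common)`, rounded to one decimal.
#'
#' @param n_low,n_high Sizes of the two DE sets.
#' @param n_common Size of their intersection
#'   (`<= min(n_low, n_high)`).
#' @return The rounded percentage (0 when both sets are empty).
#' @examples
#' common_pct(1008, 1000, 503)  # 33.4
#' common_pct(702, 953, 482)    # 41.1
#' @export
common_pct <- function(n_low, n_high, n_common) {
  if (n_common > min(n_low, n_high))
    stop("`n_common` cannot exceed either set size")
  uni <- n_low + n_high - n_common
  if (uni == 0) return(0)
  round(100 * n_common / uni, 1)
}

#' Percentage of a set covered by a subset
#'
#' @param subset_size,set_size Non-negative counts with
#'   `subset_size <= set_size` and `set_size > 0`.
#' @return `100 * subset_size / set_size` rounded to one decimal.
#' @examples
#' pct_of_set(482, 702)  # 68.7
#' @export
pct_of_set <- function(subset_size, set_size) {
  if (set_size <= 0) stop("`set_size` must be positive")
  if (subset_size < 0 || subset_size > set_size)
    stop("`subset_size` must lie in [0, set_size]")
  round(100 * subset_size / set_size, 1)
}
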