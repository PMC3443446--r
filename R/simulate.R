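#' Configuration for the synthetic expression generator
#'
#' Collects every tunable of [simulate_expression()]. The generator follows a
#' two-component intensity error model: for probe i and sample j,
#'
#'   y_ij = alpha_true + mu_ij * exp(eta_ij) + eps_ij,
#'
#' with eta ~ N(0, sigma_eta^2) (multiplicative, dominates at high signal)
#' and eps ~ N(0, sigma_eps^2) (additive, dominates near background). This is
#' the error family the generalized-log transform stabilizes, so estimated
#' glog parameters can be checked against `alpha_true` and the noise SDs.
#'
#' The expected signal mu_ij combines, on the log scale: a per-probe
#' baseline (log-normal across probes), planted differential-expression
#' shifts for the sample's (dose, time) cell, and latent module factors.
#' Each module is driven by one standard-normal factor per sample; member
#' genes load on it with weight `loading`, giving high within-module
#' correlation after transformation. Module membership is condition
#' specific: samples at `rewire_dose` use an alternative wiring in which a
#' fraction `frac_rewired` of module genes have been moved to a different
#' module — these are the ground-truth "rewired" genes that downstream
#' network comparison should flag.
#'
#' @param alpha_true Additive background common to all probes (intensity
#'   units).
#' @param sigma_eta SD of the multiplicative log-normal noise (>= 0).
#' @param sigma_eps SD of the additive Gaussian noise (intensity units,
#'   >= 0).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-probe baseline signal.
#' @param n_modules,module_size Number and size of planted coexpression
#'   modules (module genes are drawn from the expressed probes).
#' @param loading Loading of module genes on their latent factor, in glog
#'   units.
#' @param frac_rewired Fraction of module genes reassigned to a different
#'   module in the `rewire_dose` condition.
#' @param rewire_dose Dose (cGy) whose samples use the alternative module
#'   wiring; `NULL` means the highest dose in the design.
#' @param n_de Number of planted DE genes per treated dose at each time.
#' @param frac_common Fraction of each dose's planted DE genes shared with
#'   the other treated dose at the same time.
#' @param de_effect Absolute planted mean shift, in glog (natural-log)
#'   units; the sign of each gene's shift is random.
#' @param frac_unexpressed Fraction of probes simulated as unexpressed:
#'   background-level signal and detection p > 0.05 in every sample.
#' @param unexpressed_baseline Baseline signal of unexpressed probes.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(alpha_true = 100, sigma_eta = 0.15, sigma_eps = 5,
                       baseline_meanlog = log(500), baseline_sdlog = 1.5,
                       n_modules = 8, module_size = 25, loading = 0.8,
                       frac_rewired = 0.15, rewire_dose = NULL,
                       n_de = 60, frac_common = 0.5, de_effect = 1.5,
                       frac_unexpressed = 0.1, unexpressed_baseline = 2) {
  if (sigma_eta < 0 || sigma_eps < 0)
    stop("noise SDs must be non-negative")
  if (frac_rewired < 0 || frac_rewired > 1 ||
      frac_common < 0 || frac_common > 1 ||
      frac_unexpressed < 0 || frac_unexpressed >= 1)
    stop("fractions must lie in [0, 1]")
  if (!is.finite(de_effect)) stop("`de_effect` must be finite")
  structure(list(
    alpha_true = alpha_true, sigma_eta = sigma_eta, sigma_eps = sigma_eps,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    n_modules = n_modules, module_size = module_size, loading = loading,
    frac_rewired = frac_rewired, rewire_dose = rewire_dose,
    n_de = n_de, frac_common = frac_common, de_effect = de_effect,
    frac_unexpressed = frac_unexpressed,
    unexpressed_baseline = unexpressed_baseline
  ), class = "sim_config")
}

#' Simulate a probe-by-sample intensity dataset with known ground truth
#'
#' Generates raw intensities, per-probe/per-sample detection p-values and
#' the planted truth (DE genes, module wiring per condition, rewired genes)
#' under the two-component error model described in [sim_config()].
#' Detection p-values are drawn directly — Uniform(0, 0.05) for expressed
#' probes, Uniform(0.05, 1) for unexpressed probes in every sample — rather
#' than derived from a bead-level model.
#'
#' @param design A `study_design` from [radiation_design()].
#' @param n_probes Number of probes (>= 10).
#' @param config A `sim_config`.
#' @param seed Integer seed; the output is bit-identical for identical
#'   `(design, n_probes, config, seed)`.
#'
#' @return A list of class `sim_result` with elements `intensities`
#'   (probe x sample matrix), `detection` (matching matrix of detection
#'   p-values) and `truth` (class `ground_truth`: `de_genes` — named list
#'   keyed `"<dose>_<time>"` of named shift vectors; `module_assignment` —
#'   per-condition named gene -> module maps; `rewired_genes`;
#'   `error_params`; `unexpressed`; `config`).
#' @export
simulate_expression <- function(design, n_probes = 2000,
                                config = sim_config(), seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(config, "sim_config"))
  if (n_probes < 10) stop("`n_probes` must be >= 10")
  n_module_genes <- config$n_modules * config$module_size
  n_unexpr <- round(config$frac_unexpressed * n_probes)
  if (n_module_genes > n_probes - n_unexpr)
    stop("module genes exceed the number of expressed probes")

  set.seed(seed)
  S <- nrow(design)
  probes <- sprintf("P%05d", seq_len(n_probes))
  doses <- design$dose_cGy
  times <- design$time_h
  rewire_dose <- if (is.null(config$rewire_dose)) max(doses) else config$rewire_dose

  unexpressed <- sort(sample(probes, n_unexpr))
  expressed <- setdiff(probes, unexpressed)

  baseline <- stats::setNames(numeric(n_probes), probes)
  baseline[expressed] <- stats::rlnorm(length(expressed),
                                       config$baseline_meanlog,
                                       config$baseline_sdlog)
  baseline[unexpressed] <- config$unexpressed_baseline

  # module wiring: baseline condition, then rewired variant for rewire_dose
  module_low <- integer(0)
  rewired <- character(0)
  module_high <- integer(0)
  if (config$n_modules > 0 && config$module_size > 0) {
    module_genes <- sample(expressed, n_module_genes)
    module_low <- stats::setNames(rep(seq_len(config$n_modules),
                                      each = config$module_size),
                                  module_genes)
    module_high <- module_low
    if (config$frac_rewired > 0 && config$n_modules > 1) {
      rewired <- sort(sample(module_genes,
                             round(config$frac_rewired * n_module_genes)))
      for (g in rewired) {
        others <- setdiff(seq_len(config$n_modules), module_low[[g]])
        module_high[[g]] <- if (length(others) == 1L) others else sample(others, 1L)
      }
    }
  }
  non_module_expressed <- setdiff(expressed, names(module_low))

  # planted DE: per time, per treated dose, n_de genes with frac_common
  # shared between the first two treated doses
  treated <- .treated_doses(design)
  de_genes <- list()
  if (config$n_de > 0 && length(treated) > 0) {
    for (tt in sort(unique(times))) {
      n_common <- if (length(treated) >= 2) round(config$frac_common * config$n_de) else 0
      n_total <- length(treated) * config$n_de - n_common
      pool <- sample(non_module_expressed, min(n_total, length(non_module_expressed)))
      shared <- pool[seq_len(n_common)]
      rest <- setdiff(pool, shared)
      for (k in seq_along(treated)) {
        n_unique <- config$n_de - if (k <= 2) n_common else 0
        uniq <- rest[seq_len(min(n_unique, length(rest)))]
        rest <- setdiff(rest, uniq)
        genes <- c(if (k <= 2) shared, uniq)
        shifts <- stats::setNames(
          sample(c(-1, 1), length(genes), replace = TRUE) * config$de_effect,
          genes)
        de_genes[[sprintf("%g_%g", treated[k], tt)]] <- shifts
      }
    }
  }

  # expected signal on the log scale
  logmu <- matrix(log(baseline), n_probes, S,
                  dimnames = list(probes, design$sample_id))
  for (key in names(de_genes)) {
    parts <- as.numeric(strsplit(key, "_", fixed = TRUE)[[1]])
    cols <- which(doses == parts[1] & times == parts[2])
    shifts <- de_genes[[key]]
    logmu[names(shifts), cols] <- logmu[names(shifts), cols] + shifts
  }
  if (length(module_low)) {
    factors <- matrix(stats::rnorm(config$n_modules * S), config$n_modules, S)
    high_cond <- doses == rewire_dose
    mod_mat <- cbind(module_low, module_high)  # gene x condition
    for (g in rownames(mod_mat)) {
      m_per_sample <- ifelse(high_cond, mod_mat[g, 2L], mod_mat[g, 1L])
      logmu[g, ] <- logmu[g, ] +
        config$loading * factors[cbind(m_per_sample, seq_len(S))]
    }
  }

  mu <- exp(logmu)
  eta <- matrix(stats::rnorm(n_probes * S, 0, config$sigma_eta), n_probes, S)
  eps <- matrix(stats::rnorm(n_probes * S, 0, config$sigma_eps), n_probes, S)
  y <- config$alpha_true + mu * exp(eta) + eps
  dimnames(y) <- dimnames(logmu)

  detection <- matrix(stats::runif(n_probes * S, 0, 0.05), n_probes, S,
                      dimnames = dimnames(y))
  if (length(unexpressed))
    detection[unexpressed, ] <- stats::runif(length(unexpressed) * S, 0.05, 1)

  truth <- structure(list(
    de_genes = de_genes,
    module_assignment = list(low = module_low, high = module_high),
    rewired_genes = rewired,
    error_params = c(alpha_true = config$alpha_true,
                     sigma_eta = config$sigma_eta,
                     sigma_eps = config$sigma_eps),
    rewire_dose = rewire_dose,
    unexpressed = unexpressed,
    config = config
  ), class = "ground_truth")

  structure(list(intensities = y, detection = detection, truth = truth,
                 design = design),
            class = "sim_result")
}

#' Summarize the planted ground truth
#'
#' @param truth A `ground_truth` object.
#' @return A list with `de` (one row per planted DE gene: dose, time, gene,
#'   shift), `de_counts` (per dose x time), `modules` (per condition x
#'   module size) and `rewired` (character vector of rewired genes).
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  de <- do.call(rbind, lapply(names(truth$de_genes), function(key) {
    parts <- as.numeric(strsplit(key, "_", fixed = TRUE)[[1]])
    shifts <- truth$de_genes[[key]]
    data.frame(dose_cGy = parts[1], time_h = parts[2],
               gene = names(shifts), shift = unname(shifts),
               stringsAsFactors = FALSE)
  }))
  if (is.null(de))
    de <- data.frame(dose_cGy = numeric(0), time_h = numeric(0),
                     gene = character(0), shift = numeric(0))
  de_counts <- if (nrow(de)) {
    stats::aggregate(gene ~ dose_cGy + time_h, de, length)
  } else {
    data.frame(dose_cGy = numeric(0), time_h = numeric(0), gene = integer(0))
  }
  names(de_counts)[3] <- "n_de"
  modules <- do.call(rbind, lapply(names(truth$module_assignment), function(cond) {
    mm <- truth$module_assignment[[cond]]
    if (!length(mm))
      return(data.frame(condition = character(0), module = integer(0),
                        size = integer(0)))
    tab <- table(mm)
    data.frame(condition = cond, module = as.integer(names(tab)),
               size = as.integer(tab), stringsAsFactors = FALSE)
  }))
  list(de = de, de_counts = de_counts, modules = modules,
       rewired = truth$rewired_genes)
}
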