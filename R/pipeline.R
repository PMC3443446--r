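#' Collected thresholds and seeds of the full analysis
#'
#' Every constant used anywhere in the pipeline lives here so a run is
#' fully described by its config: detection filter alpha (0.05), FDR level
#' (0.10), the linking-rule parameters (0.3/top-3 and 0.9/top-50), the
#' low-TO cutoff (<= 0.1), the "high" connectivity-difference threshold
#' (>= 10 links), the number of random networks in the null (1000) and the
#' RNG seed.
#'
#' @param detection_alpha Detection p-value threshold.
#' @param fdr_q BH FDR level for DE flags.
#' @param net A [network_params()].
#' @param to_threshold Low-TO selection cutoff (inclusive).
#' @param conn_threshold Connectivity-difference selection threshold.
#' @param n_random Random networks per TO significance null.
#' @param seed Seed for the rewiring null.
#' @param control_dose Control dose (cGy).
#' @return A list of class `run_config`.
#' @export
run_config <- function(detection_alpha = 0.05, fdr_q = 0.10,
                       net = network_params(), to_threshold = 0.1,
                       conn_threshold = 10, n_random = 1000, seed = 1,
                       control_dose = 0) {
  stopifnot(inherits(net, "network_params"),
            detection_alpha > 0, detection_alpha < 1,
            fdr_q > 0, fdr_q <= 1,
            to_threshold >= 0, to_threshold <= 1,
            conn_threshold >= 1, n_random >= 2)
  structure(list(detection_alpha = detection_alpha, fdr_q = fdr_q,
                 net = net, to_threshold = to_threshold,
                 conn_threshold = conn_threshold, n_random = n_random,
                 seed = seed, control_dose = control_dose),
            class = "run_config")
}

#' Preprocess raw intensities end to end
#'
#' Background subtraction (a no-op when no background vector is supplied —
#' vendor pipelines usually subtract before export), glog parameter
#' estimation, glog transform, quantile normalization, then detection
#' filtering, in the narrative order of the upstream processing.
#'
#' @param raw Probe x sample raw intensity matrix.
#' @param detection Matching detection p-value matrix.
#' @param design `study_design`.
#' @param config `run_config`.
#' @param background Optional per-sample background vector.
#' @return List: `norm` (filtered normalized matrix), `glog_params`,
#'   `n_removed` (probes dropped by the detection filter).
#' @export
preprocess_pipeline <- function(raw, detection, design,
                                config = run_config(), background = NULL) {
  if (!is.null(background)) raw <- subtract_background(raw, background)
  params <- estimate_glog(raw, design)
  z <- glog_transform(raw, params)
  z <- quantile_normalize(z)
  norm <- filter_detection(z, detection, config$detection_alpha)
  list(norm = norm, glog_params = params,
       n_removed = nrow(z) - nrow(norm))
}

#' Differential expression over all dose/time contrasts
#'
#' Fits the per-gene cell-means ANOVA once, then runs every
#' treated-dose-versus-control comparison at every time point with BH FDR
#' within each comparison, and the common-set arithmetic between the first
#' two treated doses.
#'
#' @param norm Normalized, filtered gene x sample matrix.
#' @param design `study_design`.
#' @param config `run_config`.
#' @return List with `fit` and `times`: per time point, the
#'   `de_comparison` per treated dose plus `common` (see [common_sets()]).
#' @export
de_pipeline <- function(norm, design, config = run_config()) {
  fit <- fit_cell_means(norm, design)
  treated <- .treated_doses(design)
  times <- sort(attr(design, "times"))
  per_time <- lapply(times, function(tt) {
    cmps <- lapply(treated, function(d)
      de_comparison(fit, d, tt, q = config$fdr_q,
                    control = config$control_dose))
    names(cmps) <- as.character(treated)
    common <- if (length(treated) >= 2) common_sets(cmps[[1]], cmps[[2]])
              else NULL
    list(comparisons = cmps, common = common)
  })
  names(per_time) <- as.character(times)
  list(fit = fit, times = per_time)
}

# internal: network from `genes` using control + `dose` samples at `time`
.condition_network <- function(norm, design, genes, dose, time, config) {
  cols <- design$dose_cGy %in% c(config$control_dose, dose) &
    design$time_h == time
  corr <- suppressWarnings(pairwise_pcc(norm[genes, cols, drop = FALSE]))
  net <- build_network(corr, config$net)
  attr(net, "pcc") <- corr
  net
}

# internal: Table-1-style letter pair for the i-th time point
.time_letters <- function(i) c(LETTERS[2 * i - 1], LETTERS[2 * i])

#' Analysis I: topology of common-DE-gene networks
#'
#' For each time point, builds the two dose-specific networks over the
#' common DE genes (samples: control + that dose at that time), then
#' computes per-gene topological overlap with rewiring-null significance,
#' the low-TO gene selection, and the connectivity-difference table.
#' Time points whose common set is too small to network (fewer than
#' `k_low + 1` genes) are skipped with a log entry. Networks are named
#' `netXY1`/`netXY2` after consecutive letter pairs per time point. The
#' earliest time point is flagged `caution` (an immediate-harvest time
#' mixes shock response with dose response).
#'
#' @param norm Normalized, filtered matrix.
#' @param design `study_design`.
#' @param de Output of [de_pipeline()].
#' @param config `run_config`.
#' @return Per time point: `networks` (named pair), `to` (significance
#'   table), `low_to`, `conn_diff`, `skipped`, `caution`.
#' @export
run_analysis_I <- function(norm, design, de, config = run_config()) {
  treated <- .treated_doses(design)
  if (length(treated) < 2)
    stop("Analysis I needs two treated doses")
  times <- sort(attr(design, "times"))
  out <- lapply(seq_along(times), function(i) {
    tt <- times[i]
    genes <- de$times[[as.character(tt)]]$common$genes
    lab <- paste0(.time_letters(i), collapse = "")
    res <- list(time_h = tt, names = paste0("net", lab, 1:2),
                n_genes = length(genes), caution = tt == min(times))
    if (length(genes) < config$net$k_low + 1) {
      message(sprintf("T%g: common set of %d genes too small to network; skipped",
                      tt, length(genes)))
      res$skipped <- TRUE
      return(res)
    }
    res$skipped <- FALSE
    net1 <- .condition_network(norm, design, genes, treated[1], tt, config)
    net2 <- .condition_network(norm, design, genes, treated[2], tt, config)
    if (!setequal(net1$nodes, net2$nodes)) {
      # a zero-variance gene was dropped on one side; use the shared set
      genes <- intersect(net1$nodes, net2$nodes)
      net1 <- .condition_network(norm, design, genes, treated[1], tt, config)
      net2 <- .condition_network(norm, design, genes, treated[2], tt, config)
    }
    res$networks <- stats::setNames(list(net1, net2), res$names)
    res$to <- to_significance(net1, net2, n_random = config$n_random,
                              seed = config$seed)
    res$low_to <- select_low_to(res$to, config$to_threshold)
    res$conn_diff <- connectivity_difference(net1, net2,
                                             config$conn_threshold)
    res
  })
  names(out) <- as.character(times)
  out
}

#' Analysis II: connectivity differences in all-DE-gene networks
#'
#' For each time point, builds the two all-DE-gene networks (one per
#' treated dose, named `networkX`/`networkY` by the time point's letter
#' pair), computes the connectivity difference of the *common* DE genes
#' between them, and intersects the selection with the Analysis I
#' selection at the same time — genes whose connectivity shifts at both
#' network levels.
#'
#' @inheritParams run_analysis_I
#' @param analysis1 Output of [run_analysis_I()].
#' @return Per time point: `networks`, `conn_diff` (common genes inside
#'   the all-DE networks), `intersection`, `skipped`.
#' @export
run_analysis_II <- function(norm, design, de, analysis1,
                            config = run_config()) {
  treated <- .treated_doses(design)
  times <- sort(attr(design, "times"))
  out <- lapply(seq_along(times), function(i) {
    tt <- times[i]
    key <- as.character(tt)
    cmps <- de$times[[key]]$comparisons
    set1 <- attr(cmps[[1]], "de_set")
    set2 <- attr(cmps[[2]], "de_set")
    common <- de$times[[key]]$common$genes
    lab <- .time_letters(i)
    res <- list(time_h = tt, names = paste0("network", lab),
                n_genes = c(length(set1), length(set2)))
    if (min(length(set1), length(set2)) < config$net$k_low + 1 ||
        length(common) == 0) {
      message(sprintf("T%g: DE sets too small for Analysis II; skipped", tt))
      res$skipped <- TRUE
      return(res)
    }
    res$skipped <- FALSE
    netA <- .condition_network(norm, design, set1, treated[1], tt, config)
    netB <- .condition_network(norm, design, set2, treated[2], tt, config)
    res$networks <- stats::setNames(list(netA, netB), res$names)
    common_in_both <- intersect(intersect(common, netA$nodes), netB$nodes)
    res$conn_diff <- connectivity_difference(netA, netB,
                                             config$conn_threshold,
                                             genes = common_in_both)
    a1 <- analysis1[[key]]
    res$intersection <-
      if (!is.null(a1) && isFALSE(a1$skipped))
        cross_level_intersection(res$conn_diff, a1$conn_diff)
      else character(0)
    res
  })
  names(out) <- as.character(times)
  out
}

#' Run the whole pipeline on a simulated dataset
#'
#' Convenience driver: simulate -> preprocess -> DE -> Analysis I ->
#' Analysis II, fully determined by `(design, n_probes, sim, config,
#' seed)`.
#'
#' @param design `study_design`.
#' @param n_probes Probe count for the simulation.
#' @param sim `sim_config`.
#' @param config `run_config`.
#' @param seed Simulation seed.
#' @return List: `sim`, `pre`, `de`, `analysis1`, `analysis2`.
#' @export
run_pipeline <- function(design = radiation_design(), n_probes = 2000,
                         sim = sim_config(), config = run_config(),
                         seed = 1) {
  dat <- simulate_expression(design, n_probes, sim, seed)
  pre <- preprocess_pipeline(dat$intensities, dat$detection, design, config)
  de <- de_pipeline(pre$norm, design, config)
  a1 <- run_analysis_I(pre$norm, design, de, config)
  a2 <- run_analysis_II(pre$norm, design, de, a1, config)
  list(sim = dat, pre = pre, de = de, analysis1 = a1, analysis2 = a2)
}
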