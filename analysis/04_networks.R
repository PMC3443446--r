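#!/usr/bin/env Rscript
# Stage 4: coexpression network construction.
#
# For each time point, builds the dose-specific networks with the
# two-condition linking rule (PCC >= 0.3 with mutual top-3 rank, or
# PCC >= 0.9 within top-50): the common-DE-gene pair netXY1/netXY2 for
# Analysis I, and the all-DE-gene pair networkX/networkY for Analysis II.
# Each network uses only the control + treated samples of its dose at
# that time (4 arrays) — faithful to the original design and noisy, which
# is why significance is later judged against a rewiring null.

suppressPackageStartupMessages(library(coexdiff))

outdir <- "results/networks"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

norm <- read_matrix_tsv("results/preprocess/normalized.tsv")
design <- read_sample_sheet("results/data/samples.tsv")
cfg <- run_config(n_random = 1000, seed = 1)

de <- de_pipeline(norm, design, cfg)
a1 <- suppressWarnings(run_analysis_I(norm, design, de, cfg))
a2 <- suppressWarnings(run_analysis_II(norm, design, de, a1, cfg))

for (tt in names(a1)) {
  for (res in list(a1[[tt]], a2[[tt]])) {
    if (isTRUE(res$skipped)) {
      message(sprintf("T%s: %s skipped (too few genes)", tt,
                      paste(res$names, collapse = "/")))
      next
    }
    for (nm in names(res$networks)) {
      net <- res$networks[[nm]]
      write_network_tsv(net, file.path(outdir, paste0(nm, ".tsv")),
                        corr = attr(net, "pcc"))
      comp <- network_components(net)
      message(sprintf("T%s %s: %d nodes, %d edges, %d component(s), degrees %d-%d",
                      tt, nm, length(net$nodes), net$n_edges, comp$count,
                      min(net$degrees), max(net$degrees)))
    }
  }
}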