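# coexdiff

Differential topology of gene coexpression networks across radiation
doses.

## What this is for

Low-dose (10 cGy) and high-dose (100 cGy) ionising radiation perturb
largely overlapping sets of genes, so differentially-expressed (DE) gene
lists separate the two exposures poorly. `coexdiff` targets the part of
the response that set arithmetic cannot see: genes shared by both DE
sets whose *coexpression neighbourhood* changes with dose. It is aimed
at anyone comparing condition-specific coexpression networks built from
small designed experiments — the methods are generic, the defaults match
a 3-dose × 4-time × 2-replicate skin-tissue irradiation design.

The pipeline, each stage an exported function:

1. **Variance stabilization** — generalized-log transform
   `g(y) = ln((y−α) + √((y−α)² + λ))` with `(λ, α)` estimated by profile
   maximum likelihood (`estimate_glog()`), quantile normalization, and
   removal of probes never detected (detection p > 0.05 in all samples).
2. **Differential expression** — per-gene cell-means ANOVA
   (12 residual df on the full design), dose-vs-control t contrasts with
   the gene-specific MSE, Benjamini–Hochberg FDR at q = 0.10, and the
   common-DE-gene set arithmetic.
3. **Network construction** — link two genes if PCC ≥ 0.3 with either in
   the other's top-3, or PCC ≥ 0.9 with either in the other's top-50
   (`build_network()`); binary, symmetric, undirected.
4. **Cross-network topology** — per-gene topological overlap
   `TO_i = |X∩Y| / max(d1_i, d2_i)` between two networks on the same
   nodes, low-TO selection (TO ≤ 0.1), significance against 1000
   degree-preserving random rewirings, and ≥ 10-link connectivity
   differences at two network levels (`to_significance()`,
   `connectivity_difference()`).

A synthetic generator (`simulate_expression()`) plants DE genes and
dose-specific module wiring with known ground truth, so the whole
pipeline is testable end to end without downloads.

## Worked example

The `analysis/` directory holds the staged workflow; running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_networks.R
Rscript analysis/05_network_comparison.R
```

writes every table under `results/` and prints, among other lines:

```
estimated glog parameters: lambda = 271.3, alpha = 97.27
per-probe SD range raw: 3.412-6.978e+04 (ratio 20451)
after glog + quantile: 0.08217-0.9937 (ratio 12.1); contraction 1691x
cell-means fit: 1800 genes, 12 residual df
  T3: low 66, high 64, common 29 (28.7%)
T3 (netCD1 vs netCD2): 29 genes, 0 low-TO (0.0%), 1 with |d1-d2| >= 10 ...
module-gene networks (200 genes): mean TO 0.005 rewired vs 0.609
  non-rewired; 30/30 rewired in the low-TO set; 30/30 significant at p < 0.05
```

Reading these: the estimated background `alpha = 97.27` recovers the
simulated truth of 100; the transform contracts the per-probe SD ratio
by three orders of magnitude, which is what makes a common-variance
ANOVA defensible; each time point yields ~30 common DE genes that become
the nodes of the paired dose-specific networks; and on the module genes
— where dose-specific rewiring was actually planted — every one of the
30 rewired genes lands in the low-TO (≤ 0.1) set and is significant
against the rewiring null, while unrewired module genes average TO 0.61.

Smaller building blocks work standalone:

```r
library(coexdiff)
design <- radiation_design()            # 24 samples
dat <- simulate_expression(design, n_probes = 2000, seed = 1)
gp <- estimate_glog(dat$intensities, design)
z <- quantile_normalize(glog_transform(dat$intensities, gp))
fit <- fit_cell_means(filter_detection(z, dat$detection), design)
fit$df                                   # 12
cmp <- de_comparison(fit, dose = 10, time = 3, q = 0.10)
common_pct(1008, 1000, 503)              # 33.4
```

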