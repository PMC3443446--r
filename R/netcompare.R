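# internal: TO values from two aligned adjacency matrices
.to_values <- function(A1, A2) {
  inter <- rowSums(A1 & A2)
  d1 <- rowSums(A1 != 0)
  d2 <- rowSums(A2 != 0)
  denom <- pmax(d1, d2)
  to <- ifelse(denom > 0, inter / denom, NA_real_)
  list(to = to, d1 = d1, d2 = d2, inter = inter)
}

# internal: align net2's adjacency to net1's node order, or die
.align_nets <- function(net1, net2) {
  if (!setequal(net1$nodes, net2$nodes))
    stop("networks must share an identical node set")
  idx <- match(net1$nodes, net2$nodes)
  net2$adjacency[idx, idx, drop = FALSE]
}

#' Per-gene topological overlap between two networks
#'
#' For each gene i present in both networks (which must share their node
#' set), the cross-network topological overlap is
#' `TO_i = |X ∩ Y| / max(d1_i, d2_i)`, where X and Y are i's neighbour
#' sets and d1_i, d2_i its degrees in the two networks. TO lies in
#' `[0, 1]` and equals 1 exactly when the neighbourhoods coincide. A gene
#' isolated in both networks has undefined TO, reported as `NA` with a
#' warning (this cannot arise in networks built with the default linking
#' rule, whose minimum degree is the rank depth).
#'
#' @param net1,net2 `coexpression_network`s over the same node set.
#' @return Data frame (`gene`, `d1`, `d2`, `n_overlap`, `to`) in `net1`'s
#'   node order.
#' @export
topological_overlap <- function(net1, net2) {
  A2 <- .align_nets(net1, net2)
  v <- .to_values(net1$adjacency, A2)
  if (anyNA(v$to))
    warning(sum(is.na(v$to)), " isolated gene(s): TO undefined, reported NA")
  data.frame(gene = net1$nodes, d1 = unname(v$d1), d2 = unname(v$d2),
             n_overlap = unname(v$inter), to = unname(v$to),
             stringsAsFactors = FALSE)
}

#' Select genes with low topological overlap
#'
#' @param to_table Output of [topological_overlap()] (or
#'   [to_significance()]).
#' @param threshold Inclusive TO cutoff in `[0, 1]`, default 0.1.
#' @return List with `genes` (TO <= threshold), `n`, `n_total` and
#'   `fraction` (percentage of the network's genes selected, one decimal).
#' @export
select_low_to <- function(to_table, threshold = 0.1) {
  if (threshold < 0 || threshold > 1) stop("`threshold` must lie in [0, 1]")
  sel <- !is.na(to_table$to) & to_table$to <= threshold
  list(genes = to_table$gene[sel], n = sum(sel), n_total = nrow(to_table),
       fraction = round(100 * sum(sel) / nrow(to_table), 1))
}

#' Degree-preserving random rewiring of a network
#'
#' Randomizes a network's wiring while keeping every gene's degree exactly
#' equal to the original, via double-edge swaps that never introduce
#' self-edges or multi-edges (delegated to [igraph::rewire()] with
#' `keeping_degseq`). This is the null model for judging whether an
#' observed topological overlap is lower than expected for networks of the
#' same degree sequence.
#'
#' @param net A `coexpression_network` with >= 2 edges.
#' @param n_attempts Number of attempted swaps; default `10 * n_edges`.
#' @param seed Optional integer seed for a reproducible draw; `NULL` uses
#'   (and advances) the current RNG state.
#' @return A rewired `coexpression_network` with identical degrees. If no
#'   swap succeeded the input wiring is returned with a warning.
#' @export
rewire_network <- function(net, n_attempts = NULL, seed = NULL) {
  if (net$n_edges < 2) stop("rewiring needs >= 2 edges")
  if (is.null(n_attempts)) n_attempts <- 10 * net$n_edges
  g <- as_igraph(net)
  do_rewire <- function() {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = n_attempts))
  }
  rw <- if (is.null(seed)) do_rewire() else withr::with_seed(seed, do_rewire())
  adj <- as.matrix(igraph::as_adjacency_matrix(rw))
  storage.mode(adj) <- "integer"
  dimnames(adj) <- dimnames(net$adjacency)
  out <- coexpression_network(adj)
  stopifnot(identical(out$degrees, net$degrees))  # contract
  if (identical(out$adjacency, net$adjacency))
    warning("no rewiring occurred; network returned unchanged")
  out
}

#' Topological overlap with rewiring-null significance
#'
#' Computes observed per-gene TO between two networks and compares it with
#' a null distribution obtained by independently rewiring both networks
#' (degree-preserving double-edge swaps) `n_random` times and recomputing
#' TO. Per gene, the statistic is
#' `t = (null mean - observed TO) / (null SD / sqrt(n_random))`, a
#' one-sample t-statistic with `n_random - 1` df, and the one-sided
#' p-value asks whether the observed overlap is *lower* than expected for
#' random networks with these degree sequences. A gene whose null SD is 0
#' gets p = 0 (observed below the null mean) or 1 (otherwise) by sign
#' convention and is flagged `degenerate`.
#'
#' @param net1,net2 `coexpression_network`s over the same node set.
#' @param n_random Number of random network pairs, default 1000 (>= 2).
#' @param seed Optional integer seed making the whole null reproducible.
#' @param randomize `"both"` (default) rewires both networks each
#'   replicate; `"second"` keeps `net1` fixed.
#' @return The [topological_overlap()] table plus `null_mean`, `null_sd`,
#'   `t`, `p`, `significant` (p < 0.05) and `degenerate`.
#' @export
to_significance <- function(net1, net2, n_random = 1000, seed = NULL,
                            randomize = c("both", "second")) {
  randomize <- match.arg(randomize)
  if (n_random < 2) stop("`n_random` must be >= 2")
  obs <- topological_overlap(net1, net2)
  A2 <- .align_nets(net1, net2)
  net2a <- coexpression_network(A2)

  run_null <- function() {
    vapply(seq_len(n_random), function(r) {
      r1 <- if (randomize == "both") rewire_network(net1)$adjacency
            else net1$adjacency
      r2 <- rewire_network(net2a)$adjacency
      .to_values(r1, r2)$to
    }, numeric(length(net1$nodes)))
  }
  tos <- if (is.null(seed)) suppressWarnings(run_null())
         else withr::with_seed(seed, suppressWarnings(run_null()))
  # tos: gene x n_random
  null_mean <- rowMeans(tos)
  null_sd <- sqrt(rowSums((tos - null_mean)^2) / (n_random - 1))
  tstat <- (null_mean - obs$to) / (null_sd / sqrt(n_random))
  p <- stats::pt(tstat, df = n_random - 1, lower.tail = FALSE)
  degenerate <- !is.na(null_sd) & null_sd == 0
  p[degenerate] <- ifelse(null_mean[degenerate] > obs$to[degenerate], 0, 1)
  obs$null_mean <- null_mean
  obs$null_sd <- null_sd
  obs$t <- ifelse(degenerate, NA_real_, tstat)
  obs$p <- p
  obs$significant <- !is.na(p) & p < 0.05
  obs$degenerate <- degenerate
  obs
}

#' Per-gene connectivity difference between two networks
#'
#' Reports each gene's degrees in the two networks, the absolute
#' difference, which network has the higher connectivity, and whether the
#' difference reaches the selection threshold (default: a "high"
#' difference is >= 10 links).
#'
#' @param net1,net2 `coexpression_network`s. By default they must share
#'   their node set; alternatively `genes` restricts the comparison to a
#'   set of genes present in both (the paper compares common DE genes
#'   inside larger all-DE networks this way).
#' @param threshold Selection threshold T >= 1, default 10.
#' @param genes Optional gene subset present in both networks.
#' @return Data frame (`gene`, `d1`, `d2`, `difference`, `direction`,
#'   `selected`) with attribute `counts` = c(higher_net1, higher_net2)
#'   among selected genes.
#' @export
connectivity_difference <- function(net1, net2, threshold = 10,
                                    genes = NULL) {
  if (threshold < 1) stop("`threshold` must be >= 1")
  if (is.null(genes)) {
    if (!setequal(net1$nodes, net2$nodes))
      stop("networks must share a node set (or pass `genes`)")
    genes <- net1$nodes
  } else if (!all(genes %in% net1$nodes) || !all(genes %in% net2$nodes)) {
    stop("some `genes` are missing from one of the networks")
  }
  d1 <- net1$degrees[match(genes, net1$nodes)]
  d2 <- net2$degrees[match(genes, net2$nodes)]
  diff <- abs(d1 - d2)
  direction <- ifelse(d1 > d2, "net1", ifelse(d2 > d1, "net2", "equal"))
  out <- data.frame(gene = genes, d1 = unname(d1), d2 = unname(d2),
                    difference = unname(diff), direction = direction,
                    selected = unname(diff >= threshold),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(higher_net1 = sum(out$selected & direction == "net1"),
                           higher_net2 = sum(out$selected & direction == "net2"))
  out
}

#' Genes with high connectivity difference at both network levels
#'
#' Intersects the selections of two [connectivity_difference()] runs at
#' the same time point — typically the all-DE-gene networks and the
#' common-gene networks — keeping genes that exceed the threshold in both.
#'
#' @param diff1,diff2 `connectivity_difference` tables or plain character
#'   vectors of selected genes.
#' @return Character vector of genes selected in both.
#' @export
cross_level_intersection <- function(diff1, diff2) {
  pick <- function(x) if (is.data.frame(x)) x$gene[x$selected] else x
  intersect(pick(diff1), pick(diff2))
}
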