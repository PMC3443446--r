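#' Parameters of the two-condition linking rule
#'
#' Two genes are linked when at least one condition holds:
#' (1) their PCC is at least `t_low` and either is among the other's
#' `k_low` most correlated genes; (2) their PCC is at least `t_high` and
#' either is among the other's `k_high` most correlated genes. The
#' thresholds are inclusive (a pair at exactly 0.3 links under condition
#' 1), and "one gene is ranked ... of the other" is read as either
#' direction sufficing, giving an undirected graph.
#'
#' @param t_low PCC cutoff of condition 1 (default 0.3).
#' @param k_low Rank depth of condition 1 (default 3).
#' @param t_high PCC threshold t of condition 2 (default 0.9).
#' @param k_high Rank depth of condition 2 (default 50).
#' @param use_abs Qualify edges on `|PCC|` instead of signed PCC
#'   (default `FALSE`: only positive correlations link).
#' @return A list of class `network_params`.
#' @export
network_params <- function(t_low = 0.3, k_low = 3, t_high = 0.9,
                           k_high = 50, use_abs = FALSE) {
  if (t_low < 0 || t_high > 1 || t_low > t_high)
    stop("need 0 <= t_low <= t_high <= 1")
  if (k_low < 1 || k_low > k_high)
    stop("need 1 <= k_low <= k_high")
  structure(list(t_low = t_low, k_low = k_low, t_high = t_high,
                 k_high = k_high, use_abs = use_abs),
            class = "network_params")
}

#' Pairwise Pearson correlation between genes
#'
#' @param x Gene x sample expression matrix with >= 3 samples (a warning
#'   is raised below 4, where PCC is very noisy — dose-specific networks
#'   built from one time point use only 4 arrays). Zero-variance genes are
#'   dropped with a warning.
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#' @export
pairwise_pcc <- function(x) {
  if (ncol(x) < 3) stop("PCC needs >= 3 samples")
  if (ncol(x) < 4)
    warning("only ", ncol(x), " samples: correlations will be very noisy")
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s): ",
            paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Neighbours of a gene in descending correlation order
#'
#' Ties are broken by ascending gene index (position in the correlation
#' matrix), so the ordering is strict and stable.
#'
#' @param corr Gene x gene correlation matrix.
#' @param gene Gene name or index.
#' @return Character vector of all other genes, most correlated first.
#' @export
rank_neighbours <- function(corr, gene) {
  i <- if (is.character(gene)) match(gene, rownames(corr)) else gene
  if (is.na(i) || i < 1 || i > nrow(corr)) stop("gene not found")
  v <- corr[i, ]
  v[i] <- -Inf
  ord <- order(-v)          # ties keep ascending index order
  ord <- ord[ord != i]
  rownames(corr)[ord]
}

#' Build a coexpression network with the rank/threshold linking rule
#'
#' Applies the two conditions of [network_params()] to a correlation
#' matrix and returns the binary, symmetric, zero-diagonal adjacency.
#' Within each gene's ranking, ties are broken by ascending gene index.
#'
#' @param corr Symmetric gene x gene correlation matrix (from
#'   [pairwise_pcc()]).
#' @param params A `network_params`.
#' @return A `coexpression_network`.
#' @export
build_network <- function(corr, params = network_params()) {
  stopifnot(inherits(params, "network_params"))
  m <- nrow(corr)
  score <- if (params$use_abs) abs(corr) else corr
  diag(score) <- -Inf
  # rk[i, j] = rank of j in i's descending-correlation list (self ranks last)
  rk <- t(apply(score, 1L, function(v) rank(-v, ties.method = "first")))
  in_low <- rk <= params$k_low
  in_high <- rk <= params$k_high
  adj <- (score >= params$t_low & (in_low | t(in_low))) |
         (score >= params$t_high & (in_high | t(in_high)))
  diag(adj) <- FALSE
  storage.mode(adj) <- "integer"
  dimnames(adj) <- dimnames(corr)
  coexpression_network(adj)
}

#' Coexpression network container
#'
#' Validates and wraps a binary symmetric zero-diagonal adjacency matrix.
#'
#' @param adjacency Integer 0/1 matrix with identical row/column names.
#' @return A list of class `coexpression_network`: `nodes`, `adjacency`,
#'   `degrees` (row sums), `n_edges`.
#' @export
coexpression_network <- function(adjacency) {
  if (is.null(rownames(adjacency)))
    rownames(adjacency) <- colnames(adjacency) <- sprintf("g%d", seq_len(nrow(adjacency)))
  storage.mode(adjacency) <- "integer"
  if (!all(adjacency %in% c(0L, 1L))) stop("adjacency must be binary")
  if (!identical(adjacency, t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0L)) stop("adjacency must have a zero diagonal")
  degrees <- rowSums(adjacency)
  structure(list(nodes = rownames(adjacency), adjacency = adjacency,
                 degrees = degrees, n_edges = sum(adjacency) / 2),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("Coexpression network: %d nodes, %d edges, degree range %d-%d\n",
              length(x$nodes), x$n_edges,
              if (length(x$degrees)) min(x$degrees) else 0L,
              if (length(x$degrees)) max(x$degrees) else 0L))
  invisible(x)
}

#' Convert a network to an igraph graph
#' @param net A `coexpression_network`.
#' @return An undirected `igraph` graph with the same vertex names.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Connected components of a network
#'
#' The linking rule aims for a single connected component; this checks the
#' claim rather than enforcing it.
#'
#' @param net A `coexpression_network`.
#' @return List with `count` and `sizes` (descending).
#' @export
network_components <- function(net) {
  if (!length(net$nodes)) stop("empty network")
  comp <- igraph::components(as_igraph(net))
  list(count = comp$no, sizes = sort(as.integer(comp$csize), decreasing = TRUE))
}
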