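#' Read and write the package's tab-delimited formats
#'
#' Matrices are written probes-as-rows with a `probe_id` first column and a
#' header of sample ids; sample sheets carry `sample_id`, `dose_cGy`,
#' `time_h`, `replicate`; networks are written as an edge list
#' (`gene_a`, `gene_b`, optional `pcc`) plus a node file so isolated nodes
#' survive a round trip; ground truth is serialized as JSON.
#'
#' @param x Matrix (probe x sample) to write.
#' @param path File path.
#' @name io
NULL

#' @rdname io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyNA(m)) stop("matrix contains missing values: ", path)
  m
}

#' @rdname io
#' @param design A `study_design`.
#' @export
write_sample_sheet <- function(design, path) {
  utils::write.table(as.data.frame(design)[, c("sample_id", "dose_cGy",
                                               "time_h", "replicate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df,
            doses = sort(unique(df$dose_cGy)),
            times = sort(unique(df$time_h)),
            replicates = max(df$replicate),
            class = c("study_design", "data.frame"))
}

#' @rdname io
#' @param net A `coexpression_network`.
#' @param corr Optional correlation matrix supplying the `pcc` edge column.
#' @export
write_network_tsv <- function(net, path, corr = NULL) {
  idx <- which(net$adjacency == 1L & upper.tri(net$adjacency), arr.ind = TRUE)
  edges <- data.frame(gene_a = net$nodes[idx[, 1]],
                      gene_b = net$nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  if (!is.null(corr)) edges$pcc <- corr[idx]
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(net$nodes, paste0(path, ".nodes"))
  invisible(path)
}

#' @rdname io
#' @export
read_network_tsv <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes <- readLines(paste0(path, ".nodes"))
  adj <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    ia <- match(edges$gene_a, nodes)
    ib <- match(edges$gene_b, nodes)
    adj[cbind(ia, ib)] <- 1L
    adj[cbind(ib, ia)] <- 1L
  }
  coexpression_network(adj)
}

#' @rdname io
#' @param truth A `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  x <- truth
  x$config <- unclass(x$config)
  # named vectors must become JSON objects, not bare arrays
  x$de_genes <- lapply(x$de_genes, as.list)
  x$module_assignment <- lapply(x$module_assignment, as.list)
  x$error_params <- as.list(x$error_params)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$de_genes <- lapply(x$de_genes, unlist)
  x$module_assignment <- lapply(x$module_assignment, unlist)
  x$error_params <- unlist(x$error_params)
  x$config <- do.call(sim_config, x$config[!vapply(x$config, is.null, TRUE)])
  if (is.null(x$rewired_genes)) x$rewired_genes <- character(0)
  structure(x, class = "ground_truth")
}
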