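test_that("pairwise PCC matches hand computation and handles degeneracies", {
  x <- rbind(a = c(1, 2, 3, 4),
             b = c(2, 4, 6, 8),     # duplicate profile (scaled)
             c = c(4, 3, 2, 1),     # negation
             d = c(1, 5, 2, 7))
  r <- pairwise_pcc(x)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "d"], cor(c(1, 2, 3, 4), c(1, 5, 2, 7)))
  expect_equal(r, t(r))
  expect_true(all(diag(r) == 1))
  # zero-variance gene dropped with a warning
  x2 <- rbind(x, flat = c(3, 3, 3, 3))
  expect_warning(r2 <- pairwise_pcc(x2), "zero-variance")
  expect_false("flat" %in% rownames(r2))
  expect_error(pairwise_pcc(x[, 1:2]), ">= 3 samples")
  expect_warning(pairwise_pcc(x[, 1:3]), "noisy")
})

test_that("neighbour ranking is descending with index tie-breaks", {
  genes <- c("A", "B", "C", "D")
  corr <- corr_from_pairs(genes, list(
    list("A", "B", 0.9), list("A", "C", 0.5), list("A", "D", 0.1)))
  expect_equal(rank_neighbours(corr, "A"), c("B", "C", "D"))
  # all-equal correlations: ascending index order
  tied <- corr_from_pairs(genes, list(
    list("A", "B", 0.4), list("A", "C", 0.4), list("A", "D", 0.4)))
  expect_equal(rank_neighbours(tied, "A"), c("B", "C", "D"))
  # negative correlations rank below positive
  signed <- corr_from_pairs(genes, list(
    list("A", "B", -0.9), list("A", "C", 0.2), list("A", "D", 0.05)))
  expect_equal(rank_neighbours(signed, "A"), c("C", "D", "B"))
  expect_error(rank_neighbours(corr, "Z"), "not found")
})

test_that("the linking rule reproduces the worked 3-link and 1-link cases", {
  genes <- c("A", "B", "C", "D")
  # three candidates at 0.3, 0.32, 0.4: all three link to A
  corr3 <- corr_from_pairs(genes, list(
    list("A", "B", 0.3), list("A", "C", 0.32), list("A", "D", 0.4)))
  net3 <- build_network(corr3)
  expect_equal(unname(net3$degrees["A"]), 3)
  # candidates at 0.3, 0.28, 0.29: only the 0.3 gene links (inclusive cut)
  corr1 <- corr_from_pairs(genes, list(
    list("A", "B", 0.3), list("A", "C", 0.28), list("A", "D", 0.29)))
  net1 <- build_network(corr1)
  expect_equal(unname(net1$degrees["A"]), 1)
  expect_equal(net1$adjacency["A", "B"], 1L)
})

test_that("condition (2) links high-PCC pairs outside each other's top-3", {
  genes <- paste0("g", 1:6)
  pairs <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    pairs[[length(pairs) + 1]] <- list(genes[i], genes[j], 0.92)
  }
  corr <- corr_from_pairs(genes, pairs)
  corr["g1", "g5"] <- corr["g5", "g1"] <- 0.91
  # g5 is rank 4 for g1 and vice versa: condition (1) cannot link them
  expect_equal(rank_neighbours(corr, "g1")[4], "g5")
  net <- build_network(corr, network_params())
  expect_equal(net$adjacency["g1", "g5"], 1L)
  # with t_high above 0.91 the pair drops out again
  net_hi <- build_network(corr, network_params(t_high = 0.95))
  expect_equal(net_hi$adjacency["g1", "g5"], 0L)
})

test_that("vectorized builder equals the brute-force oracle", {
  set.seed(21)
  for (rep in 1:4) {
    x <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    corr <- pairwise_pcc(x)
    for (params in list(network_params(),
                        network_params(t_low = 0.2, k_low = 2,
                                       t_high = 0.6, k_high = 5),
                        network_params(use_abs = TRUE))) {
      net <- build_network(corr, params)
      expect_identical(net$adjacency, brute_network(corr, params))
    }
  }
})

test_that("adjacency is symmetric, binary and hollow after every build", {
  set.seed(22)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
    net <- build_network(pairwise_pcc(x))
    expect_identical(net$adjacency, t(net$adjacency))
    expect_true(all(diag(net$adjacency) == 0L))
    expect_true(all(net$adjacency %in% c(0L, 1L)))
    expect_equal(unname(net$degrees), unname(rowSums(net$adjacency)))
  }
})

test_that("raising t_high never adds edges", {
  set.seed(23)
  x <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(sprintf("g%02d", 1:60), NULL))
  corr <- pairwise_pcc(x)
  prev <- build_network(corr, network_params(t_high = 0.5, k_high = 10))
  for (t_high in c(0.7, 0.9, 1.0)) {
    cur <- build_network(corr, network_params(t_high = t_high, k_high = 10))
    expect_true(all(cur$adjacency <= prev$adjacency))
    prev <- cur
  }
})

test_that("every node reaches the minimum connectivity when its top-3 clear the cutoff", {
  # strong module structure: each gene's top-3 correlations exceed 0.3
  design8 <- radiation_design(doses = c(0, 10), times = c(0, 3),
                              replicates = 2)
  cfg <- sim_config(n_modules = 5, module_size = 20, frac_rewired = 0,
                    n_de = 0, frac_unexpressed = 0, sigma_eps = 1)
  dat <- simulate_expression(design8, 100, cfg, seed = 30)
  z <- glog_transform(dat$intensities,
                      list(lambda = 1, alpha = cfg$alpha_true))
  corr <- pairwise_pcc(z)
  top3_ok <- apply(corr - diag(2, nrow(corr)), 1,
                   function(v) sort(v, decreasing = TRUE)[3] >= 0.3)
  net <- build_network(corr)
  expect_true(all(net$degrees[top3_ok] >= 3))
})

test_that("connected components are counted correctly", {
  complete4 <- coexpression_network(matrix(1L, 4, 4) - diag(4L))
  expect_equal(network_components(complete4)$count, 1)
  two_triangles <- net_from_edges(letters[1:6], list(
    c("a", "b"), c("b", "c"), c("a", "c"),
    c("d", "e"), c("e", "f"), c("d", "f")))
  comp <- network_components(two_triangles)
  expect_equal(comp$count, 2)
  expect_equal(comp$sizes, c(3L, 3L))
})

test_that("networks survive an edge-list round trip", {
  set.seed(24)
  net <- random_net(25, 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  back <- read_network_tsv(path)
  expect_identical(back$adjacency, net$adjacency)
})
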