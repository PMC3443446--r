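test_that("topological overlap matches direct evaluation of the definition", {
  nodes <- c("i", "a", "b", "c", "d", "e")
  # X = {a,b,c}, Y = {b,c,d,e}: TO = 2 / max(3,4) = 0.5
  n1 <- net_from_edges(nodes, list(c("i", "a"), c("i", "b"), c("i", "c"),
                                   c("a", "b"), c("d", "e")))
  n2 <- net_from_edges(nodes, list(c("i", "b"), c("i", "c"), c("i", "d"),
                                   c("i", "e"), c("a", "b")))
  tt <- topological_overlap(n1, n2)
  expect_equal(tt$to[tt$gene == "i"], 0.5)
  expect_equal(tt$d1[tt$gene == "i"], 3)
  expect_equal(tt$d2[tt$gene == "i"], 4)
  # identical networks: TO = 1 everywhere
  self <- topological_overlap(n1, n1)
  expect_true(all(self$to == 1))
  # disjoint neighbourhoods: TO = 0
  d1 <- net_from_edges(c("x", "p", "q"), list(c("x", "p")))
  d2 <- net_from_edges(c("x", "p", "q"), list(c("x", "q")))
  expect_equal(suppressWarnings(topological_overlap(d1, d2))$to[1], 0)
  # node-set mismatch is a hard error
  other <- net_from_edges(c("i", "a", "zz"), list(c("i", "a")))
  expect_error(topological_overlap(n1, other), "node set")
})

test_that("TO is bounded, symmetric, equals 1 iff neighbourhoods coincide,
           and matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:3) {
    n1 <- random_net(100, 0.08)
    n2 <- random_net(100, 0.08)
    t12 <- topological_overlap(n1, n2)
    t21 <- topological_overlap(n2, n1)
    expect_true(all(t12$to >= 0 & t12$to <= 1))
    expect_equal(t12$to, t21$to)
    expect_equal(t12$to, unname(brute_to(n1, n2)))
    same <- vapply(seq_along(n1$nodes), function(i)
      identical(n1$adjacency[i, ], n2$adjacency[i, ]), logical(1))
    expect_equal(t12$to == 1, same)
  }
})

test_that("low-TO selection is inclusive and reports the network fraction", {
  tt <- data.frame(gene = sprintf("g%03d", 1:503),
                   to = c(rep(0.05, 20), rep(0.1, 11), rep(0.6, 472)))
  sel <- select_low_to(tt, 0.1)
  expect_equal(sel$n, 31)               # 0.1 itself is selected
  expect_equal(sel$fraction, 6.2)
  expect_equal(select_low_to(data.frame(gene = "a", to = 1), 0.1)$n, 0)
  expect_equal(select_low_to(tt, 1.0)$n, 503)
})

test_that("rewiring preserves the exact degree sequence", {
  set.seed(32)
  net <- random_net(30, 0.2)
  for (s in 1:5) {
    rw <- rewire_network(net, seed = s)
    expect_identical(rw$degrees, net$degrees)
    expect_true(all(diag(rw$adjacency) == 0L))
    expect_equal(rw$n_edges, net$n_edges)
  }
  # same seed reproduces the draw; different seeds generally differ
  a <- rewire_network(net, seed = 7)
  b <- rewire_network(net, seed = 7)
  expect_identical(a$adjacency, b$adjacency)
  c <- rewire_network(net, seed = 8)
  expect_identical(c$degrees, net$degrees)
})

test_that("rewiring a 4-cycle lands on a 2-regular simple graph on 4 nodes", {
  cyc <- net_from_edges(c("n1", "n2", "n3", "n4"),
                        list(c("n1", "n2"), c("n2", "n3"),
                             c("n3", "n4"), c("n4", "n1")))
  # the only 2-regular simple graphs on 4 labelled nodes are the 3 cycles
  for (s in 1:10) {
    rw <- suppressWarnings(rewire_network(cyc, seed = s))
    expect_true(all(rw$degrees == 2))
    expect_true(all(diag(rw$adjacency) == 0L))
    expect_true(all(rw$adjacency %in% c(0L, 1L)))
    expect_equal(rw$n_edges, 4)
  }
})

test_that("TO significance: identical networks are never flagged as divergent", {
  set.seed(33)
  net <- random_net(40, 0.15)
  sig <- to_significance(net, net, n_random = 60, seed = 5)
  # observed TO = 1 is the maximum: never significantly lower than null
  expect_true(all(sig$to == 1))
  expect_true(all(sig$p[!sig$degenerate] > 0.5))
  expect_false(any(sig$significant))
})

test_that("TO significance is reproducible by seed and stable in n_random", {
  set.seed(34)
  n1 <- random_net(40, 0.15)
  n2 <- random_net(40, 0.15)
  a <- to_significance(n1, n2, n_random = 50, seed = 9)
  b <- to_significance(n1, n2, n_random = 50, seed = 9)
  expect_identical(a$p, b$p)
  # doubling the null size leaves the null means stable within MC error
  c <- to_significance(n1, n2, n_random = 100, seed = 10)
  expect_equal(a$null_mean, c$null_mean, tolerance = 0.15)
})

test_that("connectivity difference selects, directs and flips correctly", {
  nodes <- sprintf("g%02d", 1:20)
  set.seed(35)
  n1 <- random_net(20, 0.3, nodes)
  n2 <- random_net(20, 0.3, nodes)
  cd <- connectivity_difference(n1, n2, threshold = 2)
  expect_equal(cd$difference, abs(cd$d1 - cd$d2))
  expect_equal(cd$selected, cd$difference >= 2)
  counts <- attr(cd, "counts")
  expect_equal(sum(counts), sum(cd$selected & cd$direction != "equal"))
  # swapping the networks flips every direction, keeps differences
  sw <- connectivity_difference(n2, n1, threshold = 2)
  expect_equal(sw$difference, cd$difference)
  expect_equal(sw$direction == "net1", cd$direction == "net2")
  # identical networks: nothing selected
  same <- connectivity_difference(n1, n1, threshold = 2)
  expect_false(any(same$selected))
  # a 15-vs-4 degree pair is a selected net1-higher gene at T = 10
  hub1 <- net_from_edges(c("h", sprintf("x%02d", 1:15)),
                         lapply(1:15, function(i) c("h", sprintf("x%02d", i))))
  hub2 <- net_from_edges(c("h", sprintf("x%02d", 1:15)),
                         lapply(1:4, function(i) c("h", sprintf("x%02d", i))))
  one <- connectivity_difference(hub1, hub2, threshold = 10)
  row <- one[one$gene == "h", ]
  expect_equal(row$difference, 11)
  expect_true(row$selected)
  expect_equal(row$direction, "net1")
})

test_that("cross-level intersection behaves as plain set intersection", {
  expect_equal(cross_level_intersection(c("a", "b", "c"), c("b", "c", "d")),
               c("b", "c"))
  expect_equal(cross_level_intersection(character(0), c("a")), character(0))
  expect_equal(cross_level_intersection(c("a"), character(0)), character(0))
  df1 <- data.frame(gene = c("a", "b", "c"),
                    selected = c(TRUE, TRUE, FALSE))
  df2 <- data.frame(gene = c("a", "b", "c"),
                    selected = c(FALSE, TRUE, TRUE))
  expect_equal(cross_level_intersection(df1, df2), "b")
})
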