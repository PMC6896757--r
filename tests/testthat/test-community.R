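test_that("modularity reproduces hand-derived closed forms", {
  tri2 <- net_two_triangles()
  p_tri <- setNames(rep(c("L", "R"), each = 3), letters[1:6])
  expect_equal(modularity_q(tri2, p_tri, "unweighted"), 0.5)

  # all-in-one-group is identically zero
  expect_equal(modularity_q(tri2, setNames(rep("g", 6), letters[1:6])), 0)

  # split single edge
  se <- net_single_edge()
  expect_equal(modularity_q(se, c(a = "x", b = "y"), "unweighted"), -0.5)

  # bridged two-triangle graph, component partition: Q = 5/14
  expect_equal(modularity_q(net_bridge(),
                            setNames(rep(c("L", "R"), each = 3), letters[1:6]),
                            "unweighted"), 5 / 14)

  expect_error(modularity_q(tri2, p_tri[-1]), "missing",
               class = "pte_input_error")
  lonely <- cooccurrence_network(c("a", "b"), NULL, 1)
  expect_error(modularity_q(lonely, c(a = "x", b = "y")), "edgeless",
               class = "pte_input_error")
})

test_that("modularity agrees with igraph on random weighted networks", {
  for (r in 1:10) {
    st <- random_study(sample(5:9, 1), sample(2:4, 1), seed = 600 + r)
    net <- build_network(st)
    if (nrow(net$edges) == 0) next
    p <- withr::with_seed(r, setNames(sample(c("u", "v", "w"),
                                             length(net$nodes), TRUE),
                                      net$nodes))
    g <- as_igraph(net)
    memb <- as.integer(factor(p[igraph::V(g)$name]))
    expect_equal(modularity_q(net, p, "similarity"),
                 igraph::modularity(g, memb, weights = igraph::E(g)$count),
                 tolerance = 1e-12)
    expect_equal(modularity_q(net, p, "unweighted"),
                 igraph::modularity(g, memb))
  }
})

test_that("girvan_newman removes the bridge first and records Q per level", {
  h <- girvan_newman(net_bridge())
  expect_s3_class(h, "merge_history")
  expect_identical(h$algorithm, "girvan_newman")
  # level 1: one component; level 2: the bridge is gone -> two triangles
  expect_equal(length(unique(h$levels[[1]])), 1L)
  expect_equal(length(unique(h$levels[[2]])), 2L)
  two <- h$levels[[2]]
  expect_equal(sort(names(two)[two == two[["a"]]]), c("a", "b", "c"))
  expect_equal(h$q[2], 5 / 14)
  # history runs to all singletons
  last <- h$levels[[length(h$levels)]]
  expect_equal(length(unique(last)), 6L)
  expect_equal(h$q[1], 0)  # connected graph, one group

  # best level is the two-triangle split
  expect_equal(best_partition(h), two)
})

test_that("girvan_newman handles edgeless networks and uniform counts", {
  lonely <- cooccurrence_network(c("a", "b", "c"), NULL, 1)
  h <- girvan_newman(lonely)
  expect_length(h$levels, 1L)
  expect_equal(length(unique(h$levels[[1]])), 3L)

  # uniform counts: inverse-weight distances are constant, so the removal
  # sequence matches the unweighted topology run
  h1 <- girvan_newman(net_two_triangles(1L))
  h3 <- girvan_newman(net_two_triangles(3L))
  expect_identical(h1$levels, h3$levels)
})

test_that("greedy modularity reproduces derived optima and records all levels", {
  h <- greedy_modularity(net_two_triangles())
  expect_identical(h$direction, "agglomerative")
  expect_length(h$levels, 6L)  # singletons down to one group
  best <- best_partition(h)
  expect_equal(length(unique(best)), 2L)
  expect_equal(max(h$q), 0.5)
  expect_equal(sort(names(best)[best == best[["d"]]]), c("d", "e", "f"))

  # single edge: Q(singletons) = -0.5, Q(one group) = 0; tie rule n/a
  hs <- greedy_modularity(net_single_edge())
  expect_equal(hs$q, c(-0.5, 0))
  expect_equal(length(unique(best_partition(hs))), 1L)

  expect_error(greedy_modularity(cooccurrence_network(c("a", "b"), NULL, 1)),
               "edge", class = "pte_input_error")
})

test_that("noise-free planted themes are recovered exactly by both algorithms", {
  sim <- clique_study(n_quotes = 12, n_themes = 3, n_sorters = 4, seed = 31)
  net <- build_network(sim$study)
  # generator makes within-theme counts S and cross-theme counts 0
  expect_true(all(net$edges$count == 4L))
  for (fn in list(greedy_modularity, girvan_newman)) {
    p <- best_partition(fn(net))
    expect_equal(adjusted_rand(p, sim$planted), 1)
  }
})

test_that("best_partition maximises Q with ties toward fewer groups", {
  lv <- list(setNames(c("a", "b", "c"), c("x", "y", "z")),
             setNames(c("a", "a", "b"), c("x", "y", "z")),
             setNames(c("a", "a", "a"), c("x", "y", "z")))
  h <- pilesortr:::new_merge_history(lv, c(-0.1, 0.4, 0.3), "toy",
                                     "agglomerative")
  expect_identical(best_partition(h), lv[[2]])

  h_tie <- pilesortr:::new_merge_history(lv, c(0.2, 0.2, 0.2), "toy",
                                         "agglomerative")
  expect_identical(best_partition(h_tie), lv[[3]])  # coarsest level

  expect_error(best_partition(pilesortr:::new_merge_history(list(), numeric(),
                                                            "toy", "d")),
               "empty", class = "pte_input_error")
})

test_that("brute-force oracle finds the exhaustive optimum", {
  expect_equal(length(unique(brute_force_best_partition(net_two_triangles()))),
               2L)
  # complete uniform graph: no split beats Q = 0
  pr <- combn(letters[1:4], 2)
  cmpl <- cooccurrence_network(letters[1:4],
                               data.frame(from = pr[1, ], to = pr[2, ],
                                          count = 2L), 2L)
  expect_equal(length(unique(brute_force_best_partition(cmpl))), 1L)
  # 2-node single edge: merged beats split (0 > -0.5)
  expect_equal(length(unique(brute_force_best_partition(net_single_edge()))),
               1L)
  big <- cooccurrence_network(letters[1:12], NULL, 1)
  expect_error(brute_force_best_partition(big), "limited",
               class = "pte_input_error")
})

test_that("greedy never beats the exhaustive optimum and usually attains it", {
  le <- logical(0); hit <- logical(0)
  for (r in 1:50) {
    st <- random_study(sample(4:8, 1), sample(2:4, 1), seed = 1000 + r)
    net <- build_network(st)
    if (nrow(net$edges) == 0) next
    qg <- max(greedy_modularity(net)$q)
    qb <- modularity_q(net, brute_force_best_partition(net))
    le <- c(le, qg <= qb + 1e-9)
    hit <- c(hit, abs(qg - qb) < 1e-9)
  }
  expect_true(all(le))
  expect_gte(mean(hit), 0.8)
})

test_that("both algorithms are invariant to node relabeling", {
  st <- random_study(7, 3, seed = 77)
  net <- build_network(st)
  relabel <- setNames(sprintf("z%02d", rev(seq_along(net$nodes))), net$nodes)
  ed <- net$edges
  net2 <- cooccurrence_network(unname(relabel),
                               data.frame(from = relabel[ed$from],
                                          to = relabel[ed$to],
                                          count = ed$count),
                               net$n_sorters)
  for (fn in list(greedy_modularity, girvan_newman)) {
    p1 <- best_partition(fn(net))
    p2 <- best_partition(fn(net2))
    names(p2) <- names(relabel)[match(names(p2), relabel)]
    expect_equal(adjusted_rand(p1, p2), 1)
  }
})

test_that("detected partitions agree with igraph's implementations on toys", {
  # independent cross-check: igraph's CNM and edge-betweenness clusterings
  net <- net_two_triangles()
  g <- as_igraph(net)
  ig_fg <- igraph::membership(igraph::cluster_fast_greedy(
    g, weights = igraph::E(g)$count))
  expect_equal(adjusted_rand(best_partition(greedy_modularity(net)),
                             setNames(as.character(ig_fg), names(ig_fg))), 1)
  ig_eb <- igraph::membership(suppressWarnings(igraph::cluster_edge_betweenness(
    g, weights = igraph::E(g)$weight)))
  expect_equal(adjusted_rand(best_partition(girvan_newman(net)),
                             setNames(as.character(ig_eb), names(ig_eb))), 1)
})
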