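test_that("adjusted Rand index matches hand-verified values", {
  ids <- paste0("q", 1:5)
  p <- setNames(c("a", "a", "b", "b", "c"), ids)
  expect_equal(adjusted_rand(p, p), 1)

  # label-permuted copy is still perfect agreement
  perm <- setNames(c("z", "z", "x", "x", "y"), ids)
  expect_equal(adjusted_rand(p, perm), 1)

  # trivial vs singletons has zero chance-corrected agreement
  allone <- setNames(rep("g", 5), ids)
  singles <- setNames(as.character(1:5), ids)
  expect_equal(adjusted_rand(allone, singles), 0)

  # nested split (one group halved), n = 8: ARI = 16/23, NMI = 0.8
  # (frozen from direct evaluation of the contingency-table formulas)
  ids8 <- paste0("q", 1:8)
  p1 <- setNames(rep(c("A", "B"), each = 4), ids8)
  p2 <- setNames(c("A1", "A1", "A2", "A2", "B", "B", "B", "B"), ids8)
  expect_equal(adjusted_rand(p1, p2), 16 / 23)
  expect_equal(norm_mutual_info(p1, p2), 0.8)
  expect_gt(adjusted_rand(p1, p2), 0)
  expect_lt(adjusted_rand(p1, p2), 1)

  # symmetry
  expect_equal(adjusted_rand(p1, p2), adjusted_rand(p2, p1))
  expect_equal(norm_mutual_info(p1, p2), norm_mutual_info(p2, p1))

  expect_error(adjusted_rand(p, p2), "different node sets",
               class = "pte_input_error")
})

test_that("ARI and NMI agree with igraph's implementations", {
  for (r in 1:10) {
    p <- withr::with_seed(300 + r, {
      n <- sample(6:15, 1)
      list(a = setNames(sample(letters[1:4], n, TRUE), paste0("q", 1:n)),
           b = setNames(sample(letters[1:4], n, TRUE), paste0("q", 1:n)))
    })
    ma <- as.integer(factor(p$a)); mb <- as.integer(factor(p$b))
    expect_equal(adjusted_rand(p$a, p$b),
                 igraph::compare(ma, mb, method = "adjusted.rand"),
                 tolerance = 1e-12)
    expect_equal(norm_mutual_info(p$a, p$b),
                 igraph::compare(ma, mb, method = "nmi"),
                 tolerance = 1e-12)
  }
})

test_that("independent random partitions score near-zero ARI", {
  aris <- vapply(1:40, function(r) {
    withr::with_seed(5000 + r, {
      ids <- paste0("q", 1:60)
      adjusted_rand(setNames(sample(letters[1:4], 60, TRUE), ids),
                    setNames(sample(letters[1:4], 60, TRUE), ids))
    })
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("compare_partitions reports ARI, NMI and the contingency table", {
  ids <- paste0("q", 1:6)
  p <- setNames(rep(c("u", "v"), each = 3), ids)
  cmp <- compare_partitions(p, p)
  expect_equal(cmp$ari, 1)
  expect_equal(cmp$nmi, 1)
  expect_equal(sum(cmp$contingency > 0), 2L)  # diagonal only
})

test_that("select_final picks the higher-Q history and keeps disagreement visible", {
  ids <- c("x", "y", "z")
  pA <- setNames(c("a", "a", "b"), ids)
  pB <- setNames(c("a", "b", "b"), ids)
  hA <- pilesortr:::new_merge_history(list(pA), 0.42, "alpha", "agglomerative")
  hB <- pilesortr:::new_merge_history(list(pB), 0.37, "beta", "divisive")
  final <- select_final(hA, hB)
  expect_identical(final$source, "alpha")
  expect_identical(final$partition, pA)
  expect_identical(final$other$algorithm, "beta")
  expect_identical(final$other$partition, pB)
  expect_s3_class(final$comparison, "partition_comparison")

  # equal max-Q with identical partitions -> consensus
  hB2 <- pilesortr:::new_merge_history(list(setNames(c("k", "k", "m"), ids)),
                                       0.42, "beta", "divisive")
  expect_identical(select_final(hA, hB2)$source, "consensus")

  # node-set mismatch is fatal
  hC <- pilesortr:::new_merge_history(list(setNames("a", "w")), 0.1, "c", "d")
  expect_error(select_final(hA, hC), "node sets", class = "pte_input_error")
})

test_that("noise-free synthetic studies make both algorithms agree exactly", {
  sim <- clique_study(n_quotes = 15, n_themes = 3, n_sorters = 5, seed = 12)
  net <- build_network(sim$study)
  final <- select_final(greedy_modularity(net), girvan_newman(net))
  expect_identical(final$source, "consensus")
  expect_equal(final$comparison$ari, 1)
  expect_equal(adjusted_rand(final$partition, sim$planted), 1)
})

test_that("manual reassignment is append-only, replayable provenance", {
  ids <- paste0("q", 1:4)
  g <- final_grouping(setNames(c("G1", "G1", "G2", "G2"), ids), "toy")
  g <- reassign(g, "q3", "G1", note = "fits discussion of access")
  expect_identical(unname(g$partition[["q3"]]), "G1")
  expect_length(g$edits, 1L)

  # no-op move is still recorded
  g <- reassign(g, "q1", "G1", note = "confirmed placement")
  expect_length(g$edits, 2L)

  g <- reassign(g, "q4", "G3", note = "new sub-theme")
  expect_identical(replay_edits(g), g$partition)
  expect_identical(g$base[["q3"]], "G2")  # original recoverable

  expect_error(reassign(g, "zz", "G1"), "unknown quote",
               class = "pte_input_error")
})

test_that("final groupings serialize, reload and replay bit-identically", {
  sim <- clique_study(9, 3, 3, seed = 4)
  net <- build_network(sim$study)
  final <- select_final(greedy_modularity(net), girvan_newman(net))
  final <- reassign(final, names(final$partition)[1],
                    "G9", note = "panel override")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_final_grouping(final, f1)
  re <- read_final_grouping(f1)
  expect_identical(re$partition, final$partition)
  expect_identical(replay_edits(re), re$partition)
  write_final_grouping(re, f2)
  expect_identical(readLines(f1), readLines(f2))
})
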