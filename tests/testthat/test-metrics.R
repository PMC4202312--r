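clique_pair_net <- function() {
  # two 4-cliques joined by one edge
  cl <- function(ids) {
    p <- utils::combn(ids, 2)
    data.frame(a = p[1, ], b = p[2, ], evalue = 1e-20,
               stringsAsFactors = FALSE)
  }
  mk_net(rbind(cl(paste0("u", 1:4)), cl(paste0("v", 1:4)),
               data.frame(a = "u1", b = "v1", evalue = 1e-20)))
}

test_that("the first Louvain pass separates two bridged cliques", {
  net <- clique_pair_net()
  part <- louvain_first_pass(net, seed = 7)
  memb <- part$membership
  expect_equal(length(unique(memb[paste0("u", 1:4)])), 1L)
  expect_equal(length(unique(memb[paste0("v", 1:4)])), 1L)
  expect_false(memb[["u1"]] == memb[["v1"]])
  # exhaustive check: no partition of the 8 nodes has higher modularity
  g <- as_igraph(net)
  best <- max(vapply(all_partitions(8L), function(p)
    igraph::modularity(g, p), numeric(1)))
  expect_equal(part$modularity, best, tolerance = 1e-12)
})

test_that("degenerate networks partition sensibly", {
  edgeless <- mk_net(data.frame(a = character(), b = character(),
                                evalue = numeric()),
                     extra_nodes = c("p", "q", "r"))
  part <- louvain_first_pass(edgeless)
  expect_equal(length(unique(part$membership)), 3L)
  expect_equal(part$modularity, 0)
  empty <- edgeless
  empty$nodes <- empty$nodes[0, ]
  expect_error(louvain_first_pass(empty), "empty")
})

test_that("community sweeps are deterministic given the seed", {
  net <- random_ssn(60, p = 0.1, seed = 5)
  p1 <- louvain_first_pass(net, seed = 3)
  p2 <- louvain_first_pass(net, seed = 3)
  expect_identical(p1$membership, p2$membership)
})

test_that("first-pass modularity never falls below the singleton partition", {
  for (seed in c(2, 4, 8)) {
    net <- random_ssn(40, p = 0.12, seed = seed)
    g <- as_igraph(net)
    part <- louvain_first_pass(net, seed = 1)
    q_singletons <- igraph::modularity(g, seq_len(igraph::vcount(g)))
    expect_gte(part$modularity, q_singletons)
  }
})

test_that("supergraph cycle flags: triangles cycle, trees do not", {
  tri <- data.frame(c1 = c(1L, 2L, 3L), c2 = c(2L, 3L, 1L))
  expect_true(all(cycle_edges(tri)))
  tree <- data.frame(c1 = c(1L, 1L, 2L, 2L), c2 = c(2L, 3L, 4L, 5L))
  expect_false(any(cycle_edges(tree)))
})

test_that("cycle flags equal the bridge-removal oracle on random supergraphs", {
  for (seed in 1:50) {
    g <- withr::with_seed(seed, {
      n <- sample(4:30, 1)
      igraph::sample_gnp(n, runif(1, 0.08, 0.3))
    })
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0L) next
    df <- data.frame(c1 = el[, 1], c2 = el[, 2])
    expect_equal(cycle_edges(df), bridge_removal_cycle_flags(df))
  }
})

test_that("community supergraph pools sizes and inter-edges correctly", {
  net <- clique_pair_net()
  part <- louvain_first_pass(net, seed = 1)
  sg <- community_supergraph(net, part)
  expect_equal(sort(sg$nodes$size), c(4L, 4L))
  expect_equal(nrow(sg$edges), 1L)
  expect_equal(sg$edges$n_edges, 1L)
  expect_false(sg$edges$in_cycle)  # a single bridge between communities
  expect_equal(sg$edges$log_width, 1 + log(1))
})

test_that("assortativity closed forms: same-label cliques and bipartite sides", {
  cl <- function(ids) {
    p <- utils::combn(ids, 2)
    data.frame(a = p[1, ], b = p[2, ], evalue = 1e-20)
  }
  two_cliques <- mk_net(rbind(cl(paste0("x", 1:4)), cl(paste0("y", 1:4))))
  labels <- stats::setNames(rep(c("L1", "L2"), each = 4),
                            c(paste0("x", 1:4), paste0("y", 1:4)))
  expect_equal(attribute_assortativity(two_cliques, labels), 1.0)

  bip <- mk_net(expand.grid(a = paste0("l", 1:3), b = paste0("r", 1:3),
                            stringsAsFactors = FALSE) |>
                  transform(evalue = 1e-20))
  lab_bip <- stats::setNames(rep(c("left", "right"), each = 3),
                             c(paste0("l", 1:3), paste0("r", 1:3)))
  expect_equal(attribute_assortativity(bip, lab_bip), -1.0)
})

test_that("random labels on a random graph give near-zero assortativity", {
  net <- random_ssn(300, p = 0.05, seed = 99)
  labels <- withr::with_seed(1, stats::setNames(
    sample(c("A", "B", "C"), 300, replace = TRUE), net$nodes$seq_id))
  r <- attribute_assortativity(net, labels)
  expect_lt(abs(r), 0.06)
})

test_that("assortativity matches igraph and is label-rename invariant", {
  net <- random_ssn(80, p = 0.1, seed = 12)
  labels <- withr::with_seed(2, stats::setNames(
    sample(c("I", "II", "III", "IV"), 80, replace = TRUE),
    net$nodes$seq_id))
  g <- as_igraph(net)
  r_igraph <- igraph::assortativity_nominal(
    g, as.integer(factor(labels[igraph::V(g)$name])), directed = FALSE)
  r <- attribute_assortativity(net, labels)
  expect_equal(r, r_igraph, tolerance = 1e-12)
  renamed <- stats::setNames(paste0("class_", labels), names(labels))
  expect_equal(attribute_assortativity(net, renamed), r)
})

test_that("single-label edge sets are an error, not r = 1", {
  net <- mk_net(data.frame(a = c("m", "n"), b = c("n", "o"),
                           evalue = 1e-20))
  labels <- stats::setNames(rep("only", 3), c("m", "n", "o"))
  expect_error(attribute_assortativity(net, labels), "single")
})

test_that("per-class coefficients follow the indicator construction", {
  # x1-x2 (X,X), x2-y1 (X,Y), y1-y2 (Y,Y): hand-computed r = 1/3 per class
  net <- mk_net(data.frame(a = c("x1", "x2", "y1"), b = c("x2", "y1", "y2"),
                           evalue = 1e-20))
  labels <- stats::setNames(c("X", "X", "Y", "Y"), c("x1", "x2", "y1", "y2"))
  pc <- per_class_assortativity(net, labels)
  expect_equal(unname(pc["X"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(pc["Y"]), 1 / 3, tolerance = 1e-12)

  # an isolated same-label block scores 1.0
  blocks <- mk_net(data.frame(a = c("a1", "b1", "b2"), b = c("a2", "b2", "b3"),
                              evalue = 1e-20))
  lab2 <- stats::setNames(c("A", "A", "B", "B", "B"),
                          c("a1", "a2", "b1", "b2", "b3"))
  pc2 <- per_class_assortativity(blocks, lab2)
  expect_equal(unname(pc2["A"]), 1.0)

  # a class connecting only outward is disassortative
  star <- mk_net(data.frame(a = "hub", b = paste0("leaf", 1:4),
                            evalue = 1e-20))
  lab3 <- stats::setNames(c("H", rep("L", 4)),
                          c("hub", paste0("leaf", 1:4)))
  pc3 <- per_class_assortativity(star, lab3)
  expect_true(pc3["H"] >= -1 && pc3["H"] < 0)
})

test_that("aggregating two classes changes the recomputed coefficient", {
  net <- random_ssn(60, p = 0.15, seed = 33)
  labels <- withr::with_seed(3, stats::setNames(
    sample(c("VI", "VII", "I"), 60, replace = TRUE), net$nodes$seq_id))
  r_sep <- per_class_assortativity(net, labels)
  merged <- stats::setNames(ifelse(labels %in% c("VI", "VII"), "RT", labels),
                            names(labels))
  r_merged <- per_class_assortativity(net, merged)
  expect_true("RT" %in% names(r_merged))
  expect_false(isTRUE(all.equal(unname(r_merged["RT"]),
                                unname(r_sep["VI"]))))
})

test_that("betweenness closed forms: path center and star hub", {
  path <- mk_net(data.frame(a = c("a", "b"), b = c("b", "c"),
                            evalue = 1e-20))
  b <- betweenness_centrality(path, "exact")
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))
  star <- mk_net(data.frame(a = "hub", b = paste0("s", 1:5), evalue = 1e-20))
  bs <- betweenness_centrality(star, "exact")
  expect_equal(unname(bs["hub"]), 1.0)
  expect_true(all(bs[paste0("s", 1:5)] == 0))
})

test_that("pivot sampling with k = n reproduces exact betweenness", {
  for (seed in c(6, 16)) {
    net <- random_ssn(60, p = 0.08, seed = seed)
    exact <- betweenness_centrality(net, "exact")
    approx <- betweenness_centrality(net, "approximate", k_pivots = 60,
                                     seed = 1)
    expect_equal(approx, exact, tolerance = 1e-10)
  }
})

test_that("k_pivots above the node count is clamped with a notice", {
  net <- random_ssn(20, p = 0.2, seed = 2)
  expect_message(betweenness_centrality(net, "approximate",
                                        k_pivots = 5000, seed = 1),
                 "clamped")
})

test_that("the pivot estimator is unbiased across seeds", {
  net <- random_ssn(40, p = 0.15, seed = 44)
  exact <- betweenness_centrality(net, "exact")
  ests <- sapply(1:50, function(s)
    betweenness_centrality(net, "approximate", k_pivots = 20, seed = s))
  m <- rowMeans(ests)
  expect_lt(mean(abs(m - exact)) / mean(exact), 0.05)
})

test_that("group contrast reports means and rounded ratios", {
  b <- stats::setNames(c(4e-5, 2e-5, 2e-6, 1e-6), c("c1", "c2", "n1", "n2"))
  ct <- group_betweenness_contrast(b, c("c1", "c2"))
  expect_equal(ct$mean_composite, 3e-5)
  expect_equal(ct$mean_noncomposite, 1.5e-6)
  expect_equal(ct$ratio, 20)
  expect_error(group_betweenness_contrast(b, names(b)), "empty")
  same <- stats::setNames(rep(2, 4), names(b))
  expect_equal(group_betweenness_contrast(same, c("c1", "c2"))$ratio, 1.0)
})
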