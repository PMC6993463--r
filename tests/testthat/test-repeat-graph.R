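test_that("edge filter is inclusive at the 100-bit threshold", {
  hits <- data.frame(read_a = c("a", "a", "b"), read_b = c("b", "c", "d"),
                     bitscore = c(150, 99.9, 100.0))
  g <- build_graph(hits, min_bits = 100)
  expect_equal(igraph::ecount(g), 2L)         # 99.9 dropped, 100.0 kept
  expect_setequal(igraph::V(g)$name, c("a", "b", "d"))

  empty <- build_graph(hits[0, ], min_bits = 100)
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("mean degree is 2E/V, matching the published graph summary", {
  # the reported read graph: 2,956,096 vertices, 244,031,339 edges,
  # mean degree 165.10
  expect_equal(mean_degree(2956096, 244031339), 165.10, tolerance = 5e-5)
  g <- build_graph(data.frame(read_a = c("a", "a"), read_b = c("b", "c"),
                              bitscore = c(120, 130)))
  expect_equal(mean_degree(g), 2 * 2 / 3)
})

test_that("largest_component picks size then lexicographic tie-break", {
  hits <- data.frame(
    read_a = c("a", "b", "c", "d", "x", "y"),
    read_b = c("b", "c", "d", "e", "y", "z"),
    bitscore = rep(120, 6))
  g <- build_graph(hits)
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, c("a", "b", "c", "d", "e"))

  # tie: two components of 2 edges / 3 vertices each
  tie <- build_graph(data.frame(read_a = c("m", "m", "b", "b"),
                                read_b = c("n", "o", "c", "d"),
                                bitscore = rep(120, 4)))
  lt <- largest_component(tie)
  expect_setequal(igraph::V(lt)$name, c("b", "c", "d"))

  conn <- build_graph(hits[1:4, ])
  expect_equal(igraph::vcount(largest_component(conn)), igraph::vcount(conn))
})

test_that("greedy communities match the exhaustive modularity optimum", {
  # two 4-cliques joined by one edge: oracle = exhaustive search over all
  # 4140 partitions of 8 vertices with a direct-formula modularity
  g <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4))
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- letters[1:8]
  igraph::E(g)$weight <- 1
  asg <- detect_communities(g)

  adj <- adj_of(g)
  mods <- vapply(all_partitions(8), function(m) modularity_bf(adj, m),
                 numeric(1))
  best_bf <- max(mods)
  expect_equal(attr(asg, "modularity"), best_bf, tolerance = 1e-12)
  memb <- stats::setNames(asg$cluster_id, asg$read_id)[letters[1:8]]
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[1:4])), 1L)
  expect_equal(length(unique(memb[5:8])), 1L)
})

test_that("a single edge merges into one community", {
  # merged Q = 0 beats singleton Q = -0.5 (closed form for one edge)
  g <- igraph::graph_from_literal(a - b)
  igraph::E(g)$weight <- 150
  asg <- detect_communities(g)
  expect_equal(length(unique(asg$cluster_id)), 1L)
  expect_equal(attr(asg, "modularity"), 0)
})

test_that("weighted modularity optimum on the heavy-bridge graph", {
  # two unit triangles joined by a weight-1000 edge; the exhaustive optimum
  # keeps the bridge endpoints together
  g <- igraph::graph_from_literal(a - b, b - c, a - c, d - e, e - f, d - f,
                                  c - d)
  igraph::E(g)$weight <- c(1, 1, 1, 1, 1, 1, 1000)
  asg <- detect_communities(g)
  adj <- adj_of(g)
  mods <- vapply(all_partitions(6), function(m) modularity_bf(adj, m),
                 numeric(1))
  expect_equal(attr(asg, "modularity"), max(mods), tolerance = 1e-12)
  memb <- stats::setNames(asg$cluster_id, asg$read_id)
  expect_equal(memb[["c"]], memb[["d"]])    # the heavy edge is intra-cluster
})

test_that("cluster ids are ranked by size with a documented tie-break", {
  # sizes 3 and 2: the size-3 community is cluster_0
  hits <- data.frame(read_a = c("p", "p", "q", "x"),
                     read_b = c("q", "r", "r", "y"),
                     bitscore = rep(120, 4))
  g <- build_graph(hits)
  asg <- detect_communities(g)
  tab <- table(asg$cluster_id)
  expect_equal(as.integer(tab[order(names(tab))]), c(3L, 2L))
  expect_setequal(asg$read_id[asg$cluster_id == "cluster_0"],
                  c("p", "q", "r"))
  # partition property: every vertex in exactly one cluster
  expect_setequal(asg$read_id, igraph::V(g)$name)
  expect_false(anyDuplicated(asg$read_id) > 0)
  # modularity of the returned partition is >= the singleton partition's
  adj <- adj_of(g)
  singletons <- seq_len(igraph::vcount(g))
  expect_gte(attr(asg, "modularity"), modularity_bf(adj, singletons))
})

test_that("abundance matrix counts reads per individual and cluster", {
  asg <- data.frame(read_id = c("r1", "r2", "r3", "r4", "r5", "r6", "r7", "r8"),
                    cluster_id = c(rep("cluster_0", 5), rep("cluster_1", 3)),
                    stringsAsFactors = FALSE)
  labels <- data.frame(
    read_id = sprintf("r%d", 1:8),
    individual = c("i1", "i1", "i1", "i2", "i2", "i2", "i2", "i3"),
    population = c("SS", "SS", "SS", "NSS", "NSS", "NSS", "NSS", "SS"),
    stringsAsFactors = FALSE)
  ab <- abundance_matrix(asg, labels)
  expect_equal(ab["i1", "cluster_0"], 3L)
  expect_equal(ab["i2", "cluster_0"], 2L)
  expect_equal(ab["i3", "cluster_0"], 0L)     # contributes nothing here
  expect_equal(sum(ab), nrow(asg))            # conservation
  expect_equal(unname(attr(ab, "populations")[c("i1", "i2", "i3")]),
               c("SS", "NSS", "SS"))
  expect_error(abundance_matrix(asg, labels[-1, ]), "r1")
})

test_that("cluster meta-graph sums cross-cluster weights and conserves", {
  hits <- data.frame(
    read_a = c("a1", "a1", "a2", "b1", "a1", "a2", "a2"),
    read_b = c("a2", "a3", "a3", "b2", "b1", "b1", "b2"),
    bitscore = c(200, 210, 220, 230, 120, 150, 130))
  g <- build_graph(hits)
  asg <- data.frame(read_id = c("a1", "a2", "a3", "b1", "b2"),
                    cluster_id = c("A", "A", "A", "B", "B"),
                    stringsAsFactors = FALSE)
  mg <- cluster_metagraph(g, asg)
  expect_equal(igraph::vcount(mg), 2L)
  expect_equal(igraph::E(mg)$weight, 120 + 150 + 130)
  # conservation: intra + inter = total
  expect_equal(sum(igraph::V(mg)$intra_weight) + sum(igraph::E(mg)$weight),
               sum(igraph::E(g)$weight))

  single <- cluster_metagraph(
    build_graph(hits[1:3, ]),
    data.frame(read_id = c("a1", "a2", "a3"), cluster_id = "A"))
  expect_equal(igraph::vcount(single), 1L)
  expect_equal(igraph::ecount(single), 0L)
})

test_that("meta-graph conservation holds on random graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    g <- igraph::sample_gnp(n, 0.2)
    igraph::V(g)$name <- sprintf("v%02d", 1:n)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 100, 300)
    asg <- data.frame(read_id = igraph::V(g)$name,
                      cluster_id = sprintf("c%d", sample(3, n, replace = TRUE)),
                      stringsAsFactors = FALSE)
    mg <- cluster_metagraph(g, asg)
    expect_equal(sum(igraph::V(mg)$intra_weight) + sum(igraph::E(mg)$weight),
                 sum(igraph::E(g)$weight))
  }
})

test_that("force-directed layout separates cliques and is deterministic", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10), igraph::make_full_graph(10))
  g <- igraph::add_edges(g, c(1, 11))
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  igraph::E(g)$weight <- 120
  asg <- data.frame(read_id = igraph::V(g)$name, cluster_id = "cluster_0",
                    stringsAsFactors = FALSE)
  lay <- layout_cluster(g, asg, "cluster_0", seed = 5, iterations = 300L)
  expect_true(all(is.finite(c(lay$x, lay$y))))
  pos <- as.matrix(lay[, c("x", "y")])
  d <- as.matrix(dist(pos))
  intra <- mean(c(d[1:10, 1:10][upper.tri(d[1:10, 1:10])],
                  d[11:20, 11:20][upper.tri(d[11:20, 11:20])]))
  inter <- mean(d[1:10, 11:20])
  expect_lt(intra, inter)

  lay2 <- layout_cluster(g, asg, "cluster_0", seed = 5, iterations = 300L)
  expect_identical(lay, lay2)

  one <- igraph::make_graph(character(0), isolates = "solo")
  asg1 <- data.frame(read_id = "solo", cluster_id = "cluster_0")
  l1 <- layout_cluster(one, asg1, "cluster_0", seed = 1)
  expect_equal(c(l1$x, l1$y), c(0, 0))
  expect_error(layout_cluster(g, asg, "cluster_99", seed = 1), "unknown")
})
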