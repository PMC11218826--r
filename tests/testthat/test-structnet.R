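# Similarity graphs, modularity, Louvain communities, cross-tabulation.

edges_df <- function(...) {
  x <- list(...)
  data.frame(id_a = vapply(x, `[[`, "", 1), id_b = vapply(x, `[[`, "", 2),
             score = vapply(x, function(e) as.numeric(e[[3]]), 0),
             stringsAsFactors = FALSE)
}

test_that("threshold semantics: >= tau kept, isolates retained", {
  g <- build_graph(edges_df(c("A", "B", 0.62), c("A", "C", 0.49)), tau = 0.5)
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(g$nodes, c("A", "B", "C"))          # C isolated but present
  g2 <- build_graph(edges_df(c("A", "B", 0.5)), tau = 0.5)
  expect_equal(nrow(g2$edges), 1L)                    # boundary kept

  set.seed(61)
  n <- 20
  pairs <- utils::combn(sprintf("n%02d", 1:n), 2)
  sc <- stats::runif(ncol(pairs))
  df <- data.frame(id_a = pairs[1, ], id_b = pairs[2, ], score = sc)
  for (tau in c(0.2, 0.5, 0.8)) {
    g3 <- build_graph(df, tau = tau)
    expect_equal(nrow(g3$edges), sum(sc >= tau))
  }
  # monotone: raising tau never increases the edge count
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                   function(t) nrow(build_graph(df, tau = t)$edges), 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("malformed score lists are rejected", {
  expect_error(build_graph(edges_df(c("A", "B", 1.2))), "\\[0, 1\\]")
  expect_error(build_graph(edges_df(c("A", "A", 0.6))), "self-pairs")
  expect_error(build_graph(edges_df(c("A", "B", 0.6), c("B", "A", 0.7))),
               "conflicting")
  # exact duplicates collapse silently
  g <- build_graph(edges_df(c("A", "B", 0.6), c("B", "A", 0.6)))
  expect_equal(nrow(g$edges), 1L)
})

test_that("modularity closed forms hold", {
  clique <- function(prefix, k)
    do.call(edges_df, lapply(asplit(utils::combn(paste0(prefix, 1:k), 2), 2),
                             function(p) c(p, 1)))
  g <- build_graph(rbind(clique("a", 4), clique("b", 4)), tau = 0)
  one <- stats::setNames(rep(1, 8), g$nodes)
  expect_equal(modularity_q(g, one), 0)               # single community
  split2 <- stats::setNames(rep(c(1, 2), each = 4), sort(g$nodes))
  expect_equal(modularity_q(g, split2), 0.5)          # two disjoint cliques
  expect_error(modularity_q(g, one[-1]), "misses")
})

test_that("modularity equals the direct double-sum oracle on random partitions", {
  set.seed(67)
  for (i in 1:10) {
    rg <- random_graph(sample(4:8, 1))
    g <- build_graph(rg$edges, tau = 0, nodes = rg$ids)
    A <- graph_adjacency(g)
    comm <- sample(1:3, length(g$nodes), replace = TRUE)
    mem <- stats::setNames(comm, g$nodes)
    expect_equal(modularity_q(g, mem), oracle_modularity(A, comm),
                 tolerance = 1e-12)
  }
})

test_that("modularity agrees with the igraph reference implementation", {
  skip_if_not_installed("igraph")
  set.seed(71)
  for (i in 1:5) {
    rg <- random_graph(7)
    g <- build_graph(rg$edges, tau = 0, nodes = rg$ids)
    ig <- igraph::graph_from_data_frame(g$edges[, c("a", "b")],
                                        directed = FALSE,
                                        vertices = g$nodes)
    comm <- sample(1:3, length(g$nodes), replace = TRUE)
    mem <- stats::setNames(comm, g$nodes)
    expect_equal(modularity_q(g, mem),
                 igraph::modularity(ig, comm[match(igraph::V(ig)$name,
                                                   names(mem))],
                                    weights = g$edges$weight),
                 tolerance = 1e-12)
  }
})

test_that("louvain separates two cliques joined by one edge (exhaustive check)", {
  clique_edges <- function(prefix, k)
    lapply(asplit(utils::combn(paste0(prefix, 1:k), 2), 2), function(p) c(p, 1))
  df <- do.call(edges_df, c(clique_edges("a", 4), clique_edges("b", 4),
                            list(c("a1", "b1", 1))))
  g <- build_graph(df, tau = 0)
  pt <- louvain(g, seed = 1)
  expect_equal(pt$n_communities, 2L)
  expect_length(unique(pt$membership[paste0("a", 1:4)]), 1L)
  expect_length(unique(pt$membership[paste0("b", 1:4)]), 1L)
  expect_equal(pt$Q, oracle_max_modularity(graph_adjacency(g)),
               tolerance = 1e-9)
})

test_that("louvain degenerate graphs: no edges, single edge", {
  g0 <- build_graph(edges_df(c("A", "B", 0.1)), tau = 0.5)   # edge dropped
  p0 <- louvain(g0)
  expect_equal(p0$n_communities, 2L)
  expect_equal(p0$Q, 0)

  g1 <- build_graph(edges_df(c("A", "B", 0.9)), tau = 0.5)
  p1 <- louvain(g1)
  expect_equal(p1$n_communities, 1L)      # Q = 0 beats the -0.5 split
  expect_equal(p1$Q, 0)
})

test_that("louvain Q is self-consistent and never below all-singletons", {
  set.seed(73)
  for (i in 1:10) {
    rg <- random_graph(sample(5:9, 1))
    g <- build_graph(rg$edges, tau = 0, nodes = rg$ids)
    pt <- louvain(g, seed = i)
    expect_equal(pt$Q, modularity_q(g, pt$membership), tolerance = 1e-12)
    singles <- stats::setNames(seq_along(g$nodes), g$nodes)
    expect_gte(pt$Q, modularity_q(g, singles) - 1e-12)
  }
})

test_that("louvain is deterministic for a fixed seed", {
  cfg <- sim_config(seed = 79, n_structures = 40, n_communities = 3)
  tm <- gen_tm_matrix(cfg)
  g <- build_graph(tm$edges)
  p1 <- louvain(g, seed = 5)
  p2 <- louvain(g, seed = 5)
  expect_identical(p1$membership, p2$membership)
})

test_that("planted partitions are recovered", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(seed = 83, n_structures = 80, n_communities = 4,
                    within_mu = 0.8, between_mu = 0.2)
  tm <- gen_tm_matrix(cfg)
  g <- build_graph(tm$edges, tau = 0.5)
  pt <- louvain(g, seed = 1)
  ari <- mclust::adjustedRandIndex(pt$membership[tm$truth$id],
                                   tm$truth$community)
  expect_gte(ari, 0.95)
})

test_that("community filtering applies both size boundaries", {
  mem <- stats::setNames(rep(1:3, c(1, 2, 20)), sprintf("x%02d", 1:23))
  fc <- filter_communities(list(membership = mem))
  expect_equal(fc$n_communities, 2L)
  expect_equal(fc$n_major, 1L)
  all_single <- stats::setNames(1:5, letters[1:5])
  expect_equal(filter_communities(list(membership = all_single))$n_communities, 0L)
})

test_that("crosstab counts shared members and reports the remainder", {
  og <- c(p1 = "O1", p2 = "O1", p3 = "O2")
  af <- c(p1 = "A1", p2 = "A1", p3 = "A1")
  xt <- crosstab(og, af)
  expect_equal(unname(xt$matrix["O1", "A1"]), 2L)
  expect_equal(unname(xt$matrix["O2", "A1"]), 1L)

  xt2 <- crosstab(c(a = "O1"), c(b = "A1"))
  expect_equal(nrow(xt2$matrix), 0L)
  expect_equal(xt2$only_og, "a")
  expect_equal(xt2$only_af, "b")

  # identical truth on both sides -> strictly diagonal overlap
  cfg <- sim_config(seed = 89, n_structures = 30, n_communities = 3)
  tm <- gen_tm_matrix(cfg)
  truth <- stats::setNames(tm$truth$community, tm$truth$id)
  xt3 <- crosstab(paste0("OG", truth) |> stats::setNames(names(truth)), truth)
  expect_equal(sum(xt3$matrix > 0), 3L)
})
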