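graph_from_wadj <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
}

expect_valid_partition <- function(P, vertices, exactly_two = FALSE) {
  expect_gte(length(P), 2L)
  if (exactly_two) expect_equal(length(P), 2L)
  expect_true(all(lengths(P) >= 1L))
  expect_setequal(unlist(P), vertices)
  expect_equal(length(unlist(P)), length(vertices))
}

random_weighted_graph <- function(n, p = 0.5) {
  repeat {
    W <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
    up <- upper.tri(W) & matrix(stats::runif(n * n) < p, n, n)
    W[up] <- sample(1:5, sum(up), replace = TRUE)
    W <- W + t(W)
    g <- graph_from_wadj(W)
    if (igraph::is_connected(g)) return(list(W = W, g = g))
  }
}

test_that("unnormalized modularity is the graph-size multiple of the classical score", {
  set.seed(41)
  for (i in 1:8) {
    rw <- random_weighted_graph(7)
    memb <- sample(1:3, 7, replace = TRUE)
    q <- graph_modularity(rw$W, memb)
    m2 <- sum(rw$W)
    expect_equal(q / m2,
                 igraph::modularity(rw$g, memb, weights = igraph::E(rw$g)$weight))
  }
  # single community: q = 0 by construction
  expect_equal(graph_modularity(matrix(c(0, 1, 1, 0), 2), c(1, 1)), 0)
})

test_that("the Stoer-Wagner bipartition attains the exhaustive minimum cut weight", {
  set.seed(42)
  for (i in 1:10) {
    rw <- random_weighted_graph(sample(4:8, 1))
    P <- mincut_partition(rw$g)
    expect_valid_partition(P, rownames(rw$W), exactly_two = TRUE)
    cutw <- sum(rw$W[P[[1]], P[[2]]])
    expect_equal(cutw, min_cut_oracle(rw$W))
  }
  expect_error(mincut_partition(igraph::make_graph(c("a", "b"), directed = FALSE) +
                                  igraph::vertices("c")), "connected")
})

test_that("Karger contraction yields bipartitions and more runs never cost more", {
  set.seed(43)
  for (i in 1:5) {
    G <- random_colored_digraph(8, 3)
    W <- matrix(1, 8, 8, dimnames = list(G$vertices, G$vertices)); diag(W) <- 0
    H <- graph_from_wadj(W)
    P1 <- karger_partition(H, G, runs = 1L)
    expect_valid_partition(P1, G$vertices, exactly_two = TRUE)
    set.seed(1000 + i)
    c1 <- ur_cost(G, karger_partition(H, G, runs = 1L))
    set.seed(1000 + i)
    c10 <- ur_cost(G, karger_partition(H, G, runs = 10L))
    expect_lte(c10, c1)
  }
})

test_that("the greedy heuristic finds the one-insertion split of the two-arc example", {
  G <- three_vertex_example()
  set.seed(44)
  P <- greedy_partition(G)
  expect_valid_partition(P, G$vertices, exactly_two = TRUE)
  expect_equal(ur_cost(G, P), 1L)  # exhaustive optimum over all bipartitions
  # on a BMG, splitting by Aho components of the informative triples costs 0;
  # greedy must match that optimum on an easy two-component instance
  ex <- two_cherry_example()
  set.seed(45)
  Pg <- greedy_partition(ex$bmg)
  expect_equal(ur_cost(ex$bmg, Pg), 0L)
})

test_that("the gradient walk reaches a local optimum no worse than its neighbors", {
  set.seed(46)
  for (i in 1:5) {
    G <- random_colored_digraph(7, 3)
    P <- gradient_walk_partition(G)
    expect_valid_partition(P, G$vertices, exactly_two = TRUE)
    cost <- ur_cost(G, P)
    expect_gte(cost, nrow(u_star(G)))
    # no single-vertex move that keeps both blocks non-empty improves it
    for (b in 1:2) {
      if (length(P[[b]]) < 2L) next
      for (vtx in P[[b]]) {
        Q <- list(setdiff(P[[b]], vtx), c(P[[3 - b]], vtx))
        expect_gte(ur_cost(G, Q), cost)
      }
    }
  }
})

test_that("both Louvain variants return non-trivial partitions that beat the discrete start", {
  set.seed(47)
  for (i in 1:5) {
    rw <- random_weighted_graph(8)
    G <- random_colored_digraph(8, 3)
    dimnames(rw$W) <- list(G$vertices, G$vertices)
    H <- graph_from_wadj(rw$W)

    Pm <- louvain_partition(H, "modularity")
    expect_valid_partition(Pm, G$vertices)
    memb <- stats::setNames(rep(seq_along(Pm), lengths(Pm)), unlist(Pm))[G$vertices]
    expect_gte(graph_modularity(rw$W, memb), graph_modularity(rw$W, 1:8))

    Pc <- louvain_partition(H, "ur-cost", G)
    expect_valid_partition(Pc, G$vertices)
    expect_lte(ur_cost(G, Pc), ur_cost(G, as.list(G$vertices)))
  }
  expect_error(louvain_partition(graph_from_wadj(matrix(c(0, 1, 1, 0), 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "ur-cost"), "requires G")
})

test_that("modularity Louvain recovers two planted dense clusters", {
  set.seed(48)
  n <- 10
  v <- paste0("v", 1:n)
  W <- matrix(0, n, n, dimnames = list(v, v))
  inside <- outer(rep(1:2, each = 5), rep(1:2, each = 5), `==`)
  W[inside] <- 3; W[!inside] <- 0
  # a single weak bridge keeps the graph connected
  W[5, 6] <- W[6, 5] <- 1
  diag(W) <- 0
  P <- louvain_partition(graph_from_wadj(W), "modularity")
  expect_equal(length(P), 2L)
  expect_setequal(P[[which(vapply(P, function(b) "v1" %in% b, logical(1)))]], v[1:5])
})

test_that("largest differencing balances sums and never splits a block when coarsening", {
  np <- number_partition(c(8, 7, 6, 5, 4))
  expect_equal(abs(sum(c(8, 7, 6, 5, 4)[np$group1]) -
                     sum(c(8, 7, 6, 5, 4)[np$group2])), np$difference)
  expect_equal(np$difference, 2)  # differencing is heuristic; optimum here is 0
  expect_setequal(c(np$group1, np$group2), 1:5)

  expect_equal(number_partition(c(1, 1))$difference, 0)
  set.seed(49)
  for (i in 1:10) {
    sizes <- sample(1:9, sample(2:7, 1), replace = TRUE)
    np <- number_partition(sizes)
    expect_setequal(c(np$group1, np$group2), seq_along(sizes))
    expect_equal(abs(sum(sizes[np$group1]) - sum(sizes[np$group2])), np$difference)
    # parity of the difference always matches the total
    expect_equal(np$difference %% 2, sum(sizes) %% 2)
  }

  P <- list(c("a", "b"), c("c"), c("d", "e"), c("f"))
  B <- coarsen_to_bipartition(P)
  expect_equal(length(B), 2L)
  expect_setequal(unlist(B), unlist(P))
  for (blk in P) {
    expect_true(all(blk %in% B[[1]]) || all(blk %in% B[[2]]))
  }
  expect_identical(coarsen_to_bipartition(P[1:2]), P[1:2])
})

test_that("best-of-runs selection never returns a worse partition than a single run", {
  set.seed(50)
  G <- random_colored_digraph(8, 3)
  W <- matrix(1, 8, 8, dimnames = list(G$vertices, G$vertices)); diag(W) <- 0
  H <- graph_from_wadj(W)
  for (nm in c("karger", "greedy", "gradient", "louvain-c")) {
    set.seed(60)
    single <- ur_cost(G, best_of(partition_strategy(nm, runs = 1L), H, G))
    set.seed(60)
    multi <- ur_cost(G, best_of(partition_strategy(nm, runs = 6L), H, G))
    expect_lte(multi, single)
  }
  P <- best_of(partition_strategy("mincut"), H, G)
  expect_valid_partition(P, G$vertices, exactly_two = TRUE)
})
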