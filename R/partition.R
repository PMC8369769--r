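#' Partitioning heuristics for low UR-cost splits
#'
#' The recursive editor needs, at every step with a connected Aho graph, a
#' non-trivial partition of the current vertex set with low UR-cost.  This
#' file implements the partitioning strategies: exact global minimum edge
#' cut (Stoer-Wagner via igraph), Karger's randomized contraction selected by
#' UR-cost, a simple greedy bipartitioner, gradient walks on the bipartition
#' landscape, and two Louvain community-detection variants (modularity and
#' UR-cost objectives).
#'
#' @name partition-heuristics
NULL

# weighted symmetric adjacency matrix (unit weights unless a weight attribute
# is present) from an igraph
as_wadj <- function(H) {
  m <- igraph::as_adjacency_matrix(
    H, sparse = FALSE,
    attr = if ("weight" %in% igraph::edge_attr_names(H)) "weight" else NULL)
  storage.mode(m) <- "double"
  m
}

#' Unnormalized modularity of a partition of a weighted graph
#'
#' `q = sum_W sum_{u,v in W} (a_uv - d_u d_v / (2m))` over ordered vertex
#' pairs (including `u = v`) within communities; `m` is the total edge
#' weight.  Only differences of `q` matter for optimization, so no
#' normalisation is applied.
#'
#' @param W weighted symmetric adjacency matrix.
#' @param membership integer community assignment per vertex.
#' @return numeric modularity value.
#' @export
graph_modularity <- function(W, membership) {
  d <- rowSums(W)
  m2 <- sum(W)  # = 2m for undirected graphs stored symmetrically
  if (m2 == 0) return(0)
  same <- outer(membership, membership, `==`)
  sum((W - outer(d, d) / m2)[same])
}

#' Global minimum edge cut bipartition
#'
#' Exact minimum cut of a connected undirected graph via the Stoer-Wagner
#' algorithm.
#'
#' @param H connected undirected [igraph::igraph] on at least two vertices
#'   (unit edge weights unless a `weight` attribute is set).
#' @return a partition (list of two character-vector blocks).
#' @export
mincut_partition <- function(H) {
  if (igraph::vcount(H) < 2L) stop("need at least two vertices")
  if (!igraph::is_connected(H)) stop("graph must be connected; use its components instead")
  cap <- if ("weight" %in% igraph::edge_attr_names(H)) igraph::E(H)$weight else NULL
  mc <- igraph::min_cut(H, capacity = cap, value.only = FALSE)
  list(sort(names(mc$partition1)), sort(names(mc$partition2)))
}

#' Karger contraction bipartition selected by UR-cost
#'
#' Randomly contracts edges (probability proportional to weight) until two
#' super-vertices remain; over `runs` repetitions the bipartition with the
#' lowest UR-cost on `G` is kept.
#'
#' @param H connected undirected [igraph::igraph] on the vertex set of `G`.
#' @param G the properly colored `colored_digraph` supplying the UR-cost.
#' @param runs number of independent contractions.
#' @return a partition (list of two blocks).
#' @export
karger_partition <- function(H, G, runs = 1L) {
  v <- igraph::V(H)$name
  if (length(v) < 2L) stop("need at least two vertices")
  if (!setequal(v, G$vertices)) stop("H and G must share the vertex set")
  if (length(v) == 2L) return(list(v[1L], v[2L]))
  W <- as_wadj(H)
  best <- NULL; best_cost <- Inf
  for (r in seq_len(runs)) {
    grp <- seq_along(v)
    while (length(unique(grp)) > 2L) {
      # aggregate weights between current groups and sample one merger
      cross <- which(outer(grp, grp, `!=`) & upper.tri(W) & W > 0, arr.ind = TRUE)
      if (nrow(cross) == 0L) stop("graph must be connected")
      wts <- W[cross]
      pick <- cross[sample.int(nrow(cross), 1L, prob = wts), ]
      grp[grp == grp[pick[2L]]] <- grp[pick[1L]]
    }
    P <- unname(lapply(split(v, grp), sort))
    cost <- ur_cost(G, P)
    if (cost < best_cost) { best <- P; best_cost <- cost }
  }
  best
}

#' Simple greedy bipartition
#'
#' Starts from the bipartition `{{}, V'}` and moves one vertex at a time into
#' the first block, always choosing the move with the lowest UR-cost (random
#' tie-break).  The best of the `|V'| - 1` visited non-trivial bipartitions
#' is returned.
#'
#' @param G a properly colored `colored_digraph`.
#' @param Vp the vertex set to split (defaults to all of `G`).
#' @return a partition (list of two blocks).
#' @export
greedy_partition <- function(G, Vp = G$vertices) {
  Vp <- as.character(Vp)
  if (length(Vp) >= 2L && !setequal(Vp, G$vertices)) G <- induced_subdigraph(G, Vp)
  n <- length(Vp)
  if (n < 2L) stop("need at least two vertices")
  V1 <- character(0); V2 <- Vp
  best <- NULL; best_cost <- Inf
  for (step in seq_len(n - 1L)) {
    costs <- vapply(V2, function(vtx)
      ur_cost(G, list(c(V1, vtx), setdiff(V2, vtx))), numeric(1))
    cand <- which(costs == min(costs))
    pick <- if (length(cand) > 1L) sample(cand, 1L) else cand
    V1 <- c(V1, V2[pick]); V2 <- V2[-pick]
    if (min(costs) < best_cost) {
      best <- list(sort(V1), sort(V2)); best_cost <- min(costs)
    }
  }
  best
}

#' Gradient walk on the bipartition landscape
#'
#' Starts from a uniformly random balanced bipartition and repeatedly applies
#' the single-vertex move that most improves the UR-cost (strict improvement,
#' random tie-break, moves that empty a block forbidden) until a local
#' optimum is reached.
#'
#' @inheritParams greedy_partition
#' @return a partition (list of two blocks).
#' @export
gradient_walk_partition <- function(G, Vp = G$vertices) {
  Vp <- as.character(Vp)
  if (length(Vp) >= 2L && !setequal(Vp, G$vertices)) G <- induced_subdigraph(G, Vp)
  n <- length(Vp)
  if (n < 2L) stop("need at least two vertices")
  shuffled <- sample(Vp)
  side <- c(rep(1L, ceiling(n / 2)), rep(2L, floor(n / 2)))
  names(side) <- shuffled
  side <- side[Vp]
  current_cost <- ur_cost(G, split(Vp, side))
  repeat {
    movable <- Vp[tabulate(side, 2L)[side] > 1L]  # moving must not empty a block
    if (length(movable) == 0L) break
    costs <- vapply(movable, function(vtx) {
      s2 <- side; s2[vtx] <- 3L - s2[vtx]
      ur_cost(G, split(Vp, s2))
    }, numeric(1))
    if (min(costs) >= current_cost) break
    cand <- which(costs == min(costs))
    pick <- if (length(cand) > 1L) sample(cand, 1L) else cand
    vtx <- movable[pick]
    side[vtx] <- 3L - side[vtx]
    current_cost <- min(costs)
  }
  unname(lapply(split(Vp, side), sort))
}

#' Louvain community detection with a pluggable objective
#'
#' Two-phase Louvain: phase one repeatedly moves vertices into the community
#' of a neighbor while the objective improves (vertex traversal order
#' randomized); phase two contracts communities into a weighted quotient
#' graph and repeats.  The `modularity` objective maximizes
#' [graph_modularity()] of the partition of `H`; the `ur-cost` objective
#' minimizes [ur_cost()] of the induced partition of the vertices of `G`.
#' Merging the last two communities is excluded, so the result is always a
#' non-trivial partition.
#'
#' @param H connected undirected [igraph::igraph] with at least two vertices.
#' @param objective `"modularity"` or `"ur-cost"`.
#' @param G the `colored_digraph` backing the UR-cost objective (required for
#'   `objective = "ur-cost"`; its vertex set must equal that of `H`).
#' @return a partition (list of character-vector blocks, at least two).
#' @export
louvain_partition <- function(H, objective = c("modularity", "ur-cost"), G = NULL) {
  objective <- match.arg(objective)
  v0 <- igraph::V(H)$name
  if (length(v0) < 2L) stop("need at least two vertices")
  if (objective == "ur-cost") {
    if (is.null(G)) stop("objective 'ur-cost' requires G")
    if (!setequal(v0, G$vertices)) stop("H and G must share the vertex set")
  }
  W <- as_wadj(H)
  groups <- as.list(v0)  # quotient vertex -> original vertices
  score <- function(memb) {
    if (objective == "modularity") graph_modularity(W, memb)
    else -ur_cost(G, unname(lapply(split(seq_along(memb), memb),
                                   function(ix) sort(unlist(groups[ix])))))
  }
  repeat {
    m <- nrow(W)
    comm <- seq_len(m)
    current <- score(comm)
    improved_any <- FALSE
    repeat {
      moved <- FALSE
      for (x in sample.int(m)) {
        nb <- which(W[x, ] > 0)
        cand_comms <- setdiff(unique(comm[nb]), comm[x])
        if (length(cand_comms) == 0L) next
        # never merge the last two communities
        if (length(unique(comm)) == 2L && sum(comm == comm[x]) == 1L) next
        vals <- vapply(cand_comms, function(cc) {
          c2 <- comm; c2[x] <- cc
          score(c2)
        }, numeric(1))
        if (max(vals) > current) {
          best <- cand_comms[which.max(vals)]
          comm[x] <- best
          current <- max(vals)
          moved <- TRUE; improved_any <- TRUE
        }
      }
      if (!moved) break
    }
    if (!improved_any) break
    # phase 2: contract communities into a weighted quotient graph
    ids <- sort(unique(comm))
    comm <- match(comm, ids)
    k <- length(ids)
    agg <- matrix(0, k, k)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      agg[comm[i], comm[j]] <- agg[comm[i], comm[j]] + W[i, j]
    }
    groups <- lapply(seq_len(k), function(cc) unlist(groups[comm == cc]))
    W <- agg
    if (k == m) break
  }
  unname(lapply(groups, sort))
}

#' Largest-differencing number partitioning
#'
#' Splits a multiset of sizes into two groups with approximately equal sums
#' (Karmarkar-Karp differencing heuristic).
#'
#' @param sizes numeric vector of item sizes (length >= 2).
#' @return list with integer index vectors `group1`, `group2` and the
#'   achieved `difference`.
#' @export
number_partition <- function(sizes) {
  stopifnot(length(sizes) >= 2L)
  items <- lapply(seq_along(sizes), function(i)
    list(value = sizes[i], A = i, B = integer(0)))
  while (length(items) > 1L) {
    ord <- order(vapply(items, `[[`, numeric(1), "value"), decreasing = TRUE)
    i1 <- items[[ord[1L]]]; i2 <- items[[ord[2L]]]
    merged <- list(value = i1$value - i2$value,
                   A = c(i1$A, i2$B), B = c(i1$B, i2$A))
    items <- c(items[-ord[1:2]], list(merged))
  }
  list(group1 = sort(items[[1L]]$A), group2 = sort(items[[1L]]$B),
       difference = items[[1L]]$value)
}

#' Coarsen a partition to a balanced bipartition
#'
#' Merges the blocks of a partition into two groups whose total sizes are as
#' balanced as the largest-differencing heuristic achieves.  Blocks are never
#' split.
#'
#' @param P a partition (list of at least two blocks).
#' @return a partition with exactly two blocks.
#' @export
coarsen_to_bipartition <- function(P) {
  if (length(P) < 2L) stop("need at least two blocks")
  if (length(P) == 2L) return(P)
  np <- number_partition(lengths(P))
  list(sort(unlist(P[np$group1])), sort(unlist(P[np$group2])))
}

#' Partitioning strategy specification
#'
#' @param name one of `"mincut"`, `"karger"`, `"greedy"`, `"gradient"`,
#'   `"louvain-m"`, `"louvain-c"`.
#' @param runs independent runs per call; the best partition by objective
#'   value is kept (deterministic strategies are run once).
#' @return an object of class `partition_strategy`.
#' @export
partition_strategy <- function(name = c("louvain-c", "mincut", "karger",
                                        "greedy", "gradient", "louvain-m"),
                               runs = 5L) {
  name <- match.arg(name)
  stopifnot(runs >= 1L)
  structure(list(name = name, runs = as.integer(runs)),
            class = "partition_strategy")
}

strategy_names <- function() {
  c("mincut", "karger", "greedy", "gradient", "louvain-m", "louvain-c")
}

run_strategy_once <- function(name, H, G) {
  switch(name,
         "mincut"    = mincut_partition(H),
         "karger"    = karger_partition(H, G),
         "greedy"    = greedy_partition(G),
         "gradient"  = gradient_walk_partition(G),
         "louvain-m" = louvain_partition(H, "modularity"),
         "louvain-c" = louvain_partition(H, "ur-cost", G),
         stop("unknown strategy: ", name))
}

#' Best-of-several-runs partition
#'
#' Runs a strategy repeatedly and returns the partition with the best
#' objective value: highest modularity for `louvain-m`, lowest UR-cost for
#' everything else.  The deterministic Stoer-Wagner cut is run once.
#'
#' @param strategy a [partition_strategy()].
#' @param H the (connected) Aho graph of the current step, an igraph.
#' @param G the `colored_digraph` on the same vertex set.
#' @return a partition (list of blocks).
#' @export
best_of <- function(strategy, H, G) {
  runs <- if (strategy$name == "mincut") 1L else strategy$runs
  best <- NULL; best_val <- -Inf
  W <- if (strategy$name == "louvain-m") as_wadj(H) else NULL
  for (r in seq_len(runs)) {
    P <- run_strategy_once(strategy$name, H, G)
    val <- if (strategy$name == "louvain-m") {
      memb <- partition_membership(igraph::V(H)$name, P)
      graph_modularity(W, memb)
    } else {
      -ur_cost(G, P)
    }
    if (val > best_val) { best <- P; best_val <- val }
  }
  best
}
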