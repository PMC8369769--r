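# Independent brute-force oracles used across the suite.  Everything here is
# deliberately naive: exhaustive enumeration at tiny n, no sharing with the
# implementation paths under test.

# all set partitions of a character vector (list of lists of blocks)
all_set_partitions <- function(xs) {
  if (length(xs) == 1L) return(list(list(xs)))
  first <- xs[1L]
  rest <- all_set_partitions(xs[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

nontrivial_partitions <- function(xs) {
  Filter(function(p) length(p) >= 2L, all_set_partitions(xs))
}

# all rooted phylogenetic trees on a leaf set (exhaustive, n <= 6);
# each tree is counted once via its unique root partition
all_phylo_trees <- function(leaves) {
  leaves <- sort(leaves)
  if (length(leaves) == 1L) return(list(leaf_tree(leaves)))
  out <- list()
  for (p in nontrivial_partitions(leaves)) {
    sub_choices <- lapply(p, all_phylo_trees)
    combos <- expand.grid(lapply(sub_choices, seq_along))
    for (r in seq_len(nrow(combos))) {
      subs <- lapply(seq_along(p), function(i) sub_choices[[i]][[combos[r, i]]])
      out[[length(out) + 1L]] <- join_trees(subs)
    }
  }
  out
}

# trees whose root partition equals P (children subtrees enumerated freely)
trees_with_root_partition <- function(P) {
  sub_choices <- lapply(P, all_phylo_trees)
  combos <- expand.grid(lapply(sub_choices, seq_along))
  lapply(seq_len(nrow(combos)), function(r)
    join_trees(lapply(seq_along(P), function(i) sub_choices[[i]][[combos[r, i]]])))
}

pair_key <- function(m) if (NROW(m) == 0L) character(0) else paste(m[, 1L], m[, 2L])

# brute-force unsatisfiable relations of a partition: intersection of the
# per-tree edit sets over all trees with that root partition
ur_pairs_oracle <- function(G, P) {
  trees <- trees_with_root_partition(P)
  keys <- Reduce(intersect, lapply(trees, function(tr) pair_key(ur_of_tree(G, tr))))
  sort(keys)
}

# brute-force universally unsatisfiable relations: intersection over all trees
u_star_oracle <- function(G) {
  trees <- all_phylo_trees(G$vertices)
  sort(Reduce(intersect, lapply(trees, function(tr) pair_key(ur_of_tree(G, tr)))))
}

# brute-force gain over distinct-color ordered pairs: pairs whose status
# agrees with the BMG of every tree with root partition P
gain_oracle <- function(G, P) {
  trees <- trees_with_root_partition(P)
  v <- sort(G$vertices)
  agree <- NULL
  for (tr in trees) {
    H <- bmg_of_tree(tr, G$color)
    a <- G$adj[v, v] == H$adj[v, v]
    agree <- if (is.null(agree)) a else agree & a
  }
  cross <- outer(G$color[v], G$color[v], `!=`)
  sum(agree & cross)
}

# ordered same-colored pairs lying in different blocks of P
same_color_cross_block <- function(G, P) {
  memb <- stats::setNames(rep(seq_along(P), lengths(P)), unlist(P))
  v <- G$vertices
  sum(outer(G$color[v], G$color[v], `==`) &
        outer(memb[v], memb[v], `!=`))
}

# random properly colored digraph on given vertices
random_colored_digraph <- function(n, ell, p_arc = 0.4) {
  v <- paste0("v", seq_len(n))
  cols <- paste0("c", c(seq_len(ell), sample.int(ell, n - ell, replace = TRUE)))
  names(cols) <- v
  G <- colored_digraph(v, cols)
  cross <- outer(cols, cols, `!=`); diag(cross) <- FALSE
  G$adj <- cross & matrix(stats::runif(n * n) < p_arc, n, n)
  dimnames(G$adj) <- list(v, v)
  G
}

# minimum cut value by exhaustive bipartition scan on a weighted adjacency
min_cut_oracle <- function(W) {
  n <- nrow(W)
  best <- Inf
  for (mask in 1:(2^(n - 1L) - 1L)) {
    side <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    best <- min(best, sum(W[side, !side]))
  }
  best
}

random_bmg_instance <- function(N, ell, binary = FALSE) {
  tr <- random_tree(N, binary = binary)
  sig <- random_coloring(tr, ell)
  list(tree = tr, sigma = sig, bmg = bmg_of_tree(tr, sig))
}
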