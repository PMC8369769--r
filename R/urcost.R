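#' Unsatisfiable relations of a partition
#'
#' For a non-trivial partition `P` of the vertex set, the unsatisfiable
#' relations are the ordered pairs whose arc status in `G` disagrees with the
#' best match graph of *every* tree whose root partition equals `P`.  They
#' decompose into three disjoint sets:
#'
#' * `U1`: arcs `(x, y)` leaving a block `V_i` that contains the color of `y`
#'   (the best match of `x` with `y`'s color is then forced inside `V_i`);
#' * `U2`: non-arcs `(x, y)` leaving `V_i` when `V_i` misses the color of `y`
#'   (then `y` is forced to be a best match of `x`);
#' * `U3`: non-arcs `(x, y)` inside a block in which `y` is the only vertex of
#'   its color.
#'
#' Pairs are ordered throughout: `(x, y)` and `(y, x)` are independent
#' relations.  The computation runs in O(|V|^2) via per-block color counts.
#'
#' @param G a properly colored `colored_digraph`.
#' @param P a partition: list of character vectors with at least two blocks,
#'   disjoint, covering the vertex set.
#' @return a list of class `ur_decomposition` with two-column matrices `U1`,
#'   `U2`, `U3`, their union `U`, and `cost = nrow(U)`.
#' @export
ur_sets <- function(G, P) {
  assert_proper(G)
  membership <- partition_membership(G$vertices, P)
  n <- length(G$vertices)
  cols <- unique(unname(G$color))
  col_idx <- match(unname(G$color), cols)
  k <- max(membership)
  # per-block color counts n_{i,A}
  B <- matrix(0L, k, length(cols))
  for (i in seq_len(n)) B[membership[i], col_idx[i]] <- B[membership[i], col_idx[i]] + 1L
  # C[x, y] = count of sigma(y)-colored vertices in the block of x
  C <- B[membership, , drop = FALSE][, col_idx, drop = FALSE]
  same_block <- outer(membership, membership, `==`)
  diag_mask <- diag(TRUE, n)
  u1 <- G$adj & !same_block & C > 0L
  u2 <- !G$adj & !same_block & C == 0L & !diag_mask
  u3 <- !G$adj & same_block & C == 1L & !diag_mask
  as_pairs <- function(m) {
    w <- which(m, arr.ind = TRUE)
    cbind(from = G$vertices[w[, 1L]], to = G$vertices[w[, 2L]])
  }
  U1 <- as_pairs(u1); U2 <- as_pairs(u2); U3 <- as_pairs(u3)
  U <- rbind(U1, U2, U3)
  structure(list(U1 = U1, U2 = U2, U3 = U3, U = U, cost = nrow(U)),
            class = "ur_decomposition")
}

#' @export
print.ur_decomposition <- function(x, ...) {
  cat("<ur_decomposition> cost ", x$cost, " (|U1| = ", nrow(x$U1),
      ", |U2| = ", nrow(x$U2), ", |U3| = ", nrow(x$U3), ")\n", sep = "")
  invisible(x)
}

# integer block membership for the given vertices; errors on bad partitions
partition_membership <- function(vertices, P) {
  if (length(P) < 2L) stop("partition must be non-trivial (>= 2 blocks)")
  flat <- unlist(P)
  if (anyDuplicated(flat) || !setequal(flat, vertices) ||
      any(lengths(P) == 0L))
    stop("blocks must be disjoint, non-empty and cover the vertex set")
  membership <- integer(length(vertices))
  names(membership) <- vertices
  for (i in seq_along(P)) membership[P[[i]]] <- i
  unname(membership[vertices])
}

#' UR-cost of a partition
#'
#' `|U(G, P)|`, the number of arc modifications forced by fixing `P` as the
#' root partition of the explaining tree.
#'
#' @inheritParams ur_sets
#' @return non-negative integer.
#' @export
ur_cost <- function(G, P) ur_sets(G, P)$cost

#' Unsatisfied relations w.r.t. a single tree
#'
#' The symmetric difference between the arc set of `G` and the arc set of the
#' best match graph of `tree` — the edit set that turns `G` into that BMG.
#'
#' @param G a `colored_digraph`.
#' @param tree a `phylo_tree` with leaf set equal to the vertex set of `G`.
#' @return two-column character matrix of ordered pairs.
#' @export
ur_of_tree <- function(G, tree) {
  if (!setequal(tree_leaves(tree), G$vertices))
    stop("tree leaves must equal the digraph vertex set")
  H <- bmg_of_tree(tree, G$color)
  v <- G$vertices
  diffm <- G$adj[v, v] != H$adj[v, v]
  w <- which(diffm, arr.ind = TRUE)
  cbind(from = v[w[, 1L]], to = v[w[, 2L]])
}

#' Universally unsatisfiable relations
#'
#' The ordered pairs contained in the edit set of *every* phylogenetic tree
#' on the vertex set: exactly the missing arcs pointing to a color-unique
#' vertex.  `|u_star(G)|` is a lower bound on any BMG edit cost.
#'
#' @param G a properly colored `colored_digraph`.
#' @return two-column character matrix of ordered pairs (zero rows when
#'   `|V| < 2`).
#' @export
u_star <- function(G) {
  assert_proper(G)
  v <- G$vertices
  empty <- cbind(from = character(0), to = character(0))
  if (length(v) < 2L) return(empty)
  tab <- table(G$color)
  unique_color <- unname(tab[G$color] == 1L)
  m <- !G$adj & matrix(unique_color, length(v), length(v), byrow = TRUE)
  diag(m) <- FALSE
  w <- which(m, arr.ind = TRUE)
  cbind(from = v[w[, 1L]], to = v[w[, 2L]])
}

#' Gain of a partition
#'
#' The number of ordered pairs whose arc status in `G` is *satisfied* by the
#' best match graphs of all trees with root partition `P`.  Obtained from the
#' three unsatisfiable-relation sets by swapping the arc/non-arc membership
#' conditions.  This is a cursory balance-encouraging objective; see the
#' methods vignette for its limitations.
#'
#' @inheritParams ur_sets
#' @return non-negative integer.
#' @export
gain <- function(G, P) {
  assert_proper(G)
  membership <- partition_membership(G$vertices, P)
  n <- length(G$vertices)
  cols <- unique(unname(G$color))
  col_idx <- match(unname(G$color), cols)
  k <- max(membership)
  B <- matrix(0L, k, length(cols))
  for (i in seq_len(n)) B[membership[i], col_idx[i]] <- B[membership[i], col_idx[i]] + 1L
  C <- B[membership, , drop = FALSE][, col_idx, drop = FALSE]
  same_block <- outer(membership, membership, `==`)
  diag_mask <- diag(TRUE, n)
  g1 <- !G$adj & !same_block & C > 0L & !diag_mask
  g2 <- G$adj & !same_block & C == 0L
  g3 <- G$adj & same_block & C == 1L
  sum(g1 | g2 | g3)
}
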