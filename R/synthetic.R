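#' Random phylogenetic tree by vertex attachment
#'
#' Grows a tree from a single vertex: at each step a uniformly random
#' existing vertex is chosen; if it is an inner vertex one new leaf child is
#' attached, if it is a leaf it becomes an inner vertex with two new leaf
#' children.  Either way the leaf count grows by one and the tree stays
#' phylogenetic.  In `binary` mode only current leaves are eligible, so every
#' inner vertex ends up with exactly two children.
#'
#' @param N desired number of leaves (>= 1).
#' @param binary logical; grow a binary tree.
#' @return a `phylo_tree` with leaves labelled `x1 ... xN`.
#' @export
random_tree <- function(N, binary = FALSE) {
  if (N < 1L) stop("N must be at least 1")
  parent <- 0L
  is_leaf <- TRUE
  nleaves <- 1L
  while (nleaves < N) {
    cand <- if (binary) which(is_leaf) else seq_along(parent)
    v <- cand[sample.int(length(cand), 1L)]
    if (is_leaf[v]) {
      parent <- c(parent, v, v)
      is_leaf[v] <- FALSE
      is_leaf <- c(is_leaf, TRUE, TRUE)
    } else {
      parent <- c(parent, v)
      is_leaf <- c(is_leaf, TRUE)
    }
    nleaves <- sum(is_leaf)
  }
  label <- rep(NA_character_, length(parent))
  label[is_leaf] <- paste0("x", seq_len(sum(is_leaf)))
  new_phylo_tree(parent, label)
}

#' Random surjective leaf coloring
#'
#' Assigns one random distinct leaf to each of the `ell` colors, then colors
#' the remaining leaves uniformly, so every color appears at least once.
#'
#' @param tree a `phylo_tree`.
#' @param ell number of colors (1 <= ell <= number of leaves).
#' @return named character vector of colors `"c1" ... "c<ell>"`.
#' @export
random_coloring <- function(tree, ell) {
  lv <- tree_leaves(tree)
  if (ell > length(lv)) stop("more colors than leaves")
  if (ell < 1L) stop("need at least one color")
  cols <- paste0("c", seq_len(ell))
  sigma <- stats::setNames(rep(NA_character_, length(lv)), lv)
  anchors <- sample(lv, ell)
  sigma[anchors] <- cols
  rest <- is.na(sigma)
  sigma[rest] <- sample(cols, sum(rest), replace = TRUE)
  sigma
}

#' Independent arc perturbation
#'
#' Deletes every existing arc independently with probability `p_del` and
#' inserts every absent cross-color ordered pair independently with
#' probability `p_ins` (one pass; a deleted arc is never re-inserted in the
#' same call).  Arcs between same-colored vertices are never created, so the
#' output stays properly colored.
#'
#' @param G a properly colored `colored_digraph`.
#' @param p_ins,p_del probabilities in `[0, 1]`.
#' @return the perturbed `colored_digraph`.
#' @export
perturb <- function(G, p_ins, p_del) {
  if (p_ins < 0 || p_ins > 1 || p_del < 0 || p_del > 1)
    stop("probabilities must lie in [0, 1]")
  assert_proper(G)
  n <- length(G$vertices)
  cross <- cross_color_mask(G)
  rand <- matrix(stats::runif(n * n), n, n)
  del <- G$adj & rand < p_del
  ins <- !G$adj & cross & rand < p_ins
  G$adj[del] <- FALSE
  G$adj[ins] <- TRUE
  G
}

#' Benchmark instance set
#'
#' Generates `count` perturbed-BMG instances: a random colored tree, its BMG,
#' and an independently perturbed arc set.  With
#' `require_connected_aho = TRUE` instances whose perturbed digraph has a
#' disconnected Aho graph are discarded and regenerated (the partitioning
#' heuristics are only exercised on connected Aho graphs); the retention rate
#' is recorded.
#'
#' @param N leaves per tree.
#' @param ell colors (`ell <= N`, each used at least once).
#' @param p_ins,p_del perturbation probabilities.
#' @param count number of instances to return.
#' @param binary grow binary trees (instances are then binary-explainable).
#' @param require_connected_aho discard instances with a disconnected Aho
#'   graph.
#' @param seed optional integer seed.
#' @param max_attempts_factor cap on regeneration attempts
#'   (`max_attempts_factor * count`).
#' @return list of instances, each a list `(tree, sigma, bmg, perturbed)`;
#'   attribute `retention` holds the fraction of generated instances kept.
#' @export
make_benchmark_set <- function(N, ell, p_ins = 0.1, p_del = 0.1, count = 10L,
                               binary = FALSE, require_connected_aho = TRUE,
                               seed = NULL, max_attempts_factor = 100L) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", count)
  kept <- 0L; tried <- 0L
  while (kept < count && tried < max_attempts_factor * count) {
    tried <- tried + 1L
    tr <- random_tree(N, binary = binary)
    sigma <- random_coloring(tr, ell)
    bmg <- bmg_of_tree(tr, sigma)
    pert <- perturb(bmg, p_ins, p_del)
    if (require_connected_aho) {
      H <- aho_graph(informative_triples(pert), pert$vertices)
      if (length(graph_components(H)) > 1L) next
    }
    kept <- kept + 1L
    out[[kept]] <- list(tree = tr, sigma = sigma, bmg = bmg, perturbed = pert)
  }
  if (kept < count) stop("could not generate enough instances; relax the filter")
  attr(out, "retention") <- kept / tried
  out
}
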