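#' Rooted phylogenetic trees
#'
#' `bmgedit` uses a light-weight rooted tree structure in which every inner
#' vertex has at least two children ("phylogenetic") and only leaves carry
#' labels.  Trees are stored as a parent vector plus a children list; leaf
#' labels are arbitrary character ids.  Child order carries no meaning.
#'
#' @param parent integer vector; `parent[i]` is the index of the parent of
#'   node `i`, `0` for the root.
#' @param label character vector of the same length; `NA` for inner nodes,
#'   the leaf id otherwise.
#' @return an object of class `phylo_tree`.
#' @keywords internal
new_phylo_tree <- function(parent, label) {
  n <- length(parent)
  stopifnot(length(label) == n, sum(parent == 0L) == 1L)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  is_leaf <- lengths(children) == 0L
  if (any(is.na(label[is_leaf]))) stop("every leaf must be labelled")
  if (any(!is_leaf & lengths(children) < 2L))
    stop("tree is not phylogenetic: inner vertex with a single child")
  structure(
    list(parent = as.integer(parent), children = children,
         label = as.character(label), root = which(parent == 0L)),
    class = "phylo_tree")
}

#' Single-leaf tree
#' @param label leaf id.
#' @return a `phylo_tree` with one vertex.
#' @export
leaf_tree <- function(label) new_phylo_tree(0L, as.character(label))

#' Join subtrees under a new root
#'
#' Creates the tree whose root has the given trees as child subtrees.  With a
#' single subtree the subtree itself is returned (no degree-one vertex is
#' ever created).
#'
#' @param subtrees list of `phylo_tree` objects with pairwise disjoint leaf
#'   sets.
#' @return a `phylo_tree`.
#' @export
join_trees <- function(subtrees) {
  stopifnot(length(subtrees) >= 1L)
  if (length(subtrees) == 1L) return(subtrees[[1L]])
  parent <- 0L
  label <- NA_character_
  offset <- 1L
  for (st in subtrees) {
    m <- length(st$parent)
    p <- st$parent
    p[p == 0L] <- 1L - offset  # root of subtree points at new root (index 1)
    parent <- c(parent, p + offset)
    label <- c(label, st$label)
    offset <- offset + m
  }
  new_phylo_tree(parent, label)
}

#' Leaf labels of a tree
#' @param tree a `phylo_tree`.
#' @return character vector of leaf ids.
#' @export
tree_leaves <- function(tree) {
  tree$label[lengths(tree$children) == 0L]
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat("<phylo_tree> ", length(tree_leaves(x)), " leaves: ",
      write_newick(x), "\n", sep = "")
  invisible(x)
}

# index of the node carrying each requested leaf label
leaf_index <- function(tree, labels) {
  idx <- match(labels, tree$label)
  if (anyNA(idx)) stop("unknown leaf id(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  idx
}

# depth of every node (root = 0)
node_depths <- function(tree) {
  n <- length(tree$parent)
  depth <- integer(n)
  # parents are not ordered, so walk down from the root
  queue <- tree$root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ch in tree$children[[v]]) {
      depth[ch] <- depth[v] + 1L
      queue <- c(queue, ch)
    }
  }
  depth
}

# root-to-node path (indices, ending at the node)
root_path <- function(tree, v) {
  path <- v
  while (tree$parent[v] != 0L) {
    v <- tree$parent[v]
    path <- c(v, path)
  }
  path
}

#' Last common ancestor
#'
#' The unique lowest vertex of the tree ancestral to every leaf in `A`.
#'
#' @param tree a `phylo_tree`.
#' @param A non-empty character vector of leaf ids.
#' @return internal node index (use [tree_leaves_below()] to inspect it).
#' @export
tree_lca <- function(tree, A) {
  stopifnot(length(A) >= 1L)
  idx <- leaf_index(tree, A)
  path <- root_path(tree, idx[1L])
  for (v in idx[-1L]) path <- intersect(path, root_path(tree, v))
  path[length(path)]
}

#' Leaves below a node
#' @param tree a `phylo_tree`.
#' @param v node index.
#' @return character vector of leaf ids in the subtree rooted at `v`.
#' @export
tree_leaves_below <- function(tree, v) {
  out <- character(0)
  queue <- v
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    if (length(tree$children[[u]]) == 0L) out <- c(out, tree$label[u])
    else queue <- c(queue, tree$children[[u]])
  }
  out
}

#' Restriction of a tree to a leaf subset
#'
#' The minimal subtree spanning `labels`, with all degree-two vertices
#' suppressed (the root of the result is the last common ancestor of
#' `labels`).  The result is again phylogenetic.
#'
#' @param tree a `phylo_tree`.
#' @param labels non-empty subset of `tree_leaves(tree)`.
#' @return a `phylo_tree` on `labels`.
#' @export
tree_restrict <- function(tree, labels) {
  if (length(labels) == 0L) stop("cannot restrict to an empty leaf set")
  leaf_index(tree, labels)  # membership check
  keep <- unique(as.character(labels))
  rec <- function(v) {
    if (length(tree$children[[v]]) == 0L) {
      if (tree$label[v] %in% keep) return(leaf_tree(tree$label[v]))
      return(NULL)
    }
    subs <- Filter(Negate(is.null), lapply(tree$children[[v]], rec))
    if (length(subs) == 0L) return(NULL)
    join_trees(subs)  # single survivor: degree-2 vertex suppressed
  }
  rec(tree$root)
}

#' Does a tree display a rooted triple?
#'
#' `xy|z` is displayed iff `lca(x,y)` is a strict descendant of
#' `lca(x,z) = lca(y,z)`.
#'
#' @param tree a `phylo_tree`.
#' @param x,y,z distinct leaf ids; the cherry is `{x, y}`.
#' @return logical.
#' @export
displays_triple <- function(tree, x, y, z) {
  d <- node_depths(tree)
  lxy <- tree_lca(tree, c(x, y))
  lxz <- tree_lca(tree, c(x, z))
  lyz <- tree_lca(tree, c(y, z))
  lxz == lyz && d[lxy] > d[lxz]
}

#' All rooted triples displayed by a tree
#' @param tree a `phylo_tree`.
#' @return a triple set (see [triple_set()]).
#' @export
tree_triples <- function(tree) {
  lv <- tree_leaves(tree)
  n <- length(lv)
  if (n < 3L) return(triple_set())
  xs <- character(0); ys <- character(0); zs <- character(0)
  d <- node_depths(tree)
  # lca matrix over leaves
  idx <- leaf_index(tree, lv)
  paths <- lapply(idx, function(i) root_path(tree, i))
  lca_depth <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- intersect(paths[[i]], paths[[j]])
    lca_depth[i, j] <- d[p[length(p)]]
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) for (k in seq_len(n)) {
    if (k == i || k == j) next
    if (lca_depth[i, j] > lca_depth[i, k] && lca_depth[i, k] == lca_depth[j, k]) {
      xs <- c(xs, lv[i]); ys <- c(ys, lv[j]); zs <- c(zs, lv[k])
    }
  }
  triple_set(xs, ys, zs)
}

#' Rooted leaf-labelled tree isomorphism
#'
#' Trees are compared as unordered rooted trees with labelled leaves.
#'
#' @param t1,t2 `phylo_tree` objects.
#' @return logical.
#' @export
trees_isomorphic <- function(t1, t2) {
  identical(canonical_form(t1), canonical_form(t2))
}

canonical_form <- function(tree) {
  rec <- function(v) {
    if (length(tree$children[[v]]) == 0L) return(tree$label[v])
    parts <- sort(vapply(tree$children[[v]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(tree$root)
}

#' Is every inner vertex binary?
#' @param tree a `phylo_tree`.
#' @return logical.
#' @export
is_binary_tree <- function(tree) {
  all(lengths(tree$children) %in% c(0L, 2L))
}
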