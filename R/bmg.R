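#' Best match graph of a leaf-colored tree
#'
#' A leaf `y` is a best match of `x` if the two have different colors and no
#' leaf of `y`'s color has a lower last common ancestor with `x`.  The best
#' match graph (BMG) collects all best-match arcs `(x, y)`.
#'
#' @param tree a `phylo_tree`.
#' @param sigma named character vector assigning a color to every leaf.
#' @return a `colored_digraph` on the leaves of `tree`.
#' @export
bmg_of_tree <- function(tree, sigma) {
  lv <- tree_leaves(tree)
  if (!all(lv %in% names(sigma)) || anyNA(sigma[lv]))
    stop("every leaf needs a color")
  sigma <- sigma[lv]
  G <- colored_digraph(lv, sigma)
  n <- length(lv)
  if (n < 2L) return(G)
  # leaves below every node, plus the set of colors they carry
  nnodes <- length(tree$parent)
  below <- vector("list", nnodes)
  post <- integer(0)
  rec_post <- function(v) {
    for (ch in tree$children[[v]]) rec_post(ch)
    post <<- c(post, v)
  }
  rec_post(tree$root)
  for (v in post) {
    if (length(tree$children[[v]]) == 0L) below[[v]] <- tree$label[v]
    else below[[v]] <- unlist(lapply(tree$children[[v]], function(ch) below[[ch]]))
  }
  colors_below <- lapply(below, function(b) unique(unname(sigma[b])))
  for (x in lv) {
    v <- leaf_index(tree, x)
    remaining <- setdiff(unique(unname(sigma)), sigma[[x]])
    while (length(remaining) && tree$parent[v] != 0L) {
      u <- tree$parent[v]
      found <- intersect(remaining, colors_below[[u]])
      for (cl in found) {
        ys <- below[[u]][sigma[below[[u]]] == cl]
        G$adj[x, ys] <- TRUE
      }
      remaining <- setdiff(remaining, found)
      v <- u
    }
  }
  G
}

#' Informative triples of a colored digraph
#'
#' All `ab|b'` with `sigma(a) != sigma(b) = sigma(b')`, `(a,b)` an arc and
#' `(a,b')` a non-arc: the arc evidence that `a` and `b` diverged below the
#' divergence from `b'`.
#'
#' @param G a properly colored `colored_digraph`.
#' @return a triple set.
#' @export
informative_triples <- function(G) {
  assert_proper(G)
  xs <- character(0); ys <- character(0); zs <- character(0)
  for (a in G$vertices) {
    for (s in setdiff(unique(G$color), G$color[[a]])) {
      grp <- G$vertices[G$color == s]
      inn <- grp[G$adj[a, grp]]
      out <- grp[!G$adj[a, grp]]
      if (length(inn) && length(out)) {
        cmb <- expand.grid(b = inn, bp = out, stringsAsFactors = FALSE)
        xs <- c(xs, rep(a, nrow(cmb))); ys <- c(ys, cmb$b); zs <- c(zs, cmb$bp)
      }
    }
  }
  triple_set(xs, ys, zs)
}

#' Forbidden triples of a colored digraph
#'
#' All `ab|b'` with `sigma(a) != sigma(b) = sigma(b')`, `b != b'`, and both
#' `(a,b)` and `(a,b')` arcs.  Since `b` and `b'` play symmetric roles, both
#' `ab|b'` and `ab'|b` are produced whenever both arcs exist; no explaining
#' tree may display any of them.
#'
#' @param G a properly colored `colored_digraph`.
#' @return a triple set.
#' @export
forbidden_triples <- function(G) {
  assert_proper(G)
  xs <- character(0); ys <- character(0); zs <- character(0)
  for (a in G$vertices) {
    for (s in setdiff(unique(G$color), G$color[[a]])) {
      grp <- G$vertices[G$color == s]
      inn <- grp[G$adj[a, grp]]
      if (length(inn) >= 2L) {
        cmb <- expand.grid(b = inn, bp = inn, stringsAsFactors = FALSE)
        cmb <- cmb[cmb$b != cmb$bp, , drop = FALSE]
        xs <- c(xs, rep(a, nrow(cmb))); ys <- c(ys, cmb$b); zs <- c(zs, cmb$bp)
      }
    }
  }
  triple_set(xs, ys, zs)
}

#' Extended triple set for binary explainability
#'
#' The informative triples together with the cherry-forcing triples `bb'|a`
#' derived from every forbidden triple `ab|b'` with `sigma(b) = sigma(b')`.
#' Consistency of this set (plus sink-free coloring) characterises BMGs
#' explainable by a binary tree.
#'
#' @param G a properly colored `colored_digraph`.
#' @return a triple set.
#' @export
binary_triples <- function(G) {
  R <- informative_triples(G)
  Fb <- forbidden_triples(G)
  if (nrow(Fb)) {
    # a forbidden triple has cherry {a, b} and outgroup b', where b and b'
    # share a color and a is the witness; the forced cherry is {b, b'}.  The
    # stored cherry is lexicographically sorted, so recover b by color.
    cz <- unname(G$color[Fb$z])
    b <- ifelse(unname(G$color[Fb$x]) == cz, Fb$x, Fb$y)
    a <- ifelse(unname(G$color[Fb$x]) == cz, Fb$y, Fb$x)
    extra <- triple_set(b, Fb$z, a)
    R <- triple_set(c(R$x, extra$x), c(R$y, extra$y), c(R$z, extra$z))
  }
  R
}

#' Sink-free coloring test
#'
#' A coloring is sink-free if it is proper and every vertex has an
#' out-neighbor of every other color present in the graph — a necessary
#' property of BMGs.
#'
#' @param G a `colored_digraph`.
#' @return logical.
#' @export
is_sf_colored <- function(G) {
  if (!is_properly_colored(G)) return(FALSE)
  cols <- unique(G$color)
  for (x in G$vertices) {
    nb_cols <- unique(G$color[G$adj[x, ]])
    if (!all(setdiff(cols, G$color[[x]]) %in% nb_cols)) return(FALSE)
  }
  TRUE
}

#' BMG recognition
#'
#' A properly colored digraph is a BMG iff its informative triples are
#' consistent and the BMG of their Aho tree reproduces the digraph
#' arc-for-arc.  On success the Aho tree is the unique least resolved tree
#' (LRT) explaining the graph.
#'
#' @param G a properly colored `colored_digraph`.
#' @return a list with elements `is_bmg` (logical), `tree` (the LRT, or
#'   `NULL`), and `reason` (`NA`, `"triples-inconsistent"` or
#'   `"aho-bmg-mismatch"`).
#' @export
recognize_bmg <- function(G) {
  assert_proper(G)
  R <- informative_triples(G)
  tr <- build_tree(R, G$vertices)
  if (is.null(tr))
    return(list(is_bmg = FALSE, tree = NULL, reason = "triples-inconsistent"))
  if (!digraphs_equal(bmg_of_tree(tr, G$color), G))
    return(list(is_bmg = FALSE, tree = NULL, reason = "aho-bmg-mismatch"))
  list(is_bmg = TRUE, tree = tr, reason = NA_character_)
}

#' Binary-explainable BMG recognition
#'
#' A properly colored digraph is explainable by a binary tree iff it is
#' sf-colored and the extended triple set [binary_triples()] is consistent.
#' On success the Aho tree of that set is returned; every binary refinement
#' of it explains the same graph.
#'
#' @param G a properly colored `colored_digraph`.
#' @return a list with `is_bebmg`, `tree`, `reason`.
#' @export
recognize_bebmg <- function(G) {
  assert_proper(G)
  if (!is_sf_colored(G))
    return(list(is_bebmg = FALSE, tree = NULL, reason = "not-sf-colored"))
  tr <- build_tree(binary_triples(G), G$vertices)
  if (is.null(tr))
    return(list(is_bebmg = FALSE, tree = NULL, reason = "triples-inconsistent"))
  list(is_bebmg = TRUE, tree = tr, reason = NA_character_)
}
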