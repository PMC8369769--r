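#' Rooted triple sets
#'
#' A rooted triple `xy|z` is a binary tree on three leaves whose cherry is the
#' unordered pair `{x, y}` with outgroup `z`.  Triple sets are stored as
#' data frames with columns `x`, `y`, `z`; the cherry is normalised so that
#' `x < y` lexicographically and duplicates are dropped.
#'
#' @param x,y,z character vectors of equal length (cherry leaves and outgroup).
#' @return a data frame of class `triple_set`.
#' @export
triple_set <- function(x = character(0), y = character(0), z = character(0)) {
  x <- as.character(x); y <- as.character(y); z <- as.character(z)
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (any(x == y | x == z | y == z)) stop("triple leaves must be distinct")
  lo <- pmin(x, y); hi <- pmax(x, y)
  df <- unique(data.frame(x = lo, y = hi, z = z, stringsAsFactors = FALSE))
  df <- df[order(df$x, df$y, df$z), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("triple_set", "data.frame")
  df
}

#' @export
print.triple_set <- function(x, ...) {
  cat("<triple_set> ", nrow(x), " triples\n", sep = "")
  if (nrow(x)) print(paste0(x$x, x$y, "|", x$z))
  invisible(x)
}

triple_leaves <- function(R) unique(c(R$x, R$y, R$z))

#' Set equality of triple sets
#' @param R1,R2 triple sets.
#' @return logical.
#' @export
triples_equal <- function(R1, R2) {
  k1 <- paste(R1$x, R1$y, R1$z)
  k2 <- paste(R2$x, R2$y, R2$z)
  setequal(k1, k2)
}

#' Restrict a triple set to a leaf subset
#' @param R a triple set.
#' @param L character vector of retained leaves.
#' @return the triples with all three leaves inside `L`.
#' @export
triples_restrict <- function(R, L) {
  keep <- R$x %in% L & R$y %in% L & R$z %in% L
  out <- R[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("triple_set", "data.frame")
  out
}

#' Aho graph of a triple set
#'
#' The undirected graph on `L` with an edge `xy` whenever some triple `xy|z`
#' is present.  Its connected components drive the BUILD recursion.
#'
#' @param R a triple set whose leaves all lie in `L`.
#' @param L character vector of leaves.
#' @return an undirected [igraph::igraph] with vertex names `L`.
#' @export
aho_graph <- function(R, L) {
  L <- as.character(L)
  if (!all(triple_leaves(R) %in% L)) stop("triple leaves outside L")
  g <- igraph::make_empty_graph(n = length(L), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = L)
  if (nrow(R)) {
    ek <- unique(paste(R$x, R$y, sep = "\r"))
    em <- do.call(rbind, strsplit(ek, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, t(em))
  }
  g
}

# connected components of an igraph as a list of vertex-name blocks,
# deterministically ordered by their smallest member
graph_components <- function(g) {
  comp <- igraph::components(g)$membership
  blocks <- split(names(comp), comp)
  names(blocks) <- NULL
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, `[`, character(1), 1L))]
}

#' BUILD (Aho) supertree algorithm
#'
#' Decides whether a set of rooted triples is consistent and, if so, returns
#' the Aho tree displaying every triple.  The recursion splits on the
#' connected components of the Aho graph of the triples restricted to the
#' current leaf set; a connected Aho graph on two or more leaves signals
#' inconsistency.  Components are processed in a deterministic order (sorted
#' by smallest member) so the returned tree is reproducible; child order is
#' semantically irrelevant.
#'
#' @param R a triple set.
#' @param L character vector of leaves (superset of the triple leaves).
#' @param coarsen logical; if `TRUE`, every recursion step with more than two
#'   components is coarse-grained to a bipartition (balanced by
#'   [number_partition()]), yielding a binary tree.
#' @return a `phylo_tree` on `L`, or `NULL` if `R` is inconsistent.
#' @export
build_tree <- function(R, L, coarsen = FALSE) {
  L <- sort(as.character(L))
  if (!all(triple_leaves(R) %in% L)) stop("triple leaves outside L")
  rec <- function(Lp) {
    if (length(Lp) == 1L) return(leaf_tree(Lp))
    Rsub <- triples_restrict(R, Lp)
    blocks <- graph_components(aho_graph(Rsub, Lp))
    if (length(blocks) == 1L) return(NULL)
    if (coarsen && length(blocks) > 2L) {
      grp <- number_partition(lengths(blocks))
      blocks <- list(sort(unlist(blocks[grp$group1])),
                     sort(unlist(blocks[grp$group2])))
    }
    subs <- vector("list", length(blocks))
    for (i in seq_along(blocks)) {
      st <- rec(blocks[[i]])
      if (is.null(st)) return(NULL)
      subs[[i]] <- st
    }
    join_trees(subs)
  }
  rec(L)
}

#' Triples of a set displayed by a tree
#'
#' Filters a triple set down to the (always consistent) subset displayed by
#' `tree`.
#'
#' @param tree a `phylo_tree` containing all triple leaves.
#' @param R a triple set.
#' @return a triple set.
#' @export
displayed_subset <- function(tree, R) {
  if (nrow(R) == 0L) return(R)
  disp <- tree_triples(tree)
  keep <- paste(R$x, R$y, R$z) %in% paste(disp$x, disp$y, disp$z)
  out <- R[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("triple_set", "data.frame")
  out
}
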