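#' Vertex-colored digraphs
#'
#' The object being edited: a simple digraph (no self-loops) whose vertices
#' carry colors (species).  Internally the arc set is a logical adjacency
#' matrix with vertex ids as dimnames; `adj[x, y]` is `TRUE` iff the arc
#' `(x, y)` is present.
#'
#' @param vertices character vector of vertex ids.
#' @param colors character vector of colors, either named by vertex or in the
#'   order of `vertices`.
#' @param arcs two-column character matrix or data frame of arcs `(from, to)`;
#'   may have zero rows.
#' @return an object of class `colored_digraph`.
#' @export
colored_digraph <- function(vertices, colors, arcs = NULL) {
  vertices <- as.character(vertices)
  stopifnot(!anyDuplicated(vertices))
  if (!is.null(names(colors))) colors <- colors[vertices]
  colors <- as.character(colors)
  if (length(colors) != length(vertices) || anyNA(colors))
    stop("every vertex needs a color")
  names(colors) <- vertices
  n <- length(vertices)
  adj <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  if (!is.null(arcs) && NROW(arcs) > 0L) {
    arcs <- as.matrix(arcs)
    if (!all(arcs %in% vertices)) stop("arc endpoint not in vertex set")
    if (any(arcs[, 1L] == arcs[, 2L])) stop("self-loops are not allowed")
    adj[arcs[, 1:2, drop = FALSE]] <- TRUE
  }
  structure(list(vertices = vertices, color = colors, adj = adj),
            class = "colored_digraph")
}

#' @export
print.colored_digraph <- function(x, ...) {
  cat("<colored_digraph> ", length(x$vertices), " vertices (",
      length(unique(x$color)), " colors), ", sum(x$adj), " arcs\n", sep = "")
  invisible(x)
}

#' Arc list of a digraph
#' @param G a `colored_digraph`.
#' @return two-column character matrix (`from`, `to`), sorted.
#' @export
arcs <- function(G) {
  w <- which(G$adj, arr.ind = TRUE)
  m <- cbind(from = G$vertices[w[, 1L]], to = G$vertices[w[, 2L]])
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Number of arcs
#' @param G a `colored_digraph`.
#' @return integer.
#' @export
n_arcs <- function(G) sum(G$adj)

#' Is the coloring proper?
#'
#' Proper means no arc joins two vertices of the same color.
#' @param G a `colored_digraph`.
#' @return logical.
#' @export
is_properly_colored <- function(G) {
  same <- outer(G$color, G$color, `==`)
  !any(G$adj & same)
}

assert_proper <- function(G) {
  if (!is_properly_colored(G))
    stop("digraph is not properly colored (arc between same-colored vertices)")
  invisible(G)
}

#' Induced subgraph
#' @param G a `colored_digraph`.
#' @param W subset of vertex ids.
#' @return the `colored_digraph` induced on `W`.
#' @export
induced_subdigraph <- function(G, W) {
  W <- as.character(W)
  if (!all(W %in% G$vertices)) stop("unknown vertex id(s)")
  out <- list(vertices = G$vertices[G$vertices %in% W],
              color = G$color[G$vertices %in% W],
              adj = G$adj[G$vertices %in% W, G$vertices %in% W, drop = FALSE])
  class(out) <- "colored_digraph"
  out
}

#' Digraph equality
#'
#' Identical vertex sets, colorings and arc sets; no isomorphism involved.
#' @param G1,G2 `colored_digraph` objects.
#' @return logical.
#' @export
digraphs_equal <- function(G1, G2) {
  if (!setequal(G1$vertices, G2$vertices)) return(FALSE)
  v <- sort(G1$vertices)
  identical(unname(G1$color[v]), unname(G2$color[v])) &&
    identical(unname(G1$adj[v, v]), unname(G2$adj[v, v]))
}

#' Apply an arc symmetric difference
#'
#' Flips the status of every listed ordered pair: present arcs are deleted,
#' absent ones inserted.
#'
#' @param G a `colored_digraph`.
#' @param pairs two-column character matrix of ordered pairs.
#' @return the modified `colored_digraph`.
#' @export
arc_symdiff_apply <- function(G, pairs) {
  if (NROW(pairs) == 0L) return(G)
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  G$adj[pairs] <- !G$adj[pairs]
  G
}

# helper: cross-color mask (x != y and sigma(x) != sigma(y))
cross_color_mask <- function(G) {
  m <- outer(G$color, G$color, `!=`)
  diag(m) <- FALSE
  m
}
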