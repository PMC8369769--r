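#' File formats
#'
#' Colored digraphs travel as a TSV pair (vertices: `id <TAB> color`; arcs:
#' `from <TAB> to`) or as GraphML with a `color` vertex attribute.  Trees use
#' standard rooted Newick with labels on the leaves only; colors are kept in
#' a side table, never encoded in Newick.  Triple sets are three-column TSVs
#' (`x y z` meaning `xy|z`).
#'
#' @name bmgedit-io
NULL

#' @rdname bmgedit-io
#' @param G a `colored_digraph`.
#' @param vertices_file,arcs_file TSV paths.
#' @export
write_digraph_tsv <- function(G, vertices_file, arcs_file) {
  utils::write.table(
    data.frame(id = G$vertices, color = unname(G$color)),
    vertices_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(arcs(G)), arcs_file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(G)
}

#' @rdname bmgedit-io
#' @return `read_digraph_tsv()` returns a `colored_digraph`.
#' @export
read_digraph_tsv <- function(vertices_file, arcs_file) {
  vt <- utils::read.table(vertices_file, sep = "\t", header = TRUE,
                          colClasses = "character")
  ar <- utils::read.table(arcs_file, sep = "\t", header = TRUE,
                          colClasses = "character")
  colored_digraph(vt$id, stats::setNames(vt$color, vt$id), as.matrix(ar))
}

#' @rdname bmgedit-io
#' @param file GraphML path.
#' @export
write_digraph_graphml <- function(G, file) {
  ig <- igraph::graph_from_data_frame(
    as.data.frame(arcs(G)), directed = TRUE,
    vertices = data.frame(name = G$vertices, color = unname(G$color)))
  igraph::write_graph(ig, file, format = "graphml")
  invisible(G)
}

#' @rdname bmgedit-io
#' @return `read_digraph_graphml()` returns a `colored_digraph`.
#' @export
read_digraph_graphml <- function(file) {
  ig <- igraph::read_graph(file, format = "graphml")
  v <- igraph::V(ig)$name
  cols <- stats::setNames(igraph::V(ig)$color, v)
  el <- igraph::as_edgelist(ig)
  colored_digraph(v, cols, el)
}

#' @rdname bmgedit-io
#' @param tree a `phylo_tree`.
#' @return `write_newick()` returns the Newick string invisibly-printable.
#' @export
write_newick <- function(tree) {
  rec <- function(v) {
    if (length(tree$children[[v]]) == 0L) return(tree$label[v])
    paste0("(", paste(vapply(tree$children[[v]], rec, character(1)),
                      collapse = ","), ")")
  }
  paste0(rec(tree$root), ";")
}

#' @rdname bmgedit-io
#' @param x Newick string or path; `text` strings must end in `;`.
#' @return `read_newick()` returns a `phylo_tree` (inner labels and branch
#'   lengths are ignored).
#' @export
read_newick <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x), collapse = "") else x
  # single-leaf trees are not representable in ape's phylo class
  bare <- sub(";\\s*$", "", trimws(txt))
  if (!grepl("[(),]", bare)) return(leaf_tree(bare))
  ph <- ape::read.tree(text = txt)
  if (is.null(ph)) stop("could not parse Newick input")
  phylo_to_tree(ph)
}

# ape::phylo -> phylo_tree
phylo_to_tree <- function(ph) {
  ntip <- length(ph$tip.label)
  nnode <- ph$Nnode
  total <- ntip + nnode
  parent <- integer(total)
  for (e in seq_len(nrow(ph$edge))) parent[ph$edge[e, 2L]] <- ph$edge[e, 1L]
  label <- c(ph$tip.label, rep(NA_character_, nnode))
  new_phylo_tree(parent, label)
}

# phylo_tree -> ape::phylo (>= 2 leaves)
tree_to_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' @rdname bmgedit-io
#' @param R a triple set.
#' @export
write_triples_tsv <- function(R, file) {
  utils::write.table(as.data.frame(unclass(R))[c("x", "y", "z")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(R)
}

#' @rdname bmgedit-io
#' @return `read_triples_tsv()` returns a triple set.
#' @export
read_triples_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          colClasses = "character")
  triple_set(df[[1L]], df[[2L]], df[[3L]])
}
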