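# Shared fixture graphs, built in code.

# tree with root children spanning {a,b1} and {b2,b3,c1,c2}; colors a red,
# b1..b3 blue, c1 c2 green.  Its BMG has exactly six informative triples and
# a two-component Aho graph.
two_cherry_example <- function() {
  tree <- join_trees(list(
    join_trees(list(leaf_tree("a"), leaf_tree("b1"))),
    join_trees(list(leaf_tree("b2"), leaf_tree("b3"),
                    leaf_tree("c1"), leaf_tree("c2")))))
  sigma <- c(a = "red", b1 = "blue", b2 = "blue", b3 = "blue",
             c1 = "green", c2 = "green")
  list(tree = tree, sigma = sigma, bmg = bmg_of_tree(tree, sigma))
}

# three-vertex two-colored digraph that is not a BMG, has no informative
# triples, and admits a one-arc optimal edit
three_vertex_example <- function() {
  colored_digraph(c("a", "ap", "b"),
                  c(a = "red", ap = "red", b = "blue"),
                  rbind(c("a", "b"), c("ap", "b")))
}
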