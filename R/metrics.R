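#' Arc-set symmetric difference
#'
#' Number of ordered pairs that are an arc in exactly one of the two
#' digraphs — the edit distance between arc sets.
#'
#' @param G1,G2 `colored_digraph` objects over the same vertex set and
#'   coloring.
#' @return non-negative integer.
#' @export
arc_symmetric_difference <- function(G1, G2) {
  check_same_universe(G1, G2)
  nrow(arc_diff_pairs(G1, G2))
}

check_same_universe <- function(G1, G2) {
  if (!setequal(G1$vertices, G2$vertices))
    stop("digraphs must share the vertex set")
  v <- sort(G1$vertices)
  if (!identical(unname(G1$color[v]), unname(G2$color[v])))
    stop("digraphs must share the coloring")
  invisible(TRUE)
}

#' Arc confusion measures
#'
#' Treats the arcs of `truth` as positives over the universe of ordered
#' cross-color pairs (same-colored pairs can never be best matches and are
#' excluded from the universe).
#'
#' @param truth,estimate `colored_digraph` objects over the same vertex set
#'   and coloring.
#' @return list with `tp`, `fp`, `fn`, `tn`, `recall`, `precision`,
#'   `specificity`, `accuracy` and the symmetric difference `d`.
#' @export
arc_confusion <- function(truth, estimate) {
  check_same_universe(truth, estimate)
  v <- sort(truth$vertices)
  uni <- cross_color_mask(truth)[v, v]
  tadj <- truth$adj[v, v]
  eadj <- estimate$adj[v, v]
  tp <- sum(uni & tadj & eadj)
  fp <- sum(uni & !tadj & eadj)
  fn <- sum(uni & tadj & !eadj)
  tn <- sum(uni & !tadj & !eadj)
  total <- sum(uni)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = if (total > 0) (tp + tn) / total else NA_real_,
       d = fp + fn)
}

#' Benchmark harness
#'
#' Runs a set of editing methods over a generated instance ensemble and
#' returns a tidy results table: per instance, method and output variant
#' (`direct` for the tree built by the method, `rebuilt` for the Aho tree of
#' its displayed triples), the arc distances to the perturbed input (`d`) and
#' to the original unperturbed BMG (`d_orig`), confusion measures against the
#' original, the summed per-step UR-cost decomposition, the fraction of
#' recursion steps producing a single-leaf split, and wall time.
#'
#' @param instances output of [make_benchmark_set()].
#' @param methods character vector of method specs understood by [edit()].
#' @param binary logical; run the binary-explainable variants.
#' @param runs heuristic runs per recursion step.
#' @param seed optional integer seed.
#' @return a data frame; the retention rate of `instances` is carried as
#'   attribute `retention`.
#' @export
run_benchmark <- function(instances, methods = c("topdown-louvain-c", "bpmf"),
                          binary = FALSE, runs = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    for (m in methods) {
      res <- edit(inst$perturbed, method = m, rebuild = TRUE,
                  binary = binary, runs = runs)
      sls <- if (is.null(res$ledger)) NA_real_ else
        mean(res$ledger$min_block == 1L)
      for (variant in c("direct", "rebuilt")) {
        Gout <- if (variant == "direct") res$graph else res$graph_star
        conf <- arc_confusion(inst$bmg, Gout)
        rows[[length(rows) + 1L]] <- data.frame(
          instance = i, method = m, variant = variant,
          d = arc_symmetric_difference(inst$perturbed, Gout),
          d_orig = arc_symmetric_difference(inst$bmg, Gout),
          recall = conf$recall, precision = conf$precision,
          specificity = conf$specificity, accuracy = conf$accuracy,
          u1 = if (is.null(res$ledger)) NA_integer_ else sum(res$ledger$u1),
          u2 = if (is.null(res$ledger)) NA_integer_ else sum(res$ledger$u2),
          u3 = if (is.null(res$ledger)) NA_integer_ else sum(res$ledger$u3),
          cost = res$cost,
          single_leaf_split_frac = sls,
          seconds = res$seconds,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "retention") <- attr(instances, "retention")
  out
}
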