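# Distance-based descriptors and knockdown simulations.
#
# The knockdown metric is the characteristic path length -- the average of
# the finite shortest-path lengths over node pairs -- which is what the
# simulation results call the network "diameter". The classical diameter
# (maximum eccentricity) is provided separately.

to_distance_graph <- function(g, direction_mode = c("directed", "as_undirected")) {
  direction_mode <- match.arg(direction_mode)
  ig <- as_igraph(g)
  if (direction_mode == "as_undirected") ig <- igraph::as_undirected(ig, mode = "collapse")
  else if (inherits(g, "mixed_graph")) {
    # a mixed graph has genuinely undirected edges: make them two-way arcs
    e <- igraph::as_edgelist(ig, names = TRUE)
    und <- !igraph::E(ig)$directed
    if (any(und)) ig <- igraph::add_edges(ig, t(e[und, 2:1, drop = FALSE]))
  }
  ig
}

#' Characteristic path length (average shortest-path length)
#'
#' Average of the finite shortest-path lengths over all ordered node pairs
#' (directed mode) or unordered pairs (`as_undirected`); unreachable pairs
#' are excluded from both numerator and denominator.
#'
#' @param g A `directed_network`, `mixed_graph` or igraph.
#' @param direction_mode `"directed"` or `"as_undirected"`.
#' @return Mean geodesic length (>= 1 for any graph with an edge).
#' @examples
#' mean_geodesic(make_path_net(3), "as_undirected")  # 4/3
#' @export
mean_geodesic <- function(g, direction_mode = c("directed", "as_undirected")) {
  direction_mode <- match.arg(direction_mode)
  ig <- to_distance_graph(g, direction_mode)
  if (igraph::vcount(ig) < 2L) stop("mean_geodesic needs at least 2 nodes")
  dm <- igraph::distances(ig, mode = if (direction_mode == "directed") "out" else "all")
  vals <- dm[row(dm) != col(dm)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("no finite-distance node pair")
  mean(vals)  # for undirected graphs the symmetric mean equals the pair mean
}

distance_matrix <- function(g, direction_mode) {
  ig <- to_distance_graph(g, direction_mode)
  igraph::distances(ig, mode = if (direction_mode == "directed") "out" else "all")
}

#' Eccentricity, standard diameter and median eccentricity
#'
#' `eccentricity_net(g, v)` is the maximum finite distance from `v`;
#' isolated vertices (no finite distance to any other node) get `NA`. The
#' standard diameter is the maximum node eccentricity; the median
#' eccentricity over a node set summarises how easily a group of nodes is
#' reached (reported per controllability class in the field).
#'
#' @param g A graph.
#' @param v Node identifier.
#' @param node_set Character vector of nodes.
#' @param direction_mode `"directed"` or `"as_undirected"`.
#' @return A length (or `NA` for isolated vertices).
#' @export
standard_diameter <- function(g, direction_mode = c("directed", "as_undirected")) {
  direction_mode <- match.arg(direction_mode)
  dm <- distance_matrix(g, direction_mode)
  ecc <- apply(dm, 1L, function(r) {
    r <- r[is.finite(r) & r > 0]
    if (length(r)) max(r) else NA_real_
  })
  if (all(is.na(ecc))) stop("no finite-distance node pair")
  max(ecc, na.rm = TRUE)
}

#' @rdname standard_diameter
#' @export
eccentricity_net <- function(g, v, direction_mode = c("directed", "as_undirected")) {
  direction_mode <- match.arg(direction_mode)
  dm <- distance_matrix(g, direction_mode)
  if (!v %in% rownames(dm)) stop("unknown node: ", v)
  r <- dm[v, colnames(dm) != v]
  r <- r[is.finite(r)]
  if (length(r) == 0L) return(NA_real_)
  max(r)
}

#' @rdname standard_diameter
#' @export
median_eccentricity <- function(g, node_set, direction_mode = c("directed", "as_undirected")) {
  direction_mode <- match.arg(direction_mode)
  e <- vapply(node_set, function(v) eccentricity_net(g, v, direction_mode), numeric(1))
  stats::median(e, na.rm = TRUE)
}

#' First-neighbour subnetwork of a node
#'
#' The node, its first neighbours (in either direction), and all edges
#' incident to the node -- the subnetwork removed when a protein is fully
#' knocked down.
#'
#' @param g A `directed_network` or `mixed_graph`.
#' @param v Node identifier.
#' @return List with `nodes` (character) and `edges` (2-column matrix of
#'   the edges incident to `v`).
#' @export
paralog_subnetwork <- function(g, v) {
  if (!v %in% g$nodes) stop("unknown node: ", v)
  em <- all_edges(g)
  inc <- em[, 1L] == v | em[, 2L] == v
  edges <- em[inc, , drop = FALSE]
  list(nodes = unique(c(v, edges)), edges = edges)
}

#' Delete nodes or edges from a graph
#'
#' Vertex deletion removes incident edges; edge deletion preserves the
#' endpoints as (possibly isolated) nodes. Unknown targets are skipped
#' with a warning.
#'
#' @param g A `directed_network` or `mixed_graph`.
#' @param nodes Character vector of nodes to delete.
#' @param edges 2-column matrix of edges to delete (for mixed graphs an
#'   undirected edge matches in either order).
#' @return A graph of the same class as `g`.
#' @export
net_delete <- function(g, nodes = NULL, edges = NULL) {
  if (!is.null(nodes)) {
    unknown <- setdiff(nodes, g$nodes)
    if (length(unknown))
      warning("skipping unknown node(s): ", paste(unknown, collapse = ", "))
    g <- induced_subgraph_net(g, setdiff(g$nodes, nodes))
  }
  if (!is.null(edges)) {
    edges <- edge_matrix(edges)
    kill_dir <- pair_key(edges)
    kill_und <- pair_key(sort_pairs(edges))
    if (inherits(g, "directed_network")) {
      hit <- pair_key(g$edges) %in% kill_dir
      if (sum(hit) < nrow(edges))
        warning("some edges to delete were not present")
      g <- directed_network(nodes = g$nodes, edges = g$edges[!hit, , drop = FALSE])
    } else {
      hd <- pair_key(g$directed) %in% kill_dir
      hu <- pair_key(g$undirected) %in% kill_und
      if (sum(hd) + sum(hu) < nrow(edges))
        warning("some edges to delete were not present")
      g <- mixed_graph(nodes = g$nodes,
                       directed = g$directed[!hd, , drop = FALSE],
                       undirected = g$undirected[!hu, , drop = FALSE])
    }
  }
  g
}

#' Progressive random knockdown of a node's subnetwork
#'
#' Simulates a partial knockdown of `target`: at each removal fraction
#' `f` in `{0, step, ..., 1}` and each replicate, a fresh uniform random
#' subset of size `floor(f * pool)` is removed from the removal pool and
#' the characteristic path length of the remaining network is recorded.
#' The pool is either the edges incident to the target (`mode = "edges"`,
#' a knockdown removes the protein's interactions) or its first-neighbour
#' nodes (`mode = "neighbor_nodes"`). Sampling at each fraction is
#' independent by default; `nested = TRUE` grows one nested removal order
#' per replicate instead.
#'
#' @param g A `directed_network` or `mixed_graph`.
#' @param target Node whose subnetwork is knocked down.
#' @param mode `"edges"` or `"neighbor_nodes"`.
#' @param step Fraction increment in (0, 1], default 0.01.
#' @param reps Number of replicates (default 3).
#' @param seed Integer RNG seed.
#' @param direction_mode Distance mode passed to [mean_geodesic()].
#' @param nested Use nested (monotone) removal instead of independent
#'   sampling per fraction.
#' @return A `knockdown_curve`: data frame with columns `fraction`,
#'   `rep1..repK`, `mean_diameter`, plus attributes `target`, `mode`,
#'   `reps`, `seed`.
#' @export
progressive_knockdown <- function(g, target, mode = c("edges", "neighbor_nodes"),
                                  step = 0.01, reps = 3L, seed = 1L,
                                  direction_mode = "directed", nested = FALSE) {
  mode <- match.arg(mode)
  if (step <= 0 || step > 1) stop("step must be in (0, 1]")
  sub <- paralog_subnetwork(g, target)
  pool_n <- if (mode == "edges") nrow(sub$edges) else length(setdiff(sub$nodes, target))
  if (pool_n == 0L) stop("target '", target, "' has an empty removal pool")
  fr <- unique(c(seq(0, 1, by = step), 1))
  res <- matrix(NA_real_, length(fr), reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    order_r <- sample.int(pool_n)  # used in nested mode
    for (i in seq_along(fr)) {
      k <- floor(fr[i] * pool_n)
      pick <- if (nested) order_r[seq_len(k)] else sample(pool_n, k)
      h <- if (mode == "edges") {
        net_delete(g, edges = sub$edges[pick, , drop = FALSE])
      } else {
        net_delete(g, nodes = setdiff(sub$nodes, target)[pick])
      }
      res[i, r] <- mean_geodesic(h, direction_mode)
    }
  }
  out <- data.frame(fraction = fr, res, mean_diameter = rowMeans(res))
  names(out)[2:(reps + 1L)] <- paste0("rep", seq_len(reps))
  structure(out, target = target, mode = mode, reps = reps, seed = seed,
            class = c("knockdown_curve", "data.frame"))
}

#' Write / read a knockdown curve as TSV
#'
#' Metadata (target, mode, reps, seed) travels in `#` header lines so that
#' write followed by read round-trips the object.
#'
#' @param curve A `knockdown_curve`.
#' @param path File path.
#' @return `read_knockdown_curve()` returns the `knockdown_curve`;
#'   `write_knockdown_curve()` returns `path` invisibly.
#' @export
write_knockdown_curve <- function(curve, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# target: %s", attr(curve, "target")), con)
  writeLines(sprintf("# mode: %s", attr(curve, "mode")), con)
  writeLines(sprintf("# reps: %d", attr(curve, "reps")), con)
  writeLines(sprintf("# seed: %d", attr(curve, "seed")), con)
  utils::write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_knockdown_curve
#' @export
read_knockdown_curve <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- function(key) sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(df, target = meta("target"), mode = meta("mode"),
            reps = as.integer(meta("reps")), seed = as.integer(meta("seed")),
            class = c("knockdown_curve", "data.frame"))
}
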