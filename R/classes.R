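# Graph containers: a mixed graph (disjoint directed and undirected edge
# sets, pre-orientation) and a simple directed network (post-orientation).
# Edges are stored as 2-column character matrices; node identifiers are
# opaque, case-sensitive strings.

edge_matrix <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) ||
      (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(matrix(character(), ncol = 2L))
  }
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (!is.matrix(x)) x <- matrix(as.character(x), ncol = 2L, byrow = TRUE)
  storage.mode(x) <- "character"
  dimnames(x) <- NULL
  x[, 1:2, drop = FALSE]
}

# within-row canonicalization only: row order is preserved
canon_pairs <- function(m) {
  if (nrow(m) == 0L) return(m)
  swap <- m[, 1L] > m[, 2L]
  tmp <- m[swap, 1L]
  m[swap, 1L] <- m[swap, 2L]
  m[swap, 2L] <- tmp
  m
}

# canonical form of an unordered pair set: each row sorted, rows sorted
sort_pairs <- function(m) {
  if (nrow(m) == 0L) return(m)
  swap <- m[, 1L] > m[, 2L]
  tmp <- m[swap, 1L]
  m[swap, 1L] <- m[swap, 2L]
  m[swap, 2L] <- tmp
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

pair_key <- function(m) if (nrow(m) == 0L) character() else paste(m[, 1L], m[, 2L], sep = "\r")

#' Mixed graph: directed plus undirected edges
#'
#' Container for an interaction network before orientation: a node set, a
#' set of directed edges and a set of undirected edges. The constructor
#' validates the structural invariants (no self loops, simple edge sets, no
#' node pair present both directed and undirected, no antiparallel directed
#' pair); it does not repair violations -- use [assemble()] to normalise raw
#' interaction records into a valid mixed graph.
#'
#' @param nodes Character vector of node identifiers (isolated nodes
#'   allowed). Endpoints of edges are added automatically.
#' @param directed Two-column character matrix (or data frame) of ordered
#'   edges, tail then head.
#' @param undirected Two-column matrix of unordered edges.
#' @return An object of class `mixed_graph` with elements `nodes`,
#'   `directed`, `undirected`.
#' @examples
#' g <- mixed_graph(directed = rbind(c("K1", "S1")),
#'                  undirected = rbind(c("S1", "S2")))
#' g
#' @export
mixed_graph <- function(nodes = character(), directed = NULL, undirected = NULL) {
  directed <- edge_matrix(directed)
  undirected <- sort_pairs(edge_matrix(undirected))
  nodes <- sort(unique(c(as.character(nodes), directed, undirected)))
  if (any(nodes == "") || anyNA(nodes)) stop("node identifiers must be non-empty strings")
  if (nrow(directed) && any(directed[, 1L] == directed[, 2L]))
    stop("mixed_graph: self loops are not allowed")
  if (nrow(undirected) && any(undirected[, 1L] == undirected[, 2L]))
    stop("mixed_graph: self loops are not allowed")
  if (anyDuplicated(pair_key(directed))) stop("mixed_graph: duplicate directed edges")
  if (anyDuplicated(pair_key(undirected))) stop("mixed_graph: duplicate undirected edges")
  dk <- pair_key(directed)
  if (any(dk %in% pair_key(directed[, 2:1, drop = FALSE])))
    stop("mixed_graph: antiparallel directed pair; merge to an undirected edge first")
  if (any(pair_key(sort_pairs(directed)) %in% pair_key(undirected)))
    stop("mixed_graph: a node pair appears both directed and undirected")
  directed <- directed[order(directed[, 1L], directed[, 2L]), , drop = FALSE]
  structure(list(nodes = nodes, directed = directed, undirected = undirected),
            class = "mixed_graph")
}

#' Simple directed network
#'
#' A fully oriented interaction network: node set plus a set of ordered
#' edges with no self loops and no duplicate ordered pairs (antiparallel
#' pairs u->v, v->u are permitted; they arise from edges directed in both
#' directions by independent evidence).
#'
#' @param nodes Character vector of node identifiers.
#' @param edges Two-column character matrix of ordered edges.
#' @return Object of class `directed_network` with elements `nodes`, `edges`.
#' @examples
#' directed_network(edges = rbind(c("A", "B"), c("B", "C")))
#' @export
directed_network <- function(nodes = character(), edges = NULL) {
  edges <- edge_matrix(edges)
  nodes <- sort(unique(c(as.character(nodes), edges)))
  if (any(nodes == "") || anyNA(nodes)) stop("node identifiers must be non-empty strings")
  if (nrow(edges) && any(edges[, 1L] == edges[, 2L]))
    stop("directed_network: self loops are not allowed")
  if (anyDuplicated(pair_key(edges))) stop("directed_network: duplicate edges")
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "directed_network")
}

#' @export
print.mixed_graph <- function(x, ...) {
  cat(sprintf("mixed_graph: %d nodes, %d directed + %d undirected edges\n",
              length(x$nodes), nrow(x$directed), nrow(x$undirected)))
  invisible(x)
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(g) length(g$nodes)

all_edges <- function(g) {
  if (inherits(g, "directed_network")) g$edges else rbind(g$directed, g$undirected)
}

#' Convert package graphs to igraph
#'
#' Mixed graphs become directed igraph objects with a logical edge attribute
#' `directed` (FALSE rows stand for one undirected edge); directed networks
#' become plain directed igraphs.
#'
#' @param g A `mixed_graph` or `directed_network`.
#' @return An [igraph::igraph] object including isolated nodes.
#' @export
as_igraph <- function(g) UseMethod("as_igraph")

#' @export
as_igraph.directed_network <- function(g) {
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = g$nodes)
}

#' @export
as_igraph.mixed_graph <- function(g) {
  e <- rbind(g$directed, g$undirected)
  ig <- igraph::graph_from_data_frame(
    as.data.frame(e, stringsAsFactors = FALSE),
    directed = TRUE, vertices = g$nodes)
  igraph::E(ig)$directed <- rep(c(TRUE, FALSE), c(nrow(g$directed), nrow(g$undirected)))
  ig
}

#' @export
as_igraph.igraph <- function(g) g

# undirected view (support graph) of either container
support_igraph <- function(g) {
  igraph::as_undirected(as_igraph(g), mode = "collapse")
}

#' Per-node degrees of a directed network
#'
#' @param d A `directed_network`.
#' @return Data frame with columns `node`, `k_in`, `k_out`, `k` (total
#'   degree, `k = k_in + k_out`), one row per node in node order.
#' @examples
#' node_degrees(make_star_net(3))
#' @export
node_degrees <- function(d) {
  stopifnot(inherits(d, "directed_network"))
  k_out <- table(factor(d$edges[, 1L], levels = d$nodes))
  k_in <- table(factor(d$edges[, 2L], levels = d$nodes))
  data.frame(node = d$nodes, k_in = as.integer(k_in), k_out = as.integer(k_out),
             k = as.integer(k_in) + as.integer(k_out),
             row.names = NULL, stringsAsFactors = FALSE)
}

graphs_equal <- function(a, b) {
  if (!identical(class(a), class(b))) return(FALSE)
  if (!identical(a$nodes, b$nodes)) return(FALSE)
  if (inherits(a, "directed_network")) return(identical(a$edges, b$edges))
  identical(a$directed, b$directed) && identical(a$undirected, b$undirected)
}
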