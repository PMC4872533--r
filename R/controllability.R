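# Structural controllability via maximum matching.
#
# For a directed network with N nodes, the minimum number of driver nodes
# (nodes that must receive independent external signals for the whole
# network state to be steerable anywhere) is N - |M*|, where M* is a
# maximum matching of the bipartite lift that has an out-copy and an
# in-copy of every node and one left-to-right edge per network edge; a
# perfectly matched network still needs one driver, so N_D = max(N-|M*|, 1).
# A node is critical / redundant / ordinary when its removal increases /
# decreases / leaves unchanged N_D.

#' Minimum driver-node count and driver set
#'
#' Computes a maximum matching of the bipartite lift of the network (a
#' matching in the directed sense: a set of edges sharing no head and no
#' tail) and derives `n_d = max(N - |matching|, 1)`. The driver nodes are
#' the nodes unmatched as edge heads; when the matching is perfect the
#' first node (in sorted order) is designated as the single driver.
#'
#' @param d A `directed_network` with at least one node.
#' @return A `driver_analysis`: list with `n_d`, `matching` (2-column edge
#'   matrix), `drivers` (character vector, length `n_d`), `n`.
#' @examples
#' min_driver_count(make_path_net(3))$n_d   # 1
#' min_driver_count(make_star_net(3))$n_d   # 3
#' @export
min_driver_count <- function(d) {
  stopifnot(inherits(d, "directed_network"))
  n <- length(d$nodes)
  if (n == 0L) stop("empty graph: no nodes")
  m <- nrow(d$edges)
  if (m == 0L) {
    return(structure(list(n_d = max(n, 1L), matching = d$edges,
                          drivers = d$nodes, n = n), class = "driver_analysis"))
  }
  idx <- stats::setNames(seq_len(n), d$nodes)
  bg <- igraph::make_bipartite_graph(
    rep(c(FALSE, TRUE), each = n),
    rbind(idx[d$edges[, 1L]], n + idx[d$edges[, 2L]]))
  mm <- igraph::max_bipartite_match(bg)
  msize <- mm$matching_size
  # matching vector: position n+j (in-copy of node j) holds its out-partner
  inmatch <- mm$matching[(n + 1L):(2L * n)]
  matched_head <- !is.na(inmatch)
  matching <- cbind(d$nodes[inmatch[matched_head]], d$nodes[matched_head])
  matching <- matching[order(matching[, 1L], matching[, 2L]), , drop = FALSE]
  n_d <- max(n - msize, 1L)
  drivers <- d$nodes[!matched_head]
  if (length(drivers) == 0L) drivers <- d$nodes[1L]
  structure(list(n_d = as.integer(n_d), matching = matching,
                 drivers = drivers, n = n), class = "driver_analysis")
}

#' @export
print.driver_analysis <- function(x, ...) {
  cat(sprintf("driver_analysis: N = %d, |matching| = %d, N_D = %d\n",
              x$n, nrow(x$matching), x$n_d))
  invisible(x)
}

delete_node_edges <- function(d, v) {
  keep <- d$edges[d$edges[, 1L] != v & d$edges[, 2L] != v, , drop = FALSE]
  directed_network(nodes = setdiff(d$nodes, v), edges = keep)
}

#' Classify nodes as critical, redundant or ordinary
#'
#' Recomputes the minimum driver count `N'_D` on the network with each node
#' (and its incident edges) removed. The node is `critical` if
#' `N'_D > N_D`, `redundant` if `N'_D < N_D` and `ordinary` otherwise. The
#' result is independent of node order.
#'
#' @param d A `directed_network` with at least 2 nodes.
#' @return A `control_classification`: list with `baseline`
#'   (a `driver_analysis`) and `labels` (named character vector).
#' @examples
#' classify_nodes(make_path_net(3))$labels[["B"]]  # "critical"
#' @export
classify_nodes <- function(d) {
  stopifnot(inherits(d, "directed_network"))
  if (length(d$nodes) < 2L) stop("classification needs at least 2 nodes")
  base <- min_driver_count(d)
  labels <- vapply(d$nodes, function(v) {
    nd2 <- min_driver_count(delete_node_edges(d, v))$n_d
    if (nd2 > base$n_d) "critical" else if (nd2 < base$n_d) "redundant" else "ordinary"
  }, character(1))
  structure(list(baseline = base, labels = labels),
            class = "control_classification")
}

#' @export
print.control_classification <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("critical", "redundant", "ordinary")))
  cat(sprintf("control_classification: N = %d, N_D = %d | critical %d (%.0f%%), redundant %d (%.0f%%), ordinary %d (%.0f%%)\n",
              x$baseline$n, x$baseline$n_d,
              tab[1], 100 * tab[1] / x$baseline$n,
              tab[2], 100 * tab[2] / x$baseline$n,
              tab[3], 100 * tab[3] / x$baseline$n))
  invisible(x)
}

critical_nodes <- function(cc) names(cc$labels)[cc$labels == "critical"]

#' Build a weighted linear system from a directed network
#'
#' Produces the state-space pair (A, B) used by the Kalman rank check:
#' `A[i, j]` is a random nonzero weight when the network has an edge
#' `j -> i`, and `B` has one column per input. By default inputs are the
#' driver nodes of [min_driver_count()]; any matching cycle unreachable
#' from the drivers is additionally wired to the first input (no extra
#' signal is needed for such cycles, only an extra connection), so the
#' system is generically controllable with exactly `n_d` inputs. Weights
#' are independent uniform(0.2, 1) draws under the given seed.
#'
#' @param d A `directed_network`.
#' @param inputs Character vector of input nodes; default the driver set.
#' @param seed Integer RNG seed for the weights.
#' @param wire_cycles Attach unreachable matched cycles to input 1
#'   (default TRUE when `inputs` is NULL, FALSE for a user-chosen set).
#' @return A `linear_system`: list with `a` (N x N), `b` (N x M), `m`.
#' @export
control_system <- function(d, inputs = NULL, seed = 1L, wire_cycles = NULL) {
  stopifnot(inherits(d, "directed_network"))
  if (is.null(wire_cycles)) wire_cycles <- is.null(inputs)
  set.seed(seed)
  n <- length(d$nodes)
  idx <- stats::setNames(seq_len(n), d$nodes)
  a <- matrix(0, n, n, dimnames = list(d$nodes, d$nodes))
  if (nrow(d$edges))
    a[cbind(idx[d$edges[, 2L]], idx[d$edges[, 1L]])] <-
      stats::runif(nrow(d$edges), 0.2, 1)
  if (is.null(inputs)) inputs <- min_driver_count(d)$drivers
  if (!all(inputs %in% d$nodes)) stop("unknown input node(s)")
  m <- length(inputs)
  b <- matrix(0, n, m, dimnames = list(d$nodes, inputs))
  b[cbind(idx[inputs], seq_len(m))] <- stats::runif(m, 0.2, 1)
  if (wire_cycles && m > 0L) {
    ig <- as_igraph(d)
    repeat {
      reach <- unique(unlist(lapply(inputs, function(s)
        igraph::subcomponent(ig, s, mode = "out")$name)))
      todo <- setdiff(d$nodes, reach)
      if (length(todo) == 0L) break
      pick <- todo[1L]
      b[idx[pick], 1L] <- stats::runif(1, 0.2, 1)
      inputs <- c(inputs, pick)
    }
  }
  structure(list(a = a, b = b, m = ncol(b)), class = "linear_system")
}

#' @rdname control_system
#' @param a,b State matrix and input matrix.
#' @export
linear_system <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != ncol(a)) stop("a must be square")
  if (nrow(b) != nrow(a)) stop("b must have as many rows as a")
  structure(list(a = a, b = b, m = ncol(b)), class = "linear_system")
}

#' Kalman controllability rank condition
#'
#' TRUE iff the controllability matrix `[B, AB, A^2 B, ..., A^(N-1) B]` has
#' full rank N. Rank is taken from singular values with tolerance
#' `max(dim) * eps * largest singular value`. Used as a numeric
#' cross-check of the matching-based driver count: with generic (random
#' nonzero) weights and inputs at the driver nodes the system is
#' controllable, while any smaller dedicated input set is not.
#'
#' @param sys A `linear_system`.
#' @return Logical scalar.
#' @examples
#' sys <- control_system(make_path_net(3), seed = 7)
#' kalman_full_rank(sys)  # TRUE: one input at the path head suffices
#' @export
kalman_full_rank <- function(sys) {
  stopifnot(inherits(sys, "linear_system"))
  n <- nrow(sys$a)
  if (ncol(sys$b) == 0L) return(FALSE)
  blocks <- vector("list", n)
  blocks[[1L]] <- sys$b
  for (i in seq_len(n - 1L)) blocks[[i + 1L]] <- sys$a %*% blocks[[i]]
  cm <- do.call(cbind, blocks)
  sv <- svd(cm, nu = 0, nv = 0)$d
  tol <- max(dim(cm)) * .Machine$double.eps * max(sv, 0)
  sum(sv > tol) == n
}

#' Randomly invert a fraction of the edges
#'
#' Reverses `floor(fraction * |edges|)` distinct edges chosen uniformly
#' without replacement. A reversal that would duplicate an existing edge is
#' merged away to preserve the simple-graph invariant; the number of merged
#' edges is recorded in the attribute `n_merged` (and messaged).
#'
#' @param d A `directed_network`.
#' @param fraction Proportion of edges to invert, in `[0, max_fraction]`.
#' @param seed Integer RNG seed.
#' @param max_fraction Upper cap on `fraction` (default 0.2; lift to 1 to
#'   allow full reversal).
#' @return A `directed_network` with attribute `n_merged`.
#' @export
invert_random_edges <- function(d, fraction, seed = 1L, max_fraction = 0.2) {
  stopifnot(inherits(d, "directed_network"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (fraction > max_fraction)
    stop("fraction ", fraction, " exceeds the cap max_fraction = ", max_fraction)
  set.seed(seed)
  m <- nrow(d$edges)
  k <- floor(fraction * m)
  if (k == 0L) {
    out <- d
    attr(out, "n_merged") <- 0L
    return(out)
  }
  pick <- sample.int(m, k)
  flipped <- d$edges[pick, 2:1, drop = FALSE]
  kept <- d$edges[-pick, , drop = FALSE]
  all_e <- rbind(kept, flipped)
  dup <- duplicated(pair_key(all_e))
  if (any(dup)) message(sum(dup), " inverted edge(s) merged with existing edges")
  out <- directed_network(nodes = d$nodes, edges = all_e[!dup, , drop = FALSE])
  attr(out, "n_merged") <- sum(dup)
  out
}

#' Percentage difference between two critical-node sets
#'
#' `100 * |A xor B| / |A union B|` over the critical sets of two
#' classifications on the same node universe; 0 when both sets are empty.
#'
#' @param a,b `control_classification` objects.
#' @return Percentage in \[0, 100\].
#' @export
critical_set_difference <- function(a, b) {
  if (!setequal(names(a$labels), names(b$labels)))
    stop("classifications cover different node universes")
  ca <- critical_nodes(a)
  cb <- critical_nodes(b)
  u <- union(ca, cb)
  if (length(u) == 0L) return(0)
  100 * length(setdiff(u, intersect(ca, cb))) / length(u)
}

#' Robustness of the critical-node set to edge inversion
#'
#' For each inversion fraction from 0 to `max_fraction` in steps of `step`,
#' reverses that fraction of edges `reps` independent times, reclassifies
#' all nodes, and reports the percentage difference between each perturbed
#' critical set and the baseline one. Fully seeded and reproducible.
#'
#' @param d A `directed_network`.
#' @param max_fraction Largest inversion fraction (default 0.2).
#' @param step Fraction increment (> 0).
#' @param reps Replicates per fraction.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `fraction`, `rep1..repK`, `mean_diff`.
#' @export
robustness_curve <- function(d, max_fraction = 0.2, step = 0.05, reps = 3L, seed = 1L) {
  if (step <= 0) stop("step must be > 0")
  base <- classify_nodes(d)
  fr <- seq(0, max_fraction, by = step)
  out <- matrix(0, length(fr), reps)
  for (i in seq_along(fr)) {
    if (fr[i] == 0) next
    for (r in seq_len(reps)) {
      pert <- invert_random_edges(d, fr[i], seed = derive_seed(seed, i * 1000L + r),
                                  max_fraction = max_fraction)
      out[i, r] <- critical_set_difference(base, classify_nodes(pert))
    }
  }
  res <- data.frame(fraction = fr, out, mean_diff = rowMeans(out))
  names(res)[2:(reps + 1L)] <- paste0("rep", seq_len(reps))
  res
}

# deterministic per-task seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}
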