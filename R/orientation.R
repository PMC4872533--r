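# Orientation of the undirected portion of a mixed graph.
#
# The goal is to choose a direction for every undirected edge so that as
# many pre-specified source-target pairs as possible are connected by a
# directed path whose length equals the shortest-path length between the
# pair in the original graph when directions are ignored. Because every
# directed path is also a path in the undirected support, the directed
# distance can never be shorter, so a constraint is satisfied exactly when
# the target is reachable from the source within that many steps.

#' Source-target orientation constraints
#'
#' @param source,target Character vectors of node identifiers
#'   (recycled to equal length); `source != target` row-wise.
#' @param origin Evidence origin per pair, `"ko"` or `"kpi"`.
#' @return Data frame with columns `source`, `target`, `origin`.
#' @export
pair_constraints <- function(source, target, origin = "ko") {
  source <- as.character(source)
  df <- data.frame(source = source, target = as.character(target),
                   origin = rep(origin, length.out = length(source)),
                   stringsAsFactors = FALSE)
  if (any(df$source == df$target)) stop("constraint with source == target")
  if (!all(df$origin %in% c("ko", "kpi"))) stop("origin must be 'ko' or 'kpi'")
  df
}

# shortest-path lengths in the undirected support between constraint pairs
base_pair_lengths <- function(base, constraints) {
  su <- support_igraph(base)
  vapply(seq_len(nrow(constraints)), function(i) {
    igraph::distances(su, v = constraints$source[i], to = constraints$target[i])[1, 1]
  }, numeric(1))
}

#' Is a source-target constraint satisfied by an orientation?
#'
#' TRUE when the directed network contains a path from source to target
#' whose length equals the shortest-path length between the two nodes in
#' the original mixed graph with directions ignored. With
#' `reachability_only = TRUE` the length requirement is dropped and plain
#' reachability suffices.
#'
#' @param network A `directed_network`.
#' @param constraint Single-row data frame (or list) with `source`, `target`.
#' @param base The original `mixed_graph` defining undirected distances.
#' @param reachability_only Relax the criterion to reachability.
#' @return Logical scalar.
#' @export
constraint_satisfied <- function(network, constraint, base, reachability_only = FALSE) {
  s <- constraint$source[1]
  t <- constraint$target[1]
  if (!all(c(s, t) %in% network$nodes))
    stop("constraint endpoints absent from network: ", s, " -> ", t)
  dg <- igraph::distances(as_igraph(network), v = s, to = t, mode = "out")[1, 1]
  if (reachability_only) return(is.finite(dg))
  du <- igraph::distances(support_igraph(base), v = s, to = t)[1, 1]
  is.finite(dg) && dg == du
}

# --- internal machinery shared by exact/greedy: integer adjacency lists ---

# reach t from s within at most L steps on an out-adjacency list
reach_within <- function(adj, s, t, L) {
  if (!is.finite(L)) return(FALSE)
  if (s == t) return(TRUE)
  frontier <- s
  seen <- logical(length(adj))
  seen[s] <- TRUE
  steps <- 0L
  while (length(frontier) && steps < L) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (t %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
    steps <- steps + 1L
  }
  FALSE
}

#' Exact orientation by enumeration
#'
#' Finds an orientation of all undirected edges maximizing the number of
#' satisfied constraints, by exhausting the `2^U` orientation vectors
#' (`U` = number of undirected edges). Ties are broken by the
#' lexicographically smallest orientation vector, where bit 0 orients an
#' edge from its lexicographically smaller endpoint. Intended for small
#' instances; use [orient_greedy()] beyond `max_undirected` edges.
#'
#' @param g A `mixed_graph`.
#' @param constraints Data frame from [pair_constraints()] (may have 0 rows).
#' @param max_undirected Refuse instances with more undirected edges.
#' @param reachability_only Relax satisfaction to plain reachability.
#' @return An `orientation_result`: list with `network`
#'   (`directed_network`), `satisfied`, `total`, `mode`.
#' @examples
#' g <- mixed_graph(undirected = rbind(c("A", "B"), c("B", "C")))
#' orient_exact(g, pair_constraints("A", "C"))$satisfied
#' @export
orient_exact <- function(g, constraints = pair_constraints(character(), character()),
                         max_undirected = 20, reachability_only = FALSE) {
  stopifnot(inherits(g, "mixed_graph"))
  U <- nrow(g$undirected)
  if (U > max_undirected)
    stop("instance has ", U, " undirected edges (> ", max_undirected,
         "); use orient_greedy() for large instances")
  check_constraint_nodes(g, constraints)
  n <- length(g$nodes)
  idx <- stats::setNames(seq_len(n), g$nodes)
  di <- cbind(idx[g$directed[, 1L]], idx[g$directed[, 2L]])
  ui <- cbind(idx[g$undirected[, 1L]], idx[g$undirected[, 2L]])
  nc <- nrow(constraints)
  si <- idx[constraints$source]
  ti <- idx[constraints$target]
  L <- if (nc) base_pair_lengths(g, constraints) else numeric(0)
  if (reachability_only) L <- ifelse(is.finite(L), n - 1, L)

  best_bits <- rep(0L, U)
  best_sat <- -1L
  bits <- rep(0L, U)
  total <- if (U == 0L) 1L else 2L ^ U
  for (code in 0:(total - 1L)) {
    if (U > 0L) {
      v <- code
      for (b in U:1) { bits[b] <- v %% 2L; v <- v %/% 2L }
    }
    or_edges <- if (U > 0L) {
      sw <- bits == 1L
      rbind(ui[!sw, , drop = FALSE], ui[sw, 2:1, drop = FALSE])
    } else matrix(integer(), ncol = 2)
    em <- rbind(di, or_edges)
    adj <- split(em[, 2L], factor(em[, 1L], levels = seq_len(n)))
    sat <- 0L
    for (i in seq_len(nc)) if (reach_within(adj, si[i], ti[i], L[i])) sat <- sat + 1L
    if (sat > best_sat) { best_sat <- sat; best_bits <- bits }
    if (best_sat == nc) break
  }
  net <- apply_orientation(g, best_bits)
  structure(list(network = net, satisfied = as.integer(max(best_sat, 0L)),
                 total = nc, mode = "exact"),
            class = "orientation_result")
}

apply_orientation <- function(g, bits) {
  ui <- g$undirected
  sw <- bits == 1L
  oriented <- rbind(ui[!sw, , drop = FALSE], ui[sw, 2:1, drop = FALSE])
  directed_network(nodes = g$nodes, edges = rbind(g$directed, oriented))
}

check_constraint_nodes <- function(g, constraints) {
  miss <- setdiff(c(constraints$source, constraints$target), g$nodes)
  if (length(miss)) stop("constraint endpoints absent from graph: ",
                         paste(miss, collapse = ", "))
}

#' Greedy orientation heuristic
#'
#' Processes constraints in order of increasing undirected shortest-path
#' length (the cheapest to satisfy conflict least). For each constraint not
#' yet satisfied it searches for a shortest directed path of exactly that
#' length that uses pre-directed edges, edges already fixed in the travel
#' direction, or still-free undirected edges; if one exists, the free edges
#' on it are fixed along the path. Remaining free edges are finally oriented
#' from their lower- to their higher-degree endpoint (ties lexicographic).
#' Deterministic for a fixed seed.
#'
#' @inheritParams orient_exact
#' @param seed Integer RNG seed (ties among equally short paths).
#' @return An `orientation_result` with `mode = "greedy"`.
#' @export
orient_greedy <- function(g, constraints = pair_constraints(character(), character()),
                          seed = 1L, reachability_only = FALSE) {
  stopifnot(inherits(g, "mixed_graph"))
  check_constraint_nodes(g, constraints)
  set.seed(seed)
  n <- length(g$nodes)
  idx <- stats::setNames(seq_len(n), g$nodes)
  ui <- cbind(idx[g$undirected[, 1L]], idx[g$undirected[, 2L]])
  U <- nrow(ui)
  fix <- rep(0L, U)  # 0 free, 1 as stored, 2 reversed
  di <- cbind(idx[g$directed[, 1L]], idx[g$directed[, 2L]])

  nc <- nrow(constraints)
  if (nc) {
    L <- base_pair_lengths(g, constraints)
    ord <- order(L, seq_len(nc))
    # arcs available given current fixes: directed + fixed + free (both ways)
    for (i in ord) {
      if (!is.finite(L[i])) next
      lim <- if (reachability_only) n - 1 else L[i]
      arcs <- current_arcs(di, ui, fix, free_both = TRUE)
      path <- bfs_path(arcs, n, idx[constraints$source[i]],
                       idx[constraints$target[i]], lim)
      if (is.null(path)) next
      # fix the free undirected edges along the path
      for (s in seq_len(length(path) - 1L)) {
        a <- path[s]; b <- path[s + 1L]
        j <- which(fix == 0L & ((ui[, 1L] == a & ui[, 2L] == b) |
                                (ui[, 1L] == b & ui[, 2L] == a)))
        if (length(j)) fix[j[1L]] <- if (ui[j[1L], 1L] == a) 1L else 2L
      }
    }
  }
  # orient leftovers from lower- to higher-degree endpoint
  if (any(fix == 0L)) {
    deg <- tabulate(c(di, ui), nbins = n)
    for (j in which(fix == 0L)) {
      a <- ui[j, 1L]; b <- ui[j, 2L]
      fix[j] <- if (deg[a] < deg[b] || (deg[a] == deg[b] && a <= b)) 1L else 2L
    }
  }
  net <- apply_orientation(g, fix - 1L)
  sat <- count_satisfied(net, constraints, g, reachability_only)
  structure(list(network = net, satisfied = sat, total = nc, mode = "greedy"),
            class = "orientation_result")
}

current_arcs <- function(di, ui, fix, free_both = FALSE) {
  arcs <- di
  if (nrow(ui)) {
    arcs <- rbind(arcs,
                  ui[fix == 1L, , drop = FALSE],
                  ui[fix == 2L, 2:1, drop = FALSE])
    if (free_both) {
      fr <- ui[fix == 0L, , drop = FALSE]
      arcs <- rbind(arcs, fr, fr[, 2:1, drop = FALSE])
    }
  }
  arcs
}

# BFS shortest path s->t over arc list; NULL unless distance == lim exactly
# (or <= lim when the caller passed a relaxed limit and dist is finite)
bfs_path <- function(arcs, n, s, t, lim) {
  adj <- split(arcs[, 2L], factor(arcs[, 1L], levels = seq_len(n)))
  parent <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  while (length(frontier) && is.na(dist[t])) {
    nxt <- integer(0)
    for (u in frontier) {
      vs <- adj[[u]]
      vs <- vs[is.na(dist[vs])]
      dist[vs] <- dist[u] + 1L
      parent[vs] <- u
      nxt <- c(nxt, vs)
    }
    frontier <- unique(nxt)
    if (length(frontier) && dist[frontier[1L]] > lim) break
  }
  if (is.na(dist[t]) || dist[t] > lim) return(NULL)
  path <- t
  while (path[1L] != s) path <- c(parent[path[1L]], path)
  path
}

count_satisfied <- function(network, constraints, base, reachability_only = FALSE) {
  nc <- nrow(constraints)
  if (nc == 0L) return(0L)
  sum(vapply(seq_len(nc), function(i)
    constraint_satisfied(network, constraints[i, ], base, reachability_only),
    logical(1)))
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("orientation_result (%s): %d/%d constraints satisfied; %d nodes, %d edges\n",
              x$mode, x$satisfied, x$total, length(x$network$nodes),
              nrow(x$network$edges)))
  invisible(x)
}

#' Fraction of agreeing edge orientations between two directed networks
#'
#' Considers every unordered node pair adjacent in both networks (the
#' comparable support) and scores it as agreeing when the two networks
#' carry exactly the same orientation(s) of that pair.
#'
#' @param a,b `directed_network` objects.
#' @return Fraction in \[0, 1\].
#' @export
directed_edge_agreement <- function(a, b) {
  pa <- split(pair_key(a$edges), pair_key(canon_pairs(a$edges)))
  pb <- split(pair_key(b$edges), pair_key(canon_pairs(b$edges)))
  common <- intersect(names(pa), names(pb))
  if (length(common) == 0L)
    stop("no node pair is adjacent in both networks; agreement undefined")
  agree <- vapply(common, function(k) setequal(pa[[k]], pb[[k]]), logical(1))
  mean(agree)
}
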