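# Independent oracles used to cross-check the package implementations.
# They deliberately take different algorithmic routes from the package:
# bitmask dynamic programming instead of Hopcroft-Karp matching,
# hypergeometric summation instead of fisher.test, full permutation
# enumeration instead of wilcox.test, and igraph-distance enumeration
# instead of the package's bounded BFS.

# maximum "directed matching" (no shared heads, no shared tails) of an edge
# list, by DP over subsets of in-copies: process tail nodes one at a time,
# tracking which head nodes are already used.
oracle_max_matching <- function(edges, nodes) {
  n <- length(nodes)
  if (n > 14L) stop("oracle limited to 14 nodes")
  if (nrow(edges) == 0L) return(0L)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- lapply(seq_len(n), function(u) unname(idx[edges[edges[, 1L] == nodes[u], 2L]]))
  nmask <- bitwShiftL(1L, n)
  f <- rep(0L, nmask)            # f[mask+1]: best over tails processed so far
  for (u in seq_len(n)) {
    g <- f
    for (mask in 0:(nmask - 1L)) {
      for (v in adj[[u]]) {
        bit <- bitwShiftL(1L, v - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          cand <- f[mask + 1L] + 1L
          if (cand > g[bitwOr(mask, bit) + 1L]) g[bitwOr(mask, bit) + 1L] <- cand
        }
      }
    }
    # a larger used-head set never helps; propagate maxima upward lazily by
    # taking the running best when reading results
    f <- g
  }
  max(f)
}

oracle_n_d <- function(d) {
  max(length(d$nodes) - oracle_max_matching(d$edges, d$nodes), 1L)
}

# random simple digraph on n nodes with edge probability p
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  nm <- paste0("v", seq_len(n))
  pairs <- expand.grid(from = nm, to = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  directed_network(nodes = nm, edges = as.matrix(pairs[keep, ]))
}

# random mixed graph: a random undirected support split into directed and
# undirected parts
random_mixed_graph <- function(n, p, undirected_frac, seed) {
  set.seed(seed)
  nm <- paste0("v", seq_len(n))
  pairs <- t(utils::combn(nm, 2L))
  pairs <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  if (nrow(pairs)) {
    flip <- stats::runif(nrow(pairs)) < 0.5
    tmp <- pairs[flip, 1L]; pairs[flip, 1L] <- pairs[flip, 2L]; pairs[flip, 2L] <- tmp
  }
  und <- stats::runif(nrow(pairs)) < undirected_frac
  mixed_graph(nodes = nm, directed = pairs[!und, , drop = FALSE],
              undirected = pairs[und, , drop = FALSE])
}

# two-sided Fisher exact p by hypergeometric summation over all tables
# with the observed margins
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  ks <- max(0L, r1 + c1 - N):min(r1, c1)
  logp <- lchoose(c1, ks) + lchoose(N - c1, r1 - ks) - lchoose(N, r1)
  p <- exp(logp)
  pobs <- p[ks == a]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating every assignment of the pooled
# sample into groups (tie-free data)
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2L, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# satisfied-constraint count of a fixed orientation, via igraph distances
oracle_satisfied <- function(di, oriented, nodes, constraints, base_len) {
  net <- igraph::graph_from_data_frame(
    as.data.frame(rbind(di, oriented), stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
  sat <- 0L
  for (i in seq_len(nrow(constraints))) {
    dd <- igraph::distances(net, v = constraints$source[i],
                            to = constraints$target[i], mode = "out")[1, 1]
    if (is.finite(dd) && dd == base_len[i]) sat <- sat + 1L
  }
  sat
}

# brute-force optimum over all 2^U orientations, independent of the package
oracle_orient_optimum <- function(g, constraints) {
  U <- nrow(g$undirected)
  base_len <- vapply(seq_len(nrow(constraints)), function(i) {
    su <- igraph::as_undirected(as_igraph(g), mode = "collapse")
    igraph::distances(su, v = constraints$source[i],
                      to = constraints$target[i])[1, 1]
  }, numeric(1))
  best <- 0L
  for (code in 0:(2L^U - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(max(U, 1L))]
    sw <- bits[seq_len(U)] == 1L
    oriented <- rbind(g$undirected[!sw, , drop = FALSE],
                      g$undirected[sw, 2:1, drop = FALSE])
    s <- oracle_satisfied(g$directed, oriented, g$nodes, constraints, base_len)
    if (s > best) best <- s
  }
  best
}

# discrete power-law degree sampler independent of scale_free_directed
sample_plaw <- function(n, gamma, kmax = 1000L, seed = 1L) {
  set.seed(seed)
  ks <- seq_len(kmax)
  sample(ks, n, replace = TRUE, prob = ks^(-gamma))
}

# sample up to k source-target constraints among node pairs connected in
# the undirected support (NULL when the graph has no connected pair)
pick_constraints <- function(g, k) {
  su <- igraph::as_undirected(as_igraph(g), mode = "collapse")
  dm <- igraph::distances(su)
  ok <- which(is.finite(dm) & dm > 0, arr.ind = TRUE)
  if (nrow(ok) == 0L) return(NULL)
  pick <- ok[sample.int(nrow(ok), min(k, nrow(ok))), , drop = FALSE]
  pair_constraints(g$nodes[pick[, 1L]], g$nodes[pick[, 2L]])
}
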