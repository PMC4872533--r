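# Synthetic inputs for the whole pipeline: canonical toy graphs, directed
# scale-free networks, orientation test instances and node/edge attributes
# with planted class-conditional effects. Everything is seeded and fully
# deterministic, so no external database is needed to exercise any stage.

#' Canonical toy networks
#'
#' `make_star_net(L)` is a hub with `L` out-edges (or in-edges) to leaves
#' `L1..LL`; `make_path_net(n)` is the directed path `A -> B -> ...`;
#' `make_cycle_net(n)` the directed cycle `C1 -> ... -> Cn -> C1`.
#'
#' @param leaves,n Element counts (`leaves >= 1`, path `n >= 2`,
#'   cycle `n >= 3`).
#' @param direction Edge direction of the star: hub to leaves (`"out"`)
#'   or leaves to hub (`"in"`).
#' @return A `directed_network`.
#' @examples
#' make_star_net(3)
#' @export
make_star_net <- function(leaves, direction = c("out", "in")) {
  direction <- match.arg(direction)
  if (leaves < 1L) stop("star needs at least 1 leaf")
  lv <- paste0("L", seq_len(leaves))
  e <- if (direction == "out") cbind("hub", lv) else cbind(lv, "hub")
  directed_network(edges = e)
}

#' @rdname make_star_net
#' @export
make_path_net <- function(n) {
  if (n < 2L) stop("path needs at least 2 nodes")
  nm <- if (n <= 26L) LETTERS[seq_len(n)] else sprintf("N%03d", seq_len(n))
  directed_network(edges = cbind(nm[-n], nm[-1L]))
}

#' @rdname make_star_net
#' @export
make_cycle_net <- function(n) {
  if (n < 3L) stop("cycle needs at least 3 nodes")
  nm <- sprintf("C%d", seq_len(n))
  directed_network(edges = cbind(nm, nm[c(2:n, 1L)]))
}

# draw total degrees from a truncated discrete power law P(k) ~ k^-gamma
sample_powerlaw_degrees <- function(n, gamma, kmax) {
  ks <- seq_len(kmax)
  sample(ks, n, replace = TRUE, prob = ks^(-gamma))
}

#' Directed scale-free network generator
#'
#' Configuration-model digraph whose total-degree distribution follows
#' `P(k) ~ k^-gamma` for `k >= 1` (truncated at `kmax`, by default the
#' structural cutoff `sqrt(n)`). Each node's total degree is split
#' binomially into in- and out-degree; out-stubs are matched to in-stubs
#' uniformly at random, and self loops or duplicate edges are repaired by
#' re-pairing the offending stubs. Any offender surviving
#' `max_rewire_passes` is dropped; the count is recorded in the attribute
#' `n_dropped`.
#'
#' @param n Number of nodes (>= 100).
#' @param gamma Degree exponent (> 2); default 3.
#' @param seed Integer RNG seed.
#' @param kmax Degree cutoff (default `floor(sqrt(n))`).
#' @param max_rewire_passes Repair passes before dropping offenders.
#' @return A `directed_network` with nodes `P0001...`; attribute
#'   `n_dropped` counts edges sacrificed to keep the graph simple.
#' @examples
#' g <- scale_free_directed(200, seed = 1)
#' @export
scale_free_directed <- function(n, gamma = 3, seed = 1L, kmax = NULL,
                                max_rewire_passes = 200L) {
  if (n < 100L) stop("generator needs n >= 100")
  if (gamma <= 2) stop("gamma must exceed 2")
  set.seed(seed)
  if (is.null(kmax)) kmax <- max(10L, floor(sqrt(n)))
  nodes <- sprintf("P%0*d", nchar(n), seq_len(n))
  k <- sample_powerlaw_degrees(n, gamma, kmax)
  if (sum(k) %% 2L == 1L) { i1 <- sample.int(n, 1L); k[i1] <- k[i1] + 1L }
  k_in <- stats::rbinom(n, k, 0.5)
  k_out <- k - k_in
  # rebalance so that total in-stubs equal total out-stubs
  pick1 <- function(ix) if (length(ix) == 1L) ix else sample(ix, 1L)
  diff <- sum(k_in) - sum(k_out)  # always even
  while (diff > 0L) {
    i <- pick1(which(k_in > 0L))
    k_in[i] <- k_in[i] - 1L; k_out[i] <- k_out[i] + 1L; diff <- diff - 2L
  }
  while (diff < 0L) {
    i <- pick1(which(k_out > 0L))
    k_out[i] <- k_out[i] - 1L; k_in[i] <- k_in[i] + 1L; diff <- diff + 2L
  }
  froms <- rep.int(seq_len(n), k_out)
  tos <- sample(rep.int(seq_len(n), k_in))
  m <- length(froms)
  for (pass in seq_len(max_rewire_passes)) {
    key <- froms * (n + 1) + tos
    bad <- which(froms == tos | duplicated(key))
    if (length(bad) == 0L) break
    swap <- sample.int(m, length(bad), replace = length(bad) > m)
    tmp <- tos[bad]; tos[bad] <- tos[swap]; tos[swap] <- tmp
  }
  key <- froms * (n + 1) + tos
  bad <- froms == tos | duplicated(key)
  n_dropped <- sum(bad)
  out <- directed_network(nodes = nodes,
                          edges = cbind(nodes[froms[!bad]], nodes[tos[!bad]]))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Orientation test instance with known ground truth
#'
#' Generates a directed scale-free "truth" network, strips the direction
#' from a random fraction of its edges (choosing only edges without an
#' antiparallel partner, so the observed mixed graph stays valid), and
#' samples source-target constraints from ordered pairs connected in the
#' truth. An orientation of the observed graph can then be scored against
#' the truth with [directed_edge_agreement()].
#'
#' @param n Nodes in the truth network.
#' @param undirected_fraction Fraction of edges stripped of direction.
#' @param n_pairs Number of source-target constraints to sample.
#' @param seed Integer RNG seed.
#' @param gamma Degree exponent of the truth network.
#' @return List with `truth` (`directed_network`), `observed`
#'   (`mixed_graph`) and `constraints` (data frame).
#' @export
make_orientation_instance <- function(n, undirected_fraction = 0.5, n_pairs = 10L,
                                      seed = 1L, gamma = 3) {
  truth <- scale_free_directed(n, gamma, seed)
  set.seed(derive_seed(seed, 101L))
  e <- truth$edges
  # the observed mixed graph cannot host antiparallel directed pairs (they
  # would have been merged during assembly), so thin each such pair to one arc
  anti <- pair_key(e) %in% pair_key(e[, 2:1, drop = FALSE])
  drop <- anti & e[, 1L] > e[, 2L]
  if (any(drop))
    truth <- directed_network(nodes = truth$nodes, edges = e[!drop, , drop = FALSE])
  e <- truth$edges
  cand <- seq_len(nrow(e))
  s <- floor(undirected_fraction * nrow(e))
  strip <- if (s > 0L) sample(cand, min(s, length(cand))) else integer(0)
  observed <- mixed_graph(nodes = truth$nodes,
                          directed = e[setdiff(seq_len(nrow(e)), strip), , drop = FALSE],
                          undirected = e[strip, , drop = FALSE])
  constraints <- pair_constraints(character(), character())
  if (n_pairs > 0L) {
    ig <- as_igraph(truth)
    srcs <- unique(e[, 1L])
    got <- 0L
    pairs <- matrix(character(), ncol = 2)
    guard <- 0L
    while (got < n_pairs && guard < 50L * n_pairs) {
      guard <- guard + 1L
      sfrom <- sample(srcs, 1L)
      reach <- setdiff(igraph::subcomponent(ig, sfrom, mode = "out")$name, sfrom)
      if (length(reach) == 0L) next
      pairs <- rbind(pairs, c(sfrom, sample(reach, 1L)))
      got <- got + 1L
    }
    if (got == 0L) stop("no reachable ordered pairs to sample constraints from")
    constraints <- pair_constraints(pairs[, 1L], pairs[, 2L], origin = "ko")
  }
  list(truth = truth, observed = observed, constraints = constraints)
}

#' Specification for planted synthetic attributes
#'
#' Collects the generator settings: planted odds ratios of each binary
#' attribute in critical vs non-critical-class nodes, base rates, the
#' DLI-incidence odds multiplier for edges touching critical nodes, and
#' the number of designated high-degree "paralog family" hubs. The default
#' planted effects mirror the reported biology: phosphorylation,
#' acetylation and ubiquitination about twice as frequent in critical as
#' in redundant nodes, sumoylation the strongest excess, a miRNA-target
#' and phospho-binding-domain excess, complex-membership enrichment, a
#' DLI bias on critical-incident edges, and seven family hubs (one per
#' 14-3-3-like paralog).
#'
#' @param n Node count used by downstream generators.
#' @param gamma Target degree exponent.
#' @param seed Integer RNG seed.
#' @param planted_effects Named numeric vector of odds ratios (> 0).
#' @param base_rates Named numeric vector of probabilities in \[0, 1\]
#'   (non-critical rates).
#' @param ddi_dli_bias Odds multiplier for DLI on critical-incident edges.
#' @param family_hubs Number of top-degree nodes sharing the family label.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 2000L, gamma = 3, seed = 1L,
                           planted_effects = c(ptm_phos = 2, ptm_acet = 2,
                                               ptm_ubiq = 2, ptm_sumo = 6,
                                               mirna_target = 2, phospho_domain = 3,
                                               in_complex = 3),
                           base_rates = c(ptm_phos = 0.5, ptm_acet = 0.2,
                                          ptm_ubiq = 0.2, ptm_sumo = 0.05,
                                          mirna_target = 0.3, phospho_domain = 0.1,
                                          in_complex = 0.15),
                           ddi_dli_bias = 2, family_hubs = 7L) {
  if (any(base_rates < 0 | base_rates > 1)) stop("base rates must be in [0, 1]")
  if (any(planted_effects <= 0)) stop("odds ratios must be > 0")
  if (gamma <= 2) stop("gamma must exceed 2")
  miss <- setdiff(names(planted_effects), names(base_rates))
  if (length(miss)) stop("no base rate for attribute(s): ", paste(miss, collapse = ", "))
  structure(list(n = n, gamma = gamma, seed = seed,
                 planted_effects = planted_effects, base_rates = base_rates,
                 ddi_dli_bias = ddi_dli_bias, family_hubs = family_hubs),
            class = "synthetic_spec")
}

# critical-class rate q with odds(q) = OR * odds(p)
planted_rate <- function(p, or, attr = "") {
  if (!is.finite(or)) stop("infeasible planted rate for attribute '", attr, "'")
  if (p == 0) return(0)
  q <- stats::plogis(log(or) + stats::qlogis(p))
  if (q >= 1) stop("infeasible planted rate (q >= 1) for attribute '", attr, "'")
  q
}

#' Plant class-conditional node and edge attributes
#'
#' Draws biological annotations conditioned on an existing controllability
#' classification ("classify first, then annotate"): for each binary
#' attribute, critical nodes get probability `q` where
#' `odds(q) = OR * odds(p)` and all other nodes the base rate `p`. PTM
#' flags are expanded to site counts (1 + Poisson). Disorder fractions and
#' degradation rates are drawn independently of class, mirroring the
#' observation that intrinsic disorder and turnover do not differ between
#' classes. Edges touching at least one critical node get DLI interface
#' labels with odds multiplied by `ddi_dli_bias`. The `family_hubs`
#' highest-degree nodes share the family label `"hub_family"`.
#'
#' @param labels Named character vector of class labels (or a
#'   `control_classification`).
#' @param spec A [synthetic_spec()].
#' @param network Optional `directed_network`; needed for degrees (`k`
#'   column, family hubs) and edge annotations.
#' @param seed Integer RNG seed (defaults to `spec$seed`).
#' @return List with `nodes` (annotation data frame: `node`, `k`,
#'   `disorder_fraction`, `ptm_*` counts, `mirna_target`,
#'   `phospho_domain`, `degradation_rate`, `complexes`, `family`) and
#'   `edges` (data frame `source`, `target`, `interface`; NULL without a
#'   network).
#' @export
plant_attributes <- function(labels, spec = synthetic_spec(), network = NULL,
                             seed = spec$seed) {
  if (inherits(labels, "control_classification")) labels <- labels$labels
  if (is.null(names(labels))) stop("labels must be a named vector")
  if (!is.null(network) && !setequal(names(labels), network$nodes))
    stop("classification does not cover the network")
  set.seed(seed)
  nodes <- names(labels)
  nn <- length(nodes)
  crit <- labels == "critical"

  ann <- data.frame(node = nodes, stringsAsFactors = FALSE)
  if (!is.null(network)) {
    deg <- node_degrees(network)
    ann$k <- deg$k[match(nodes, deg$node)]
  }
  ann$disorder_fraction <- stats::rbeta(nn, 1.8, 4.2)  # class-independent, mean ~0.3
  flags <- list()
  for (a in names(spec$planted_effects)) {
    p <- spec$base_rates[[a]]
    q <- planted_rate(p, spec$planted_effects[[a]], a)
    flags[[a]] <- stats::runif(nn) < ifelse(crit, q, p)
  }
  for (a in grep("^ptm_", names(flags), value = TRUE))
    ann[[a]] <- ifelse(flags[[a]], 1L + stats::rpois(nn, 1.5), 0L)
  ann$mirna_target <- flags$mirna_target %||% rep(FALSE, nn)
  ann$phospho_domain <- flags$phospho_domain %||% rep(FALSE, nn)
  ann$degradation_rate <- stats::rlnorm(nn, 0, 0.5)   # class-independent
  in_cpx <- flags$in_complex %||% rep(FALSE, nn)
  cpx_pool <- paste0("CPX", 1:6)
  ann$complexes <- vapply(in_cpx, function(f) {
    if (!f) "" else paste(sample(cpx_pool, sample(1:2, 1L)), collapse = ";")
  }, character(1))
  ann$family <- NA_character_
  if (!is.null(network) && spec$family_hubs > 0L) {
    deg <- node_degrees(network)
    topk <- deg$node[order(-deg$k, deg$node)][seq_len(min(spec$family_hubs, nn))]
    ann$family[ann$node %in% topk] <- "hub_family"
  }

  edges_ann <- NULL
  if (!is.null(network)) {
    e <- network$edges
    touch_crit <- crit[match(e[, 1L], nodes)] | crit[match(e[, 2L], nodes)]
    p_dli <- 0.35
    q_dli <- planted_rate(p_dli, spec$ddi_dli_bias, "dli")
    is_dli <- stats::runif(nrow(e)) < ifelse(touch_crit, q_dli, p_dli)
    edges_ann <- data.frame(source = e[, 1L], target = e[, 2L],
                            interface = ifelse(is_dli, "DLI", "DDI"),
                            stringsAsFactors = FALSE)
  }
  list(nodes = ann, edges = edges_ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
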