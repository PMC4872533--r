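test_that("toy generators build the canonical graphs", {
  st <- make_star_net(3)
  expect_equal(st$edges, rbind(c("hub", "L1"), c("hub", "L2"), c("hub", "L3")))
  stin <- make_star_net(2, "in")
  expect_equal(stin$edges, rbind(c("L1", "hub"), c("L2", "hub")))
  expect_equal(make_path_net(3)$edges, rbind(c("A", "B"), c("B", "C")))
  cy <- make_cycle_net(3)
  deg <- node_degrees(cy)
  expect_true(all(deg$k_in == 1) && all(deg$k_out == 1))
  expect_error(make_star_net(0), "leaf")
  expect_error(make_path_net(1), "2 nodes")
  expect_error(make_cycle_net(2), "3 nodes")
})

test_that("the scale-free generator yields simple, balanced, seeded digraphs", {
  g <- scale_free_directed(100, 3, seed = 5)
  deg <- node_degrees(g)
  expect_equal(sum(deg$k_in), nrow(g$edges))
  expect_equal(sum(deg$k_out), nrow(g$edges))
  expect_false(any(g$edges[, 1] == g$edges[, 2]))
  expect_false(anyDuplicated(paste(g$edges[, 1], g$edges[, 2])) > 0)

  g2 <- scale_free_directed(100, 3, seed = 5)
  expect_true(graphs_equal(g, g2))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_graph_file(g, f1, "tsv_edgelist"); write_graph_file(g2, f2, "tsv_edgelist")
  expect_identical(readLines(f1), readLines(f2))

  expect_error(scale_free_directed(50), "n >= 100")
  expect_error(scale_free_directed(200, gamma = 1.5), "gamma")
})

test_that("generated degree tails carry the requested exponent", {
  g <- scale_free_directed(10000, 3, seed = 42)
  fit <- fit_power_law_net(node_degrees(g)$k, xmin = 1)
  expect_lt(abs(fit$exponent - 3), 0.15)
})

test_that("orientation instances expose a scorable ground truth", {
  inst0 <- make_orientation_instance(150, undirected_fraction = 0, n_pairs = 5, seed = 3)
  expect_equal(nrow(inst0$observed$undirected), 0L)
  oriented <- orient_greedy(inst0$observed, inst0$constraints, seed = 1)$network
  expect_equal(directed_edge_agreement(oriented, inst0$truth), 1)

  inst <- make_orientation_instance(150, undirected_fraction = 0.3, n_pairs = 0, seed = 4)
  expect_equal(nrow(inst$constraints), 0L)
  expect_gt(nrow(inst$observed$undirected), 0L)
  # support of observed equals support of truth
  support <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  expect_equal(support(rbind(inst$observed$directed, inst$observed$undirected)),
               support(inst$truth$edges))
})

test_that("exact orientation beats a random orientation against the truth", {
  agree_ex <- agree_rnd <- numeric(0)
  for (s in 1:40) {
    inst <- make_orientation_instance(100, undirected_fraction = 0.12,
                                      n_pairs = 12, seed = 900 + s)
    U <- nrow(inst$observed$undirected)
    if (U == 0L || U > 9L) next
    ex <- orient_exact(inst$observed, inst$constraints, max_undirected = 9)
    set.seed(s)
    bits <- sample(0:1, U, replace = TRUE)
    rnd_edges <- rbind(inst$observed$directed,
                       inst$observed$undirected[bits == 0L, , drop = FALSE],
                       inst$observed$undirected[bits == 1L, 2:1, drop = FALSE])
    rnd <- directed_network(nodes = inst$observed$nodes, edges = rnd_edges)
    agree_ex <- c(agree_ex, directed_edge_agreement(ex$network, inst$truth))
    agree_rnd <- c(agree_rnd, directed_edge_agreement(rnd, inst$truth))
  }
  expect_gt(length(agree_ex), 20L)
  # paired comparison over seeds: the constraint-informed orientation
  # recovers more true directions than an uninformed coin flip
  expect_gt(mean(agree_ex), mean(agree_rnd))
  expect_gte(mean(agree_ex >= agree_rnd), 0.5)
})

test_that("planted attributes honour base rates, odds ratios and feasibility checks", {
  labels <- stats::setNames(rep(c("critical", "redundant"), each = 2000),
                            paste0("p", 1:4000))
  # null planting: sample odds ratios stay near 1
  null_spec <- synthetic_spec(planted_effects = c(ptm_acet = 1, mirna_target = 1),
                              base_rates = c(ptm_acet = 0.2, mirna_target = 0.3))
  ann <- plant_attributes(labels, null_spec, seed = 13)$nodes
  for (a in c("mirna_target")) {
    or <- fisher_enrichment(labels == "critical", as.logical(ann[[a]]))$odds_ratio
    expect_gt(or, 0.8); expect_lt(or, 1.25)
  }
  or_acet <- fisher_enrichment(labels == "critical", ann$ptm_acet >= 1)$odds_ratio
  expect_gt(or_acet, 0.8); expect_lt(or_acet, 1.25)

  # zero base rate: attribute absent everywhere
  zero <- synthetic_spec(planted_effects = c(ptm_sumo = 6),
                         base_rates = c(ptm_sumo = 0))
  expect_true(all(plant_attributes(labels, zero, seed = 2)$nodes$ptm_sumo == 0))

  expect_error(synthetic_spec(planted_effects = c(ptm_sumo = -1),
                              base_rates = c(ptm_sumo = 0.1)), "odds ratios")
  expect_error(synthetic_spec(planted_effects = c(nope = 2),
                              base_rates = c(ptm_sumo = 0.1)), "base rate")
})

test_that("edge labels and family hubs are planted from the network", {
  g <- scale_free_directed(400, 3, seed = 6)
  cls <- classify_nodes(g)
  planted <- plant_attributes(cls, synthetic_spec(family_hubs = 7), network = g, seed = 9)
  expect_equal(sum(planted$nodes$family == "hub_family", na.rm = TRUE), 7L)
  top <- node_degrees(g)
  top <- top$node[order(-top$k, top$node)][1:7]
  expect_setequal(planted$nodes$node[!is.na(planted$nodes$family)], top)
  expect_equal(nrow(planted$edges), nrow(g$edges))
  expect_true(all(planted$edges$interface %in% c("DLI", "DDI")))
  # DLI bias: critical-incident edges carry DLI more often
  crit <- critical_nodes(cls)
  touch <- planted$edges$source %in% crit | planted$edges$target %in% crit
  expect_gt(mean(planted$edges$interface[touch] == "DLI"),
            mean(planted$edges$interface[!touch] == "DLI"))
})
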