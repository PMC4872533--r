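test_that("Fisher enrichment returns the exact p and the sample odds ratio", {
  flat <- fisher_enrichment(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(flat$p_value, 1)
  expect_equal(flat$odds_ratio, 1)

  sep <- fisher_enrichment(rep(c(TRUE, FALSE), c(5, 5)), rep(c(TRUE, FALSE), c(5, 5)))
  expect_equal(sep$p_value, 2 / 252)
  expect_equal(sep$odds_ratio, Inf)

  # OR is ad/bc, not the conditional MLE that fisher.test reports
  or4 <- fisher_enrichment(rep(c(TRUE, FALSE), c(3, 3)),
                           c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(or4$odds_ratio, 4)
  expect_error(fisher_enrichment(logical(0), logical(0)), "empty")
})

test_that("Fisher p equals hypergeometric enumeration for random small tables", {
  set.seed(11)
  for (i in 1:60) {
    tab <- as.vector(stats::rmultinom(1, sample(8:30, 1), prob = stats::runif(4, 0.1, 1)))
    in_class <- rep(c(TRUE, TRUE, FALSE, FALSE), tab)
    has_attr <- rep(c(TRUE, FALSE, TRUE, FALSE), tab)
    got <- fisher_enrichment(in_class, has_attr)$p_value
    want <- oracle_fisher_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("rank tests behave on degenerate and well-separated samples", {
  same <- compare_numeric(list(a = c(1, 2, 3), b = c(1, 2, 3)), "wilcoxon_ranksum")
  expect_equal(same$p_value, 1)
  sep <- compare_numeric(list(a = 1:50, b = 51:100), "wilcoxon_ranksum")
  expect_lt(sep$p_value, 1e-6)
  expect_error(compare_numeric(list(a = 1:3, b = numeric(0), c = 1:3),
                               "kruskal_wallis"), "empty group")
  expect_error(compare_numeric(list(a = 1:3), "kruskal_wallis"), "2 groups")
  kw <- compare_numeric(list(a = 1:5, b = 2:6, c = 3:7), "kruskal_wallis")
  expect_true(kw$p_value > 0 && kw$p_value <= 1)
})

test_that("rank-sum p equals the exact permutation null on tie-free samples", {
  set.seed(23)
  for (i in 1:8) {
    x <- sample(1:100, 6)
    y <- sample(setdiff(1:100, x), 7)
    got <- compare_numeric(list(a = x, b = y), "wilcoxon_ranksum")$p_value
    expect_equal(got, oracle_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("relative PTM frequency compares per-node fractions", {
  crit <- data.frame(ptm_sumo = c(1, 0, 2, 0, 1, 0, 0, 0, 1, 0))  # 0.4
  red <- data.frame(ptm_sumo = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0))  # 0.1
  expect_equal(ptm_relative_frequency(crit, red, "ptm_sumo"), 4)
  expect_equal(ptm_relative_frequency(crit, crit, "ptm_sumo"), 1)
  none <- data.frame(ptm_sumo = rep(0, 5))
  expect_equal(ptm_relative_frequency(crit, none, "ptm_sumo"), Inf)
  expect_warning(r0 <- ptm_relative_frequency(none, none, "ptm_sumo"), "undefined")
  expect_true(is.na(r0))
})

test_that("planted odds ratios are recovered by the frequency ratio", {
  # binomial oracle: with OR = 6 on base rate 0.05, the critical-class rate
  # is plogis(log(6) + qlogis(0.05)) ~ 0.24, i.e. an expected ratio of ~4.8
  set.seed(31)
  p <- 0.05
  q <- stats::plogis(log(6) + stats::qlogis(p))
  crit <- data.frame(ptm_sumo = stats::rbinom(2000, 1, q))
  red <- data.frame(ptm_sumo = stats::rbinom(2000, 1, p))
  ratio <- ptm_relative_frequency(crit, red, "ptm_sumo")
  expect_gt(ratio, 0.8 * q / p)
  expect_lt(ratio, 1.25 * q / p)
})

test_that("interface rates follow the double normalisation", {
  ea <- data.frame(source = c(paste0("c", 1:10), paste0("x", 1:10)),
                   target = "y",
                   interface = rep(c("DLI", "DDI"), each = 10),
                   stringsAsFactors = FALSE)
  rate <- interface_rate(paste0("c", 1:10), ea, "DLI",
                         total_interactions = 20, total_nodes = 5)
  expect_equal(rate, (10 / 20) / 5)
  expect_equal(interface_rate("nobody", ea, "DLI", 20, 5), 0)
  all_dli <- data.frame(source = "a", target = "b", interface = "DLI")
  expect_equal(interface_rate(c("a", "b"), all_dli, "DLI", 1, 1), 1)
  expect_error(interface_rate("a", ea, "DLI", 0, 5), "positive")
})

test_that("Jaccard index behaves as a set overlap measure", {
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard(letters[1:4], letters[1:4]), 1)
  expect_equal(jaccard(c("A"), c("B")), 0)
  expect_error(jaccard(character(), character()), "empty")
  for (s in 1:5) {
    set.seed(s)
    a <- sample(letters, 6); b <- sample(letters, 8)
    expect_equal(jaccard(a, b), jaccard(b, a))
  }
})

test_that("hubs are the top-decile degree nodes with ties included", {
  # 10 nodes, unique maximum degree: only the top-decile node qualifies
  star9 <- make_star_net(9)
  expect_equal(hubs(star9), "hub")
  ring <- make_cycle_net(12)
  expect_setequal(hubs(ring), ring$nodes)   # all degrees equal: all tied at cut
  # 20 nodes, ceiling(0.1 * 20) = 2, and two nodes tied at the cut
  twostars <- directed_network(
    nodes = paste0("pad", 1:8),
    edges = rbind(cbind("h1", paste0("a", 1:5)), cbind("h2", paste0("b", 1:5))))
  expect_setequal(hubs(twostars), c("h1", "h2"))
  expect_error(hubs(directed_network()), "empty")
})

test_that("degree-exponent estimates recover the generating exponent", {
  x3 <- sample_plaw(10000, 3, seed = 1)
  expect_lt(abs(fit_power_law_net(x3, xmin = 1)$exponent - 3), 0.15)
  x22 <- sample_plaw(10000, 2.2, seed = 2)
  expect_lt(abs(fit_power_law_net(x22, xmin = 1)$exponent - 2.2), 0.1)
  expect_error(fit_power_law_net(rep(1L, 100), xmin = 1), "degenerate")
  expect_error(fit_power_law_net(sample_plaw(30, 3, seed = 3)), "50 tail")
  # the fixed-xmin MLE and plfit agree when plfit picks xmin = 1
  auto <- fit_power_law_net(x3, "auto")
  manual <- fit_power_law_net(x3[x3 >= auto$xmin], xmin = auto$xmin)
  expect_lt(abs(auto$exponent - manual$exponent), 0.02)
})

test_that("exponent estimator bias stays small across seeds", {
  for (gam in c(2.5, 3)) {
    est <- vapply(1:20, function(s)
      fit_power_law_net(sample_plaw(10000, gam, seed = 700 + s), xmin = 1)$exponent,
      numeric(1))
    expect_lt(abs(mean(est) - gam), 0.05)
  }
})

test_that("class summaries detect planted excess and enforce coverage", {
  labels <- stats::setNames(rep(c("critical", "redundant", "ordinary"), each = 500),
                            paste0("p", 1:1500))
  spec <- synthetic_spec(planted_effects = c(ptm_phos = 3, ptm_acet = 1,
                                             ptm_sumo = 1, mirna_target = 1),
                         base_rates = c(ptm_phos = 0.2, ptm_acet = 0.2,
                                        ptm_sumo = 0.05, mirna_target = 0.3))
  ann <- plant_attributes(labels, spec, seed = 77)$nodes
  summ <- class_summary(labels, ann)
  expect_lt(summ$adjusted_p[summ$attribute == "ptm_phos"], 0.05)
  # class-independent numerics are present and not strongly significant
  expect_true(all(c("disorder_fraction", "degradation_rate") %in% summ$attribute))
  expect_error(class_summary(labels, ann[1:100, ]), "coverage")
  # paper-parity mode: no adjusted column filled
  raw <- class_summary(labels, ann, adjust = FALSE)
  expect_true(all(is.na(raw$adjusted_p)))
})
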