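test_that("interaction records parse from TSV with header or positional dialect", {
  recs <- parse_interactions(c(
    "protein_a\tprotein_b\tdirectedness\tevidence\tsource\tp_value",
    "A\tB\tundirected\tppi\tdb1\t",
    "C\tD\ta_to_b\tkpi\tdb2\t"))
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$directedness, c("undirected", "a_to_b"))

  # positional columns, explicit dialect, p-value parsing
  recs2 <- parse_interactions(
    c("# comment line", "X\tY\tundirected\tko\tscreen\t0.0005"),
    dialect = list(protein_a = 1, protein_b = 2, directedness = 3,
                   evidence = 4, source = 5, p_value = 6))
  expect_equal(recs2$p_value, 0.0005)

  # a self loop parses; removal is assemble's job
  loop <- parse_interactions("A\tA\tundirected\tppi\t\t",
                             dialect = list(protein_a = 1, protein_b = 2,
                                            directedness = 3, evidence = 4))
  expect_equal(loop$protein_a, loop$protein_b)
})

test_that("parse errors carry line numbers; empty input gives empty records", {
  expect_error(
    parse_interactions(c("A\tB\tundirected\tko\ts\tnot_a_p"),
                       dialect = list(protein_a = 1, protein_b = 2, directedness = 3,
                                      evidence = 4, source = 5, p_value = 6)),
    "line.*1")
  expect_error(
    parse_interactions(c("A\tB\tundirected\tko\ts\t1.5"),
                       dialect = list(protein_a = 1, protein_b = 2, directedness = 3,
                                      evidence = 4, source = 5, p_value = 6)),
    "malformed p_value")
  f <- withr::local_tempfile(lines = character())
  expect_equal(nrow(parse_interactions(f)), 0L)
})

make_ko <- function(p) {
  k <- length(p)
  data.frame(protein_a = sprintf("a%d", seq_len(k)), protein_b = rep("t", k),
             directedness = rep("a_to_b", k), evidence = rep("ko", k),
             source = rep("", k), p_value = p, stringsAsFactors = FALSE)
}

test_that("ko pairs are filtered strictly below the threshold", {
  r <- make_ko(c(0.0005, 0.001, 0.01, 0.0009999))
  kept <- filter_ko_pairs(r)
  expect_equal(kept$p_value, c(0.0005, 0.0009999))  # 0.001 itself removed
  expect_equal(nrow(filter_ko_pairs(make_ko(numeric(0)))), 0L)
  expect_error(filter_ko_pairs(make_ko(c(0.1, NA))), "missing p_value")
})

test_that("ko filtering is monotone in the threshold", {
  set.seed(42)
  r <- make_ko(round(stats::runif(100), 4))
  for (t2 in c(0.1, 0.3, 0.7)) {
    a <- filter_ko_pairs(r, threshold = t2)
    b <- filter_ko_pairs(r, threshold = t2 + 0.2)
    expect_true(all(paste(a$protein_a, a$p_value) %in% paste(b$protein_a, b$p_value)))
  }
})

rec <- function(a, b, dir = "undirected", ev = "ppi") {
  data.frame(protein_a = a, protein_b = b, directedness = dir, evidence = ev,
             source = "", p_value = NA_real_, stringsAsFactors = FALSE)
}

test_that("assembly applies precedence and merge rules", {
  # directed beats undirected on the same pair
  g <- assemble(rbind(rec("A", "B"), rec("A", "B", "a_to_b")))
  expect_equal(g$directed, rbind(c("A", "B")))
  expect_equal(nrow(g$undirected), 0L)

  # antiparallel directed edges collapse to one undirected edge
  g2 <- assemble(rbind(rec("A", "B", "a_to_b"), rec("B", "A", "a_to_b")))
  expect_equal(nrow(g2$directed), 0L)
  expect_equal(g2$undirected, rbind(c("A", "B")))

  # self loop dropped, node kept
  g3 <- assemble(rec("A", "A"))
  expect_equal(g3$nodes, "A")
  expect_equal(nrow(g3$directed) + nrow(g3$undirected), 0L)

  # kpi/ko evidence is born directed, and a ppi record never overrides it
  g4 <- assemble(rbind(rec("K", "S", "undirected", "kpi"), rec("K", "S")))
  expect_equal(g4$directed, rbind(c("K", "S")))
})

test_that("assembly is idempotent and order-independent, and invariants hold", {
  set.seed(7)
  for (s in 1:20) {
    set.seed(s)
    n <- 30L
    r <- data.frame(
      protein_a = paste0("n", sample(8, n, TRUE)),
      protein_b = paste0("n", sample(8, n, TRUE)),
      directedness = sample(c("undirected", "a_to_b"), n, TRUE),
      evidence = sample(c("ppi", "kpi", "ko"), n, TRUE, prob = c(0.7, 0.2, 0.1)),
      source = "", p_value = NA_real_, stringsAsFactors = FALSE)
    g <- assemble(r)
    expect_true(graphs_equal(g, assemble(rbind(r, r))))
    expect_true(graphs_equal(g, assemble(r[sample(n), ])))
    # no antiparallel directed pairs, no directed/undirected overlap
    dk <- paste(g$directed[, 1], g$directed[, 2])
    rk <- paste(g$directed[, 2], g$directed[, 1])
    expect_length(intersect(dk, rk), 0L)
    uk <- paste(g$undirected[, 1], g$undirected[, 2])
    sk <- paste(pmin(g$directed[, 1], g$directed[, 2]),
                pmax(g$directed[, 1], g$directed[, 2]))
    expect_length(intersect(uk, sk), 0L)
  }
})

test_that("induced subgraphs restrict nodes and edges", {
  g <- assemble(rbind(rec("A", "B"), rec("B", "C")))
  h <- induced_subgraph_net(g, c("A", "B"))
  expect_equal(h$nodes, c("A", "B"))
  expect_equal(h$undirected, rbind(c("A", "B")))
  expect_true(graphs_equal(g, induced_subgraph_net(g, g$nodes)))
  empty <- induced_subgraph_net(g, c("X", "Y"))
  expect_length(empty$nodes, 0L)
})

test_that("graph files round-trip through every format", {
  for (s in 1:5) {
    g <- random_mixed_graph(6, 0.4, 0.5, seed = s)
    g <- mixed_graph(nodes = c(g$nodes, "isolated1"), directed = g$directed,
                     undirected = g$undirected)
    for (fmt in c("tsv_edgelist", "graphml")) {
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_graph_file(g, f, fmt)
      expect_true(graphs_equal(g, read_graph_file(f, fmt, as = "mixed_graph")),
                  info = paste(fmt, "seed", s))
    }
  }
  # SIF: direction set by flag; isolated nodes as single-token lines
  d <- directed_network(nodes = c("A", "B", "C", "lonely"),
                        edges = rbind(c("A", "B"), c("B", "C")))
  f <- withr::local_tempfile(fileext = ".sif")
  write_graph_file(d, f, "sif")
  back <- read_graph_file(f, "sif", as = "directed_network", directed = TRUE)
  expect_true(graphs_equal(d, back))
  undirected_back <- read_graph_file(f, "sif", as = "mixed_graph", directed = FALSE)
  expect_equal(nrow(undirected_back$undirected), 2L)
  expect_true("lonely" %in% undirected_back$nodes)

  # empty edge list with isolated nodes survives
  iso <- mixed_graph(nodes = c("X", "Y"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_graph_file(iso, f2, "tsv_edgelist")
  expect_equal(read_graph_file(f2, "tsv_edgelist")$nodes, c("X", "Y"))
})

test_that("graph constructors reject invariant violations", {
  expect_error(mixed_graph(directed = rbind(c("A", "A"))), "self loops")
  expect_error(mixed_graph(directed = rbind(c("A", "B"), c("B", "A"))), "antiparallel")
  expect_error(mixed_graph(directed = rbind(c("A", "B")),
                           undirected = rbind(c("B", "A"))), "both directed and undirected")
  expect_error(directed_network(edges = rbind(c("A", "B"), c("A", "B"))), "duplicate")
})
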