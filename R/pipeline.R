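# End-to-end pipeline: simulate/assemble -> orient -> classify ->
# robustness -> knockdown -> enrichment, driven by a single configuration
# (an R list or a YAML file). Every artifact carries the package version,
# a hash of the configuration and the global seed in its header, and each
# stage derives its own sub-seed from the global one so stages can be
# rerun in isolation reproducibly.

#' Pipeline configuration
#'
#' Builds (and completes with defaults) the configuration consumed by
#' [run_pipeline()]. Either supply `records` (a TSV of interaction
#' records, see [parse_interactions()]) plus optionally `constraints`
#' (TSV: source, target, origin), or leave them NULL to run on a
#' simulated network.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Global integer seed.
#' @param records,constraints,annotations,edge_annotations Optional input
#'   file paths.
#' @param ko_threshold Knockout-pair p-value cutoff (default 0.001).
#' @param orientation_mode `"greedy"` or `"exact"`.
#' @param simulate List of arguments for the simulated run (`n`, `gamma`,
#'   `undirected_fraction`, `n_pairs`).
#' @param robustness NULL to skip, or list(`max_fraction`, `step`, `reps`).
#' @param knockdown NULL to skip, or list(`target` (NULL = top family
#'   hub), `mode`, `step`, `reps`).
#' @param stages Character vector of stages to run, a subset of
#'   `c("network", "orient", "classify", "robustness", "knockdown",
#'   "enrich")`; later stages are skipped automatically when their
#'   prerequisites were not run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, records = NULL, constraints = NULL,
                            annotations = NULL, edge_annotations = NULL,
                            ko_threshold = 0.001,
                            orientation_mode = c("greedy", "exact"),
                            simulate = list(n = 500L, gamma = 3,
                                            undirected_fraction = 0.4, n_pairs = 30L),
                            robustness = NULL,
                            knockdown = list(target = NULL, mode = "edges",
                                             step = 0.1, reps = 3L),
                            stages = c("network", "orient", "classify",
                                       "robustness", "knockdown", "enrich")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), records = records,
                 constraints = constraints, annotations = annotations,
                 edge_annotations = edge_annotations, ko_threshold = ko_threshold,
                 orientation_mode = match.arg(orientation_mode),
                 simulate = simulate, robustness = robustness,
                 knockdown = knockdown, stages = stages),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any of the fields above.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

artifact_header <- function(config) {
  c(sprintf("ppicontrol %s", as.character(utils::packageVersion("ppicontrol"))),
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("seed: %d", config$seed))
}

write_tsv_artifact <- function(df, path, header) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_fail <- function(stage, ...) stop("[stage ", stage, "] ", ..., call. = FALSE)

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order: network assembly (from records,
#' or simulation), orientation of undirected edges, controllability
#' classification, robustness to edge inversion, hub knockdown and
#' annotation enrichment. Artifacts (GraphML networks, TSV tables) are
#' written into `config$out_dir`; reruns with the same configuration and
#' seed reproduce them byte for byte.
#'
#' @param config A [pipeline_config()], or the path to a YAML file.
#' @return Invisibly, a list with the in-memory results and the artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- artifact_header(config)
  res <- list(config = config, artifacts = character())
  seed_of <- function(i) derive_seed(config$seed, i)
  want <- function(s) s %in% config$stages

  mixed <- NULL; constraints <- NULL; annotations <- NULL; edge_ann <- NULL
  if (want("network")) {
    if (!is.null(config$records)) {
      if (!file.exists(config$records))
        stage_fail("network", "records file not found: ", config$records)
      recs <- parse_interactions(config$records)
      ko <- recs$evidence == "ko"
      recs <- rbind(recs[!ko, ], filter_ko_pairs(recs[ko, ], config$ko_threshold))
      mixed <- assemble(recs)
      ko_kept <- recs[recs$evidence == "ko", ]
      constraints <- if (nrow(ko_kept))
        pair_constraints(ko_kept$protein_a, ko_kept$protein_b, "ko")
      else pair_constraints(character(), character())
      if (!is.null(config$constraints)) {
        if (!file.exists(config$constraints))
          stage_fail("network", "constraints file not found: ", config$constraints)
        ct <- utils::read.table(config$constraints, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
        constraints <- rbind(constraints,
                             pair_constraints(ct$source, ct$target, ct$origin))
      }
      if (!is.null(config$annotations))
        annotations <- utils::read.table(config$annotations, sep = "\t", header = TRUE,
                                         stringsAsFactors = FALSE)
      if (!is.null(config$edge_annotations))
        edge_ann <- utils::read.table(config$edge_annotations, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
    } else {
      sim <- config$simulate
      inst <- make_orientation_instance(sim$n, sim$undirected_fraction,
                                        sim$n_pairs, seed = seed_of(1L),
                                        gamma = sim$gamma)
      mixed <- inst$observed
      constraints <- inst$constraints
      res$truth <- inst$truth
    }
    res$mixed <- mixed
    res$constraints <- constraints
    p <- file.path(config$out_dir, "network.graphml")
    write_graph_file(mixed, p, "graphml")
    res$artifacts <- c(res$artifacts, p)
  }

  if (want("orient") && !is.null(mixed)) {
    orient <- if (config$orientation_mode == "exact")
      orient_exact(mixed, constraints)
    else orient_greedy(mixed, constraints, seed = seed_of(2L))
    res$orientation <- orient
    p <- file.path(config$out_dir, "directed.graphml")
    write_graph_file(orient$network, p, "graphml")
    res$artifacts <- c(res$artifacts, p)
  }

  if (want("classify") && !is.null(res$orientation)) {
    cls <- classify_nodes(res$orientation$network)
    res$classification <- cls
    deg <- node_degrees(res$orientation$network)
    lab <- data.frame(node = names(cls$labels), class = unname(cls$labels),
                      stringsAsFactors = FALSE)
    lab <- merge(lab, deg[, c("node", "k_in", "k_out")], by = "node", sort = TRUE)
    p <- file.path(config$out_dir, "labels.tsv")
    write_tsv_artifact(lab, p, hdr)
    res$artifacts <- c(res$artifacts, p)
  }

  if (want("robustness") && !is.null(config$robustness) && !is.null(res$classification)) {
    rb <- config$robustness
    curve <- robustness_curve(res$orientation$network,
                              max_fraction = rb$max_fraction %||% 0.2,
                              step = rb$step %||% 0.05,
                              reps = rb$reps %||% 3L, seed = seed_of(3L))
    res$robustness <- curve
    p <- file.path(config$out_dir, "robustness.tsv")
    write_tsv_artifact(curve, p, hdr)
    res$artifacts <- c(res$artifacts, p)
  }

  if (want("knockdown") && !is.null(config$knockdown) && !is.null(res$orientation)) {
    kd <- config$knockdown
    target <- kd$target
    if (is.null(target)) {
      deg <- node_degrees(res$orientation$network)
      target <- deg$node[order(-deg$k, deg$node)][1L]
    }
    curve <- progressive_knockdown(res$orientation$network, target,
                                   mode = kd$mode %||% "edges",
                                   step = kd$step %||% 0.01,
                                   reps = kd$reps %||% 3L, seed = seed_of(4L))
    res$knockdown <- curve
    p <- file.path(config$out_dir, "knockdown.tsv")
    write_knockdown_curve(curve, p)
    res$artifacts <- c(res$artifacts, p)
  }

  if (want("enrich") && !is.null(res$classification)) {
    if (is.null(annotations)) {
      planted <- plant_attributes(res$classification, synthetic_spec(seed = seed_of(5L)),
                                  network = res$orientation$network,
                                  seed = seed_of(5L))
      annotations <- planted$nodes
      edge_ann <- planted$edges
      res$planted <- planted
    }
    summ <- class_summary(res$classification, annotations, min_coverage = 0.5)
    res$enrichment <- summ
    p <- file.path(config$out_dir, "enrichment.tsv")
    write_tsv_artifact(summ, p, hdr)
    res$artifacts <- c(res$artifacts, p)
    if (!is.null(edge_ann)) {
      crit <- critical_nodes(res$classification)
      red <- names(res$classification$labels)[res$classification$labels == "redundant"]
      net <- res$orientation$network
      ir <- data.frame(
        class = rep(c("critical", "redundant"), each = 2L),
        interface = rep(c("DLI", "DDI"), 2L),
        rate = c(interface_rate(crit, edge_ann, "DLI", nrow(net$edges), length(net$nodes)),
                 interface_rate(crit, edge_ann, "DDI", nrow(net$edges), length(net$nodes)),
                 interface_rate(red, edge_ann, "DLI", nrow(net$edges), length(net$nodes)),
                 interface_rate(red, edge_ann, "DDI", nrow(net$edges), length(net$nodes))),
        stringsAsFactors = FALSE)
      p <- file.path(config$out_dir, "interface_rates.tsv")
      write_tsv_artifact(ir, p, hdr)
      res$artifacts <- c(res$artifacts, p)
    }
  }
  invisible(res)
}
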