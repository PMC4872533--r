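# Reading, assembling and writing interaction networks.
#
# Interaction records carry six fields: protein_a, protein_b, directedness
# ("undirected" or "a_to_b"), evidence ("ppi", "kpi" or "ko"), a free-text
# source label and an optional p-value (meaningful for knockout pairs only).

REC_FIELDS <- c("protein_a", "protein_b", "directedness", "evidence", "source", "p_value")

#' Parse interaction records from a TSV stream
#'
#' Reads a UTF-8, tab-separated file (or character vector of lines) into a
#' data frame of interaction records. Lines starting with `#` are comments.
#' Columns are resolved either from a header row naming the six canonical
#' fields or through `dialect`, a named list/vector mapping canonical field
#' names to column names or 1-based positions (as produced by
#' [yaml::read_yaml()] on a small mapping file).
#'
#' @param path File path, connection, or character vector of lines.
#' @param dialect Optional column mapping, e.g.
#'   `list(protein_a = 1, protein_b = 2, directedness = "dir", ...)`.
#'   Fields absent from the mapping get defaults (`directedness`
#'   "undirected" for ppi, `evidence` "ppi", empty source, `NA` p-value).
#' @return Data frame with columns `protein_a`, `protein_b`, `directedness`,
#'   `evidence`, `source`, `p_value`; one row per data row.
#' @examples
#' recs <- parse_interactions(c(
#'   "protein_a\tprotein_b\tdirectedness\tevidence\tsource\tp_value",
#'   "A\tB\tundirected\tppi\tdb1\t",
#'   "C\tD\ta_to_b\tkpi\tdb2\t"))
#' recs$evidence
#' @export
parse_interactions <- function(path, dialect = NULL) {
  lines <- if (is.character(path) && length(path) > 1L) path
           else if (is.character(path) && !file.exists(path) && grepl("\t", path)) strsplit(path, "\n")[[1]]
           else readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_records())

  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  has_header <- any(tolower(header) %in% REC_FIELDS)
  if (has_header) {
    colmap <- stats::setNames(match(REC_FIELDS, tolower(header)), REC_FIELDS)
    cells <- cells[-1L]
    lineno <- lineno[-1L]
  } else {
    colmap <- stats::setNames(rep(NA_integer_, 6L), REC_FIELDS)
    if (is.null(dialect)) {
      colmap[] <- 1:6  # positional default
    } else {
      for (f in names(dialect)) {
        f0 <- tolower(f)
        if (!f0 %in% REC_FIELDS) stop("unknown field in dialect: ", f)
        v <- dialect[[f]]
        colmap[f0] <- if (is.numeric(v)) as.integer(v) else stop(
          "headerless input: dialect must map '", f, "' to a column position")
      }
    }
  }
  if (anyNA(colmap[c("protein_a", "protein_b")]))
    stop("column mapping does not resolve protein_a/protein_b")
  if (length(cells) == 0L) return(empty_records())

  grab <- function(field, default) {
    i <- colmap[[field]]
    if (is.na(i)) return(rep(default, length(cells)))
    vapply(cells, function(r) if (length(r) >= i && nzchar(r[i])) r[i] else default,
           character(1))
  }
  rec <- data.frame(
    protein_a = grab("protein_a", NA_character_),
    protein_b = grab("protein_b", NA_character_),
    directedness = grab("directedness", "undirected"),
    evidence = grab("evidence", "ppi"),
    source = grab("source", ""),
    p_value = NA_real_,
    stringsAsFactors = FALSE)

  bad_id <- is.na(rec$protein_a) | is.na(rec$protein_b) |
    !nzchar(trimws(rec$protein_a)) | !nzchar(trimws(rec$protein_b))
  if (any(bad_id))
    stop("unparsable node identifiers on line(s) ",
         paste(lineno[bad_id], collapse = ", "))

  praw <- grab("p_value", NA_character_)
  p <- suppressWarnings(as.numeric(praw))
  malformed <- !is.na(praw) & (is.na(p) | p < 0 | p > 1)
  if (any(malformed))
    stop("malformed p_value on line(s) ",
         paste(sprintf("%d ('%s')", lineno[malformed], praw[malformed]), collapse = ", "))
  rec$p_value <- p

  ok_dir <- rec$directedness %in% c("undirected", "a_to_b")
  if (!all(ok_dir)) stop("invalid directedness on line(s) ",
                         paste(lineno[!ok_dir], collapse = ", "))
  ok_ev <- rec$evidence %in% c("ppi", "kpi", "ko")
  if (!all(ok_ev)) stop("invalid evidence on line(s) ",
                        paste(lineno[!ok_ev], collapse = ", "))
  rec
}

empty_records <- function() {
  data.frame(protein_a = character(), protein_b = character(),
             directedness = character(), evidence = character(),
             source = character(), p_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Filter knockout pairs by p-value
#'
#' Retains exactly the knockout (ko) records with `p_value` strictly below
#' the threshold; pairs with p at or above it are discarded. Record order is
#' preserved.
#'
#' @param records Data frame of interaction records, all with
#'   `evidence == "ko"` and a present p-value.
#' @param threshold Exclusive upper bound on the p-value (default 0.001).
#' @return The retained subset of `records`.
#' @export
filter_ko_pairs <- function(records, threshold = 0.001) {
  if (nrow(records) == 0L) return(records)
  if (!all(records$evidence == "ko"))
    stop("filter_ko_pairs expects knockout (ko) records only")
  miss <- is.na(records$p_value)
  if (any(miss))
    stop("missing p_value for ko pair(s): ",
         paste(paste(records$protein_a[miss], records$protein_b[miss], sep = "->")[
           seq_len(min(5L, sum(miss)))], collapse = ", "))
  records[records$p_value < threshold, , drop = FALSE]
}

#' Assemble a mixed graph from interaction records
#'
#' Applies the network-compilation rules to the multiset of records,
#' independent of their order:
#' \itemize{
#'   \item self loops are removed (their node is retained);
#'   \item duplicate interactions collapse;
#'   \item kinase/phosphatase-substrate (kpi) and knockout (ko) records are
#'     directed by nature and enter as a-to-b directed edges whatever their
#'     `directedness` field says;
#'   \item when both a directed and an undirected edge connect the same node
#'     pair, only the directed edge is kept;
#'   \item a pair directed in both opposite directions collapses to a single
#'     undirected edge.
#' }
#'
#' @param records Data frame of interaction records (see
#'   [parse_interactions()]).
#' @return A [mixed_graph()].
#' @examples
#' r <- data.frame(protein_a = c("A", "A"), protein_b = c("B", "B"),
#'                 directedness = c("undirected", "a_to_b"),
#'                 evidence = c("ppi", "kpi"), source = "", p_value = NA)
#' assemble(r)  # directed edge A->B wins
#' @export
assemble <- function(records) {
  if (nrow(records) == 0L) return(mixed_graph())
  nodes <- unique(c(records$protein_a, records$protein_b))
  loop <- records$protein_a == records$protein_b
  records <- records[!loop, , drop = FALSE]
  if (nrow(records) == 0L) return(mixed_graph(nodes = nodes))

  born_directed <- records$evidence %in% c("kpi", "ko") |
    records$directedness == "a_to_b"
  dm <- edge_matrix(cbind(records$protein_a, records$protein_b))[born_directed, , drop = FALSE]
  um <- sort_pairs(edge_matrix(cbind(records$protein_a, records$protein_b))[
    !born_directed, , drop = FALSE])

  dm <- dm[!duplicated(pair_key(dm)), , drop = FALSE]
  um <- um[!duplicated(pair_key(um)), , drop = FALSE]

  # antiparallel directed pairs -> one undirected edge
  rev_key <- pair_key(dm[, 2:1, drop = FALSE])
  anti <- pair_key(dm) %in% rev_key
  if (any(anti)) {
    um <- rbind(um, sort_pairs(dm[anti, , drop = FALSE]))
    um <- um[!duplicated(pair_key(um)), , drop = FALSE]
    dm <- dm[!anti, , drop = FALSE]
  }
  # directed beats undirected on the same pair
  um <- um[!(pair_key(um) %in% pair_key(sort_pairs(dm))), , drop = FALSE]
  mixed_graph(nodes = nodes, directed = dm, undirected = um)
}

#' Induced subgraph on a node set
#'
#' Restricts a graph to `nodes(g)` intersected with `keep`; edges survive
#' only when both endpoints are retained. Works for mixed graphs and
#' directed networks alike (used e.g. to keep only empirically reported
#' phosphoproteins).
#'
#' @param g A `mixed_graph` or `directed_network`.
#' @param keep Character vector of node identifiers to retain.
#' @return A graph of the same class as `g`.
#' @export
induced_subgraph_net <- function(g, keep) {
  keep <- unique(as.character(keep))
  nodes <- intersect(g$nodes, keep)
  sel <- function(m) m[m[, 1L] %in% nodes & m[, 2L] %in% nodes, , drop = FALSE]
  if (inherits(g, "directed_network"))
    return(directed_network(nodes = nodes, edges = sel(g$edges)))
  mixed_graph(nodes = nodes, directed = sel(g$directed), undirected = sel(g$undirected))
}

#' Read or write a graph file
#'
#' Supported formats:
#' \describe{
#'   \item{`tsv_edgelist`}{Tab-separated, `#` comments. Edge rows are
#'     `from TAB to TAB directed` (`directed` in TRUE/FALSE); isolated nodes
#'     are preserved as rows with an empty second column.}
#'   \item{`sif`}{Cytoscape simple interaction format, `A rel B`; a line
#'     with a single token declares an isolated node. Directedness of all
#'     edges is set by the `directed` flag.}
#'   \item{`graphml`}{GraphML via igraph, with a boolean edge attribute
#'     `directed` distinguishing directed from undirected edges.}
#' }
#' `write_graph_file()` followed by `read_graph_file()` is the identity on
#' nodes, edges and directedness flags.
#'
#' @param g A `mixed_graph` or `directed_network` (write).
#' @param path File path.
#' @param format One of `"tsv_edgelist"`, `"sif"`, `"graphml"`.
#' @param as Class to return on read: `"auto"` (mixed graph unless every
#'   edge is directed), `"mixed_graph"` or `"directed_network"`.
#' @param directed For SIF input/output: are its edges directed?
#' @param header Optional character vector written as leading `#` comment
#'   lines (tsv_edgelist and sif).
#' @return `read_graph_file()` returns a graph; `write_graph_file()` returns
#'   `path` invisibly.
#' @export
write_graph_file <- function(g, path, format = c("tsv_edgelist", "sif", "graphml"),
                             directed = FALSE, header = NULL) {
  format <- match.arg(format)
  dm <- if (inherits(g, "directed_network")) g$edges else g$directed
  um <- if (inherits(g, "directed_network")) matrix(character(), ncol = 2) else g$undirected
  iso <- setdiff(g$nodes, c(dm, um))
  if (format == "tsv_edgelist") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    writeLines("from\tto\tdirected", con)
    if (nrow(dm)) writeLines(paste(dm[, 1], dm[, 2], "TRUE", sep = "\t"), con)
    if (nrow(um)) writeLines(paste(um[, 1], um[, 2], "FALSE", sep = "\t"), con)
    if (length(iso)) writeLines(paste(iso, "", "", sep = "\t"), con)
  } else if (format == "sif") {
    if (nrow(dm) && nrow(um))
      stop("SIF cannot carry mixed directedness; write directed and undirected parts separately")
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    m <- rbind(dm, um)
    if (nrow(m)) writeLines(paste(m[, 1], "int", m[, 2], sep = "\t"), con)
    if (length(iso)) writeLines(iso, con)
  } else {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path, format = c("tsv_edgelist", "sif", "graphml"),
                            as = c("auto", "mixed_graph", "directed_network"),
                            directed = FALSE) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (!file.exists(path)) stop("cannot read graph file: ", path)
  if (format == "tsv_edgelist") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    cells <- strsplit(lines, "\t", fixed = TRUE)
    if (length(cells) && identical(tolower(cells[[1L]][1:2]), c("from", "to")))
      cells <- cells[-1L]
    from <- vapply(cells, `[`, character(1), 1L)
    to <- vapply(cells, function(x) if (length(x) >= 2L) x[2L] else "", character(1))
    dirflag <- vapply(cells, function(x) if (length(x) >= 3L) x[3L] else "", character(1))
    iso <- from[!nzchar(to)]
    e_from <- from[nzchar(to)]
    e_to <- to[nzchar(to)]
    e_dir <- toupper(dirflag[nzchar(to)]) %in% c("TRUE", "1", "T")
    dm <- cbind(e_from, e_to)[e_dir, , drop = FALSE]
    um <- cbind(e_from, e_to)[!e_dir, , drop = FALSE]
  } else if (format == "sif") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    cells <- strsplit(lines, "[\t ]+")
    iso <- unlist(lapply(cells, function(x) if (length(x) == 1L) x else NULL))
    em <- do.call(rbind, lapply(cells, function(x)
      if (length(x) >= 3L) c(x[1L], x[3L]) else NULL))
    if (is.null(em)) em <- matrix(character(), ncol = 2)
    dm <- if (directed) em else matrix(character(), ncol = 2)
    um <- if (directed) matrix(character(), ncol = 2) else em
  } else if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    em <- igraph::as_edgelist(ig, names = TRUE)
    storage.mode(em) <- "character"
    dflag <- igraph::edge_attr(ig, "directed")
    if (is.null(dflag)) dflag <- rep(igraph::is_directed(ig), nrow(em))
    dflag <- as.logical(dflag)
    dm <- em[dflag, , drop = FALSE]
    um <- em[!dflag, , drop = FALSE]
    iso <- setdiff(igraph::V(ig)$name, em)
  }
  nodes <- unique(c(iso, dm, um))
  if (as == "directed_network" || (as == "auto" && nrow(edge_matrix(um)) == 0L &&
                                   format == "graphml" && nrow(edge_matrix(dm)) > 0L)) {
    if (nrow(edge_matrix(um)) > 0L)
      stop("file contains undirected edges; cannot return a directed_network")
    return(directed_network(nodes = nodes, edges = dm))
  }
  if (as == "auto" && format != "graphml" && nrow(edge_matrix(um)) == 0L &&
      nrow(edge_matrix(dm)) > 0L)
    return(directed_network(nodes = nodes, edges = dm))
  mixed_graph(nodes = nodes, directed = dm, undirected = um)
}
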