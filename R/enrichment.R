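# Node/edge annotation statistics: enrichment of attributes in
# controllability classes, interface-type rates, complex overlap, hub
# detection and degree-distribution fitting.

#' Fisher exact enrichment of an attribute in a class
#'
#' Builds the 2x2 table (in class x has attribute) and returns the
#' two-sided Fisher exact p-value (sum of hypergeometric probabilities of
#' tables no more likely than the observed one) together with the sample
#' odds ratio `ad / bc` (infinite when `bc = 0` and `ad > 0`).
#'
#' @param in_class Logical vector, one flag per node.
#' @param has_attr Logical vector, same length.
#' @return An `enrichment_result`: list with `table` (2x2 matrix, rows =
#'   in-class yes/no, cols = attribute yes/no), `odds_ratio`, `p_value`,
#'   `adjusted_p` (NA here; filled by [class_summary()]).
#' @examples
#' r <- fisher_enrichment(rep(c(TRUE, FALSE), c(5, 5)),
#'                        rep(c(TRUE, FALSE), c(5, 5)))
#' r$p_value  # 2/252
#' @export
fisher_enrichment <- function(in_class, has_attr) {
  if (length(in_class) == 0L) stop("empty node universe")
  if (length(in_class) != length(has_attr)) stop("flag vectors differ in length")
  a <- sum(in_class & has_attr)
  b <- sum(in_class & !has_attr)
  c_ <- sum(!in_class & has_attr)
  d <- sum(!in_class & !has_attr)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(class = c("yes", "no"), attr = c("yes", "no")))
  p <- stats::fisher.test(tab)$p.value
  or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NaN
  structure(list(table = tab, odds_ratio = or, p_value = min(p, 1),
                 adjusted_p = NA_real_),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: OR = %.3g, p = %.3g\n", x$odds_ratio, x$p_value))
  print(x$table)
  invisible(x)
}

#' Rank-based comparison of numeric distributions between classes
#'
#' Two groups: two-sided Wilcoxon rank-sum with tie correction. More
#' groups: Kruskal-Wallis.
#'
#' @param groups Named list of numeric vectors, one per class; all
#'   non-empty (exactly 2 for `wilcoxon_ranksum`).
#' @param test `"wilcoxon_ranksum"` or `"kruskal_wallis"`.
#' @return List with `statistic`, `p_value`, `test`.
#' @export
compare_numeric <- function(groups, test = c("wilcoxon_ranksum", "kruskal_wallis")) {
  test <- match.arg(test)
  if (any(lengths(groups) == 0L))
    stop("empty group(s): ", paste(names(groups)[lengths(groups) == 0L], collapse = ", "))
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (test == "wilcoxon_ranksum") {
    if (length(groups) != 2L) stop("wilcoxon_ranksum needs exactly 2 groups")
    ht <- suppressWarnings(stats::wilcox.test(groups[[1L]], groups[[2L]]))
  } else {
    ht <- stats::kruskal.test(groups)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
}

#' Relative per-node PTM frequency, critical vs redundant
#'
#' Fraction of critical nodes carrying at least one site of the given
#' modification divided by the same fraction among redundant nodes.
#' Infinite when only critical nodes carry it; `NA` (with a warning) when
#' neither group does.
#'
#' @param critical,redundant Annotation data frames (rows = nodes) with a
#'   count column for the modification.
#' @param ptm Column name, e.g. `"ptm_sumo"`.
#' @return Ratio of per-node frequencies.
#' @export
ptm_relative_frequency <- function(critical, redundant, ptm) {
  if (nrow(critical) == 0L || nrow(redundant) == 0L) stop("both groups must be non-empty")
  if (!ptm %in% names(critical) || !ptm %in% names(redundant))
    stop("no such PTM column: ", ptm)
  fc <- mean(critical[[ptm]] >= 1)
  fr <- mean(redundant[[ptm]] >= 1)
  if (fc == 0 && fr == 0) {
    warning("modification '", ptm, "' absent from both groups; ratio undefined")
    return(NA_real_)
  }
  if (fr == 0) return(Inf)
  fc / fr
}

#' Normalised interface-type interaction rate for a node class
#'
#' Counts the annotated edges of the given interface type (DDI or DLI)
#' incident to at least one class member, divides by the total number of
#' interactions, then by the total number of proteins in the network.
#'
#' @param class_nodes Character vector of class members.
#' @param edge_annotations Data frame with columns `source`, `target`,
#'   `interface` (`"DDI"`, `"DLI"` or `"unknown"`).
#' @param interface Interface type to count.
#' @param total_interactions,total_nodes Whole-network totals (> 0).
#' @param per_class Normalise by the class size instead of the whole
#'   network (alternative reading of the denominator).
#' @return Non-negative rate.
#' @export
interface_rate <- function(class_nodes, edge_annotations, interface = c("DLI", "DDI"),
                           total_interactions, total_nodes, per_class = FALSE) {
  interface <- match.arg(interface)
  if (total_interactions <= 0 || total_nodes <= 0) stop("totals must be positive")
  hit <- edge_annotations$interface == interface &
    (edge_annotations$source %in% class_nodes |
       edge_annotations$target %in% class_nodes)
  denom <- if (per_class) length(class_nodes) else total_nodes
  (sum(hit) / total_interactions) / denom
}

#' Jaccard index between two sets
#'
#' `|A intersect B| / |A union B|`; used for overlap between protein
#' complexes or between paralog subnetworks.
#'
#' @param a,b Vectors treated as sets; their union must be non-empty.
#' @return Index in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) stop("both sets are empty; Jaccard undefined")
  length(intersect(a, b)) / length(u)
}

#' Hub nodes (top 10% by total degree)
#'
#' Nodes whose total degree is at least the `ceiling(0.1 * N)`-th largest
#' degree; ties at the threshold are included, so at least 10% of nodes
#' are always returned.
#'
#' @param d A `directed_network`.
#' @param top Fraction defining a hub (default 0.1).
#' @return Character vector of hub node identifiers.
#' @export
hubs <- function(d, top = 0.1) {
  deg <- node_degrees(d)
  if (nrow(deg) == 0L) stop("empty network")
  thr <- sort(deg$k, decreasing = TRUE)[ceiling(top * nrow(deg))]
  deg$node[deg$k >= thr]
}

# Hurwitz zeta via Euler-Maclaurin (enough terms for gamma in (1, 6])
hurwitz_zeta <- function(gamma, xmin, terms = 1000L) {
  j <- 0:(terms - 1L)
  head_sum <- sum((xmin + j)^(-gamma))
  x <- xmin + terms
  head_sum + x^(1 - gamma) / (gamma - 1) + 0.5 * x^(-gamma) +
    gamma * x^(-gamma - 1) / 12
}

#' Discrete power-law fit of a degree distribution
#'
#' Maximum-likelihood exponent of `P(k) ~ k^-gamma` on the degree tail
#' `k >= xmin`. With `xmin = "auto"` the cutoff is chosen by minimising the
#' Kolmogorov-Smirnov distance (plfit, via igraph); with a fixed `xmin` the
#' discrete likelihood (normalised by the Hurwitz zeta function) is
#' maximised numerically.
#'
#' @param degrees Positive integer degrees.
#' @param xmin Integer cutoff, or `"auto"`.
#' @return A `power_law_fit`: list with `exponent`, `xmin`, `n_tail`,
#'   `ks_stat` (auto mode only).
#' @export
fit_power_law_net <- function(degrees, xmin = 1L) {
  degrees <- degrees[degrees > 0]
  if (identical(xmin, "auto")) {
    fit <- igraph::fit_power_law(degrees, implementation = "plfit")
    n_tail <- sum(degrees >= fit$xmin)
    check_tail(degrees[degrees >= fit$xmin])
    return(structure(list(exponent = fit$alpha, xmin = fit$xmin,
                          n_tail = n_tail, ks_stat = fit$KS.stat),
                     class = "power_law_fit"))
  }
  xmin <- as.integer(xmin)
  tail <- degrees[degrees >= xmin]
  check_tail(tail)
  slk <- sum(log(tail))
  nll <- function(g) length(tail) * log(hurwitz_zeta(g, xmin)) + g * slk
  opt <- stats::optimize(nll, interval = c(1.01, 8))
  structure(list(exponent = opt$minimum, xmin = xmin, n_tail = length(tail),
                 ks_stat = NA_real_),
            class = "power_law_fit")
}

check_tail <- function(tail) {
  if (length(tail) < 50L)
    stop("power-law fit needs at least 50 tail observations (got ", length(tail), ")")
  if (length(unique(tail)) == 1L)
    stop("degenerate tail: all degrees equal")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: gamma = %.3f (xmin = %d, n_tail = %d)\n",
              x$exponent, x$xmin, x$n_tail))
  invisible(x)
}

binary_attrs <- function(ann) {
  out <- list()
  for (col in grep("^ptm_", names(ann), value = TRUE)) out[[col]] <- ann[[col]] >= 1
  for (col in intersect(c("mirna_target", "phospho_domain"), names(ann)))
    out[[col]] <- as.logical(ann[[col]])
  if ("complexes" %in% names(ann)) out[["in_complex"]] <- nzchar(ann$complexes)
  out
}

attr_family <- function(attr) {
  if (grepl("^ptm_", attr)) "ptm"
  else if (attr %in% c("k", "disorder_fraction", "degradation_rate")) "distribution"
  else "regulation"
}

#' Per-class summary table with enrichment statistics
#'
#' For each annotation attribute, reports class sizes and summaries plus a
#' test of class association: numeric attributes (`k`, `disorder_fraction`,
#' `degradation_rate`) are compared across the three classes by
#' Kruskal-Wallis; binary attributes (PTM presence, miRNA-target flag,
#' phospho-binding-domain flag, complex membership) are tested for
#' critical-vs-redundant enrichment by Fisher's exact test. Raw p-values
#' are always reported; Benjamini-Hochberg adjusted p-values are added
#' within each attribute family unless `adjust = FALSE` (parity with
#' analyses that report raw p only).
#'
#' @param classification A `control_classification`, or a named character
#'   vector of class labels.
#' @param annotations Data frame with a `node` column and any of the
#'   attribute columns above (PTM counts in `ptm_*` columns; `complexes`
#'   as a semicolon-separated string).
#' @param min_coverage Minimum fraction of classified nodes that must be
#'   annotated (default 1).
#' @param adjust Add BH-adjusted p-values.
#' @return Data frame with one row per attribute: `attribute`, `family`,
#'   `type`, per-class `n`, per-class summary (median or fraction),
#'   `statistic`, `odds_ratio` (binary rows), `p_value`, `adjusted_p`.
#' @export
class_summary <- function(classification, annotations, min_coverage = 1,
                          adjust = TRUE) {
  labels <- if (inherits(classification, "control_classification"))
    classification$labels else classification
  if (is.null(names(labels))) stop("labels must be named by node")
  missing_nodes <- setdiff(names(labels), annotations$node)
  cov <- 1 - length(missing_nodes) / length(labels)
  if (cov < min_coverage)
    stop("annotation coverage ", sprintf("%.2f", cov), " below minimum ",
         min_coverage, "; missing nodes: ",
         paste(utils::head(missing_nodes, 10L), collapse = ", "),
         if (length(missing_nodes) > 10L) ", ..." else "")
  ann <- annotations[annotations$node %in% names(labels), , drop = FALSE]
  cls <- labels[ann$node]
  classes <- c("critical", "redundant", "ordinary")

  rows <- list()
  for (col in intersect(c("k", "disorder_fraction", "degradation_rate"), names(ann))) {
    vals <- split(ann[[col]], factor(cls, levels = classes))
    vals <- lapply(vals, function(v) v[!is.na(v)])
    nonempty <- vals[lengths(vals) > 0]
    ht <- if (length(nonempty) >= 2L) compare_numeric(nonempty, "kruskal_wallis")
          else list(statistic = NA_real_, p_value = NA_real_)
    rows[[col]] <- data.frame(
      attribute = col, family = attr_family(col), type = "numeric",
      n_critical = length(vals$critical), n_redundant = length(vals$redundant),
      n_ordinary = length(vals$ordinary),
      critical = stats::median(vals$critical), redundant = stats::median(vals$redundant),
      ordinary = stats::median(vals$ordinary),
      statistic = ht$statistic, odds_ratio = NA_real_, p_value = ht$p_value,
      stringsAsFactors = FALSE)
  }
  for (col in names(binary_attrs(ann))) {
    flag <- binary_attrs(ann)[[col]]
    cr <- cls == "critical"; rd <- cls == "redundant"
    fe <- fisher_enrichment(cls[cr | rd] == "critical", flag[cr | rd])
    rows[[col]] <- data.frame(
      attribute = col, family = attr_family(col), type = "binary",
      n_critical = sum(cr), n_redundant = sum(rd), n_ordinary = sum(cls == "ordinary"),
      critical = mean(flag[cr]), redundant = mean(flag[rd]),
      ordinary = mean(flag[cls == "ordinary"]),
      statistic = NA_real_, odds_ratio = fe$odds_ratio, p_value = fe$p_value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no recognised attribute columns in annotations")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$adjusted_p <- NA_real_
  if (adjust) {
    for (fam in unique(out$family)) {
      i <- out$family == fam
      out$adjusted_p[i] <- stats::p.adjust(out$p_value[i], method = "BH")
    }
  }
  out
}
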