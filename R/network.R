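#' Abundance filter for network construction
#'
#' Retains taxa whose mean relative abundance across samples is at least
#' `min_mean_rel`; taxa strictly below the bound (default 0.01%) are
#' dropped before correlation screening.
#'
#' @param table_rel Relative-abundance samples x taxa table.
#' @param min_mean_rel Minimum mean relative abundance (default `1e-4`).
#' @return Filtered tibble.
#' @export
filter_for_network <- function(table_rel, min_mean_rel = 1e-4) {
  m <- asv_matrix(table_rel)
  as_asv_table(m[, colMeans(m) >= min_mean_rel, drop = FALSE])
}

#' Spearman co-occurrence network
#'
#' Tests every taxon pair with Spearman rank correlation (t approximation
#' for the p value, valid under ties) and keeps an edge when
#' `|rho| > rho_threshold` (strict) and the Benjamini-Hochberg adjusted p
#' over all tested pairs is below `fdr_alpha`.  Edge signs are recorded;
#' constant taxa are skipped with a warning (rho undefined).
#'
#' @inheritParams filter_for_network
#' @param rho_threshold Absolute-correlation threshold (strict `>`).
#' @param fdr_alpha FDR threshold on the BH-adjusted p values.
#' @param positive_only Keep only positive correlations.
#' @return Object of class `cooccurrence_network`: list with `nodes`
#'   (taxa incident to at least one edge), `edges` (tibble `taxon_a`,
#'   `taxon_b`, `rho`, `p_value`, `q_value`, `sign`), `n_tested`.
#' @export
spearman_edges <- function(table_rel, rho_threshold = 0.6, fdr_alpha = 0.05,
                           positive_only = FALSE) {
  m <- asv_matrix(table_rel)
  n <- nrow(m)
  if (n < 4) stop("need at least 4 samples for correlation screening")
  constant <- apply(m, 2, function(v) length(unique(v)) == 1)
  if (any(constant)) {
    warning("skipping constant taxa: ",
            paste(colnames(m)[constant], collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  taxa <- colnames(m)
  if (length(taxa) < 2) stop("fewer than two variable taxa")
  rho <- cor(m, method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  keep <- abs(r) > rho_threshold & q < fdr_alpha
  if (positive_only) keep <- keep & r > 0
  edges <- tibble::tibble(taxon_a = taxa[idx[keep, 1]],
                          taxon_b = taxa[idx[keep, 2]],
                          rho = r[keep], p_value = p[keep], q_value = q[keep],
                          sign = ifelse(r[keep] > 0, "positive", "negative"))
  cooccurrence_network(edges, n_tested = length(r))
}

#' Construct a co-occurrence network from an edge table
#'
#' @param edges Tibble with columns `taxon_a`, `taxon_b` (plus optional
#'   `rho`, `sign`, ...), one row per unordered pair, no self-loops.
#' @param nodes Node ids; defaults to the taxa incident to the edges.
#' @param n_tested Number of pairs screened (bookkeeping for FDR reporting).
#' @return A `cooccurrence_network` object.
#' @export
cooccurrence_network <- function(edges, nodes = NULL, n_tested = NA_integer_) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) && any(edges$taxon_a == edges$taxon_b)) stop("self-loop in edge table")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  structure(list(nodes = nodes, edges = edges, n_tested = n_tested),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' @method tidy cooccurrence_network
#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("taxon_a", "taxon_b")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes))
}

#' Topological summary of a co-occurrence network
#'
#' Six network-level features: graph density `2E / (N (N - 1))`, average
#' degree `2E / N`, mean local clustering coefficient (nodes of degree < 2
#' contribute 0), diameter and average path length over the largest
#' connected component, and modularity of the best greedy
#' (Clauset-Newman-Moore) partition of the unweighted graph — a
#' deterministic, seedless algorithm.  An empty network returns all zeros
#' with a warning.
#'
#' @param network A `cooccurrence_network` object.
#' @return One-row tibble `n_nodes`, `n_edges`, `diameter`, `modularity`,
#'   `clustering_coefficient`, `graph_density`, `average_degree`,
#'   `average_path_length`.
#' @export
network_metrics <- function(network) {
  g <- as_igraph(network)
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  if (E == 0) {
    warning("empty network; all metrics reported as 0")
    return(tibble::tibble(n_nodes = N, n_edges = 0, diameter = 0, modularity = 0,
                          clustering_coefficient = 0, graph_density = 0,
                          average_degree = 0, average_path_length = 0))
  }
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  cl <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  mod <- igraph::modularity(igraph::cluster_fast_greedy(g))
  tibble::tibble(
    n_nodes = N, n_edges = E,
    diameter = igraph::diameter(giant, unconnected = FALSE),
    modularity = mod,
    clustering_coefficient = cl,
    graph_density = 2 * E / (N * (N - 1)),
    average_degree = 2 * E / N,
    average_path_length = igraph::mean_distance(giant))
}

#' @method glance cooccurrence_network
#' @export
glance.cooccurrence_network <- function(x, ...) network_metrics(x)
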