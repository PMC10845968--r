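# Spearman co-occurrence network: all-pairs correlation screening, edge
# rule, network-level topology, node centralities (Gephi-compatible
# conventions), and the centrality-threshold hub classifier.

#' All-pairs Spearman correlation of taxa
#'
#' Tie-corrected Spearman rho between every pair of taxa on per-sample
#' relative abundances, with two-sided p-values from the t approximation
#' `t = rho*sqrt((n-2)/(1-rho^2))` (`|rho| = 1` gives `p = 0`). Taxa present
#' in fewer than `min_prevalence` samples are dropped first to avoid
#' degenerate rank vectors; taxa constant across samples yield `NA` rho/p
#' for their pairs.
#'
#' @param table Abundance table (or counts matrix) with >= 4 samples.
#' @param min_prevalence Minimum number of samples a taxon must be present
#'   in (default 3).
#' @return An object of class `spearman_matrix`: `rho` and `p` matrices over
#'   the retained taxa, `n_samples`, `taxa`, and their `mean_rel_abundance`.
#' @export
spearman_matrix <- function(table, min_prevalence = 3) {
  cts <- count_matrix(table)
  if (nrow(cts) < 4L) {
    stopf("co-occurrence screening needs >= 4 samples (got %d)", nrow(cts))
  }
  keep <- colSums(cts > 0) >= check_count(min_prevalence, "min_prevalence", 0L)
  if (!any(keep)) stopf("no taxa pass the prevalence filter")
  rel <- relative_abundance(cts)[, keep, drop = FALSE]
  n <- nrow(rel)
  rho <- suppressWarnings(stats::cor(rel, method = "spearman"))
  p <- array(spearman_p_tapprox(rho, n), dim = dim(rho), dimnames = dimnames(rho))
  diag(p) <- NA_real_
  structure(list(rho = rho, p = p, n_samples = n, taxa = colnames(rel),
                 mean_rel_abundance = colMeans(rel)),
            class = "spearman_matrix")
}

#' Edge rule for the co-occurrence network
#'
#' An edge joins two taxa iff `|rho| > rho_threshold` and
#' `p < p_threshold` (both strict).
#'
#' @param rho_threshold Correlation magnitude threshold in (0, 1);
#'   default 0.6.
#' @param p_threshold Significance threshold in (0, 1); default 0.05.
#' @return A list of class `edge_rule`.
#' @export
edge_rule <- function(rho_threshold = 0.6, p_threshold = 0.05) {
  structure(list(
    rho_threshold = check_fraction(rho_threshold, "rho_threshold", 1e-12, 1 - 1e-12),
    p_threshold = check_fraction(p_threshold, "p_threshold", 1e-12, 1 - 1e-12)),
    class = "edge_rule")
}

#' Build the co-occurrence network
#'
#' Applies the [edge_rule()] to a Spearman screen; nodes are the endpoints
#' of surviving edges (isolated taxa are excluded), edges carry rho and
#' sign. Pairs with `NA` rho or p never form edges.
#'
#' @param rho A `spearman_matrix` object, or a symmetric rho matrix.
#' @param p Matching p matrix (ignored when `rho` is a `spearman_matrix`).
#' @param rule An [edge_rule()].
#' @param mean_abundance Optional named mean relative abundances attached to
#'   nodes (taken from the `spearman_matrix` when available).
#' @return An object of class `cooccurrence_network`: `graph` (igraph),
#'   `edges` (data.frame from/to/rho/p/sign), `nodes` (data.frame with taxon
#'   and mean relative abundance), `rule`.
#' @export
build_network <- function(rho, p = NULL, rule = edge_rule(),
                          mean_abundance = NULL) {
  if (inherits(rho, "spearman_matrix")) {
    sm <- rho
    rho <- sm$rho; p <- sm$p
    if (is.null(mean_abundance)) mean_abundance <- sm$mean_rel_abundance
  }
  if (is.null(p)) stopf("`p` matrix is required")
  if (!identical(dim(rho), dim(p)) || !identical(dimnames(rho), dimnames(p))) {
    stopf("rho and p matrices must share dimensions and taxon names")
  }
  if (is.null(rownames(rho))) stopf("rho matrix must carry taxon names")
  ut <- upper.tri(rho)
  sel <- ut & !is.na(rho) & !is.na(p) &
    abs(rho) > rule$rho_threshold & p < rule$p_threshold
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(rho)[idx[, 1L]],
    to = colnames(rho)[idx[, 2L]],
    rho = rho[idx],
    p = p[idx],
    sign = ifelse(rho[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  node_ids <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = if (length(node_ids)) node_ids else NULL)
  nodes <- data.frame(taxon = node_ids, stringsAsFactors = FALSE)
  nodes$mean_rel_abundance <- if (!is.null(mean_abundance) && length(node_ids)) {
    unname(mean_abundance[node_ids])
  } else {
    rep(NA_real_, length(node_ids))
  }
  structure(list(graph = g, edges = edges, nodes = nodes, rule = rule),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (|rho| > %g, p < %g)\n",
              nrow(x$nodes), nrow(x$edges),
              x$rule$rho_threshold, x$rule$p_threshold))
  if (nrow(x$edges)) {
    cat(sprintf("  %.1f%% positive / %.1f%% negative edges\n",
                100 * mean(x$edges$sign == "positive"),
                100 * mean(x$edges$sign == "negative")))
  }
  invisible(x)
}

#' @export
plot.cooccurrence_network <- function(x, ...) {
  igraph::plot.igraph(
    x$graph,
    edge.color = ifelse(igraph::E(x$graph)$sign == "positive", "firebrick",
                        "forestgreen"),
    vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Average degree of a network
#'
#' `avgK = 2 * n_edges / n_nodes`, the network-level average connectivity.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges.
#' @return The average degree.
#' @export
avg_degree <- function(n_nodes, n_edges) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  2 * check_count(n_edges, "n_edges", 0L) / n_nodes
}

#' Network-level topology summary
#'
#' Average degree (`avgK = 2E/N`), average local clustering coefficient
#' (nodes with degree < 2 contribute 0), average shortest-path length over
#' connected pairs only, modularity Q of a seeded Louvain partition, and
#' edge-sign percentages. An empty network returns all zeros with a warning.
#'
#' @param net A `cooccurrence_network`.
#' @param seed Seed for the Louvain community search (Q depends on the
#'   partition found).
#' @return A list of class `network_topology` with fields `n_nodes`,
#'   `n_edges`, `avgK`, `avgCC`, `avg_path`, `modularity`,
#'   `pct_positive_edges`, `pct_negative_edges`.
#' @export
network_topology <- function(net, seed = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) {
    warnf("empty network: topology is all-zero")
    return(structure(list(n_nodes = 0L, n_edges = 0L, avgK = 0, avgCC = 0,
                          avg_path = 0, modularity = 0,
                          pct_positive_edges = 0, pct_negative_edges = 0),
                     class = "network_topology"))
  }
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  apl <- if (e > 0L) igraph::mean_distance(g, directed = FALSE, unconnected = TRUE) else 0
  q <- if (e > 0L) {
    comm <- with_seed(seed, igraph::cluster_louvain(g))
    igraph::modularity(comm)
  } else 0
  structure(list(
    n_nodes = n, n_edges = e,
    avgK = avg_degree(n, e),
    avgCC = mean(cc),
    avg_path = apl,
    modularity = q,
    pct_positive_edges = if (e > 0L) 100 * mean(net$edges$sign == "positive") else 0,
    pct_negative_edges = if (e > 0L) 100 * mean(net$edges$sign == "negative") else 0),
    class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(paste0(
    "network_topology: %d nodes, %d edges\n",
    "  avgK %.1f | avgCC %.2f | avg path %.2f | modularity %.2f\n",
    "  edges: %.1f%% positive, %.1f%% negative\n"),
    x$n_nodes, x$n_edges, x$avgK, x$avgCC, x$avg_path, x$modularity,
    x$pct_positive_edges, x$pct_negative_edges))
  invisible(x)
}

#' Node centralities
#'
#' Degree centrality `k/(N-1)`, Brandes shortest-path betweenness normalized
#' by `(N-1)(N-2)/2`, and Wasserman-Faust closeness: within the node's
#' component `(N_c - 1)/sum(d)`, scaled by `(N_c - 1)/(N - 1)` so values are
#' comparable across components of a disconnected graph (Gephi's
#' convention).
#'
#' @param net A `cooccurrence_network` with >= 2 nodes.
#' @return A data.frame with columns `taxon`, `degree_centrality`,
#'   `betweenness_centrality`, `closeness_centrality`; all in \[0, 1\].
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 2L) stopf("centralities need at least 2 nodes")
  deg <- igraph::degree(g) / (n - 1)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  d <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    nc1 <- sum(reach)
    if (nc1 == 0L) return(0)
    (nc1 / sum(di[reach])) * (nc1 / (n - 1))
  }, numeric(1))
  data.frame(taxon = igraph::V(g)$name,
             degree_centrality = unname(deg),
             betweenness_centrality = unname(btw),
             closeness_centrality = clo,
             stringsAsFactors = FALSE)
}

#' Hub (core) classification rule
#'
#' A node is a hub iff it strictly exceeds all three centrality thresholds.
#'
#' @param degree_min Degree-centrality threshold (default 0.2).
#' @param closeness_min Closeness threshold (default 0.35).
#' @param betweenness_min Betweenness threshold (default 0.35).
#' @return A list of class `hub_rule`.
#' @export
hub_rule <- function(degree_min = 0.2, closeness_min = 0.35,
                     betweenness_min = 0.35) {
  structure(list(
    degree_min = check_fraction(degree_min, "degree_min", 1e-12, 1 - 1e-12),
    closeness_min = check_fraction(closeness_min, "closeness_min", 1e-12, 1 - 1e-12),
    betweenness_min = check_fraction(betweenness_min, "betweenness_min", 1e-12, 1 - 1e-12)),
    class = "hub_rule")
}

#' Hub-rule core microbiome
#'
#' Nodes strictly exceeding all three [hub_rule()] thresholds, sorted by
#' degree centrality descending (ties broken lexicographically).
#'
#' @param net A `cooccurrence_network`.
#' @param rule A [hub_rule()].
#' @return Character vector of hub taxa.
#' @export
hub_core <- function(net, rule = hub_rule()) {
  if (igraph::vcount(net$graph) < 2L) return(character(0))
  ct <- centralities(net)
  hit <- ct$degree_centrality > rule$degree_min &
    ct$closeness_centrality > rule$closeness_min &
    ct$betweenness_centrality > rule$betweenness_min
  ct <- ct[hit, , drop = FALSE]
  ct$taxon[order(-ct$degree_centrality, ct$taxon)]
}

#' Combined core microbiome
#'
#' The union of the membership core (present in every sample, top abundance
#' ranks) and the hub core (network centrality thresholds), with the rule
#' parameters that produced them.
#'
#' @param membership Character vector from [membership_core()].
#' @param hubs Character vector from [hub_core()].
#' @param rule_params Optional list of the thresholds used.
#' @return An object of class `core_set`: `membership_core`, `hub_core`,
#'   `combined` (union), `rule_params`.
#' @export
core_set <- function(membership, hubs, rule_params = list()) {
  structure(list(membership_core = as.character(membership),
                 hub_core = as.character(hubs),
                 combined = union(as.character(membership), as.character(hubs)),
                 rule_params = rule_params),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d membership + %d hub = %d combined core taxa\n",
              length(x$membership_core), length(x$hub_core),
              length(x$combined)))
  cat("  membership:", paste(x$membership_core, collapse = ", "), "\n")
  cat("  hub:       ", paste(x$hub_core, collapse = ", "), "\n")
  invisible(x)
}

#' Export a network as GraphML and edge-list TSV
#'
#' @param net A `cooccurrence_network`.
#' @param graphml_path,edges_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    ensure_parent_dir(graphml_path)
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    ensure_parent_dir(edges_path)
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml = graphml_path, edges = edges_path))
}
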