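# End-to-end pipeline: synthesize or load inputs -> depth normalization ->
# alpha/beta diversity -> composition -> co-occurrence network -> combined
# core microbiome -> compound association, under a single reproducibility
# seed fanned out to per-stage child seeds.

#' Pipeline configuration
#'
#' Exactly one input source must be supplied: a [synth_config()] (the
#' synthetic generator) or a set of file paths (abundance + metadata TSV,
#' optional Newick tree and compound TSV). All analysis thresholds default
#' to the study values: edge rule 0.6 / 0.05, hub rule 0.2 / 0.35 / 0.35,
#' top-10 membership core.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Mandatory integer seed; every stochastic stage derives its
#'   own child seed from it, so stages are individually re-runnable.
#' @param synth Optional [synth_config()].
#' @param table_path,metadata_path,tree_path,compounds_path Input file
#'   paths for the loading mode.
#' @param metrics Distance metrics to compute, subset of
#'   `c("braycurtis", "wunifrac")`; `"wunifrac"` requires a tree.
#' @param edge_rule,hub_rule The network [edge_rule()] and [hub_rule()].
#' @param top_n Membership-core size (default 10).
#' @param n_perm ANOSIM permutations (default 999).
#' @param min_prevalence Network prevalence filter (default 3).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, synth = NULL,
                            table_path = NULL, metadata_path = NULL,
                            tree_path = NULL, compounds_path = NULL,
                            metrics = c("braycurtis", "wunifrac"),
                            edge_rule = endocore::edge_rule(),
                            hub_rule = endocore::hub_rule(),
                            top_n = 10, n_perm = 999, min_prevalence = 3) {
  if (missing(seed) || is.null(seed)) stopf("`seed` is mandatory")
  have_synth <- !is.null(synth)
  have_paths <- !is.null(table_path)
  if (have_synth == have_paths) {
    stopf("supply exactly one of `synth` or `table_path` (+ companions)")
  }
  if (have_synth && !inherits(synth, "synth_config")) {
    stopf("`synth` must be a synth_config")
  }
  if (have_paths && is.null(metadata_path)) {
    stopf("`metadata_path` is required when loading from files")
  }
  metrics <- match.arg(metrics, c("braycurtis", "wunifrac"), several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = check_count(seed, "seed", 0L),
                 synth = synth, table_path = table_path,
                 metadata_path = metadata_path, tree_path = tree_path,
                 compounds_path = compounds_path, metrics = metrics,
                 edge_rule = edge_rule, hub_rule = hub_rule,
                 top_n = check_count(top_n, "top_n"),
                 n_perm = check_count(n_perm, "n_perm"),
                 min_prevalence = check_count(min_prevalence, "min_prevalence", 0L)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: input (synthesize or load), rarefaction to minimum
#' depth, alpha diversity, distance matrices + PCoA + ANOSIM, Venn sets +
#' top-abundance matrix, Spearman co-occurrence network + topology +
#' centralities, membership/hub/combined core set, and compound association
#' (group comparison, core-compound Spearman). Each stage writes a
#' self-describing TSV/JSON artifact under `out_dir`, and a `manifest.json`
#' records the package version, seed, parameters, per-stage child seeds and
#' md5 checksums of all inputs and outputs; re-running the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result and the file `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # fail before any computation if a requested metric is impossible
  if ("wunifrac" %in% config$metrics && is.null(config$synth) &&
      is.null(config$tree_path)) {
    stopf("configuration error: metric 'wunifrac' requested but no tree supplied")
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- stats::setNames(
    vapply(1:4, function(i) child_seed(config$seed, i), integer(1)),
    c("synth", "rarefy", "anosim", "modularity"))
  paths <- list()

  ## stage: inputs
  if (!is.null(config$synth)) {
    synth_cfg <- config$synth
    synth_cfg$seed <- seeds[["synth"]]
    bundle <- write_synth_bundle(synth_cfg, file.path(out, "inputs"))
    table <- bundle$table; metadata <- bundle$metadata
    tree <- bundle$tree; compounds <- bundle$compounds
    input_files <- unlist(bundle$paths)
  } else {
    table <- read_abundance(config$table_path)
    metadata <- read_metadata(config$metadata_path)
    tree <- if (!is.null(config$tree_path)) read_tree(config$tree_path)
    compounds <- if (!is.null(config$compounds_path)) {
      read_compounds(config$compounds_path)
    }
    input_files <- c(config$table_path, config$metadata_path,
                     config$tree_path, config$compounds_path)
  }
  group_vector(table, metadata)   # abort early on metadata gaps

  ## stage: depth normalization
  norm <- normalize_to_min_depth(table, seed = seeds[["rarefy"]])
  paths$normalized <- write_abundance(norm, file.path(out, "normalized_abundance.tsv"))

  ## stage: alpha diversity
  alpha <- alpha_diversity(norm, tree = tree, metadata = metadata)
  paths$alpha <- file.path(out, "alpha.tsv")
  utils::write.table(alpha, paths$alpha, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage: beta diversity
  dms <- list()
  if ("braycurtis" %in% config$metrics) dms$braycurtis <- bray_curtis(norm)
  if ("wunifrac" %in% config$metrics) dms$wunifrac <- weighted_unifrac(norm, tree)
  ords <- list(); anosims <- list()
  grp <- unname(group_vector(norm, metadata))
  for (metric in names(dms)) {
    paths[[paste0("dm_", metric)]] <-
      write_distance_matrix(dms[[metric]], file.path(out, sprintf("dm_%s.tsv", metric)))
    ords[[metric]] <- pcoa(dms[[metric]])
    coords <- ords[[metric]]$coordinates
    df <- data.frame(sample_id = rownames(coords), coords, check.names = FALSE)
    paths[[paste0("ordination_", metric)]] <- file.path(out, sprintf("ordination_%s.tsv", metric))
    utils::write.table(df, paths[[paste0("ordination_", metric)]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    anosims[[metric]] <- anosim(dms[[metric]], grp, n_perm = config$n_perm,
                                seed = seeds[["anosim"]])
  }
  paths$anosim <- file.path(out, "anosim.json")
  jsonlite::write_json(
    lapply(anosims, function(a) list(R = a$R, p = a$p, n_perm = a$n_perm)),
    paths$anosim, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## stage: composition
  venn <- venn_sets(norm, metadata)
  paths$venn <- file.path(out, "venn.json")
  jsonlite::write_json(
    list(rule = venn$rule, shared = venn$shared,
         unique_counts = as.list(venn$unique_counts),
         group_sets = venn$group_sets),
    paths$venn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  topmat <- top_abundance_matrix(norm, metadata, n = config$top_n)
  paths$top_abundance <- file.path(out, "top_abundance.tsv")
  utils::write.table(
    data.frame(group = rownames(topmat), topmat, check.names = FALSE),
    paths$top_abundance, sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: network
  sm <- spearman_matrix(norm, min_prevalence = config$min_prevalence)
  net <- build_network(sm, rule = config$edge_rule)
  topo <- network_topology(net, seed = seeds[["modularity"]])
  paths$topology <- file.path(out, "topology.json")
  jsonlite::write_json(unclass(topo), paths$topology, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pw <- write_network(net, graphml_path = file.path(out, "network.graphml"),
                      edges_path = file.path(out, "network_edges.tsv"))
  paths$network_graphml <- pw[["graphml"]]; paths$network_edges <- pw[["edges"]]
  nodes <- if (igraph::vcount(net$graph) >= 2L) {
    merge(net$nodes, centralities(net), by = "taxon", sort = TRUE)
  } else {
    net$nodes
  }
  paths$network_nodes <- file.path(out, "network_nodes.tsv")
  utils::write.table(nodes, paths$network_nodes, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## stage: core set
  memb <- membership_core(norm, metadata, top_n = config$top_n)
  hubs <- hub_core(net, rule = config$hub_rule)
  cores <- core_set(memb, hubs, rule_params = list(
    top_n = config$top_n,
    edge_rule = unclass(config$edge_rule),
    hub_rule = unclass(config$hub_rule)))
  paths$core_set <- file.path(out, "core_set.json")
  jsonlite::write_json(
    list(membership_core = cores$membership_core, hub_core = cores$hub_core,
         combined = cores$combined, rule_params = cores$rule_params),
    paths$core_set, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## stage: association
  comparison <- assoc <- NULL
  if (!is.null(compounds)) {
    comparison <- compare_groups(compounds, metadata)
    cmp_df <- comparison$summary
    for (g in colnames(comparison$means)) {
      cmp_df[[paste0("mean_", g)]] <- comparison$means[, g]
      cmp_df[[paste0("se_", g)]] <- comparison$se[, g]
      cmp_df[[paste0("letters_", g)]] <- comparison$letters[, g]
    }
    paths$comparison <- file.path(out, "comparison.tsv")
    utils::write.table(cmp_df, paths$comparison, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (length(cores$combined)) {
      assoc <- core_compound_spearman(norm, compounds, cores)
      paths$association <- write_association(assoc, file.path(out, "association.tsv"))
    }
  }

  ## manifest
  all_files <- c(input_files, unlist(paths, use.names = FALSE))
  manifest <- list(
    package = "endocore",
    version = as.character(utils::packageVersion("endocore")),
    seed = config$seed,
    stage_seeds = as.list(seeds),
    parameters = list(metrics = config$metrics,
                      edge_rule = unclass(config$edge_rule),
                      hub_rule = unclass(config$hub_rule),
                      top_n = config$top_n, n_perm = config$n_perm,
                      min_prevalence = config$min_prevalence,
                      synth = if (!is.null(config$synth)) unclass(config$synth)),
    files = lapply(stats::setNames(all_files, basename(all_files)),
                   function(f) unname(tools::md5sum(f))))
  paths$manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(table = table, metadata = metadata, tree = tree,
                 compounds = compounds, normalized = norm, alpha = alpha,
                 distances = dms, ordinations = ords, anosim = anosims,
                 venn = venn, top_abundance = topmat, spearman = sm,
                 network = net, topology = topo, core_set = cores,
                 comparison = comparison, association = assoc,
                 truth = if (!is.null(config$synth)) bundle$truth,
                 stage_seeds = seeds, paths = paths))
}
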