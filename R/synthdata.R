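# Synthetic community generator: compositional genus counts with planted
# correlation cliques (future network hubs) and planted monotone
# taxon-compound relationships, plus a random rooted tree over the taxa.
#
# Correlations are planted through a latent Gaussian factor on log
# abundance.  A target Spearman correlation rho_s is mapped to the latent
# Pearson correlation rho_p = 2*sin(pi*rho_s/6) (the exact bivariate-normal
# relation), so the realized rank correlation on the exp/multinomial scale
# matches the target approximately; calibration is statistical, not exact.

#' Configuration for the synthetic community generator
#'
#' Defaults emulate the study design the generator stands in for: a
#' 4-group x 3-replicate design (12 samples), heavy-tailed genus abundances
#' with a few dominant taxa, planted correlated cliques producing
#' high-centrality hub genera, and compound vectors with planted monotone
#' taxon-compound relationships.
#'
#' @param n_groups Number of groups (stages or organs).
#' @param n_reps Replicates per group.
#' @param n_taxa Number of taxa.
#' @param depth Reads per sample (every sample's counts sum to this).
#' @param n_hub_cliques Number of planted correlated cliques.
#' @param clique_size Taxa per clique (>= 3).
#' @param clique_rho Target within-clique Spearman correlation in \[0, 1\].
#' @param n_assoc_taxa Number of taxa with planted compound links (<= 4; one
#'   compound is driven by at most one taxon so each target calibrates
#'   independently).
#' @param assoc_rho Target taxon-compound Spearman correlation in \[0, 1\].
#' @param base_sigma Log-normal sd of the fixed per-taxon base abundances;
#'   1.5 gives the dominance structure typical of endophyte genus tables
#'   (top genus tens of percent).
#' @param noise_sd Per-sample log-abundance noise sd (biological replicate
#'   variation; 1 corresponds to roughly a coefficient of variation of 130%).
#' @param group_effect_sd Sd of group-by-taxon log-abundance shifts; 0 (the
#'   default) plants no group structure.
#' @param seed RNG seed; identical configs generate identical data.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_groups = 4, n_reps = 3, n_taxa = 40, depth = 50000,
                         n_hub_cliques = 2, clique_size = 6, clique_rho = 0.95,
                         n_assoc_taxa = 2, assoc_rho = 0.9,
                         base_sigma = 1.5, noise_sd = 1, group_effect_sd = 0,
                         seed = 1) {
  cfg <- list(
    n_groups = check_count(n_groups, "n_groups"),
    n_reps = check_count(n_reps, "n_reps"),
    n_taxa = check_count(n_taxa, "n_taxa", min = 2L),
    depth = check_count(depth, "depth"),
    n_hub_cliques = check_count(n_hub_cliques, "n_hub_cliques", min = 0L),
    clique_size = check_count(clique_size, "clique_size", min = 0L),
    clique_rho = check_fraction(clique_rho, "clique_rho"),
    n_assoc_taxa = check_count(n_assoc_taxa, "n_assoc_taxa", min = 0L),
    assoc_rho = check_fraction(assoc_rho, "assoc_rho"),
    base_sigma = check_fraction(base_sigma, "base_sigma", 0, Inf),
    noise_sd = check_fraction(noise_sd, "noise_sd", 0, Inf),
    group_effect_sd = check_fraction(group_effect_sd, "group_effect_sd", 0, Inf),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_groups * cfg$n_reps < 4L) {
    stopf("n_groups * n_reps must be >= 4 (correlation across samples needs >= 4 points); got %d",
          cfg$n_groups * cfg$n_reps)
  }
  if (cfg$n_hub_cliques > 0L && cfg$clique_size < 3L) {
    stopf("clique_size must be >= 3 when cliques are planted; got %d", cfg$clique_size)
  }
  if (cfg$n_hub_cliques * cfg$clique_size > cfg$n_taxa) {
    stopf("n_hub_cliques * clique_size (%d) exceeds n_taxa (%d)",
          cfg$n_hub_cliques * cfg$clique_size, cfg$n_taxa)
  }
  if (cfg$n_assoc_taxa > 4L) {
    stopf("n_assoc_taxa must be <= 4 (one planted taxon per compound); got %d",
          cfg$n_assoc_taxa)
  }
  if (cfg$n_assoc_taxa > cfg$n_taxa) stopf("n_assoc_taxa exceeds n_taxa")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "synth_config: %d groups x %d reps, %d taxa, depth %d, seed %d\n",
    x$n_groups, x$n_reps, x$n_taxa, x$depth, x$seed))
  cat(sprintf("  cliques: %d x %d taxa at Spearman rho %.2f\n",
              x$n_hub_cliques, x$clique_size, x$clique_rho))
  cat(sprintf("  compound links: %d at Spearman rho %.2f\n",
              x$n_assoc_taxa, x$assoc_rho))
  invisible(x)
}

# Spearman target -> latent bivariate-normal Pearson correlation.
latent_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

assoc_compounds <- c("OMA", "MA", "SC", "OSC")

#' Generate a synthetic community table with planted structure
#'
#' Draws fixed heavy-tailed (log-normal) base abundances per taxon, adds a
#' shared Gaussian factor on log abundance within each planted clique scaled
#' to the target Spearman correlation, and realizes counts multinomially per
#' sample at the configured depth. Clique taxa are drawn from the
#' mid-to-upper abundance band (40th-80th percentile of the base profile) so
#' their ranks stay resolvable at finite depth without dominating the
#' community.
#'
#' @param config A [synth_config()].
#' @return A list with `table` (an [abundance_table()]), `metadata`
#'   (a [sample_metadata()]) and `truth` (class `synth_truth`: the planted
#'   `hub_taxa`, `assoc_pairs` data.frame of taxon/compound/sign, and
#'   `group_labels`).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_s <- config$n_groups * config$n_reps
  taxa <- sprintf("taxon_%03d", seq_len(config$n_taxa))
  groups <- rep(sprintf("G%d", seq_len(config$n_groups)), each = config$n_reps)
  reps <- rep(seq_len(config$n_reps), times = config$n_groups)
  samples <- sprintf("%s_r%d", groups, reps)

  n_clique_taxa <- config$n_hub_cliques * config$clique_size
  clique_idx <- seq_len(n_clique_taxa)           # first taxa host the cliques
  clique_of <- rep(seq_len(max(config$n_hub_cliques, 1L)),
                   each = config$clique_size)[seq_len(n_clique_taxa)]

  counts <- with_seed(config$seed, {
    base <- stats::rlnorm(config$n_taxa, meanlog = 0, sdlog = config$base_sigma)
    if (n_clique_taxa > 0) {
      # mid-to-upper quantile band of the same log-normal profile
      base[clique_idx] <- stats::qlnorm(stats::runif(n_clique_taxa, 0.4, 0.8),
                                        meanlog = 0, sdlog = config$base_sigma)
    }
    rp <- latent_rho(config$clique_rho)
    b <- if (rp >= 1) Inf else sqrt(rp / (1 - rp))   # factor loading
    z <- matrix(stats::rnorm(n_s * max(config$n_hub_cliques, 1L)),
                nrow = n_s)                           # clique factors
    eps <- matrix(stats::rnorm(n_s * config$n_taxa), nrow = n_s)
    u <- eps
    if (n_clique_taxa > 0) {
      if (is.infinite(b)) {
        u[, clique_idx] <- z[, clique_of]
      } else {
        u[, clique_idx] <- (b * z[, clique_of] + eps[, clique_idx]) / sqrt(1 + b^2)
      }
    }
    geff <- if (config$group_effect_sd > 0) {
      ge <- matrix(stats::rnorm(config$n_groups * config$n_taxa,
                                sd = config$group_effect_sd),
                   nrow = config$n_groups)
      ge[match(groups, sprintf("G%d", seq_len(config$n_groups))), , drop = FALSE]
    } else {
      matrix(0, nrow = n_s, ncol = config$n_taxa)
    }
    la <- matrix(log(base), nrow = n_s, ncol = config$n_taxa, byrow = TRUE) +
      geff + config$noise_sd * u
    ab <- exp(la)
    t(apply(ab, 1L, function(w) stats::rmultinom(1L, config$depth, w)[, 1L]))
  })
  dimnames(counts) <- list(samples, taxa)

  # planted compound links: background taxa from the upper half of the base
  # profile (deterministic given the seed-driven draw above)
  assoc <- data.frame(taxon = character(0), compound = character(0),
                      sign = integer(0), stringsAsFactors = FALSE)
  if (config$n_assoc_taxa > 0) {
    bg <- setdiff(seq_len(config$n_taxa), clique_idx)
    if (length(bg) < config$n_assoc_taxa) {
      stopf("not enough non-clique taxa (%d) for %d planted compound links",
            length(bg), config$n_assoc_taxa)
    }
    mean_counts <- colMeans(counts)[bg]
    pick <- bg[order(-mean_counts, taxa[bg])][seq_len(config$n_assoc_taxa)]
    assoc <- data.frame(
      taxon = taxa[pick],
      compound = assoc_compounds[seq_len(config$n_assoc_taxa)],
      sign = rep_len(c(1L, -1L), config$n_assoc_taxa),
      stringsAsFactors = FALSE)
  }

  truth <- structure(list(
    hub_taxa = taxa[clique_idx],
    clique = if (n_clique_taxa > 0) split(taxa[clique_idx], clique_of) else list(),
    assoc_pairs = assoc,
    group_labels = stats::setNames(groups, samples)
  ), class = "synth_truth")

  list(table = abundance_table(counts, rank = "genus"),
       metadata = sample_metadata(samples, groups, reps),
       truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("synth_truth: %d planted hub taxa in %d clique(s); %d compound link(s)\n",
              length(x$hub_taxa), length(x$clique), nrow(x$assoc_pairs)))
  if (nrow(x$assoc_pairs)) {
    cat(paste(sprintf("  %s ~ %s (%+d)", x$assoc_pairs$taxon,
                      x$assoc_pairs$compound, x$assoc_pairs$sign),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Generate a random rooted tree over a taxon set
#'
#' Random binary topology with exponential branch lengths (mean 0.1),
#' round-trippable through Newick.
#'
#' @param taxa Character vector of unique taxon ids (>= 2).
#' @param seed Integer seed.
#' @return A rooted [ape::phylo] tree whose leaves are exactly `taxa`.
#' @export
generate_tree <- function(taxa, seed = 1) {
  taxa <- as.character(taxa)
  if (length(taxa) < 2L) stopf("need at least 2 taxa to build a tree")
  if (anyDuplicated(taxa)) {
    stopf("duplicate taxon ids: %s",
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  with_seed(seed, {
    tr <- ape::rtree(length(taxa), rooted = TRUE)
    tr$tip.label <- sample(taxa)                 # random leaf assignment
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 10)  # mean 0.1
    validate_tree(tr)
  })
}

#' Generate compound contents with planted taxon links
#'
#' One row per sample with columns OMA, MA, SC, OSC and TOTAL (mg/g). Each
#' planted (taxon, compound, sign) pair makes the compound a monotone
#' (log-linear in the normal scores of the taxon's relative-abundance ranks)
#' function of the taxon, with Gaussian noise calibrated so the realized
#' Spearman correlation is approximately `assoc_rho * sign`; unlinked
#' compounds are independent log-normal noise around typical quinolizidine
#' alkaloid magnitudes. TOTAL is the exact row sum of the four components.
#'
#' @param table Abundance table the links refer to.
#' @param truth `synth_truth` from [generate_community()].
#' @param config The [synth_config()] used.
#' @return A [compound_table()].
#' @export
generate_compounds <- function(table, truth, config) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "synth_truth"))
  cts <- count_matrix(table)
  pairs <- truth$assoc_pairs
  unknown <- setdiff(pairs$taxon, colnames(cts))
  if (length(unknown)) {
    stopf("assoc_pairs reference unknown taxa: %s", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(pairs$compound)) {
    stopf("at most one planted taxon per compound")
  }
  rel <- relative_abundance(cts)
  n <- nrow(cts)
  base_mg <- c(OMA = 30, MA = 5, SC = 20, OSC = 50)  # typical magnitudes, mg/g
  content_sigma <- 0.4

  vals <- with_seed(child_seed(config$seed, 1L), {
    out <- matrix(NA_real_, n, 4, dimnames = list(rownames(cts), assoc_compounds))
    for (cp in assoc_compounds) {
      hit <- which(pairs$compound == cp)
      if (length(hit) == 1L) {
        x <- rel[, pairs$taxon[hit]]
        q <- stats::qnorm((rank(x) - 0.5) / n)    # normal scores of the ranks
        q <- q / max(stats::sd(q), 1e-12)
        rp <- latent_rho(config$assoc_rho)
        l <- pairs$sign[hit] * rp * q +
          if (rp >= 1) 0 else sqrt(1 - rp^2) * stats::rnorm(n)
      } else {
        l <- stats::rnorm(n)
      }
      out[, cp] <- base_mg[[cp]] * exp(content_sigma * l)
    }
    out
  })
  vals <- cbind(vals, TOTAL = rowSums(vals))
  compound_table(vals)
}

#' Write a synthetic data bundle to a directory
#'
#' Writes the abundance table, metadata and compound table as TSV, the tree
#' as Newick, and the planted truth as JSON.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
write_synth_bundle <- function(config, dir) {
  comm <- generate_community(config)
  tree <- generate_tree(taxon_ids(comm$table), seed = child_seed(config$seed, 2L))
  compounds <- generate_compounds(comm$table, comm$truth, config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    abundance = file.path(dir, "abundance.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    compounds = file.path(dir, "compounds.tsv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json"))
  write_abundance(comm$table, paths$abundance)
  write_metadata(comm$metadata, paths$metadata)
  write_compounds(compounds, paths$compounds)
  write_tree(tree, paths$tree)
  jsonlite::write_json(
    list(hub_taxa = comm$truth$hub_taxa,
         assoc_pairs = comm$truth$assoc_pairs,
         group_labels = as.list(comm$truth$group_labels),
         config = unclass(config)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table = comm$table, metadata = comm$metadata,
                 truth = comm$truth, tree = tree, compounds = compounds,
                 paths = paths))
}
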