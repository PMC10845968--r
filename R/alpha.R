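# Alpha diversity: Chao1 richness, Shannon evenness, finite-sample Simpson
# dominance, and rooted Faith phylogenetic diversity.

#' Chao1 richness estimate
#'
#' Bias-corrected Chao1 by default (the common mothur default):
#' `S_obs + F1*(F1-1)/(2*(F2+1))` with `F1` singletons and `F2` doubletons.
#' The classic form `S_obs + F1^2/(2*F2)` is available by flag (falling back
#' to the bias-corrected term when `F2 = 0`).
#'
#' @param counts Non-negative integer counts of one sample.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return The richness estimate; always `>= S_obs`, and equal to `S_obs`
#'   when there are no singletons.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_sample_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Shannon evenness
#'
#' `H / ln(S_obs)` with `H = -sum(p_i * ln p_i)` over taxa with positive
#' counts (natural log). Undefined for a single-taxon sample, reported as
#' `NA` rather than 0.
#'
#' @param counts Non-negative integer counts of one sample.
#' @return Evenness in \[0, 1\], or `NA` when only one taxon is present.
#' @export
shannon_evenness <- function(counts) {
  counts <- check_sample_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  if (length(p) == 1L) return(NA_real_)
  h <- -sum(p * log(p))
  h / log(length(p))
}

#' Simpson dominance index
#'
#' The finite-sample dominance form `sum(n_i*(n_i-1)) / (N*(N-1))`
#' (mothur's "simpson" calculator): smaller values mean a more diverse,
#' less dominated community. The complement `1 - D` and inverse `1/D` are
#' exposed as variants.
#'
#' @param counts Non-negative integer counts of one sample, total `N >= 2`.
#' @param variant `"dominance"` (default), `"complement"` or `"inverse"`.
#' @return The index value.
#' @export
simpson_dominance <- function(counts, variant = c("dominance", "complement", "inverse")) {
  variant <- match.arg(variant)
  counts <- check_sample_counts(counts)
  n <- sum(counts)
  if (n < 2) stopf("Simpson dominance needs a total count of at least 2")
  d <- sum(counts * (counts - 1)) / (n * (n - 1))
  switch(variant, dominance = d, complement = 1 - d, inverse = 1 / d)
}

check_sample_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 1L || anyNA(counts)) {
    stopf("counts must be a numeric vector without NA")
  }
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stopf("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stopf("all-zero sample: no positive counts")
  round(counts)
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting the present
#' leaves. The default rooted form includes the path up to the root
#' (mothur/QIIME behaviour); `include_root = FALSE` stops at the most recent
#' common ancestor of the present leaves.
#'
#' @param present_taxa Character vector of taxa observed in the sample.
#' @param tree Rooted [ape::phylo] tree with branch lengths whose leaves
#'   cover `present_taxa`.
#' @param include_root Include the MRCA-to-root path (default `TRUE`).
#' @return Total branch length (0 for an empty taxon set).
#' @export
faith_pd <- function(present_taxa, tree, include_root = TRUE) {
  validate_tree(tree)
  present_taxa <- unique(as.character(present_taxa))
  missing <- setdiff(present_taxa, tree$tip.label)
  if (length(missing)) {
    stopf("taxa absent from tree: %s", paste(missing, collapse = ", "))
  }
  if (!length(present_taxa)) return(0)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  top <- if (include_root || length(present_taxa) == 1L) {
    root
  } else {
    ape::getMRCA(tree, present_taxa)
  }
  keep <- logical(ntip + tree$Nnode)
  for (tip in match(present_taxa, tree$tip.label)) {
    v <- tip
    while (v != top && v != root && !keep[v]) {
      keep[v] <- TRUE
      v <- parent[v]
    }
  }
  sum(tree$edge.length[keep[tree$edge[, 2L]]])
}

#' Per-sample alpha diversity table
#'
#' Computes observed richness, Chao1, Shannon evenness, Simpson dominance
#' and (when a tree is supplied) rooted Faith PD for every sample.
#'
#' @param table Abundance table (or counts matrix).
#' @param tree Optional rooted [ape::phylo] tree covering the table's taxa.
#' @param metadata Optional [sample_metadata()]; adds a `group` column.
#' @return A data.frame with one row per sample and columns `sample_id`,
#'   optionally `group`, `s_obs`, `chao`, `shannoneven`, `simpson`, and `pd`.
#' @export
alpha_diversity <- function(table, tree = NULL, metadata = NULL) {
  cts <- count_matrix(table)
  res <- data.frame(
    sample_id = rownames(cts),
    s_obs = apply(cts, 1L, function(r) sum(r > 0)),
    chao = apply(cts, 1L, chao1),
    shannoneven = apply(cts, 1L, shannon_evenness),
    simpson = apply(cts, 1L, simpson_dominance),
    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    res$pd <- apply(cts, 1L, function(r) faith_pd(colnames(cts)[r > 0], tree))
  }
  if (!is.null(metadata)) {
    res <- cbind(res[1L], group = unname(group_vector(table, metadata)),
                 res[-1L])
  }
  rownames(res) <- NULL
  res
}
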