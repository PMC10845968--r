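# Compound group comparisons (one-way ANOVA + Tukey letters, with ln
# transform when residual normality is rejected), fold changes between
# group means, and the Spearman association of core taxa with compound
# content.

#' Compare compound content across groups
#'
#' Per compound: one-way ANOVA with Tukey HSD letters at `alpha`. With
#' `transform = "auto"` (default) a Shapiro-Wilk test is run on the ANOVA
#' residuals; when normality is rejected at 0.05 the response is
#' ln-transformed and the model refit. Group means and standard errors are
#' reported on the original scale. Groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param compounds A [compound_table()] (or samples x compounds matrix).
#' @param metadata [sample_metadata()] covering every sample; >= 2 groups
#'   with >= 2 replicates each.
#' @param alpha Significance level for the Tukey letters (default 0.05).
#' @param transform `"auto"` (Shapiro-Wilk gated ln), `"none"` or `"ln"`.
#' @return An object of class `group_comparison`: `summary` (one row per
#'   compound: `F`, `p`, `transform_applied`), `means` (group means),
#'   `se` (group standard errors), `letters` (Tukey letter display),
#'   `tukey_p` (list of pairwise adjusted p matrices), `alpha`.
#' @export
compare_groups <- function(compounds, metadata, alpha = 0.05,
                           transform = c("auto", "none", "ln")) {
  transform <- match.arg(transform)
  vals <- compound_values(compounds)
  m <- match(rownames(vals), metadata$sample_id)
  if (anyNA(m)) {
    stopf("samples without metadata: %s",
          paste(rownames(vals)[is.na(m)], collapse = ", "))
  }
  grp <- factor(metadata$group[m])
  sizes <- table(grp)
  if (length(sizes) < 2L) stopf("group comparison needs >= 2 groups")
  if (any(sizes < 2L)) {
    stopf("every group needs >= 2 replicates (violated by: %s)",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  groups <- levels(grp)
  cps <- colnames(vals)
  means <- se <- matrix(NA_real_, length(cps), length(groups),
                        dimnames = list(cps, groups))
  letters_m <- matrix("", length(cps), length(groups),
                      dimnames = list(cps, groups))
  summ <- data.frame(compound = cps, F = NA_real_, p = NA_real_,
                     transform_applied = "none", stringsAsFactors = FALSE)
  tukey_p <- vector("list", length(cps)); names(tukey_p) <- cps
  for (k in seq_along(cps)) {
    y <- vals[, k]
    used <- "none"
    fit <- stats::aov(y ~ grp)
    if (transform == "ln" ||
        (transform == "auto" && shapiro_rejects(stats::residuals(fit)))) {
      if (any(y <= 0)) {
        stopf("compound %s has non-positive values; ln transform impossible (consider an offset)",
              cps[k])
      }
      fit <- stats::aov(log(y) ~ grp)
      used <- "ln"
    }
    an <- stats::anova(fit)
    summ$F[k] <- an[["F value"]][1L]
    summ$p[k] <- an[["Pr(>F)"]][1L]
    summ$transform_applied[k] <- used
    means[k, ] <- tapply(y, grp, mean)[groups]
    se[k, ] <- tapply(y, grp, function(v) stats::sd(v) / sqrt(length(v)))[groups]
    pm <- tukey_p_matrix(fit, groups)
    tukey_p[[k]] <- pm
    letters_m[k, ] <- cld_letters(groups, means[k, ], pm, alpha)
  }
  structure(list(summary = summ, means = means, se = se,
                 letters = letters_m, tukey_p = tukey_p, alpha = alpha),
            class = "group_comparison")
}

# Shapiro-Wilk rejection at 0.05; degenerate residual vectors (all equal)
# are treated as consistent with normality.
shapiro_rejects <- function(res) {
  if (stats::sd(res) < 1e-12) return(FALSE)
  out <- tryCatch(stats::shapiro.test(res), error = function(e) NULL)
  !is.null(out) && out$p.value < 0.05
}

# symmetric matrix of Tukey HSD adjusted p-values over groups
tukey_p_matrix <- function(fit, groups) {
  tk <- stats::TukeyHSD(fit)[[1L]]
  pm <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(groups, groups))
  diag(pm) <- 1
  parts <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_len(nrow(tk))) {
    a <- parts[[i]][1L]; b <- parts[[i]][2L]
    pm[a, b] <- pm[b, a] <- tk[i, "p adj"]
  }
  # groups with identical values give NaN adjusted p (zero variance): the
  # difference is also zero, so treat as not significantly different
  pm[is.nan(pm)] <- 1
  pm
}

# Compact letter display: maximal cliques of the "not significantly
# different" graph, lettered in order of the best (largest-mean) member.
cld_letters <- function(groups, means, pmat, alpha) {
  k <- length(groups)
  nsd <- pmat >= alpha
  diag(nsd) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g, min = 1)
  cl <- lapply(cl, function(v) igraph::V(g)$name[as.integer(v)])
  best <- vapply(cl, function(v) max(means[v]), numeric(1))
  cl <- cl[order(-best)]
  out <- stats::setNames(rep("", k), groups)
  for (i in seq_along(cl)) {
    out[cl[[i]]] <- paste0(out[cl[[i]]], letters[i])
  }
  out[groups]
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: %d compounds x %d groups (Tukey letters at %g)\n",
              nrow(x$summary), ncol(x$means), x$alpha))
  df <- x$summary
  df$F <- round(df$F, 2)
  df$p <- signif(df$p, 3)
  for (g in colnames(x$means)) {
    df[[g]] <- sprintf("%.1f %s", x$means[, g], x$letters[, g])
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fold change between two group means
#'
#' `mean(group_a) / mean(group_b)` for one compound, reported at full
#' precision alongside the 1-decimal rounding the ratios are quoted at.
#'
#' @param compounds A [compound_table()] (or matrix).
#' @param metadata [sample_metadata()].
#' @param compound Compound id.
#' @param group_a,group_b Numerator and denominator groups.
#' @return A list with `ratio`, `rounded` (1 d.p.), `mean_a`, `mean_b`.
#'   A non-positive denominator mean gives `ratio = NA` with a warning.
#' @export
fold_change <- function(compounds, metadata, compound, group_a, group_b) {
  vals <- compound_values(compounds)
  if (!compound %in% colnames(vals)) stopf("unknown compound: %s", compound)
  m <- match(rownames(vals), metadata$sample_id)
  if (anyNA(m)) stopf("samples without metadata")
  grp <- metadata$group[m]
  for (g in c(group_a, group_b)) {
    if (!g %in% grp) stopf("group not present: %s", g)
  }
  ma <- mean(vals[grp == group_a, compound])
  mb <- mean(vals[grp == group_b, compound])
  if (mb <= 0) {
    warnf("denominator group mean is not positive; fold change undefined")
    return(list(ratio = NA_real_, rounded = NA_real_, mean_a = ma, mean_b = mb))
  }
  r <- ma / mb
  list(ratio = r, rounded = round(r, 1), mean_a = ma, mean_b = mb)
}

#' Spearman association of core taxa with compound content
#'
#' Per (core taxon, compound) pair: tie-corrected Spearman rho between the
#' taxon's per-sample relative abundance and the compound content, with a
#' two-sided p (exact permutation for `n <= 9`, t approximation otherwise)
#' and significance stars (`"*"` for p < 0.05, `"**"` for p < 0.01). A
#' compound or taxon constant across samples yields `NA` with no star.
#'
#' @param table Abundance table, sample-aligned with `compounds`.
#' @param compounds A [compound_table()] (or matrix).
#' @param core A `core_set` (its `combined` member is used) or a character
#'   vector of taxa; all must be columns of `table`.
#' @param exact_max_n Largest n for the exact permutation p (default 9).
#' @return An object of class `association_matrix`: `rho`, `p`, `star`
#'   matrices (taxa x compounds), `n`, `p_method`.
#' @export
core_compound_spearman <- function(table, compounds, core, exact_max_n = 9) {
  cts <- count_matrix(table)
  vals <- compound_values(compounds)
  unmatched <- c(setdiff(rownames(cts), rownames(vals)),
                 setdiff(rownames(vals), rownames(cts)))
  if (length(unmatched)) {
    stopf("sample ids do not match between tables: %s",
          paste(unique(unmatched), collapse = ", "))
  }
  vals <- vals[rownames(cts), , drop = FALSE]
  n <- nrow(cts)
  if (n < 4L) stopf("association needs >= 4 aligned samples (got %d)", n)
  taxa <- if (inherits(core, "core_set")) core$combined else as.character(core)
  missing <- setdiff(taxa, colnames(cts))
  if (length(missing)) {
    stopf("core taxa absent from abundance table: %s",
          paste(missing, collapse = ", "))
  }
  rel <- relative_abundance(cts)
  cps <- colnames(vals)
  rho <- p <- matrix(NA_real_, length(taxa), length(cps),
                     dimnames = list(taxa, cps))
  for (i in seq_along(taxa)) {
    for (j in seq_along(cps)) {
      st <- spearman_test(rel[, taxa[i]], vals[, cps[j]], method = "auto",
                          exact_max_n = exact_max_n)
      rho[i, j] <- st$rho
      p[i, j] <- st$p
    }
  }
  star <- matrix("", length(taxa), length(cps), dimnames = dimnames(rho))
  star[!is.na(p) & p < 0.05] <- "*"
  star[!is.na(p) & p < 0.01] <- "**"
  structure(list(rho = rho, p = p, star = star, n = n,
                 p_method = if (n <= exact_max_n) "exact" else "tapprox"),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d core taxa x %d compounds (n = %d, %s p)\n",
              nrow(x$rho), ncol(x$rho), x$n, x$p_method))
  disp <- matrix(sprintf("%.2f%s", x$rho, x$star), nrow(x$rho),
                 dimnames = dimnames(x$rho))
  disp[is.na(x$rho)] <- "NA"
  print(as.data.frame(disp))
  invisible(x)
}

#' Export an association matrix as long-format TSV
#'
#' Columns `taxon`, `compound`, `rho`, `p`, `star`.
#'
#' @param assoc An `association_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  ensure_parent_dir(path)
  df <- expand.grid(taxon = rownames(assoc$rho), compound = colnames(assoc$rho),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$rho <- as.vector(assoc$rho)
  df$p <- as.vector(assoc$p)
  df$star <- as.vector(assoc$star)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
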