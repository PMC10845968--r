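# Shared/unique taxon sets across groups, the membership-rule core
# microbiome, and group-level top-abundance summaries.

#' Shared and unique taxon sets across groups (Venn arithmetic)
#'
#' A taxon is "present in a group" if it has a positive count in at least
#' one sample of the group (`presence_rule = "any"`, default) or in every
#' sample of the group (`"all"`). Unique taxa occur in exactly one group;
#' shared taxa occur in all groups.
#'
#' @param table Abundance table (or counts matrix).
#' @param metadata [sample_metadata()] covering every sample.
#' @param presence_rule `"any"` or `"all"`.
#' @return An object of class `venn_summary`: `group_sets` (list of taxon
#'   vectors), `shared`, `unique_sets`, `unique_counts`, `rule`.
#' @export
venn_sets <- function(table, metadata, presence_rule = c("any", "all")) {
  presence_rule <- match.arg(presence_rule)
  cts <- count_matrix(table)
  grp <- group_vector(table, metadata)
  groups <- unique(unname(grp))
  group_sets <- lapply(groups, function(g) {
    sub <- cts[grp == g, , drop = FALSE]
    pres <- if (presence_rule == "any") colSums(sub > 0) > 0 else
      colSums(sub > 0) == nrow(sub)
    colnames(cts)[pres]
  })
  names(group_sets) <- groups
  shared <- Reduce(intersect, group_sets)
  n_in <- rowSums(sapply(group_sets, function(s) colnames(cts) %in% s))
  unique_sets <- lapply(groups, function(g) {
    intersect(group_sets[[g]], colnames(cts)[n_in == 1])
  })
  names(unique_sets) <- groups
  structure(list(group_sets = group_sets,
                 shared = shared,
                 unique_sets = unique_sets,
                 unique_counts = vapply(unique_sets, length, integer(1)),
                 rule = presence_rule),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("venn_summary (%s-sample presence): %d groups, %d shared taxa\n",
              x$rule, length(x$group_sets), length(x$shared)))
  for (g in names(x$group_sets)) {
    cat(sprintf("  %s: %d taxa, %d unique\n", g, length(x$group_sets[[g]]),
                x$unique_counts[[g]]))
  }
  invisible(x)
}

#' Membership-rule core microbiome
#'
#' Taxa with a positive count in every sample (strict per-sample
#' membership), ranked by mean per-sample relative abundance (so deep
#' samples do not dominate the ranking) and truncated to the `top_n` most
#' abundant. Ties are broken lexicographically by taxon id. With
#' `rule = "groups"` membership instead requires presence in at least one
#' sample of every group.
#'
#' @param table Abundance table (or counts matrix).
#' @param metadata Required only for `rule = "groups"`.
#' @param top_n Number of top-ranked members to keep (default 10; `Inf`
#'   keeps all members).
#' @param rule `"samples"` (default, strictest) or `"groups"`.
#' @param pooled Rank by pooled counts instead of mean per-sample relative
#'   abundance.
#' @return Character vector of core taxa in rank order, with the ranking
#'   statistic attached as attribute `abundance`.
#' @export
membership_core <- function(table, metadata = NULL, top_n = 10,
                            rule = c("samples", "groups"), pooled = FALSE) {
  rule <- match.arg(rule)
  cts <- count_matrix(table)
  if (rule == "samples") {
    member <- colSums(cts > 0) == nrow(cts)
  } else {
    if (is.null(metadata)) stopf("`metadata` is required for rule = \"groups\"")
    grp <- group_vector(table, metadata)
    member <- Reduce(`&`, lapply(unique(unname(grp)), function(g) {
      colSums(cts[grp == g, , drop = FALSE] > 0) > 0
    }))
  }
  stat <- if (pooled) colSums(cts) / sum(cts) else colMeans(relative_abundance(cts))
  cand <- colnames(cts)[member]
  cand <- cand[order(-stat[cand], cand)]
  if (is.finite(top_n)) cand <- utils::head(cand, check_count(top_n, "top_n"))
  structure(cand, abundance = stat[cand])
}

#' Group-by-taxon mean relative-abundance matrix for the top taxa
#'
#' Rows are groups, columns the globally `n` highest-ranked taxa by overall
#' mean per-sample relative abundance; all remaining taxa are aggregated
#' into an `"other"` column so every row sums to 1.
#'
#' @param table Abundance table (or counts matrix).
#' @param metadata [sample_metadata()] covering every sample.
#' @param n Number of top taxa (clamped with a warning if it exceeds the
#'   taxon count).
#' @return Numeric matrix, groups x (n top taxa + `"other"`).
#' @export
top_abundance_matrix <- function(table, metadata, n = 10) {
  n <- check_count(n, "n")
  cts <- count_matrix(table)
  if (n > ncol(cts)) {
    warnf("n = %d exceeds taxon count %d; clamping", n, ncol(cts))
    n <- ncol(cts)
  }
  rel <- relative_abundance(cts)
  stat <- colMeans(rel)
  top <- colnames(cts)[order(-stat, colnames(cts))][seq_len(n)]
  grp <- group_vector(table, metadata)
  groups <- unique(unname(grp))
  out <- t(vapply(groups, function(g) {
    gm <- colMeans(rel[grp == g, , drop = FALSE])
    c(gm[top], other = sum(gm[setdiff(colnames(cts), top)]))
  }, numeric(n + 1L)))
  rownames(out) <- groups
  out
}
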