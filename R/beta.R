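# Beta diversity: Bray-Curtis and normalized weighted UniFrac distance
# matrices, UPGMA clustering, principal coordinates analysis, and the
# ANOSIM rank permutation test of group separation.

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = 1 - 2*sum(min(x_i, y_i)) / sum(x_i + y_i)` on counts,
#' computed with [vegan::vegdist()].
#'
#' @param table Abundance table (or counts matrix).
#' @return A [stats::dist] object with attribute `metric = "braycurtis"`.
#' @export
bray_curtis <- function(table) {
  cts <- count_matrix(table)
  if (any(rowSums(cts) == 0)) {
    stopf("Bray-Curtis undefined for zero-total samples: %s",
          paste(rownames(cts)[rowSums(cts) == 0], collapse = ", "))
  }
  d <- vegan::vegdist(cts, method = "bray")
  attr(d, "metric") <- "braycurtis"
  d
}

#' Weighted UniFrac distance matrix
#'
#' Normalized weighted UniFrac:
#' `sum_b L_b * |p_A(b) - p_B(b)| / sum_b L_b * (p_A(b) + p_B(b))`,
#' where `p_X(b)` is the fraction of sample X's reads descending from branch
#' `b`. Values lie in \[0, 1\]; `normalized = FALSE` returns the raw
#' numerator. Every taxon with a positive count must be a leaf of `tree`;
#' extra leaves carry zero abundance.
#'
#' @param table Abundance table (or counts matrix).
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param normalized Divide by the branch-weighted abundance sum (default).
#' @return A [stats::dist] object with attribute `metric = "wunifrac"`.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  validate_tree(tree)
  rel <- relative_abundance(table)
  present <- colnames(rel)[colSums(rel) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    stopf("taxa with positive counts absent from tree: %s",
          paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # tip-by-node clade membership via postorder accumulation
  memb <- matrix(FALSE, ntip, nnode)
  memb[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    memb[, po[k, 1L]] <- memb[, po[k, 1L]] | memb[, po[k, 2L]]
  }
  # per-sample proportion descending from each branch (indexed by child node)
  rel_full <- matrix(0, nrow(rel), ntip,
                     dimnames = list(rownames(rel), tree$tip.label))
  shared <- intersect(colnames(rel), tree$tip.label)
  rel_full[, shared] <- rel[, shared]
  p_branch <- rel_full %*% memb[, tree$edge[, 2L], drop = FALSE]
  len <- tree$edge.length
  n <- nrow(rel)
  dm <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      num <- sum(len * abs(p_branch[i, ] - p_branch[j, ]))
      if (normalized) {
        den <- sum(len * (p_branch[i, ] + p_branch[j, ]))
        dm[i, j] <- dm[j, i] <- if (den > 0) num / den else 0
      } else {
        dm[i, j] <- dm[j, i] <- num
      }
    }
  }
  d <- stats::as.dist(dm)
  attr(d, "metric") <- "wunifrac"
  d
}

as_square_dist <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) != ncol(m)) stopf("distance matrix must be square")
  if (anyNA(m) || any(!is.finite(m))) stopf("distance matrix contains NA/NaN/Inf")
  if (max(abs(m - t(m))) > 1e-12) stopf("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stopf("distance matrix diagonal must be zero")
  m
}

#' Write / read a distance matrix as square TSV
#' @param dm A `dist` or square matrix.
#' @param path File path.
#' @return `read_distance_matrix` returns a [stats::dist].
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as_square_dist(dm)
  ensure_parent_dir(path)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  m <- read_tsv_matrix(path, "distance")
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  stats::as.dist(as_square_dist(num))
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomerative clustering of a distance matrix via
#' [stats::hclust()]; merge heights are non-decreasing and leaves are the
#' samples.
#'
#' @param dm A `dist` or square symmetric matrix (>= 2 samples).
#' @param linkage `"average"` (UPGMA, default), `"complete"` or `"single"`.
#' @return An [stats::hclust] tree.
#' @export
upgma_cluster <- function(dm, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  m <- as_square_dist(dm)
  if (nrow(m) < 2L) stopf("clustering needs at least 2 samples")
  stats::hclust(stats::as.dist(m), method = linkage)
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the double-centred squared-distance matrix
#' `-1/2 * J %*% D^2 %*% J`. Axes are ordered by eigenvalue; the proportion
#' explained is computed over the positive eigenvalues only (Legendre
#' convention) while negative eigenvalues are reported, not dropped.
#'
#' @param dm A `dist` or square symmetric matrix.
#' @return An object of class `pcoa_result`: `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, decreasing), and
#'   `proportion_explained` (per positive axis).
#' @export
pcoa <- function(dm) {
  m <- as_square_dist(dm)
  n <- nrow(m)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (m^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                   nrow = length(pos))
  dimnames(coords) <- list(rownames(m),
                           if (length(pos)) paste0("Axis.", seq_along(pos)))
  prop <- if (length(pos)) e$values[pos] / sum(e$values[pos]) else numeric(0)
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = prop),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  npos <- length(x$proportion_explained)
  nneg <- sum(x$eigenvalues < 0)
  cat(sprintf("pcoa_result: %d samples, %d positive axes (%d negative eigenvalues)\n",
              nrow(x$coordinates), npos, nneg))
  if (npos) {
    cat(sprintf("  first axes explain: %s\n",
                paste(sprintf("%.2f%%", 100 * utils::head(x$proportion_explained, 3)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.pcoa_result <- function(x, groups = NULL, axes = c(1, 2), ...) {
  if (ncol(x$coordinates) < max(axes)) stopf("not enough positive axes to plot")
  xy <- x$coordinates[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  labs <- sprintf("Axis %d (%.1f%%)", axes, 100 * x$proportion_explained[axes])
  graphics::plot(xy, col = col, pch = 19, xlab = labs[1], ylab = labs[2], ...)
  invisible(x)
}

#' ANOSIM permutation test of group separation
#'
#' Clarke's R on ranked distances:
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n*(n-1)/2` pairs, so perfectly separated groups give `R = 1`. The
#' p-value is the one-sided upper tail over seeded label permutations with
#' the +1 correction: `p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)`.
#'
#' @param dm A `dist` or square symmetric matrix.
#' @param groups Group label per sample (>= 2 groups, each with >= 2
#'   samples), in the order of the matrix.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return An object of class `anosim_result`: `R`, `p`, `n_perm`,
#'   `perm_R` (the permutation statistics).
#' @export
anosim <- function(dm, groups, n_perm = 999, seed = NULL) {
  m <- as_square_dist(dm)
  n <- nrow(m)
  groups <- as.character(groups)
  if (length(groups) != n) stopf("`groups` must have one label per sample")
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("ANOSIM needs at least 2 groups")
  if (any(sizes < 2L)) {
    stopf("every group needs at least 2 samples (violated by: %s)",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  n_perm <- check_count(n_perm, "n_perm")
  pr <- t(utils::combn(n, 2L))          # pair order matches dist vectors
  r <- rank(m[pr])                      # ranked distances, average ties
  bign <- length(r)                     # M = n(n-1)/2
  sum_r <- sum(r)
  r_stat <- function(within) {
    (mean(r[!within]) - mean(r[within])) / (bign / 2)
  }
  obs <- r_stat(groups[pr[, 1L]] == groups[pr[, 2L]])
  perm_R <- with_seed(seed, {
    labm <- replicate(n_perm, sample(groups))
    wm <- labm[pr[, 1L], , drop = FALSE] == labm[pr[, 2L], , drop = FALSE]
    cw <- colSums(wm)
    sw <- colSums(r * wm)
    ((sum_r - sw) / (bign - cw) - sw / cw) / (bign / 2)
  })
  p <- (1 + sum(perm_R >= obs - 1e-12)) / (1 + n_perm)
  structure(list(R = obs, p = p, n_perm = n_perm, perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, P = %.4f (%d permutations)\n",
              x$R, x$p, x$n_perm))
  invisible(x)
}

#' PERMANOVA group-separation test
#'
#' Alternative to [anosim()]: partitions the distance matrix variance by
#' group via [vegan::adonis2()] under seeded permutations.
#'
#' @inheritParams anosim
#' @return A list with `F`, `R2`, `p` and `n_perm`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  m <- as_square_dist(dm)
  df <- data.frame(group = factor(groups))
  fit <- with_seed(seed,
                   vegan::adonis2(stats::as.dist(m) ~ group, data = df,
                                  permutations = n_perm))
  list(F = fit$F[1L], R2 = fit$R2[1L], p = fit$`Pr(>F)`[1L], n_perm = n_perm)
}
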