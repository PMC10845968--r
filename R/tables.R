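# Abundance/metadata/compound containers, TSV io, and depth normalization.

#' Construct an abundance table
#'
#' A samples-by-taxa matrix of non-negative integer counts, the universe for
#' all diversity, composition and network computation. Row names are sample
#' ids, column names taxon ids; both must be unique and non-empty.
#'
#' @param counts Numeric matrix or data.frame, samples in rows, taxa in
#'   columns, with integral non-negative entries.
#' @param rank Taxonomic rank label the columns are resolved at
#'   (e.g. `"genus"`, `"OTU"`); informational only.
#' @return An object of class `abundance_table`: a list with elements
#'   `counts` (numeric matrix) and `rank`.
#' @examples
#' m <- matrix(c(5, 0, 3, 2, 4, 3), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' abundance_table(m)
#' @export
abundance_table <- function(counts, rank = "genus") {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("`counts` must be a numeric matrix (samples x taxa)")
  }
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stopf("abundance table needs at least 1 sample and 1 taxon")
  }
  sn <- rownames(counts); tn <- colnames(counts)
  if (is.null(sn) || anyNA(sn) || any(sn == "")) {
    stopf("abundance table rows must carry sample ids")
  }
  if (is.null(tn) || anyNA(tn) || any(tn == "")) {
    stopf("abundance table columns must carry taxon ids")
  }
  if (anyDuplicated(sn)) stopf("duplicate sample ids: %s",
                               paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (anyDuplicated(tn)) stopf("duplicate taxon ids: %s",
                               paste(unique(tn[duplicated(tn)]), collapse = ", "))
  if (anyNA(counts)) stopf("abundance counts contain NA")
  if (any(counts < 0)) stopf("abundance counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stopf("abundance counts must be integral")
  }
  structure(list(counts = round(counts), rank = as.character(rank)[1L]),
            class = "abundance_table")
}

# Accept an abundance_table, matrix or data.frame and return the count matrix.
count_matrix <- function(x) {
  if (inherits(x, "abundance_table")) return(x$counts)
  abundance_table(x)$counts
}

#' @export
print.abundance_table <- function(x, ...) {
  cts <- x$counts
  cat(sprintf("abundance_table: %d samples x %d taxa (rank: %s)\n",
              nrow(cts), ncol(cts), x$rank))
  d <- rowSums(cts)
  cat(sprintf("  depth: min %s, max %s\n", format(min(d)), format(max(d))))
  top <- sort(colMeans(sweep(cts, 1, pmax(d, 1), "/")), decreasing = TRUE)
  top <- utils::head(top, 3)
  cat(sprintf("  top taxa by mean relative abundance: %s\n",
              paste(sprintf("%s (%.1f%%)", names(top), 100 * top), collapse = ", ")))
  invisible(x)
}

#' Sample ids and taxon ids of a table
#' @param x An `abundance_table` (or counts matrix).
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(count_matrix(x))

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) colnames(count_matrix(x))

#' Construct sample metadata
#'
#' One row per sample with its group (developmental stage or organ) and
#' replicate index.
#'
#' @param sample_id Character vector of sample ids.
#' @param group Group label per sample (stage or organ).
#' @param replicate Replicate index per sample.
#' @return A `data.frame` with columns `sample_id`, `group`, `replicate`,
#'   class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, group, replicate) {
  if (anyDuplicated(sample_id)) stopf("duplicate sample ids in metadata")
  md <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  class(md) <- c("sample_metadata", "data.frame")
  md
}

# Check metadata covers exactly the table's samples; return group factor
# aligned to table sample order.
group_vector <- function(table, metadata) {
  sid <- sample_ids(table)
  m <- match(sid, metadata$sample_id)
  if (anyNA(m)) {
    stopf("samples without metadata: %s", paste(sid[is.na(m)], collapse = ", "))
  }
  stats::setNames(metadata$group[m], sid)
}

#' Construct a compound-content table
#'
#' Samples-by-compounds matrix of contents (mg/g). The canonical compound set
#' is OMA, MA, SC, OSC and TOTAL; the SC column holds the pooled SC+SR
#' content (the two co-elute), and TOTAL must be at least each component.
#'
#' @param values Numeric matrix, samples in rows, compounds in columns.
#' @return An object of class `compound_table` wrapping the matrix.
#' @export
compound_table <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix (samples x compounds)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("compound table must carry sample ids (rows) and compound ids (columns)")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stopf("duplicate sample or compound ids in compound table")
  }
  if (anyNA(values) || any(values < 0)) {
    stopf("compound contents must be non-negative and non-missing")
  }
  if ("TOTAL" %in% colnames(values)) {
    comp <- setdiff(colnames(values), "TOTAL")
    if (length(comp) && any(values[, "TOTAL"] + 1e-8 < values[, comp, drop = FALSE])) {
      stopf("TOTAL must be >= each component for every sample")
    }
  }
  structure(list(values = values), class = "compound_table")
}

compound_values <- function(x) {
  if (inherits(x, "compound_table")) return(x$values)
  compound_table(x)$values
}

#' @export
print.compound_table <- function(x, ...) {
  v <- x$values
  cat(sprintf("compound_table: %d samples x %d compounds (mg/g)\n",
              nrow(v), ncol(v)))
  print(round(v, 2))
  invisible(x)
}

## ---- TSV / Newick io -------------------------------------------------------

read_tsv_matrix <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stopf("%s table %s has no data columns", what, path)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read / write an abundance table as TSV
#'
#' The dialect is a UTF-8 tab-separated file: header row of taxon ids, first
#' column of sample ids, integer counts. Malformed cells are rejected with
#' their coordinates; a write followed by a read reproduces the object
#' exactly.
#'
#' @param path File path.
#' @param rank Rank label to attach on read.
#' @return `read_abundance` returns an `abundance_table`; `write_abundance`
#'   returns `path` invisibly.
#' @export
read_abundance <- function(path, rank = "genus") {
  m <- read_tsv_matrix(path, "abundance")
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  bad <- is.na(num) | num < 0 | abs(num - round(num)) > 1e-8
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("invalid count '%s' at sample '%s', taxon '%s' in %s",
          m[w[1L], w[2L]], rownames(m)[w[1L]], colnames(m)[w[2L]], path)
  }
  abundance_table(num, rank = rank)
}

#' @rdname read_abundance
#' @param table An `abundance_table`.
#' @export
write_abundance <- function(table, path) {
  cts <- count_matrix(table)
  ensure_parent_dir(path)
  df <- data.frame(sample_id = rownames(cts), cts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata as TSV
#'
#' Columns `sample_id`, `group`, `replicate`.
#' @param path File path.
#' @return `read_metadata` returns a `sample_metadata` data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  need <- c("sample_id", "group", "replicate")
  if (!all(need %in% colnames(df))) {
    stopf("metadata must have columns %s", paste(need, collapse = ", "))
  }
  sample_metadata(df$sample_id, df$group, as.integer(df$replicate))
}

#' @rdname read_metadata
#' @param metadata A `sample_metadata` data.frame.
#' @export
write_metadata <- function(metadata, path) {
  ensure_parent_dir(path)
  utils::write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a compound-content table as TSV
#' @param path File path.
#' @return `read_compounds` returns a `compound_table`.
#' @export
read_compounds <- function(path) {
  m <- read_tsv_matrix(path, "compound")
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  if (anyNA(num)) {
    w <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("invalid content '%s' at sample '%s', compound '%s' in %s",
          m[w[1L], w[2L]], rownames(m)[w[1L]], colnames(m)[w[2L]], path)
  }
  compound_table(num)
}

#' @rdname read_compounds
#' @param compounds A `compound_table`.
#' @export
write_compounds <- function(compounds, path) {
  v <- compound_values(compounds)
  ensure_parent_dir(path)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phylogenetic tree (Newick)
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that insist on
#' a rooted tree with branch lengths and unique leaf names, the input
#' contract for Faith PD and weighted UniFrac.
#'
#' @param path File path.
#' @return `read_tree` returns an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stopf("tree file not found: %s", path)
  tr <- ape::read.tree(path)
  validate_tree(tr)
  tr
}

#' @rdname read_tree
#' @param tree An [ape::phylo] tree.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  ensure_parent_dir(path)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stopf("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stopf("tree branch lengths must be >= 0")
  if (anyDuplicated(tree$tip.label)) stopf("tree leaf names must be unique")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  invisible(tree)
}

## ---- normalization ---------------------------------------------------------

#' Rarefy every sample to the minimum depth
#'
#' Subsamples each sample's counts (without replacement by default) to the
#' smallest per-sample total so that richness and diversity comparisons are
#' depth-fair; all output samples then share the same total.
#'
#' @param table Abundance table (or counts matrix).
#' @param seed Integer seed controlling the subsampling; required for exact
#'   reproducibility, `NULL` uses the current RNG stream.
#' @param replace Subsample with replacement (multinomial resampling) instead
#'   of without (hypergeometric rarefaction, the default).
#' @param drop_empty Drop taxa whose counts are zero in every sample after
#'   subsampling. Default keeps them so taxon universes stay aligned across
#'   analyses.
#' @return An `abundance_table` whose sample sums all equal the input's
#'   minimum sample sum.
#' @export
normalize_to_min_depth <- function(table, seed = NULL, replace = FALSE,
                                   drop_empty = FALSE) {
  cts <- count_matrix(table)
  sums <- rowSums(cts)
  if (any(sums == 0)) {
    stopf("cannot rarefy samples with zero total: %s",
          paste(rownames(cts)[sums == 0], collapse = ", "))
  }
  d <- min(sums)
  out <- with_seed(seed, {
    if (replace) {
      t(apply(cts, 1L, function(r) stats::rmultinom(1L, d, r)[, 1L]))
    } else {
      res <- cts
      for (i in seq_len(nrow(cts))) {
        if (sums[i] > d) {
          drawn <- sample.int(sums[i], d)
          res[i, ] <- tabulate(findInterval(drawn - 1L, cumsum(cts[i, ])) + 1L,
                               nbins = ncol(cts))
        }
      }
      res
    }
  })
  dimnames(out) <- dimnames(cts)
  if (drop_empty) out <- out[, colSums(out) > 0, drop = FALSE]
  rank <- if (inherits(table, "abundance_table")) table$rank else "genus"
  abundance_table(out, rank = rank)
}

#' Relative abundance matrix
#'
#' @param table Abundance table (or counts matrix).
#' @return Numeric matrix of per-sample proportions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  cts <- count_matrix(table)
  sums <- rowSums(cts)
  if (any(sums == 0)) {
    stopf("cannot compute proportions for zero-total samples: %s",
          paste(rownames(cts)[sums == 0], collapse = ", "))
  }
  sweep(cts, 1L, sums, "/")
}
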