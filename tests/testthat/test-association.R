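# Group comparisons, fold changes, and the core-compound association matrix.

make_compounds <- function(values_by_group, reps = 3, spread = 0.2) {
  # build a compound table whose group means are exact (replicates are
  # mean + symmetric offsets)
  groups <- names(values_by_group)
  offs <- seq(-spread, spread, length.out = reps)
  rows <- list(); ids <- character(0); glab <- character(0)
  for (g in groups) {
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1L]] <- values_by_group[[g]] + offs[r]
      ids <- c(ids, sprintf("%s_r%d", g, r))
      glab <- c(glab, g)
    }
  }
  v <- do.call(rbind, rows)
  rownames(v) <- ids
  list(compounds = compound_table(v),
       metadata = sample_metadata(ids, glab, rep(seq_len(reps), length(groups))))
}

test_that("one-way ANOVA F matches hand evaluation and identical groups share letters", {
  x <- make_compounds(list(g1 = c(OMA = 2), g2 = c(OMA = 12)), reps = 3, spread = 1)
  # groups (1,2,3) and (11,12,13): between-SS 150, within-SS 4 -> F = 150/1
  cmp <- compare_groups(x$compounds, x$metadata, transform = "none")
  expect_equal(cmp$summary$F, 150, tolerance = 1e-10)
  expect_false(any(cmp$letters[1, "g1"] == strsplit(cmp$letters[1, "g2"], "")[[1]]))

  same <- make_compounds(list(g1 = c(OMA = 5), g2 = c(OMA = 5)), reps = 3, spread = 1)
  cmp2 <- compare_groups(same$compounds, same$metadata, transform = "none")
  expect_equal(cmp2$summary$F, 0, tolerance = 1e-12)
  expect_true(any(strsplit(cmp2$letters[1, "g1"], "")[[1]] %in%
                    strsplit(cmp2$letters[1, "g2"], "")[[1]]))
})

test_that("tukey letters agree with brute-force pairwise HSD comparisons", {
  set.seed(6)
  for (i in 1:15) {
    means <- c(g1 = runif(1, 3, 6), g2 = runif(1, 3, 10), g3 = runif(1, 3, 14))
    x <- make_compounds(lapply(means, function(m) c(OMA = m)), reps = 4,
                        spread = runif(1, 0.3, 1.5))
    cmp <- compare_groups(x$compounds, x$metadata, transform = "none")
    pm <- cmp$tukey_p$OMA
    letters <- cmp$letters[1, ]
    share <- function(a, b) {
      any(strsplit(letters[[a]], "")[[1]] %in% strsplit(letters[[b]], "")[[1]])
    }
    for (a in names(means)) for (b in names(means)) {
      if (a == b) next
      # sharing a letter must mean not significantly different, and any
      # NSD pair must share a letter
      expect_equal(share(a, b), pm[a, b] >= 0.05,
                   info = sprintf("iter %d pair %s-%s", i, a, b))
    }
  }
})

test_that("non-normal residuals trigger the ln transform and non-positive values error", {
  set.seed(3)
  skewed <- lapply(c(g1 = 1, g2 = 5, g3 = 25), function(m) c(OMA = m))
  x <- make_compounds(skewed, reps = 4, spread = 0.1)
  # inject strong skew so Shapiro rejects
  v <- x$compounds$values
  v[, 1] <- exp(seq(0.1, 4, length.out = nrow(v)))[rank(v[, 1], ties.method = "first")]
  cmp <- compare_groups(compound_table(v), x$metadata, transform = "auto")
  res <- stats::residuals(stats::aov(v[, 1] ~ factor(x$metadata$group)))
  want <- if (stats::shapiro.test(res)$p.value < 0.05) "ln" else "none"
  expect_equal(cmp$summary$transform_applied, want)
  cmp_ln <- compare_groups(compound_table(v), x$metadata, transform = "ln")
  expect_equal(cmp_ln$summary$transform_applied, "ln")
  v0 <- v; v0[1, 1] <- 0
  expect_error(compare_groups(compound_table(v0), x$metadata, transform = "ln"),
               "non-positive")
})

test_that("fold change reproduces ratios from group means and inverts cleanly", {
  x <- make_compounds(list(mature = c(OMA = 52.5), flowering = c(OMA = 12.6)))
  fc <- fold_change(x$compounds, x$metadata, "OMA", "mature", "flowering")
  expect_equal(fc$rounded, 4.2)
  inv <- fold_change(x$compounds, x$metadata, "OMA", "flowering", "mature")
  expect_equal(fc$ratio * inv$ratio, 1, tolerance = 1e-12)
  same <- fold_change(x$compounds, x$metadata, "OMA", "mature", "mature")
  expect_equal(same$ratio, 1)
  expect_error(fold_change(x$compounds, x$metadata, "XX", "mature", "flowering"),
               "unknown compound")
})

test_that("association matrix handles perfect monotone, degenerate and planted cases", {
  com <- generate_community(synth_config(seed = 19))
  tab <- com$table
  rel <- relative_abundance(tab)
  tax <- taxon_ids(tab)[1]
  v <- cbind(OMA = rank(rel[, tax]) + 10, MA = rep(5, 12), SC = rep(2, 12),
             OSC = seq_len(12), TOTAL = rank(rel[, tax]) + 10 + 5 + 2 + seq_len(12))
  rownames(v) <- sample_ids(tab)
  am <- core_compound_spearman(tab, compound_table(v), tax)
  expect_equal(am$rho[tax, "OMA"], 1)
  expect_equal(am$star[tax, "OMA"], "**")     # p = 0 at n = 12
  expect_true(is.na(am$rho[tax, "MA"]))       # constant compound
  expect_equal(am$star[tax, "MA"], "")

  # stars are a deterministic function of p
  expect_true(all((am$star == "**") == (!is.na(am$p) & am$p < 0.01)))
  expect_true(all((am$star == "*") == (!is.na(am$p) & am$p >= 0.01 & am$p < 0.05)))
})

test_that("association is invariant to monotone rescaling of compound units", {
  com <- generate_community(synth_config(n_assoc_taxa = 2, seed = 23))
  cp <- generate_compounds(com$table, com$truth, synth_config(n_assoc_taxa = 2, seed = 23))
  core <- taxon_ids(com$table)[1:5]
  a1 <- core_compound_spearman(com$table, cp, core)
  v2 <- cp$values
  v2[, c("OMA", "MA", "SC", "OSC")] <- exp(v2[, c("OMA", "MA", "SC", "OSC")] / 50)
  v2[, "TOTAL"] <- rowSums(v2[, c("OMA", "MA", "SC", "OSC")])
  a2 <- core_compound_spearman(com$table, compound_table(v2), core)
  expect_equal(a1$rho[, c("OMA", "MA", "SC", "OSC")],
               a2$rho[, c("OMA", "MA", "SC", "OSC")], tolerance = 1e-12)

  # sample mismatch errors list the offending ids
  bad <- cp$values[-1, , drop = FALSE]
  expect_error(core_compound_spearman(com$table, compound_table(bad), core),
               sample_ids(com$table)[1])
})

test_that("planted associations at rho 0.9 are starred in most seeds", {
  hits <- vapply(1:40, function(s) {
    cfg <- synth_config(n_assoc_taxa = 1, assoc_rho = 0.9, seed = 400 + s)
    com <- generate_community(cfg)
    cp <- generate_compounds(com$table, com$truth, cfg)
    pr <- com$truth$assoc_pairs
    am <- core_compound_spearman(com$table, cp, pr$taxon)
    abs(am$rho[pr$taxon, pr$compound]) >= 0.6 && am$star[pr$taxon, pr$compound] != ""
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
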