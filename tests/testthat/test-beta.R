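# Distances, clustering, ordination and the ANOSIM permutation test.

test_that("bray-curtis matches hand evaluation and its boundary cases", {
  m <- matrix(c(5, 0, 3,
                2, 4, 3,
                5, 0, 3,
                0, 7, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  d <- as.matrix(bray_curtis(abundance_table(m)))
  expect_equal(d["s1", "s2"], 1 - 2 * 5 / 17, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)                       # identical samples
  expect_equal(d["s1", "s4"], 1)                       # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
})

test_that("weighted unifrac matches hand evaluation and the branch-sum oracle", {
  # two-leaf tree, unit branches, samples on opposite leaves -> 1
  tr <- ape::read.tree(text = "(a:1,b:1);")
  m <- matrix(c(10, 0,
                0, 10,
                10, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("a", "b")))
  d <- as.matrix(weighted_unifrac(abundance_table(m), tr))
  expect_equal(d["A", "B"], 1)
  expect_equal(d["A", "C"], 0)                         # identical proportions

  skip_if_not_installed("phangorn")
  set.seed(3)
  for (i in 1:30) {
    tr6 <- generate_tree(letters[1:6], seed = 100 + i)
    tab <- random_table(4, 6, seed = 200 + i, depth = 300)
    colnames(tab$counts) <- letters[1:6]
    tab <- abundance_table(tab$counts)
    d <- as.matrix(weighted_unifrac(tab, tr6))
    rel <- relative_abundance(tab)
    for (a in 1:3) for (b in (a + 1):4) {
      expect_equal(d[a, b],
                   oracle_wunifrac_pair(tr6, rel[a, ], rel[b, ]),
                   tolerance = 1e-12)
    }
  }
  expect_error(weighted_unifrac(tiny_table(), tr), "absent from tree")
})

test_that("UPGMA reproduces ultrametric inputs and the naive-agglomeration oracle", {
  # two samples: single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  h2 <- upgma_cluster(d2)
  expect_equal(h2$height, 0.4)

  # ultrametric matrix is reproduced exactly in the cophenetic distances
  um <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 4,
                 6, 6, 4, 0), 4, byrow = TRUE,
               dimnames = list(letters[1:4], letters[1:4]))
  hc <- upgma_cluster(um)
  expect_equal(as.matrix(stats::cophenetic(hc))[letters[1:4], letters[1:4]], um)

  set.seed(5)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    dm <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
    dm[upper.tri(dm)] <- runif(n * (n - 1) / 2, 0.1, 1)
    dm <- dm + t(dm)
    hc <- upgma_cluster(dm)
    orc <- oracle_upgma(dm)
    expect_equal(sort(hc$height), sort(orc$heights), tolerance = 1e-12)
    expect_equal(unname(as.matrix(stats::cophenetic(hc))[paste0("s", 1:n), paste0("s", 1:n)]),
                 unname(orc$cophenetic), tolerance = 1e-12)
  }
  bad <- d2; bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(upgma_cluster(bad), "NA/NaN")
})

test_that("pcoa recovers collinear geometry and handles symmetric cases", {
  pts <- c(0, 1, 2)
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoa(dm)
  tol <- max(abs(ord$eigenvalues)) * 1e-8
  expect_equal(sum(ord$eigenvalues > tol), 1L)
  rec <- as.matrix(stats::dist(ord$coordinates[, 1]))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-9)

  # all-equal distances: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(paste0("s", 1:3), paste0("s", 1:3))
  orde <- pcoa(eq)
  pos <- orde$eigenvalues[orde$eigenvalues > 1e-9]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  expect_equal(sum(orde$proportion_explained), 1, tolerance = 1e-9)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2,
                           dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("pcoa proportions are non-increasing and identical samples give zero coordinates", {
  tab <- random_table(6, 10, seed = 21)
  ord <- pcoa(bray_curtis(tab))
  expect_true(all(diff(ord$proportion_explained) <= 1e-12))
  same <- abundance_table(matrix(rep(c(3, 2, 5), each = 4), nrow = 4,
                                 dimnames = list(paste0("s", 1:4), c("a", "b", "c"))))
  os <- pcoa(bray_curtis(same))
  expect_equal(ncol(os$coordinates), 0L)
})

test_that("anosim matches hand evaluation, vegan, and its boundary behaviour", {
  # perfect separation: within < between everywhere -> R = 1
  m <- matrix(c(0, 1, 5, 6,
                1, 0, 7, 8,
                5, 7, 0, 2,
                6, 8, 2, 0), 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  g <- c("A", "A", "B", "B")
  res <- anosim(m, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)

  # hand evaluation on 6 samples: ranks written out explicitly
  set.seed(8)
  d6 <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  d6[upper.tri(d6)] <- sample(1:15)          # distinct ranks 1..15
  d6 <- d6 + t(d6)
  g6 <- c("A", "A", "A", "B", "B", "B")
  pairs <- t(utils::combn(6, 2))
  within <- g6[pairs[, 1]] == g6[pairs[, 2]]
  rk <- d6[pairs]                            # already ranks
  hand_R <- (mean(rk[!within]) - mean(rk[within])) / (15 / 2)
  expect_equal(anosim(d6, g6, n_perm = 9, seed = 1)$R, hand_R, tolerance = 1e-12)

  skip_if_not_installed("vegan")
  vr <- vegan::anosim(stats::as.dist(d6), grouping = factor(g6), permutations = 0)
  expect_equal(anosim(d6, g6, n_perm = 9, seed = 1)$R, unname(vr$statistic),
               tolerance = 1e-12)

  expect_error(anosim(m, c("A", "A", "A", "B")), "at least 2 samples")
  expect_error(anosim(m, rep("A", 4)), "at least 2 groups")
})

test_that("anosim p is seed-reproducible and invariant to label renaming", {
  tab <- random_table(8, 10, seed = 31)
  dm <- bray_curtis(tab)
  g <- rep(c("A", "B"), each = 4)
  r1 <- anosim(dm, g, n_perm = 199, seed = 5)
  r2 <- anosim(dm, g, n_perm = 199, seed = 5)
  expect_identical(r1$p, r2$p)
  g2 <- ifelse(g == "A", "group_one", "group_two")
  r3 <- anosim(dm, g2, n_perm = 199, seed = 5)
  expect_equal(r1$R, r3$R)
  expect_identical(r1$p, r3$p)
})

test_that("distance matrices round-trip through square TSV", {
  tab <- random_table(5, 7, seed = 13)
  dm <- bray_curtis(tab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, path)
  back <- read_distance_matrix(path)
  expect_equal(as.matrix(back), as.matrix(dm), tolerance = 1e-12)
})
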