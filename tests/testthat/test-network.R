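# Spearman screening, the edge rule, topology, centralities and the hub
# classifier.

test_that("spearman matrix handles monotone, reversed and degenerate taxa", {
  # equal row sums, so relative abundance ranks equal count ranks
  m <- matrix(c(1, 5, 7, 7,
                2, 4, 7, 7,
                3, 3, 7, 7,
                4, 2, 7, 7,
                5, 1, 7, 7), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:5),
                              c("up", "down", "flat", "flat2")))
  sm <- spearman_matrix(abundance_table(m), min_prevalence = 0)
  expect_equal(sm$rho["up", "down"], -1)
  expect_equal(sm$p["up", "down"], 0)
  # a taxon constant in relative abundance gives NA rho/p for its pairs
  expect_true(is.na(sm$rho["flat", "up"]))
  expect_true(is.na(sm$p["flat", "up"]))
  # and a perfectly monotone pair is +1 with p = 0
  m2 <- m; m2[, "down"] <- c(1, 3, 5, 9, 11); m2[, "flat"] <- c(13, 10, 6, 2, 0)
  sm2 <- spearman_matrix(abundance_table(m2), min_prevalence = 0)
  expect_equal(sm2$rho["up", "down"], 1)
  expect_error(spearman_matrix(abundance_table(m[1:3, ])), ">= 4 samples")
})

test_that("spearman test matches the midrank and exact-permutation oracles", {
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 4)
  st <- spearman_test(x, y, method = "exact")
  expect_equal(st$rho, 0.5)                    # Pearson on midranks, by hand
  expect_equal(st$rho, oracle_spearman_rho(x, y))
  expect_equal(st$p, 2 / 3)                    # 16 of 24 permutations tie or beat
  expect_equal(st$p, oracle_spearman_p_exact(x, y))
  # randomized equivalence at n = 5..6, with and without ties
  set.seed(14)
  for (i in 1:40) {
    n <- sample(5:6, 1)
    xx <- sample(1:4, n, replace = TRUE)
    yy <- sample(1:5, n, replace = TRUE)
    if (length(unique(xx)) < 2 || length(unique(yy)) < 2) next
    ours <- spearman_test(xx, yy, method = "exact")
    expect_equal(ours$rho, oracle_spearman_rho(xx, yy), tolerance = 1e-12)
    expect_equal(ours$p, oracle_spearman_p_exact(xx, yy), tolerance = 1e-12)
  }
})

test_that("the edge rule is strict on both thresholds and records sign", {
  taxa <- c("a", "b", "c", "d")
  rho <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  p <- matrix(1, 4, 4, dimnames = list(taxa, taxa))
  rho["a", "b"] <- rho["b", "a"] <- 0.59; p["a", "b"] <- p["b", "a"] <- 0.001
  rho["a", "c"] <- rho["c", "a"] <- -0.8; p["a", "c"] <- p["c", "a"] <- 0.01
  rho["b", "c"] <- rho["c", "b"] <- 0.7;  p["b", "c"] <- p["c", "b"] <- 0.05
  net <- build_network(rho, p)
  expect_equal(nrow(net$edges), 1L)            # 0.59 fails rho; p = 0.05 fails p
  expect_equal(net$edges$sign, "negative")
  expect_setequal(net$nodes$taxon, c("a", "c"))  # isolated taxa excluded

  # random matrices vs brute-force double filter
  set.seed(9)
  for (i in 1:30) {
    n <- 8
    ids <- sprintf("t%02d", 1:n)
    r <- matrix(runif(n * n, -1, 1), n, dimnames = list(ids, ids))
    r[lower.tri(r)] <- t(r)[lower.tri(r)]; diag(r) <- 1
    q <- matrix(runif(n * n), n, dimnames = list(ids, ids))
    q[lower.tri(q)] <- t(q)[lower.tri(q)]; diag(q) <- NA
    net <- build_network(r, q)
    want <- 0L
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (abs(r[a, b]) > 0.6 && q[a, b] < 0.05) want <- want + 1L
    }
    expect_equal(nrow(net$edges), want)
  }
})

test_that("topology matches the triangle case and avgK is always 2E/N", {
  taxa <- c("a", "b", "c")
  rho <- matrix(0.9, 3, 3, dimnames = list(taxa, taxa))
  p <- matrix(1e-6, 3, 3, dimnames = list(taxa, taxa)); diag(p) <- NA
  net <- build_network(rho, p)
  topo <- network_topology(net, seed = 1)
  expect_equal(topo$avgK, 2)
  expect_equal(topo$avgCC, 1)
  expect_equal(topo$avg_path, 1)
  expect_equal(topo$pct_positive_edges, 100)

  for (s in 1:10) {
    adj <- endocore:::with_seed(s, random_adjacency(7, 0.35))
    if (sum(adj) == 0) next
    net <- network_from_adjacency(adj)
    topo <- network_topology(net, seed = s)
    expect_equal(topo$avgK, 2 * topo$n_edges / topo$n_nodes, tolerance = 1e-15)
  }
})

test_that("centralities match extremal cases and the brute-force oracle", {
  # star with 3 leaves: center maximal on all three measures
  adj <- matrix(0L, 4, 4); adj[1, 2:4] <- adj[2:4, 1] <- 1L
  net <- network_from_adjacency(adj)
  ct <- centralities(net)
  center <- ct[ct$taxon == "n01", ]
  expect_equal(center$degree_centrality, 1)
  expect_equal(center$betweenness_centrality, 1)
  expect_equal(center$closeness_centrality, 1)

  # path a-b-c: middle has betweenness 1, ends 0
  adj3 <- matrix(0L, 3, 3); adj3[1, 2] <- adj3[2, 1] <- 1L
  adj3[2, 3] <- adj3[3, 2] <- 1L
  ct3 <- centralities(network_from_adjacency(adj3))
  expect_equal(ct3$betweenness_centrality[ct3$taxon == "n02"], 1)
  expect_equal(ct3$betweenness_centrality[ct3$taxon == "n01"], 0)

  # randomized equivalence on graphs up to 8 nodes (incl. disconnected)
  set.seed(4)
  for (i in 1:30) {
    n <- sample(5:8, 1)
    adj <- random_adjacency(n, runif(1, 0.25, 0.5))
    if (sum(adj) == 0) next
    keep <- rowSums(adj) > 0                 # package keeps only edge endpoints
    adj <- adj[keep, keep, drop = FALSE]
    if (nrow(adj) < 3) next
    ct <- centralities(network_from_adjacency(adj))
    ord <- match(sprintf("n%02d", which(keep)), ct$taxon)
    ord <- order(ct$taxon)
    ct <- ct[ord, ]
    expect_equal(ct$degree_centrality, oracle_degree_centrality(adj),
                 tolerance = 1e-12)
    expect_equal(ct$betweenness_centrality, oracle_betweenness(adj),
                 tolerance = 1e-12)
    expect_equal(ct$closeness_centrality, oracle_closeness(adj),
                 tolerance = 1e-12)
  }
})

test_that("hub rule is a strict triple filter sorted by degree", {
  net <- network_from_adjacency({
    adj <- matrix(0L, 4, 4); adj[1, 2:4] <- adj[2:4, 1] <- 1L; adj
  })
  # star center exceeds every threshold; leaves fail
  expect_equal(hub_core(net), "n01")

  # boundary: thresholds are strict (values exactly at a threshold fail)
  ct <- centralities(net)
  rule <- hub_rule(degree_min = 0.2, closeness_min = 0.35, betweenness_min = 0.35)
  hits <- ct$degree_centrality > 0.2 & ct$closeness_centrality > 0.35 &
    ct$betweenness_centrality > 0.35
  expect_setequal(hub_core(net, rule), ct$taxon[hits])

  # random centrality tables vs brute-force triple filter via adjacency graphs
  set.seed(22)
  for (i in 1:20) {
    adj <- random_adjacency(7, 0.3)
    if (sum(adj) == 0) next
    keep <- rowSums(adj) > 0
    adj <- adj[keep, keep, drop = FALSE]
    if (nrow(adj) < 3) next
    netr <- network_from_adjacency(adj)
    ctr <- centralities(netr)
    want <- ctr$taxon[ctr$degree_centrality > 0.2 &
                        ctr$closeness_centrality > 0.35 &
                        ctr$betweenness_centrality > 0.35]
    expect_setequal(hub_core(netr), want)
  }
})

test_that("network is invariant to sample order and per-sample depth scaling", {
  tab <- generate_community(synth_config(n_taxa = 20, n_hub_cliques = 1,
                                         clique_size = 4, seed = 33))$table
  sm1 <- spearman_matrix(tab)
  net1 <- build_network(sm1)
  key <- function(net) sort(paste(net$edges$from, net$edges$to))

  perm <- sample_ids(tab)[c(7, 1, 12, 3, 9, 2, 11, 4, 10, 5, 8, 6)]
  net2 <- build_network(spearman_matrix(abundance_table(tab$counts[perm, ])))
  expect_identical(key(net1), key(net2))

  # scaling every count by a constant preserves all relative-abundance ranks
  net3 <- build_network(spearman_matrix(abundance_table(tab$counts * 7L)))
  expect_identical(key(net1), key(net3))
  expect_equal(sm1$rho, spearman_matrix(abundance_table(tab$counts * 7L))$rho,
               tolerance = 1e-12)
})

test_that("a planted clique is recovered as a connected subgraph", {
  connected <- vapply(1:50, function(s) {
    cfg <- synth_config(n_taxa = 26, n_hub_cliques = 1, clique_size = 6,
                        clique_rho = 0.95, n_assoc_taxa = 0, depth = 50000,
                        seed = s)
    com <- generate_community(cfg)
    net <- build_network(spearman_matrix(com$table))
    cl <- com$truth$hub_taxa
    ed <- net$edges
    prs <- utils::combn(cl, 2)
    all(apply(prs, 2, function(p) {
      any((ed$from == p[1] & ed$to == p[2]) | (ed$from == p[2] & ed$to == p[1]))
    }))
  }, logical(1))
  expect_gte(mean(connected), 0.8)
})

test_that("empty networks are handled with a warning, not an error", {
  taxa <- c("a", "b")
  rho <- matrix(0.1, 2, 2, dimnames = list(taxa, taxa))
  p <- matrix(0.9, 2, 2, dimnames = list(taxa, taxa)); diag(p) <- NA
  net <- build_network(rho, p)
  expect_equal(nrow(net$edges), 0L)
  expect_warning(topo <- network_topology(net), "empty")
  expect_equal(topo$n_nodes, 0L)
  expect_equal(topo$avgK, 0)
})
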