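# Independent brute-force oracles used to validate the package's optimized
# routines on small instances. Everything here favours clarity over speed
# and shares no code path with the implementation under test.

# --- graph oracles (adjacency-matrix input, nodes 1..N) ---------------------

# all shortest-path distances by breadth-first search from each node
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (d[s, w] > lev) {
            d[s, w] <- lev
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# enumerate every simple path between two nodes (tiny graphs only)
oracle_all_paths <- function(adj, from, to) {
  paths <- list()
  walk <- function(v, seen) {
    if (v == to) {
      paths[[length(paths) + 1L]] <<- seen
      return(invisible())
    }
    for (w in which(adj[v, ] > 0)) {
      if (!w %in% seen) walk(w, c(seen, w))
    }
  }
  walk(from, from)
  paths
}

# betweenness by explicit shortest-path enumeration, normalized by
# (N-1)(N-2)/2
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bt <- numeric(n)
  d <- oracle_distances(adj)
  for (s in seq_len(n - 1L)) {
    for (t in seq((s + 1L), n)) {
      if (!is.finite(d[s, t])) next
      paths <- oracle_all_paths(adj, s, t)
      lens <- vapply(paths, length, integer(1)) - 1L
      short <- paths[lens == d[s, t]]
      for (v in setdiff(seq_len(n), c(s, t))) {
        thru <- sum(vapply(short, function(p) v %in% p, logical(1)))
        bt[v] <- bt[v] + thru / length(short)
      }
    }
  }
  bt / ((n - 1) * (n - 2) / 2)
}

# Wasserman-Faust closeness from the BFS distance matrix
oracle_closeness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) return(0)
    nc1 <- sum(reach)
    (nc1 / sum(di[reach])) * (nc1 / (n - 1))
  }, numeric(1))
}

oracle_degree_centrality <- function(adj) rowSums(adj > 0) / (nrow(adj) - 1)

# random connected-ish undirected graph as adjacency matrix
random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

# wrap an adjacency matrix as a cooccurrence_network so the package's
# centrality code can run on it
network_from_adjacency <- function(adj) {
  n <- nrow(adj)
  taxa <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(taxa, taxa)
  rho <- matrix(0, n, n, dimnames = dimnames(adj))
  rho[adj > 0] <- 0.9
  p <- matrix(1, n, n, dimnames = dimnames(adj))
  p[adj > 0] <- 1e-6
  diag(p) <- NA
  build_network(rho, p)
}

# --- UPGMA oracle -----------------------------------------------------------

# naive average-linkage agglomeration; returns the sorted merge heights and
# the cophenetic matrix (averages computed over the ORIGINAL distances,
# which is exactly UPGMA)
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_len(m - 1L)) {
      for (b in seq((a + 1L), m)) {
        avg <- mean(d[clusters[[a]], clusters[[b]]])
        if (avg < bestd) { bestd <- avg; best <- c(a, b) }
      }
    }
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- bestd
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- bestd
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# --- weighted UniFrac oracle ------------------------------------------------

# brute-force branch enumeration using phangorn::Descendants for the clade
# tip sets; normalized weighted UniFrac between two relative-abundance
# vectors named by tip label
oracle_wunifrac_pair <- function(tree, pa, pb) {
  num <- 0; den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2L]
    tips <- tree$tip.label[phangorn::Descendants(tree, child, "tips")[[1L]]]
    wa <- sum(pa[tips]); wb <- sum(pb[tips])
    num <- num + tree$edge.length[k] * abs(wa - wb)
    den <- den + tree$edge.length[k] * (wa + wb)
  }
  if (den > 0) num / den else 0
}

# --- Faith PD oracle --------------------------------------------------------

# union of root-to-leaf paths via ape::nodepath
oracle_pd <- function(tree, present) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- cbind(tree$edge, seq_len(nrow(tree$edge)))
  used <- logical(nrow(tree$edge))
  for (tip in match(present, tree$tip.label)) {
    np <- ape::nodepath(tree, root, tip)
    for (k in seq_len(length(np) - 1L)) {
      hit <- which(edges[, 1L] == np[k] & edges[, 2L] == np[k + 1L])
      used[hit] <- TRUE
    }
  }
  sum(tree$edge.length[used])
}

# --- Spearman oracles -------------------------------------------------------

oracle_spearman_rho <- function(x, y) stats::cor(rank(x), rank(y))

# exact permutation p by explicit loop over every permutation of y
oracle_spearman_p_exact <- function(x, y) {
  n <- length(x)
  perms <- permutations_list(n)
  obs <- abs(oracle_spearman_rho(x, y))
  hits <- 0L
  for (pm in perms) {
    if (abs(stats::cor(rank(x), rank(y)[pm])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / length(perms)
}

permutations_list <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_list(n - 1L)
  out <- vector("list", 0L)
  for (k in seq_len(n)) {
    out <- c(out, lapply(sub, function(pm) {
      c(k, pm + (pm >= k))
    }))
  }
  out
}
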