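# Independent brute-force oracles used by the tests. These deliberately share
# no code with the package implementations they check.

# --- random fixtures --------------------------------------------------------

# random weighted bipartite network with no all-zero rows/columns
random_net <- function(np, nb, max_count = 9, fill = 0.5) {
  repeat {
    w <- matrix(ifelse(runif(np * nb) < fill,
                       sample.int(max_count, np * nb, replace = TRUE), 0),
                nrow = np,
                dimnames = list(sprintf("p%02d", seq_len(np)),
                                sprintf("b%02d", seq_len(nb))))
    if (all(rowSums(w) > 0) && all(colSums(w) > 0)) return(w)
  }
}

as_net <- function(w, site = "s", year = "2013", round = 1) {
  structure(list(weights = w, site = site, year = year, round = round),
            class = "interaction_network")
}

# --- UPGMA total branch length ----------------------------------------------

# from-scratch average-linkage clustering on a profile matrix: cluster
# distance = mean over all cross pairs of the original Euclidean distances;
# total branch length under node height = merge distance, leaves at 0
oracle_upgma_branch_length <- function(prof) {
  n <- nrow(prof)
  if (n < 2) return(0)
  d0 <- as.matrix(dist(prof))
  clusters <- as.list(seq_len(n))
  heights <- rep(0, n)           # height of each active cluster's root
  total <- 0
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dd <- mean(d0[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    h <- best[1]; i <- best[2]; j <- best[3]
    total <- total + (h - heights[i]) + (h - heights[j])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    heights[i] <- h
    clusters[[j]] <- NULL
    heights <- heights[-j]
  }
  total
}

# --- shortest-path centralities ---------------------------------------------

oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in which(adj[v, ])) {
      if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
    }
    frontier <- unique(nxt)
  }
  d
}

# enumerate all shortest s-t paths by layered DFS
oracle_shortest_paths <- function(adj, s, t, d_s) {
  res <- list()
  expand <- function(path) {
    v <- path[length(path)]
    if (v == t) { res[[length(res) + 1]] <<- path; return(invisible()) }
    for (w in which(adj[v, ]))
      if (d_s[w] == d_s[v] + 1 && d_s[w] <= d_s[t]) expand(c(path, w))
  }
  if (is.finite(d_s[t])) expand(s)
  res
}

# normalized betweenness on an undirected unweighted graph (adjacency matrix)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  if (n < 3) return(btw)
  dl <- lapply(seq_len(n), function(s) oracle_bfs_dist(adj, s))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_shortest_paths(adj, s, t, dl[[s]])
    if (length(paths) == 0) next
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / length(paths)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# normalized harmonic closeness: sum of inverse distances over n - 1
oracle_harmonic_closeness <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(s) {
    d <- oracle_bfs_dist(adj, s)[-s]
    sum(1 / d[is.finite(d) & d > 0]) / (n - 1)
  }, numeric(1))
}

# --- multivariate dispersion ------------------------------------------------

# mean distance to centroid straight from a dissimilarity matrix:
# z_i^2 = (1/n) sum_j d_ij^2 - (1/n^2) sum_{j<k} d_jk^2
oracle_dispersion <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  ss <- sum(d[upper.tri(d)]^2) / n^2
  z2 <- rowSums(d^2) / n - ss
  mean(sqrt(pmax(z2, 0)))
}

# --- small utilities --------------------------------------------------------

# simulated dataset small enough for fast replicate tests
small_params <- function(seed, ...) {
  sim_params(n_sites = 10, grid_size = 30, n_plants = 12, n_pollinators = 15,
             seed = seed, ...)
}
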