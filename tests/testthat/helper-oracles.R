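# Independent brute-force oracles, written directly from the definitions and
# deliberately sharing no code with the package (pure base R, no igraph).

# All-pairs shortest-path matrix by Floyd-Warshall.
bf_distances <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_degree <- function(adj) as.integer(rowSums(adj))

bf_density <- function(adj) {
  n <- nrow(adj)
  sum(adj) / (n * (n - 1))
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  D <- bf_distances(adj)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    }
  }
  s / (n * (n - 1))
}

# Triangles through each node by exhaustive triple scan.
bf_clustering <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    k <- sum(adj[v, ])
    if (k < 2) next
    tri <- 0
    nb <- which(adj[v, ] == 1)
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]] == 1) tri <- tri + 1
      }
    }
    out[v] <- tri / (k * (k - 1) / 2)
  }
  out
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) next
    out[v] <- bf_global_efficiency(adj[nb, nb, drop = FALSE])
  }
  out
}

# Betweenness by shortest-path counting: number of geodesics from s passing
# through v is nsp_s(v) * nsp_t(v) when dist_s(v) + dist_t(v) == dist_s(t).
bf_path_counts <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  nsp <- rep(0, n)
  dist[s] <- 0
  nsp[s] <- 1
  frontier <- s
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (dist[w] >= d) {
          if (is.infinite(dist[w])) {
            dist[w] <- d
            nxt <- c(nxt, w)
          }
          if (dist[w] == d) nsp[w] <- nsp[w] + nsp[v]
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, nsp = nsp)
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  pc <- lapply(seq_len(n), function(s) bf_path_counts(adj, s))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      dst <- pc[[s]]$dist[t]
      if (!is.finite(dst)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (pc[[s]]$dist[v] + pc[[t]]$dist[v] == dst) {
          btw[v] <- btw[v] + pc[[s]]$nsp[v] * pc[[t]]$nsp[v] / pc[[s]]$nsp[t]
        }
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# Benjamini-Hochberg step-up, literal definition.
bf_bh <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ord <- order(p)
  sorted <- p[ord]
  passing <- which(sorted <= seq_len(m) * q / m)
  if (!length(passing)) return(rep(FALSE, m))
  p <= sorted[max(passing)]
}

# Random binary symmetric hollow adjacency with labels.
random_adjacency <- function(n, prob) {
  adj <- matrix(0L, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- stats::rbinom(sum(ut), 1, prob)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("R%02d", 1:n), sprintf("R%02d", 1:n))
  adj
}
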