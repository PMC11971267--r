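# Independent oracles used across tests. These deliberately share no code with
# the package: distances and betweenness come from exhaustive enumeration of
# all simple paths, and the remaining statistics from direct formula
# recomputation on the enumerated distances.

# Enumerate every simple path between every pair; return shortest-path
# distances, multiplicities, and fractional betweenness credit (overall and
# restricted to cross-community pairs).
oracle_network_stats <- function(W, comm, tol = 1e-12) {
  p <- nrow(W)
  A <- abs(W)
  dist <- matrix(Inf, p, p)
  diag(dist) <- 0
  sigma <- matrix(0, p, p)
  diag(sigma) <- 1
  btw <- numeric(p)
  bbtw <- numeric(p)

  paths_between <- function(i, j) {
    out <- list()
    dfs <- function(v, visited, len) {
      if (v == j) {
        out[[length(out) + 1L]] <<- list(path = visited, len = len)
        return(invisible())
      }
      for (u in seq_len(p)) {
        if (A[v, u] > 0 && !(u %in% visited)) {
          dfs(u, c(visited, u), len + 1 / A[v, u])
        }
      }
    }
    dfs(i, i, 0)
    out
  }

  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ps <- paths_between(i, j)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      minimal <- which(lens <= dmin + tol * max(1, dmin))
      dist[i, j] <- dist[j, i] <- dmin
      sigma[i, j] <- sigma[j, i] <- length(minimal)
      cross <- comm[i] != comm[j]
      for (k in minimal) {
        interior <- setdiff(ps[[k]]$path, c(i, j))
        for (v in interior) {
          btw[v] <- btw[v] + 1 / length(minimal)
          if (cross) bbtw[v] <- bbtw[v] + 1 / length(minimal)
        }
      }
    }
  }

  strength <- rowSums(A)
  bridge_strength <- vapply(seq_len(p), function(i)
    sum(A[i, comm != comm[i]]), numeric(1))
  closeness <- vapply(seq_len(p), function(i) {
    d <- dist[i, -i]
    d <- d[is.finite(d)]
    if (!length(d) || sum(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  bridge_closeness <- vapply(seq_len(p), function(i) {
    d <- dist[i, comm != comm[i]]
    d <- d[is.finite(d)]
    if (!length(d) || mean(d) == 0) 0 else 1 / mean(d)
  }, numeric(1))

  list(dist = dist, sigma = sigma,
       strength = unname(strength), closeness = closeness, betweenness = btw,
       bridge_strength = bridge_strength,
       bridge_closeness = bridge_closeness, bridge_betweenness = bbtw)
}

# Random signed weighted graph with a random 2-community split.
random_graph <- function(p, edge_prob = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < edge_prob) {
      w <- runif(1, 0.1, 1) * sample(c(-1, 1), 1)
      W[i, j] <- W[j, i] <- w
    }
  }
  labels <- paste0("n", seq_len(p))
  dimnames(W) <- list(labels, labels)
  k <- sample(seq_len(p - 1), 1)
  comm <- setNames(rep("Bs", p), labels)
  comm[sample(p, k)] <- "Ls"
  network_graph(W, labels, comm)
}

# The 3-node toy used throughout: w12 = 0.5, w13 = 0.25, w23 = 0,
# communities {1, 2} Ls vs {3} Bs.
toy_graph <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.25
  labels <- c("a", "b", "c")
  dimnames(W) <- list(labels, labels)
  network_graph(W, labels, setNames(c("Ls", "Ls", "Bs"), labels))
}

# Small panel sampled from the default spec, shared across tests.
small_panel <- function(n = 1500, seed = 42) {
  sample_panel(default_skill_spec(), n, seed = seed)
}
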