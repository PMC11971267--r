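#' Construct a signed weighted network with two communities
#'
#' @param W Symmetric weight matrix (regularized partial correlations), zero
#'   diagonal; an edge is present wherever `W[i,j] != 0`.
#' @param labels Node names; defaults to `colnames(W)`.
#' @param community_of Named map node -> `"Ls"`/`"Bs"`.
#' @return A `network_graph`.
#' @export
network_graph <- function(W, labels = colnames(W), community_of) {
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-10)
    stop("weight matrix is not symmetric", call. = FALSE)
  if (any(diag(W) != 0)) stop("weight matrix must have zero diagonal",
                              call. = FALSE)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  if (!all(labels %in% names(community_of)))
    stop("community_of must name every node", call. = FALSE)
  structure(list(W = W, labels = labels,
                 community_of = community_of[labels]),
            class = "network_graph")
}

#' Network graph of a fitted model
#'
#' @param fit A `ggm_fit`.
#' @param community_of Community map; defaults to the TGMD-3 schema when the
#'   labels match it.
#' @return A `network_graph`.
#' @export
ggm_network <- function(fit, community_of = NULL) {
  if (is.null(community_of)) {
    s <- tgmd3_schema()
    if (!all(fit$C$labels %in% s$labels))
      stop("supply community_of for non-TGMD-3 labels", call. = FALSE)
    community_of <- s$community_of
  }
  network_graph(fit$W, fit$C$labels, community_of)
}

comm_int <- function(G) as.integer(factor(G$community_of)) - 1L

check_two_communities <- function(G) {
  if (length(unique(G$community_of)) < 2)
    stop("bridge statistics need two nonempty communities", call. = FALSE)
}

stats_cols <- c("strength", "closeness", "betweenness",
                "bridge_strength", "bridge_closeness", "bridge_betweenness")

compute_stats <- function(G, tol = 1e-12) {
  out <- network_stats_cpp(G$W, comm_int(G), tol = tol)
  dimnames(out$dist) <- list(G$labels, G$labels)
  dimnames(out$sigma) <- list(G$labels, G$labels)
  dimnames(out$stats) <- list(G$labels, stats_cols)
  out
}

#' Shortest-path distances with path multiplicities
#'
#' Edge length is the inverse absolute weight `1/|w|`; Dijkstra's algorithm is
#' run from every source. Unreachable pairs get `Inf`. `sigma[i,j]` counts the
#' distinct shortest paths from `i` to `j` (ties resolved at tolerance `tol`).
#'
#' @param G A `network_graph`.
#' @param tol Path-length tie tolerance.
#' @return List with `dist` and `sigma` matrices.
#' @export
shortest_path_distances <- function(G, tol = 1e-12) {
  out <- compute_stats(G, tol)
  out$dist <- (out$dist + t(out$dist)) / 2
  list(dist = out$dist, sigma = out$sigma)
}

#' Strength centrality
#'
#' Sum of absolute edge weights at each node.
#'
#' @param G A `network_graph`.
#' @return Named numeric vector.
#' @export
strength <- function(G) {
  s <- rowSums(abs(G$W))
  setNames(s, G$labels)
}

#' Closeness centrality
#'
#' Inverse of the summed shortest-path distances to all reachable nodes
#' (unreachable nodes are excluded from the sum; a node with nothing
#' reachable scores 0).
#'
#' @param G A `network_graph`.
#' @return Named numeric vector.
#' @export
closeness <- function(G) compute_stats(G)$stats[, "closeness"]

# Full-credit tie counting: a node v intermediates the pair (j, k) if it lies
# on ANY shortest j-k path; each such pair contributes 1 (not a fraction).
betweenness_count_all <- function(G, cross_only = FALSE, tol = 1e-12) {
  d <- shortest_path_distances(G, tol)$dist
  p <- nrow(d)
  comm <- comm_int(G)
  out <- setNames(numeric(p), G$labels)
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    if (!is.finite(d[j, k])) next
    if (cross_only && comm[j] == comm[k]) next
    for (v in seq_len(p)) {
      if (v == j || v == k) next
      through <- d[j, v] + d[v, k]
      if (is.finite(through) &&
          abs(through - d[j, k]) <= tol * max(1, abs(through)))
        out[v] <- out[v] + 1
    }
  }
  out
}

#' Betweenness centrality
#'
#' Sum over unordered node pairs of the fraction of shortest paths passing
#' through the node (Brandes accumulation; equal-length paths share credit).
#' `ties = "count"` switches to full credit: every pair whose shortest-path
#' set contains the node contributes 1, for cross-checking against other
#' conventions.
#'
#' @param G A `network_graph`.
#' @param ties `"fractional"` (default) or `"count"`.
#' @return Named numeric vector.
#' @export
betweenness <- function(G, ties = c("fractional", "count")) {
  ties <- match.arg(ties)
  if (ties == "count") return(betweenness_count_all(G))
  compute_stats(G)$stats[, "betweenness"]
}

#' Bridge strength
#'
#' Sum of absolute weights of edges to the other community.
#'
#' @param G A `network_graph` with two nonempty communities.
#' @return Named numeric vector.
#' @export
bridge_strength <- function(G) {
  check_two_communities(G)
  compute_stats(G)$stats[, "bridge_strength"]
}

#' Bridge closeness
#'
#' Inverse of the mean shortest-path distance to reachable nodes outside the
#' node's own community (0 if none reachable). Note the deliberate asymmetry
#' with [closeness()]: closeness inverts the SUM of distances, bridge
#' closeness the MEAN of out-community distances.
#'
#' @param G A `network_graph` with two nonempty communities.
#' @return Named numeric vector.
#' @export
bridge_closeness <- function(G) {
  check_two_communities(G)
  compute_stats(G)$stats[, "bridge_closeness"]
}

#' Bridge betweenness
#'
#' Betweenness restricted to unordered pairs of nodes in different
#' communities (fractional credit on ties; `ties = "count"` as in
#' [betweenness()]).
#'
#' @param G A `network_graph` with two nonempty communities.
#' @param ties `"fractional"` (default) or `"count"`.
#' @return Named numeric vector.
#' @export
bridge_betweenness <- function(G, ties = c("fractional", "count")) {
  check_two_communities(G)
  ties <- match.arg(ties)
  if (ties == "count") return(betweenness_count_all(G, cross_only = TRUE))
  compute_stats(G)$stats[, "bridge_betweenness"]
}

#' All six centrality statistics per node
#'
#' Strength, closeness and betweenness, plus their bridge versions, in the
#' graph's fixed node order.
#'
#' @param G A `network_graph` with two nonempty communities.
#' @return A `centrality_table` data frame: `node`, `community`, and the six
#'   statistics.
#' @export
centrality_table <- function(G) {
  check_two_communities(G)
  st <- compute_stats(G)$stats
  df <- data.frame(node = G$labels,
                   community = unname(G$community_of),
                   st, row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("centrality_table", "data.frame")
  df
}

#' Write a centrality table as TSV
#'
#' @param tab A `centrality_table`.
#' @param path Output path.
#' @export
write_centrality_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
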