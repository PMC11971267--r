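#' TGMD-3 skill labels, communities and per-skill maxima
#'
#' The Test of Gross Motor Development (3rd ed.) measures 13 skills in two
#' subscales: six Locomotor skills (`Ls`, subscale maximum 46) and seven Ball
#' skills (`Bs`, subscale maximum 54). Per-skill maxima are not fixed by the
#' subscale totals alone; the defaults here are one configuration consistent
#' with the TGMD-3 criterion counts (each criterion scored 0/1 over two
#' trials) that sums to 46 and 54.
#'
#' @return A list with `labels`, `community_of` (named character vector with
#'   values `"Ls"`/`"Bs"`) and `score_max` (named integer vector).
#' @export
tgmd3_schema <- function() {
  labels <- c("run", "gallop", "hop", "skip", "horizontal_jump", "slide",
              "two_hand_strike", "forehand_strike", "one_hand_dribble",
              "two_hand_catch", "kick", "overhand_throw", "underhand_throw")
  community_of <- setNames(c(rep("Ls", 6), rep("Bs", 7)), labels)
  score_max <- setNames(c(8L, 8L, 8L, 8L, 6L, 8L,
                          10L, 8L, 8L, 6L, 8L, 8L, 6L), labels)
  stopifnot(sum(score_max[community_of == "Ls"]) == 46L,
            sum(score_max[community_of == "Bs"]) == 54L)
  list(labels = labels, community_of = community_of, score_max = score_max)
}

pcor_from_theta <- function(theta) {
  d <- sqrt(diag(theta))
  P <- -theta / outer(d, d)
  diag(P) <- 1
  P
}

# Add to the diagonal in steps of 0.05 until the smallest eigenvalue reaches
# `target`; errors after `max_steps` loadings.
load_to_pd <- function(theta, target = 0.05, step = 0.05, max_steps = 100L) {
  for (k in 0:max_steps) {
    ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= target) return(theta)
    diag(theta) <- diag(theta) + step
  }
  stop("could not repair positive definiteness within ", max_steps,
       " diagonal loading steps", call. = FALSE)
}

new_precision_spec <- function(theta, labels, community_of, hub_nodes,
                               connectivity_scale = 1) {
  p <- nrow(theta)
  dimnames(theta) <- list(labels, labels)
  spec <- structure(list(
    size = p,
    labels = labels,
    community_of = community_of[labels],
    theta = theta,
    true_pcor = pcor_from_theta(theta),
    hub_nodes = hub_nodes,
    connectivity_scale = connectivity_scale
  ), class = "precision_spec")
  validate_precision_spec(spec)
}

validate_precision_spec <- function(spec) {
  th <- spec$theta
  if (max(abs(th - t(th))) > 1e-10)
    stop("precision matrix is not symmetric", call. = FALSE)
  ev <- eigen(th, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("precision matrix is not positive definite", call. = FALSE)
  if (!all(spec$hub_nodes %in% spec$labels))
    stop("hub node(s) not in labels: ",
         paste(setdiff(spec$hub_nodes, spec$labels), collapse = ", "),
         call. = FALSE)
  for (h in spec$hub_nodes) {
    other <- spec$labels[spec$community_of != spec$community_of[h]]
    if (!any(abs(spec$true_pcor[h, other]) > 1e-12))
      stop("hub node '", h, "' has no cross-community edge", call. = FALSE)
  }
  spec
}

#' Build a random community-structured precision spec
#'
#' Constructs a sparse symmetric positive-definite precision matrix over two
#' node communities: within-community edges are placed at random with the
#' requested density, cross-community edges exactly at the requested pairs,
#' and every hub node is guaranteed at least two cross-community partners
#' (extra partners are added at random if the supplied `cross_edges` give it
#' fewer). Edge magnitudes are drawn uniformly from `weight_range` (these are
#' the target partial correlations; the matrix has unit diagonal before any
#' loading). Positive definiteness is repaired, if needed, by adding 0.05 to
#' the diagonal repeatedly, after which the implied partial correlations are
#' recomputed — so `true_pcor` is always exact for the returned `theta`.
#'
#' @param p Node count.
#' @param community_sizes Integer pair summing to `p` (first community `Ls`,
#'   second `Bs`).
#' @param within_density Fraction of within-community pairs that get an edge.
#' @param cross_edges List of length-2 label (or index) vectors joining the
#'   two communities.
#' @param hub_nodes Labels designated as cross-community hubs.
#' @param weight_range Interval in (0, 1) for edge magnitudes.
#' @param prob_negative Probability that an edge weight is negative.
#' @param connectivity_scale Multiplier applied to all off-diagonal structure.
#' @param labels Node names; defaults to the TGMD-3 names when `p = 13` with
#'   communities 6/7, else `Ls1..`, `Bs1..`.
#' @param seed Integer seed; identical seeds give identical specs.
#' @return A `precision_spec`.
#' @export
build_precision_spec <- function(p, community_sizes, within_density = 0.3,
                                 cross_edges = list(), hub_nodes = character(),
                                 weight_range = c(0.1, 0.25),
                                 prob_negative = 0,
                                 connectivity_scale = 1,
                                 labels = NULL, seed = 1L) {
  stopifnot(length(community_sizes) == 2, sum(community_sizes) == p,
            within_density >= 0, within_density <= 1,
            length(weight_range) == 2,
            weight_range[1] > 0, weight_range[2] < 1,
            connectivity_scale > 0)
  if (is.null(labels)) {
    if (p == 13 && all(community_sizes == c(6, 7))) {
      labels <- tgmd3_schema()$labels
    } else {
      labels <- c(paste0("Ls", seq_len(community_sizes[1])),
                  paste0("Bs", seq_len(community_sizes[2])))
    }
  }
  community_of <- setNames(rep(c("Ls", "Bs"), community_sizes), labels)
  hub_nodes <- as.character(hub_nodes)
  if (!all(hub_nodes %in% labels))
    stop("hub node(s) not in labels: ",
         paste(setdiff(hub_nodes, labels), collapse = ", "), call. = FALSE)

  idx_of <- function(x) if (is.character(x)) match(x, labels) else as.integer(x)
  set.seed(child_seed(seed, 0L, stream = 11L))

  P <- matrix(0, p, p)
  for (comm in c("Ls", "Bs")) {
    members <- which(community_of == comm)
    if (length(members) >= 2) {
      pairs <- utils::combn(members, 2)
      on <- runif(ncol(pairs)) < within_density
      for (k in which(on)) {
        i <- pairs[1, k]; j <- pairs[2, k]
        P[i, j] <- P[j, i] <- 1
      }
    }
  }
  for (e in cross_edges) {
    i <- idx_of(e[[1]]); j <- idx_of(e[[2]])
    if (anyNA(c(i, j))) stop("unknown node in cross_edges", call. = FALSE)
    if (community_of[i] == community_of[j])
      stop("cross_edges pair within one community: ", labels[i], "-", labels[j],
           call. = FALSE)
    P[i, j] <- P[j, i] <- 1
  }
  for (h in hub_nodes) {
    i <- match(h, labels)
    other <- which(community_of != community_of[i])
    have <- sum(P[i, other] != 0)
    if (have < 2) {
      add <- sample(other[P[i, other] == 0], 2 - have)
      P[i, add] <- P[add, i] <- 1
    }
  }

  theta <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (P[i, j] != 0) {
      w <- runif(1, weight_range[1], weight_range[2])
      if (runif(1) < prob_negative) w <- -w
      # pcor w corresponds to theta off-diagonal -w (unit diagonal)
      theta[i, j] <- theta[j, i] <- -w * connectivity_scale
    }
  }
  theta <- load_to_pd(theta)
  new_precision_spec(theta, labels, community_of, hub_nodes, connectivity_scale)
}

#' The default TGMD-3-like generating network
#'
#' A fixed, handcrafted 13-node precision spec emulating the estimated
#' motor-skill networks: two communities (6 Locomotor, 7 Ball skills), dense
#' positive within-community structure, sparse cross-community structure
#' concentrated on the hubs `run` and `two_hand_catch` (each with at least
#' three cross-community partners), one weak negative edge, and every true
#' partial correlation at least 0.10 in magnitude. The edge targets are
#' diagonally dominant, so the matrix is positive definite without loading and
#' the true partial correlations equal the targets exactly.
#'
#' @param connectivity_scale Multiplier on all off-diagonal structure;
#'   values below 1 weaken every conditional association (used to emulate the
#'   developmental weakening across age groups).
#' @return A `precision_spec`.
#' @export
default_skill_spec <- function(connectivity_scale = 1) {
  stopifnot(connectivity_scale > 0, connectivity_scale <= 1.2)
  s <- tgmd3_schema()
  edges <- list(
    # within Locomotor
    list("run", "gallop", 0.20), list("run", "hop", 0.18),
    list("run", "slide", 0.12), list("gallop", "slide", 0.15),
    list("hop", "skip", 0.18), list("hop", "horizontal_jump", 0.15),
    list("skip", "slide", 0.15), list("skip", "horizontal_jump", 0.12),
    # within Ball
    list("two_hand_strike", "forehand_strike", 0.18),
    list("forehand_strike", "one_hand_dribble", 0.15),
    list("one_hand_dribble", "two_hand_catch", 0.18),
    list("two_hand_catch", "two_hand_strike", 0.15),
    list("two_hand_catch", "kick", 0.12),
    list("kick", "overhand_throw", 0.15),
    list("overhand_throw", "underhand_throw", 0.18),
    list("two_hand_strike", "underhand_throw", 0.12),
    list("one_hand_dribble", "overhand_throw", 0.12),
    # cross-community, concentrated on the two hubs
    list("run", "two_hand_catch", 0.15),
    list("run", "one_hand_dribble", 0.12),
    list("run", "two_hand_strike", 0.12),
    list("two_hand_catch", "hop", 0.15),
    list("two_hand_catch", "gallop", 0.12),
    list("horizontal_jump", "kick", 0.10),
    list("slide", "kick", -0.10)
  )
  p <- 13L
  theta <- diag(p)
  dimnames(theta) <- list(s$labels, s$labels)
  for (e in edges) {
    theta[e[[1]], e[[2]]] <- theta[e[[2]], e[[1]]] <- -e[[3]] * connectivity_scale
  }
  new_precision_spec(load_to_pd(theta), s$labels, s$community_of,
                     hub_nodes = c("run", "two_hand_catch"),
                     connectivity_scale = connectivity_scale)
}

# Rescale a spec's off-diagonal structure, re-repairing positive definiteness.
scale_spec <- function(spec, scale) {
  stopifnot(scale > 0)
  theta <- spec$theta
  base <- theta / spec$connectivity_scale  # undo previous scaling of off-diagonals
  off <- base
  diag(off) <- 0
  theta2 <- diag(diag(theta)) + off * scale
  new_precision_spec(load_to_pd(theta2), spec$labels, spec$community_of,
                     spec$hub_nodes, connectivity_scale = scale)
}

#' Write a spec's true edges as a TSV edge list
#'
#' Columns `node_i`, `node_j`, `true_pcor`, one row per nonzero edge (i < j).
#'
#' @param spec A `precision_spec`.
#' @param path Output file path.
#' @export
write_truth_tsv <- function(spec, path) {
  P <- spec$true_pcor
  p <- nrow(P)
  rows <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (abs(P[i, j]) > 1e-12) {
      rows[[length(rows) + 1L]] <- data.frame(
        node_i = spec$labels[i], node_j = spec$labels[j],
        true_pcor = P[i, j], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.precision_spec <- function(x, ...) {
  E <- sum(abs(x$true_pcor[upper.tri(x$true_pcor)]) > 1e-12)
  cat("<precision_spec> ", x$size, " nodes (",
      sum(x$community_of == "Ls"), " Ls / ", sum(x$community_of == "Bs"),
      " Bs), ", E, " true edges, hubs: ",
      paste(x$hub_nodes, collapse = ", "),
      ", connectivity scale ", x$connectivity_scale, "\n", sep = "")
  invisible(x)
}
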