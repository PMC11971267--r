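#' Pearson correlation matrix of a skill panel
#'
#' @param panel A `skill_panel` (or plain numeric matrix with column names).
#' @return A `corr_matrix`: list with `C` (symmetric, unit diagonal), `n`,
#'   `labels`.
#' @export
pearson_correlation <- function(panel) {
  X <- if (inherits(panel, "skill_panel")) panel$scores else as.matrix(panel)
  if (nrow(X) < 3) stop("need at least 3 rows", call. = FALSE)
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    stop("constant column(s): ",
         paste(colnames(X)[v == 0], collapse = ", "), call. = FALSE)
  C <- stats::cor(X)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(list(C = C, n = nrow(X), labels = colnames(X)),
            class = "corr_matrix")
}

as_corr <- function(x, n = NULL) {
  if (inherits(x, "corr_matrix")) return(x)
  C <- as.matrix(x)
  structure(list(C = C, n = n, labels = colnames(C)), class = "corr_matrix")
}

#' Unregularized partial correlations
#'
#' Inverts the correlation matrix and standardizes the negated off-diagonal:
#' `P[i,j] = -K[i,j] / sqrt(K[i,i] K[j,j])` with unit diagonal. Provided for
#' comparison with the regularized network.
#'
#' @param C A `corr_matrix` or plain correlation matrix.
#' @return Symmetric matrix of partial correlations (diagonal 1).
#' @export
partial_correlations_unregularized <- function(C) {
  C <- as_corr(C)$C
  if (kappa(C, exact = TRUE) >= 1e12)
    stop("correlation matrix is near-singular; use the regularized path ",
         "(select_network) instead", call. = FALSE)
  K <- solve(C)
  d <- sqrt(diag(K))
  P <- -K / outer(d, d)
  P <- (P + t(P)) / 2
  diag(P) <- 1
  P
}

#' Logarithmic lambda grid for the graphical lasso path
#'
#' `lambda_max` is the largest absolute off-diagonal correlation (above it the
#' estimated network is empty); the grid descends log-linearly to
#' `lambda_max * min_ratio`.
#'
#' @param C A `corr_matrix` or correlation matrix.
#' @param nlambda Number of grid points (`>= 2`).
#' @param min_ratio Ratio of smallest to largest lambda, in (0, 1).
#' @return Strictly decreasing positive vector.
#' @export
lambda_grid <- function(C, nlambda = 100L, min_ratio = 0.01) {
  stopifnot(nlambda >= 2, min_ratio > 0, min_ratio < 1)
  C <- as_corr(C)$C
  off <- abs(C[upper.tri(C)])
  lam_max <- if (length(off)) max(off) else 0
  if (lam_max == 0) {
    warning("all off-diagonal correlations are zero; using a single nominal ",
            "lambda of 1e-3")
    return(1e-3)
  }
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = nlambda))
}

#' Graphical lasso at a single penalty
#'
#' Maximizes `log det(Theta) - tr(C Theta) - lambda * sum_{i != j} |Theta_ij|`
#' over positive-definite symmetric matrices (off-diagonal L1 penalty) by
#' block coordinate descent.
#'
#' @param C A `corr_matrix` or correlation matrix.
#' @param lambda Non-negative penalty.
#' @param tol Convergence tolerance on the working covariance (scaled by the
#'   mean absolute off-diagonal of `C`).
#' @param maxit Outer iteration cap.
#' @return The estimated precision matrix.
#' @export
glasso_fit <- function(C, lambda, tol = 1e-4, maxit = 200L) {
  stopifnot(lambda >= 0)
  Cm <- as_corr(C)$C
  fit <- glasso_path_cpp(Cm, lambda, tol = tol, maxit = maxit)
  if (fit$converged[1] != 1)
    stop("graphical lasso did not converge at lambda = ", signif(lambda, 6),
         " within ", fit$iterations[1], " iterations", call. = FALSE)
  theta <- fit$theta[, , 1]
  dimnames(theta) <- dimnames(Cm)
  theta
}

count_edges <- function(theta, tol = 1e-8) {
  d <- sqrt(diag(theta))
  P <- abs(theta) / outer(d, d)
  sum(P[upper.tri(P)] > tol)
}

#' Extended BIC of a Gaussian graphical model
#'
#' With log-likelihood `l = (n/2) (log det Theta - tr(C Theta))` and `E` the
#' number of nonzero off-diagonal pairs, returns
#' `-2 l + E log(n) + 4 E gamma log(p)` (the EBIC form for GGMs); `gamma = 0`
#' reduces to the plain BIC penalty.
#'
#' @param theta Positive-definite precision matrix.
#' @param C A `corr_matrix` or correlation matrix.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter (`>= 0`).
#' @return The EBIC value.
#' @export
ebic_score <- function(theta, C, n, gamma = 0.25) {
  stopifnot(gamma >= 0, n > 0)
  Cm <- as_corr(C)$C
  p <- nrow(Cm)
  ch <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(ch))
    stop("theta is not positive definite", call. = FALSE)
  ll <- (n / 2) * (2 * sum(log(diag(ch))) - sum(Cm * theta))
  E <- count_edges(theta)
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

#' Convert a precision matrix to a partial-correlation network
#'
#' `P[i,j] = -theta[i,j] / sqrt(theta[i,i] theta[j,j])` with zero diagonal
#' (network form, so the matrix can be read directly as a weighted adjacency).
#'
#' @param theta Positive-definite precision matrix.
#' @return Symmetric matrix with zero diagonal, entries in (-1, 1).
#' @export
precision_to_pcor <- function(theta) {
  if (any(diag(theta) <= 0))
    stop("theta has a non-positive diagonal entry", call. = FALSE)
  d <- sqrt(diag(theta))
  P <- -theta / outer(d, d)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  P
}

# Shared estimation core: correlation matrix in, EBIC-selected precision and
# partial-correlation network out. select_network() adds validation and the
# user-facing object; the bootstrap loops call this directly.
ggm_core <- function(Cmat, n, gamma, nlambda, min_ratio, tol = 1e-4,
                     maxit = 200L) {
  p <- ncol(Cmat)
  off <- abs(Cmat[upper.tri(Cmat)])
  lam_max <- max(off)
  lambdas <- if (lam_max == 0) 1e-3 else
    exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = nlambda))
  path <- glasso_path_cpp(Cmat, lambdas, tol = tol, maxit = maxit)
  ebic <- -2 * (n / 2) * (path$logdet - path$trace) +
    path$edges * log(n) + 4 * path$edges * gamma * log(p)
  sel <- which.min(ebic)  # grid descends: first minimum = sparsest model
  theta <- path$theta[, , sel]
  dimnames(theta) <- dimnames(Cmat)
  W <- precision_to_pcor(theta)
  hard_zero <- abs(W) < 1e-8
  W[hard_zero] <- 0
  theta[hard_zero & row(theta) != col(theta)] <- 0
  list(lambdas = lambdas, ebic = ebic, sel = sel, theta = theta, W = W,
       converged = path$converged == 1, path_theta = path$theta)
}

#' Estimate the regularized partial-correlation network
#'
#' Runs the full graphical-lasso path on the panel's Pearson correlation
#' matrix, scores every lambda by EBIC, selects the minimizer (ties go to the
#' larger lambda, i.e. the sparser model) and converts the selected precision
#' matrix to partial correlations. Entries below `1e-8` in absolute value are
#' set to exactly zero; this hard-zero rule defines an "edge" for the edge
#' count and every downstream statistic.
#'
#' @param panel A `skill_panel`.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param nlambda,min_ratio Path grid controls, see [lambda_grid()].
#' @param tol,maxit Solver controls, see [glasso_fit()].
#' @return A `ggm_fit`: correlation input, path (`lambda_grid`, `theta_path`,
#'   `ebic_path`), the selection (`selected_lambda`, `theta`, `W`,
#'   `edge_count`) and `gamma`.
#' @export
select_network <- function(panel, gamma = 0.25, nlambda = 100L,
                           min_ratio = 0.01, tol = 1e-4, maxit = 200L) {
  if (inherits(panel, "skill_panel") && nrow(panel$scores) <= length(panel$labels))
    stop("estimation needs n > p; increase the sample size", call. = FALSE)
  C <- pearson_correlation(panel)
  if (max(abs(C$C[upper.tri(C$C)])) == 0)
    warning("all off-diagonal correlations are zero; using a single nominal ",
            "lambda of 1e-3")
  core <- ggm_core(C$C, C$n, gamma, nlambda, min_ratio, tol, maxit)
  if (any(!core$converged))
    warning(sum(!core$converged), " of ", length(core$lambdas),
            " path fits did not converge")
  if (!core$converged[core$sel])
    stop("graphical lasso did not converge at the selected lambda",
         call. = FALSE)
  structure(list(
    C = C,
    gamma = gamma,
    lambda_grid = core$lambdas,
    theta_path = core$path_theta,
    ebic_path = core$ebic,
    converged = core$converged,
    selected_lambda = core$lambdas[core$sel],
    selected_index = core$sel,
    theta = core$theta,
    W = core$W,
    edge_count = sum(core$W[upper.tri(core$W)] != 0)
  ), class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat("<ggm_fit> ", length(x$C$labels), " nodes, n = ", x$C$n,
      ", gamma = ", x$gamma,
      ", selected lambda = ", signif(x$selected_lambda, 4),
      " (", x$edge_count, " edges)\n", sep = "")
  invisible(x)
}

#' Write a network's nonzero edges as a TSV edge list
#'
#' Columns `node_i`, `node_j`, `pcor`; one row per nonzero edge with `i < j`
#' in the canonical node order.
#'
#' @param x A `ggm_fit`, `network_graph`, or weight matrix.
#' @param path Output path.
#' @export
write_edge_list <- function(x, path) {
  W <- if (inherits(x, "ggm_fit")) x$W else if (inherits(x, "network_graph"))
    x$W else as.matrix(x)
  labels <- colnames(W)
  p <- nrow(W)
  rows <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (W[i, j] != 0)
      rows[[length(rows) + 1L]] <- data.frame(
        node_i = labels[i], node_j = labels[j], pcor = W[i, j],
        stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_i = character(), node_j = character(), pcor = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Signed `weight` edge attributes and a `community` node attribute.
#'
#' @param G A `network_graph` (or `ggm_fit` plus community map).
#' @param path Output path.
#' @export
write_graphml <- function(G, path) {
  if (inherits(G, "ggm_fit"))
    stop("pass a network_graph (see ggm_network())", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(G$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$community <- unname(G$community_of[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
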