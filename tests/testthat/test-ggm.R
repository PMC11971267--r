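test_that("pearson correlation is symmetric, unit-diagonal, and flags constants", {
  panel <- small_panel(500)
  C <- pearson_correlation(panel)
  expect_identical(C$C, t(C$C))
  expect_equal(diag(C$C), rep(1, 13), ignore_attr = TRUE)
  expect_equal(C$n, 500)
  # duplicated column correlates perfectly
  X <- cbind(a = rnorm(100), b = rnorm(100))
  X <- cbind(X, c = X[, "a"])
  expect_equal(pearson_correlation(X)$C["a", "c"], 1)
  # independent columns are near zero at n = 10000
  set.seed(1)
  Y <- cbind(u = rnorm(10000), v = rnorm(10000))
  expect_lt(abs(pearson_correlation(Y)$C["u", "v"]), 0.05)
  Z <- cbind(u = rnorm(10), konst = rep(2, 10))
  expect_error(pearson_correlation(Z), "konst")
})

test_that("unregularized partial correlations match closed forms", {
  # identity: independence
  P <- partial_correlations_unregularized(diag(3))
  expect_equal(P[upper.tri(P)], rep(0, 3))
  # 3-variable equicorrelation 0.5: every partial is 1/3
  C <- matrix(0.5, 3, 3); diag(C) <- 1
  P <- partial_correlations_unregularized(C)
  expect_equal(P[upper.tri(P)], rep(1 / 3, 3), tolerance = 1e-10)
  # bivariate: partial equals marginal
  C2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(partial_correlations_unregularized(C2)[1, 2], 0.6)
  # near-singular input is rejected with advice
  Cs <- matrix(1 - 1e-13, 3, 3); diag(Cs) <- 1
  expect_error(partial_correlations_unregularized(Cs), "regularized")
})

test_that("lambda grid is log-spaced from lambda_max down", {
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  g <- lambda_grid(C, nlambda = 3, min_ratio = 0.01)
  expect_equal(g, c(0.5, 0.05, 0.005))
  g2 <- lambda_grid(C, nlambda = 100, min_ratio = 0.01)
  expect_equal(length(g2), 100)
  expect_true(all(diff(g2) < 0))
  ratios <- g2[-1] / g2[-100]
  expect_equal(ratios, rep(0.01^(1 / 99), 99), tolerance = 1e-12)
  expect_warning(lambda_grid(diag(3)), "zero")
})

test_that("glasso matches its closed-form limits", {
  panel <- small_panel(800)
  C <- pearson_correlation(panel)
  # above the threshold the network is empty
  lam_max <- max(abs(C$C[upper.tri(C$C)]))
  th <- glasso_fit(C, lam_max * 1.001)
  off <- th; diag(off) <- 0
  expect_equal(max(abs(off)), 0)
  # at lambda = 0 the precision equals the inverse correlation
  th0 <- glasso_fit(C, 0)
  expect_lt(max(abs(th0 - solve(C$C))), 1e-3)
  # feasibility: always positive definite
  th2 <- glasso_fit(C, 0.05)
  expect_gt(min(eigen(th2, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("bivariate glasso equals the soft-threshold solution", {
  # for p = 2 the penalized covariance is [[1, st(r)], [st(r), 1]] with
  # st(r) = sign(r) max(|r| - lambda, 0), hence pcor = st(r)
  r <- 0.6
  C <- matrix(c(1, r, r, 1), 2)
  for (lam in c(0.1, 0.3, 0.55)) {
    th <- glasso_fit(C, lam)
    W <- precision_to_pcor(th)
    expect_equal(W[1, 2], max(r - lam, 0), tolerance = 1e-6)
  }
})

test_that("EBIC matches its closed form and penalty increment", {
  # C = theta = I: loglik = -np/2, E = 0, EBIC = np for any gamma
  expect_equal(ebic_score(diag(3), diag(3), n = 100, gamma = 0.25), 300)
  expect_equal(ebic_score(diag(3), diag(3), n = 100, gamma = 2), 300)
  # one extra nonzero pair costs log(n) + 4 gamma log(p) on top of the
  # likelihood change
  p <- 13
  C <- diag(p)
  th1 <- diag(p)
  th2 <- diag(p); th2[1, 2] <- th2[2, 1] <- 1e-4
  loglik <- function(th) (100 / 2) * (determinant(th)$modulus[1] - sum(C * th))
  d_pen <- (ebic_score(th2, C, 100, 0.25) + 2 * loglik(th2)) -
    (ebic_score(th1, C, 100, 0.25) + 2 * loglik(th1))
  expect_equal(d_pen, log(100) + 4 * 0.25 * log(13), tolerance = 1e-10)
  # gamma = 0 reduces to the BIC penalty
  d_bic <- (ebic_score(th2, C, 100, 0) + 2 * loglik(th2))
  expect_equal(d_bic, log(100), tolerance = 1e-10)
  expect_error(ebic_score(diag(c(1, -1)), diag(2), 100), "positive definite")
})

test_that("precision_to_pcor standardizes and bounds the network", {
  th <- matrix(c(2, -1, -1, 2), 2)
  W <- precision_to_pcor(th)
  expect_equal(W[1, 2], 0.5)
  expect_equal(diag(W), rep(0, 2))
  # any PD input gives entries in (-1, 1)
  set.seed(4)
  for (i in 1:10) {
    A <- matrix(rnorm(25), 5)
    th <- crossprod(A) + diag(5) * 0.1
    W <- precision_to_pcor(th)
    expect_true(all(abs(W[upper.tri(W)]) < 1))
  }
  expect_error(precision_to_pcor(matrix(c(0, 0, 0, 0), 2)), "diagonal")
})

test_that("select_network carries the study defaults and argmin selection", {
  expect_equal(formals(select_network)$gamma, 0.25)
  panel <- small_panel(1500)
  fit <- select_network(panel)
  expect_equal(fit$ebic_path[fit$selected_index], min(fit$ebic_path))
  # ties (if any) go to the larger lambda: no earlier grid point ties the min
  if (fit$selected_index > 1)
    expect_true(all(fit$ebic_path[seq_len(fit$selected_index - 1)] >
                      min(fit$ebic_path)))
  # W and theta share their zero pattern exactly
  offd <- upper.tri(fit$W)
  expect_identical(fit$W[offd] == 0, fit$theta[offd] == 0)
  expect_equal(fit$edge_count, sum(fit$W[offd] != 0))
  expect_error(select_network(panel_rows(panel, 1:10)), "n > p")
})

test_that("edge count is non-increasing along the descending-lambda path", {
  panel <- small_panel(1000)
  C <- pearson_correlation(panel)
  lams <- lambda_grid(C, nlambda = 30)
  path <- skillnets:::glasso_path_cpp(C$C, lams)
  # lams descend, so edges grow (weakly) along the grid
  expect_true(all(diff(path$edges) >= 0))
})

test_that("the weakest penalty agrees with unregularized partials", {
  panel <- small_panel(4000)
  C <- pearson_correlation(panel)
  lam_min <- min(lambda_grid(C))
  W <- precision_to_pcor(glasso_fit(C, lam_min))
  P <- partial_correlations_unregularized(C)
  diag(P) <- 0
  expect_lt(max(abs(W - P)), 0.02)
})

test_that("the selected network is invariant to positive column scaling", {
  panel <- small_panel(800)
  fit1 <- select_network(panel)
  scaled <- panel
  scaled$scores[, 3] <- scaled$scores[, 3] * 7L
  scaled$score_max[3] <- scaled$score_max[3] * 7L
  fit2 <- select_network(scaled)
  expect_equal(fit1$W, fit2$W)
  expect_identical(fit1$selected_lambda, fit2$selected_lambda)
})

test_that("identical panels give bit-identical fits", {
  panel <- small_panel(600)
  f1 <- select_network(panel)
  f2 <- select_network(panel)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$ebic_path, f2$ebic_path)
})

test_that("an identity-spec panel yields an (almost) empty network", {
  id <- build_precision_spec(13, c(6, 7), within_density = 0, seed = 5)
  edges <- vapply(1:10, function(s) {
    select_network(sample_panel(id, 5000, seed = 300 + s))$edge_count
  }, numeric(1))
  expect_gte(mean(edges <= 2), 0.95)
})

test_that("network export formats carry the fitted edges", {
  panel <- small_panel(1200)
  fit <- select_network(panel)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(fit, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), fit$edge_count)
  k <- which(fit$W[cbind(tab$node_i, tab$node_j)] != 0)
  expect_equal(tab$pcor, fit$W[cbind(tab$node_i, tab$node_j)])

  g <- withr::local_tempfile(fileext = ".graphml")
  G <- ggm_network(fit)
  write_graphml(G, g)
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gsize(back), fit$edge_count)
  expect_setequal(igraph::vertex_attr(back, "community"), c("Ls", "Bs"))
  w <- igraph::edge_attr(back, "weight")
  expect_equal(sort(abs(w)), sort(abs(fit$W[upper.tri(fit$W)][fit$W[upper.tri(fit$W)] != 0])))
})
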