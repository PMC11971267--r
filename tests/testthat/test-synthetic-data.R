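test_that("precision specs are symmetric positive definite with exact pcor map", {
  spec <- build_precision_spec(13, c(6, 7), within_density = 0.3,
                               cross_edges = list(c("run", "two_hand_catch")),
                               hub_nodes = c("run", "two_hand_catch"),
                               seed = 3)
  expect_lte(max(abs(spec$theta - t(spec$theta))), 1e-10)
  ev <- eigen(spec$theta, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  d <- sqrt(diag(spec$theta))
  expect_equal(spec$true_pcor[1, 2],
               -spec$theta[1, 2] / (d[1] * d[2]), ignore_attr = TRUE)
  expect_equal(diag(spec$true_pcor), rep(1, 13), ignore_attr = TRUE)
  off <- spec$true_pcor[upper.tri(spec$true_pcor)]
  expect_true(all(off > -1 & off < 1))
  # hubs have >= 2 cross-community partners
  for (h in spec$hub_nodes) {
    other <- spec$labels[spec$community_of != spec$community_of[h]]
    expect_gte(sum(abs(spec$true_pcor[h, other]) > 1e-12), 2)
  }
})

test_that("empty within/cross structure gives the identity spec", {
  spec <- build_precision_spec(3, c(2, 1), within_density = 0,
                               cross_edges = list(), seed = 1)
  expect_equal(spec$theta, diag(3), ignore_attr = TRUE)
  P <- spec$true_pcor
  expect_equal(P[upper.tri(P)], rep(0, 3))
})

test_that("the default 13-node spec matches the TGMD-3 configuration", {
  spec <- default_skill_spec()
  expect_equal(spec$size, 13L)
  expect_equal(as.integer(table(spec$community_of)[c("Ls", "Bs")]), c(6L, 7L))
  expect_setequal(spec$hub_nodes, c("run", "two_hand_catch"))
  # spec was built diagonally dominant: no loading, so every true edge >= 0.1
  off <- abs(spec$true_pcor[upper.tri(spec$true_pcor)])
  expect_true(all(off[off > 1e-12] >= 0.1))
  s <- tgmd3_schema()
  expect_equal(sum(s$score_max[s$community_of == "Ls"]), 46L)
  expect_equal(sum(s$score_max[s$community_of == "Bs"]), 54L)
})

test_that("identical seeds reproduce specs and panels exactly", {
  a <- build_precision_spec(8, c(4, 4), within_density = 0.4, seed = 9)
  b <- build_precision_spec(8, c(4, 4), within_density = 0.4, seed = 9)
  expect_identical(a$theta, b$theta)
  p1 <- sample_panel(default_skill_spec(), 100, seed = 5)
  p2 <- sample_panel(default_skill_spec(), 100, seed = 5)
  expect_identical(p1$scores, p2$scores)
  p3 <- sample_panel(default_skill_spec(), 100, seed = 6)
  expect_false(identical(p1$scores, p3$scores))
})

test_that("sampled scores honour bounds and discretization is monotone", {
  spec <- default_skill_spec()
  panel <- sample_panel(spec, 400, seed = 11)
  s <- tgmd3_schema()
  for (j in spec$labels) {
    expect_true(all(panel$scores[, j] >= 0 & panel$scores[, j] <= s$score_max[[j]]))
  }
  # monotone map: a latent variable and its score column have perfect rank
  # agreement up to ties, so scores sorted by score equal scores sorted by rank
  z <- rnorm(500)
  sc <- skillnets:::discretize_latent(z, 8)
  expect_true(all(diff(sc[order(z)]) >= 0))
  expect_true(all(sc >= 0 & sc <= 8))
})

test_that("identity-spec scores are pairwise uncorrelated at n = 10000", {
  id <- build_precision_spec(6, c(3, 3), within_density = 0, seed = 2)
  panel <- sample_panel(id, 10000, seed = 3)
  C <- pearson_correlation(panel)$C
  expect_lte(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("a true edge dominates true-zero pairs in sample partial correlation", {
  spec <- default_skill_spec()
  panel <- sample_panel(spec, 5000, seed = 17)
  P <- partial_correlations_unregularized(pearson_correlation(panel))
  truth <- abs(spec$true_pcor) > 1e-12 & upper.tri(spec$true_pcor)
  zero_pairs <- !truth & upper.tri(P)
  expect_gt(P["run", "gallop"], 0)
  expect_gt(P["run", "gallop"], max(abs(P[zero_pairs])))
})

test_that("study panels carry the study's stratum sizes and sex balance", {
  spec <- default_skill_spec()
  panels <- make_study_panels(spec, seed = 1)
  expect_equal(vapply(panels, function(p) nrow(p$scores), numeric(1)),
               c("3-5" = 3525, "6-8" = 7882, "9-11" = 5582))
  all_panel <- bind_panels(panels)
  expect_equal(nrow(all_panel$scores), 16989)
  fem <- mean(all_panel$sex == "F")
  expect_lt(abs(fem - 0.51), 0.03)
  expect_error(
    make_study_panels(spec, group_sizes = c(young = 100),
                      connectivity_scales = c(old = 1)),
    "unknown age group")
})

test_that("weaker connectivity scales weaken the sampled dependence", {
  spec <- default_skill_spec()
  panels <- make_study_panels(spec,
                              group_sizes = c("3-5" = 1500, "6-8" = 1500,
                                              "9-11" = 1500),
                              seed = 21)
  mean_abs_cor <- vapply(panels, function(p) {
    C <- pearson_correlation(p)$C
    mean(abs(C[upper.tri(C)]))
  }, numeric(1))
  expect_true(all(diff(mean_abs_cor) < 0))
})

test_that("panel CSV and truth TSV round-trip", {
  spec <- default_skill_spec()
  panels <- make_study_panels(spec,
                              group_sizes = c("3-5" = 40, "6-8" = 40,
                                              "9-11" = 40),
                              seed = 4)
  panel <- bind_panels(panels)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  back <- read_panel(f)
  expect_identical(back$scores, panel$scores)
  expect_identical(back$age_group, panel$age_group)
  expect_identical(back$sex, panel$sex)

  ft <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(spec, ft)
  edges <- read.delim(ft)
  expect_equal(nrow(edges),
               sum(abs(spec$true_pcor[upper.tri(spec$true_pcor)]) > 1e-12))
  expect_equal(edges$true_pcor[edges$node_i == "run" & edges$node_j == "gallop"],
               spec$true_pcor["run", "gallop"])
})

test_that("read_panel rejects out-of-range and malformed scores by row", {
  panel <- sample_panel(default_skill_spec(), 10, seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  txt <- readLines(f)
  # corrupt row 3: put 47 in the run column (max 8)
  fields <- strsplit(txt[4], ",")[[1]]
  fields[4] <- "47"
  txt[4] <- paste(fields, collapse = ",")
  writeLines(txt, f)
  expect_error(read_panel(f), "row 3.*'run'")
  expect_error(read_panel(f), "invalid score")
})

test_that("panel validation catches bad input", {
  s <- tgmd3_schema()
  good <- matrix(1L, 4, 13, dimnames = list(NULL, s$labels))
  expect_s3_class(skill_panel(good, s$labels, s$community_of, s$score_max),
                  "skill_panel")
  bad <- good; bad[2, 5] <- 99L
  expect_error(skill_panel(bad, s$labels, s$community_of, s$score_max),
               "maximum")
  bad2 <- good; bad2[1, 1] <- NA
  expect_error(skill_panel(bad2, s$labels, s$community_of, s$score_max),
               "missing")
  expect_error(sample_panel(default_skill_spec(), 0), "at least 1")
})
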