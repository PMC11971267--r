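#' Percentile confidence interval
#'
#' Linear-interpolation quantiles at `(1 - level)/2` and `1 - (1 - level)/2`
#' (the 2.5th and 97.5th percentiles at the default 95% level).
#'
#' @param values Replicate values (at least 2).
#' @param level CI level in (0, 1).
#' @return Numeric `c(low, high)`.
#' @export
percentile_interval <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("need at least 2 replicate values", call. = FALSE)
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  unname(stats::quantile(values, probs = c(a, 1 - a), type = 7))
}

pair_names <- function(labels) {
  p <- length(labels)
  out <- character(0)
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    out <- c(out, paste0(labels[i], "|", labels[j]))
  out
}

fit_stats_once <- function(panel, gamma, nlambda, min_ratio) {
  fit <- select_network(panel, gamma = gamma, nlambda = nlambda,
                        min_ratio = min_ratio)
  G <- network_graph(fit$W, fit$C$labels, panel$community_of)
  st <- compute_stats(G)$stats
  list(stats = st, edges = fit$W[upper.tri(fit$W)], fit = fit)
}

# Replicate-speed path: skips panel revalidation and object assembly but
# reproduces select_network's computation (same symmetrized correlation, same
# path, same hard-zero rule) exactly.
fit_stats_matrix <- function(X, comm, gamma, nlambda, min_ratio) {
  C <- suppressWarnings(stats::cor(X))
  if (anyNA(C)) stop("constant column in resample", call. = FALSE)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  core <- ggm_core(C, nrow(X), gamma, nlambda, min_ratio)
  st <- network_stats_cpp(core$W, comm)$stats
  list(stats = st, edges = core$W[upper.tri(core$W)])
}

#' Nonparametric bootstrap of edge weights and centralities
#'
#' Resamples the panel's rows with replacement `B` times, re-estimates the
#' network and all six centrality statistics each time, and summarizes every
#' edge weight and statistic by its replicate mean and percentile CI.
#' Replicates whose estimation fails (e.g. a constant resampled column) are
#' recorded and excluded; more than 10% failures aborts. Replicate `r` uses a
#' child seed derived from `(seed, r)`, so results do not depend on execution
#' order.
#'
#' @param panel A `skill_panel`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param gamma EBIC hyperparameter.
#' @param level CI level (default 0.95).
#' @param seed Integer seed.
#' @param nlambda,min_ratio Path controls passed to [select_network()].
#' @return A `boot_summary` with observed values, replicate matrices, means
#'   and CIs for the six statistics per node and for every node pair's edge
#'   weight.
#' @export
nonparametric_bootstrap <- function(panel, B = 1000L, gamma = 0.25,
                                    level = 0.95, seed = 1L,
                                    nlambda = 100L, min_ratio = 0.01) {
  stopifnot(B >= 2, level > 0, level < 1)
  n <- nrow(panel$scores)
  p <- length(panel$labels)
  full <- fit_stats_once(panel, gamma, nlambda, min_ratio)
  npair <- p * (p - 1) / 2
  stat_reps <- array(NA_real_, c(B, p, 6),
                     dimnames = list(NULL, panel$labels, stats_cols))
  edge_reps <- matrix(NA_real_, B, npair,
                      dimnames = list(NULL, pair_names(panel$labels)))
  failed <- integer(0)
  cc <- as.integer(factor(panel$community_of)) - 1L
  for (r in seq_len(B)) {
    set.seed(child_seed(seed, r, stream = 4L))
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      fit_stats_matrix(panel$scores[idx, , drop = FALSE], cc,
                       gamma, nlambda, min_ratio),
      error = function(e) NULL)
    if (is.null(res)) { failed <- c(failed, r); next }
    stat_reps[r, , ] <- res$stats
    edge_reps[r, ] <- res$edges
  }
  if (length(failed) > 0.1 * B)
    stop(length(failed), " of ", B, " bootstrap replicates failed estimation ",
         "(more than 10%); first failures at replicates ",
         paste(utils::head(failed, 5), collapse = ", "), call. = FALSE)
  keep <- setdiff(seq_len(B), failed)
  stat_reps <- stat_reps[keep, , , drop = FALSE]
  edge_reps <- edge_reps[keep, , drop = FALSE]

  stat_mean <- apply(stat_reps, c(2, 3), mean)
  stat_ci <- apply(stat_reps, c(2, 3), percentile_interval, level = level)
  edge_mean <- colMeans(edge_reps)
  edge_ci <- apply(edge_reps, 2, percentile_interval, level = level)

  structure(list(
    B = B, B_ok = length(keep), failed = failed,
    level = level, seed = seed, gamma = gamma,
    labels = panel$labels, statistics = stats_cols,
    observed_stats = full$stats,
    observed_edges = full$edges,
    stat_reps = stat_reps, edge_reps = edge_reps,
    stat_mean = stat_mean,
    stat_ci_low = stat_ci[1, , ], stat_ci_high = stat_ci[2, , ],
    edge_mean = edge_mean,
    edge_ci_low = edge_ci[1, ], edge_ci_high = edge_ci[2, ],
    fit = full$fit
  ), class = "boot_summary")
}

#' @export
print.boot_summary <- function(x, ...) {
  cat("<boot_summary> B = ", x$B, " (", length(x$failed), " failed), ",
      length(x$labels), " nodes, ", 100 * x$level, "% percentile CIs\n",
      sep = "")
  invisible(x)
}

#' Case-dropping subset bootstrap
#'
#' For each drop proportion `q`, draws `B_per_level` subsamples of size
#' `round(n (1 - q))` without replacement, re-estimates the network and
#' centralities, and records the product-moment correlation between each
#' subsample's per-node statistic vector and the full-sample vector. A
#' proportion whose retained size would not exceed `p + 1` is skipped with a
#' warning. Correlations that are undefined (zero-variance statistic vector)
#' are stored as `NA`.
#'
#' @param panel A `skill_panel`.
#' @param drop_proportions Increasing drop fractions (default 0.05..0.75 by
#'   0.05).
#' @param B_per_level Subsamples per proportion (default 250).
#' @param gamma EBIC hyperparameter.
#' @param seed Integer seed.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param nlambda,min_ratio Path controls passed to [select_network()].
#' @param cs_threshold,cs_confidence CS coefficient controls, see
#'   [cs_coefficient()].
#' @return A `stability_profile` with the correlation array
#'   (`proportion x replicate x statistic`) and the CS coefficient per
#'   statistic.
#' @export
case_drop_bootstrap <- function(panel,
                                drop_proportions = seq(0.05, 0.75, by = 0.05),
                                B_per_level = 250L, gamma = 0.25, seed = 1L,
                                cor_method = c("pearson", "spearman"),
                                nlambda = 100L, min_ratio = 0.01,
                                cs_threshold = 0.70, cs_confidence = 0.95) {
  cor_method <- match.arg(cor_method)
  n <- nrow(panel$scores)
  p <- length(panel$labels)
  full <- fit_stats_once(panel, gamma, nlambda, min_ratio)$stats
  keep_q <- logical(length(drop_proportions))
  for (qi in seq_along(drop_proportions)) {
    m <- round(n * (1 - drop_proportions[qi]))
    keep_q[qi] <- m > p + 1
    if (!keep_q[qi])
      warning("drop proportion ", drop_proportions[qi], " retains only ", m,
              " rows (<= p + 1); skipped")
  }
  props <- drop_proportions[keep_q]
  cors <- array(NA_real_, c(length(props), B_per_level, 6),
                dimnames = list(paste0(props), NULL, stats_cols))
  cc <- as.integer(factor(panel$community_of)) - 1L
  for (qi in seq_along(props)) {
    m <- round(n * (1 - props[qi]))
    for (r in seq_len(B_per_level)) {
      set.seed(child_seed(seed, r, stream = 100L + qi))
      idx <- if (m == n) seq_len(n) else sample.int(n, m, replace = FALSE)
      res <- tryCatch(
        fit_stats_matrix(panel$scores[idx, , drop = FALSE], cc,
                         gamma, nlambda, min_ratio),
        error = function(e) NULL)
      if (is.null(res)) next
      for (s in seq_len(6)) {
        cors[qi, r, s] <- suppressWarnings(
          stats::cor(res$stats[, s], full[, s], method = cor_method))
      }
    }
  }
  profile <- structure(list(
    statistics = stats_cols,
    drop_proportions = props,
    correlations = cors,
    full_stats = full,
    B_per_level = B_per_level,
    threshold = cs_threshold,
    confidence = cs_confidence,
    seed = seed
  ), class = "stability_profile")
  # the replicate-count caution is for ad-hoc calls; here B_per_level is the
  # caller's explicit choice
  profile$cs <- suppressWarnings(
    cs_coefficient(profile, threshold = cs_threshold,
                   confidence = cs_confidence))
  profile
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("<stability_profile> drop proportions ",
      paste(range(x$drop_proportions), collapse = "-"),
      ", B = ", x$B_per_level, " per level\nCS(cor = ", x$threshold, "): ",
      paste(sprintf("%s = %.2f", x$statistics, x$cs), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Stability quantiles by drop proportion
#'
#' The empirical `1 - confidence` quantile (default the 5th percentile) of
#' the subsample-to-full-sample correlations, per statistic and proportion.
#'
#' @param profile A `stability_profile`.
#' @param confidence Confidence level (default 0.95).
#' @return Matrix proportions x statistics.
#' @export
stability_quantiles <- function(profile, confidence = 0.95) {
  apply(profile$correlations, c(1, 3), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    unname(stats::quantile(v, probs = 1 - confidence, type = 7))
  })
}

#' Correlation stability from precomputed quantiles
#'
#' The CS coefficient is the largest drop proportion `q` such that at `q` and
#' every smaller tabulated proportion the correlation quantile stays at or
#' above the threshold (monotone qualification); 0 if even the smallest
#' proportion fails.
#'
#' @param quantiles Numeric vector of correlation quantiles, ordered as
#'   `proportions`.
#' @param proportions Increasing drop proportions.
#' @param threshold Correlation threshold (default 0.70).
#' @return The CS value.
#' @export
cs_from_quantiles <- function(quantiles, proportions, threshold = 0.70) {
  stopifnot(length(quantiles) == length(proportions))
  ord <- order(proportions)
  proportions <- proportions[ord]
  quantiles <- quantiles[ord]
  ok <- !is.na(quantiles) & quantiles >= threshold
  qualified <- cumprod(ok) == 1
  if (!any(qualified)) return(0)
  max(proportions[qualified])
}

#' Correlation stability coefficient CS(cor = threshold)
#'
#' For each statistic, the largest proportion of cases that can be dropped
#' while the subsample statistics keep a correlation of at least `threshold`
#' with the full-sample statistics with the stated confidence (default: 5th
#' percentile of correlations >= 0.70). Values above 0.25 are conventionally
#' considered acceptable.
#'
#' @param profile A `stability_profile`.
#' @param threshold Correlation threshold (default 0.70).
#' @param confidence Confidence level (default 0.95).
#' @return Named per-statistic CS values, with an `acceptable` attribute
#'   (`cs > 0.25`).
#' @export
cs_coefficient <- function(profile, threshold = 0.70, confidence = 0.95) {
  nrep <- apply(!is.na(profile$correlations), 1, sum)
  if (!any(nrep >= 20))
    warning("fewer than 20 replicates at every proportion; ",
            "CS quantiles are unreliable")
  q <- stability_quantiles(profile, confidence)
  cs <- vapply(profile$statistics, function(s) {
    cs_from_quantiles(q[, s], profile$drop_proportions, threshold)
  }, numeric(1))
  attr(cs, "acceptable") <- cs > 0.25
  cs
}

#' Write bootstrap summaries as TSV
#'
#' Per-statistic table `node  statistic  boot_mean  ci_low  ci_high`.
#'
#' @param bs A `boot_summary`.
#' @param path Output path.
#' @export
write_bootstrap_tsv <- function(bs, path) {
  df <- expand.grid(node = bs$labels, statistic = bs$statistics,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$boot_mean <- as.vector(bs$stat_mean)
  df$ci_low <- as.vector(bs$stat_ci_low)
  df$ci_high <- as.vector(bs$stat_ci_high)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stability profile as TSV
#'
#' `statistic  proportion  q05_correlation` rows.
#'
#' @param profile A `stability_profile`.
#' @param path Output path.
#' @export
write_stability_tsv <- function(profile, path) {
  q <- stability_quantiles(profile, profile$confidence)
  df <- expand.grid(proportion = profile$drop_proportions,
                    statistic = profile$statistics,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("statistic", "proportion")]
  df$q05_correlation <- as.vector(q)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CS coefficients as TSV
#'
#' @param cs Named CS vector (from [cs_coefficient()]).
#' @param path Output path.
#' @export
write_cs_tsv <- function(cs, path) {
  df <- data.frame(statistic = names(cs), cs = as.numeric(cs),
                   acceptable = as.numeric(cs) > 0.25,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
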