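#' Compare two bootstrapped networks by CI overlap
#'
#' For every (statistic, node) cell, the two groups differ when their
#' bootstrap confidence intervals share no point; intervals that merely touch
#' (equal endpoints) count as overlapping, i.e. no difference. No
#' multiple-testing correction is applied; the number of comparisons is
#' carried in the result so users can judge.
#'
#' @param a,b `boot_summary` objects with identical node labels, statistics
#'   and CI level.
#' @param group_names Length-2 labels for the two groups.
#' @return A `group_comparison` data frame: per cell, each group's bootstrap
#'   mean and CI, a `differs` flag, and `direction` (which group is higher;
#'   `NA` when not different).
#' @export
compare_groups <- function(a, b, group_names = c("a", "b")) {
  if (!identical(a$labels, b$labels)) {
    extra <- c(setdiff(a$labels, b$labels), setdiff(b$labels, a$labels))
    stop("node label mismatch: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(a$statistics, b$statistics))
    stop("statistic mismatch between summaries", call. = FALSE)
  if (!identical(a$level, b$level))
    stop("CI level mismatch between summaries", call. = FALSE)
  df <- expand.grid(node = a$labels, statistic = a$statistics,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("statistic", "node")]
  df$mean_a <- as.vector(a$stat_mean)
  df$low_a <- as.vector(a$stat_ci_low)
  df$high_a <- as.vector(a$stat_ci_high)
  df$mean_b <- as.vector(b$stat_mean)
  df$low_b <- as.vector(b$stat_ci_low)
  df$high_b <- as.vector(b$stat_ci_high)
  df$differs <- df$high_a < df$low_b | df$high_b < df$low_a
  df$direction <- ifelse(!df$differs, NA_character_,
                         ifelse(df$high_a < df$low_b,
                                group_names[2], group_names[1]))
  attr(df, "groups") <- group_names
  attr(df, "n_comparisons") <- nrow(df)
  class(df) <- c("group_comparison", "data.frame")
  df
}

#' Pairwise CI-overlap comparisons across strata
#'
#' Defaults to the three age-group pairs (3-5 vs 6-8, 6-8 vs 9-11, 3-5 vs
#' 9-11), annotated with the conventional marker symbols `*`, `°`, `+`.
#'
#' @param summaries Named list of `boot_summary`, one per stratum.
#' @param pairs List of length-2 character vectors of stratum names; `NULL`
#'   uses all consecutive-and-extreme pairs of the first three strata if they
#'   are the age groups, else all pairwise combinations.
#' @return Named list of `group_comparison`, one per pair, each carrying a
#'   `marker` attribute.
#' @export
compare_all <- function(summaries, pairs = NULL) {
  strata <- names(summaries)
  if (is.null(pairs)) {
    if (all(c("3-5", "6-8", "9-11") %in% strata)) {
      pairs <- list(c("3-5", "6-8"), c("6-8", "9-11"), c("3-5", "9-11"))
    } else {
      cmb <- utils::combn(strata, 2)
      pairs <- lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
    }
  }
  markers <- c("*", "°", "+")
  out <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    missing_strata <- setdiff(pr, strata)
    if (length(missing_strata))
      stop("unknown stratum: ", paste(missing_strata, collapse = ", "),
           call. = FALSE)
    cmp <- compare_groups(summaries[[pr[1]]], summaries[[pr[2]]],
                          group_names = pr)
    attr(cmp, "marker") <- if (k <= 3) markers[k] else as.character(k)
    out[[paste(pr, collapse = "_vs_")]] <- cmp
  }
  out
}

#' Write a stratified comparison table as TSV
#'
#' One row per statistic x node; per-group columns `mean [ci_low-ci_high]`
#' and one marker column per comparison pair (marker when the pair's CIs do
#' not overlap, empty otherwise).
#'
#' @param summaries Named list of `boot_summary` per stratum.
#' @param comparisons Result of [compare_all()].
#' @param path Output path.
#' @export
write_comparison_tsv <- function(summaries, comparisons, path) {
  first <- summaries[[1]]
  df <- expand.grid(node = first$labels, statistic = first$statistics,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("statistic", "node")]
  for (g in names(summaries)) {
    s <- summaries[[g]]
    df[[g]] <- sprintf("%.4g [%.4g-%.4g]", as.vector(s$stat_mean),
                       as.vector(s$stat_ci_low), as.vector(s$stat_ci_high))
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    col <- paste0("diff_", gsub("_vs_", "v", nm))
    df[[col]] <- ifelse(cmp$differs, attr(cmp, "marker"), "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
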