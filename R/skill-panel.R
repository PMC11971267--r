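#' Construct and validate a skill panel
#'
#' A skill panel is the pipeline's sole input: an `n x p` matrix of
#' non-negative integer skill scores with node labels, a two-community map
#' (`Ls`/`Bs`), per-skill score maxima, and optional per-row `age_group` and
#' `sex` strata labels.
#'
#' @param scores Integer matrix (`n x p`).
#' @param labels Skill names (length `p`).
#' @param community_of Named map label -> `"Ls"`/`"Bs"`.
#' @param score_max Named per-skill maxima.
#' @param age_group Optional per-row labels (e.g. `"3-5"`, `"6-8"`, `"9-11"`).
#' @param sex Optional per-row labels (`"M"`/`"F"`).
#' @return A `skill_panel`.
#' @export
skill_panel <- function(scores, labels, community_of, score_max,
                        age_group = NULL, sex = NULL) {
  scores <- as.matrix(scores)
  p <- length(labels)
  stopifnot(ncol(scores) == p, length(score_max) == p)
  colnames(scores) <- labels
  if (anyNA(scores)) stop("panel contains missing scores", call. = FALSE)
  if (any(scores != round(scores)) || any(scores < 0))
    stop("scores must be non-negative integers", call. = FALSE)
  bad <- which(t(scores) > score_max[labels])
  if (length(bad))
    stop("score above per-skill maximum in column(s): ",
         paste(unique(labels[(bad - 1L) %% p + 1L]), collapse = ", "),
         call. = FALSE)
  if (!is.null(age_group)) stopifnot(length(age_group) == nrow(scores))
  if (!is.null(sex)) stopifnot(length(sex) == nrow(scores))
  structure(list(
    scores = matrix(as.integer(scores), nrow(scores), p,
                    dimnames = list(NULL, labels)),
    labels = labels,
    community_of = community_of[labels],
    score_max = score_max[labels],
    age_group = age_group,
    sex = sex
  ), class = "skill_panel")
}

#' @export
print.skill_panel <- function(x, ...) {
  cat("<skill_panel> ", nrow(x$scores), " children x ", length(x$labels),
      " skills (", sum(x$community_of == "Ls"), " Ls / ",
      sum(x$community_of == "Bs"), " Bs)", sep = "")
  if (!is.null(x$age_group))
    cat("; age groups:", paste(names(table(x$age_group)), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
dim.skill_panel <- function(x) dim(x$scores)

# Equal-probability discretization of a standardized latent normal variable
# into integers 0..m: breaks at the m interior standard-normal quantiles, so
# every category has probability 1/(m+1) and ranks are preserved.
discretize_latent <- function(z, m) {
  breaks <- stats::qnorm(seq_len(m) / (m + 1))
  findInterval(z, breaks)
}

#' Sample an integer skill panel from a precision spec
#'
#' Draws `n` latent vectors from the zero-mean Gaussian with the spec's
#' precision matrix, then maps each variable to integers `0..score_max[j]` by
#' partitioning the standard-normal scale into `score_max[j] + 1`
#' equal-probability bins. The discretization is monotone, so score ranks
#' follow latent ranks and Pearson correlations of scores approximate the
#' latent correlations.
#'
#' @param spec A `precision_spec`.
#' @param n Number of rows to draw (`>= 1`).
#' @param score_max Per-skill maxima; defaults to the TGMD-3 configuration
#'   when the spec carries the 13 TGMD-3 labels, else 8 per skill.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A `skill_panel`.
#' @export
sample_panel <- function(spec, n, score_max = NULL, seed = 1L) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  s <- tgmd3_schema()
  if (is.null(score_max)) {
    score_max <- if (identical(spec$labels, s$labels)) s$score_max else
      setNames(rep(8L, spec$size), spec$labels)
  }
  stopifnot(all(score_max > 0), all(score_max == round(score_max)))
  sigma <- solve(spec$theta)
  R <- chol(sigma)       # upper triangular, sigma = R'R
  set.seed(child_seed(seed, 0L, stream = 1L))
  Z <- matrix(rnorm(n * spec$size), n, spec$size) %*% R
  sds <- sqrt(diag(sigma))
  scores <- vapply(seq_len(spec$size), function(j) {
    discretize_latent(Z[, j] / sds[j], score_max[[j]])
  }, numeric(n))
  if (n == 1L) scores <- matrix(scores, nrow = 1L)
  skill_panel(scores, spec$labels, spec$community_of, score_max)
}

#' Generate age-stratified study panels
#'
#' Produces one panel per age group at the study's stratum sizes, all sharing
#' the base spec's structure but with the off-diagonal precision entries
#' multiplied by a per-group connectivity scale (re-repaired to positive
#' definiteness). The default scales decrease strictly with age, emulating the
#' developmental weakening of conditional associations; the age effect is
#' modelled only through connectivity (no mean shift), since the network
#' pipeline is location-invariant. Rows carry `age_group` and `sex` labels
#' (`sex_split` is the probability of `"F"`).
#'
#' @param base_spec A `precision_spec`.
#' @param group_sizes Named counts per age group (defaults to the study's
#'   3525 / 7882 / 5582).
#' @param connectivity_scales Named positive scales per age group, strictly
#'   decreasing with age by default (1.0, 0.7, 0.5).
#' @param sex_split Probability a row is labelled `"F"` (default 0.51, the
#'   study's female share).
#' @param score_max Per-skill maxima passed to [sample_panel()].
#' @param seed Integer seed; each group uses a derived child seed.
#' @return Named list of `skill_panel`, one per age group.
#' @export
make_study_panels <- function(base_spec,
                              group_sizes = c("3-5" = 3525L, "6-8" = 7882L,
                                              "9-11" = 5582L),
                              connectivity_scales = c("3-5" = 1.0,
                                                      "6-8" = 0.7,
                                                      "9-11" = 0.5),
                              sex_split = 0.51,
                              score_max = NULL,
                              seed = 1L) {
  stopifnot(all(connectivity_scales > 0), sex_split > 0, sex_split < 1)
  groups <- names(group_sizes)
  if (is.null(groups) || !all(groups %in% names(connectivity_scales)))
    stop("unknown age group key: connectivity_scales must name every group in ",
         "group_sizes", call. = FALSE)
  panels <- list()
  for (g in seq_along(groups)) {
    gname <- groups[g]
    spec_g <- scale_spec(base_spec, connectivity_scales[[gname]])
    panel <- sample_panel(spec_g, group_sizes[[gname]], score_max = score_max,
                          seed = child_seed(seed, g, stream = 2L))
    set.seed(child_seed(seed, g, stream = 3L))
    sex <- ifelse(rbinom(group_sizes[[gname]], 1L, sex_split) == 1L, "F", "M")
    panel$age_group <- rep(gname, group_sizes[[gname]])
    panel$sex <- sex
    panels[[gname]] <- panel
  }
  panels
}

#' Combine panels row-wise
#'
#' @param panels List of `skill_panel` objects sharing labels and maxima.
#' @return A single `skill_panel`.
#' @export
bind_panels <- function(panels) {
  stopifnot(length(panels) >= 1)
  first <- panels[[1]]
  for (p in panels) stopifnot(identical(p$labels, first$labels))
  skill_panel(do.call(rbind, lapply(panels, `[[`, "scores")),
              first$labels, first$community_of, first$score_max,
              age_group = unname(unlist(lapply(panels, `[[`, "age_group"))),
              sex = unname(unlist(lapply(panels, `[[`, "sex"))))
}

#' Subset a panel's rows
#'
#' @param panel A `skill_panel`.
#' @param idx Row indices.
#' @return A `skill_panel` with the selected rows.
#' @export
panel_rows <- function(panel, idx) {
  skill_panel(panel$scores[idx, , drop = FALSE], panel$labels,
              panel$community_of, panel$score_max,
              age_group = panel$age_group[idx], sex = panel$sex[idx])
}

#' Write a skill panel to CSV
#'
#' Header `id,age_group,sex,<skill labels>`; integer scores; UTF-8. Missing
#' strata are written as empty fields.
#'
#' @param panel A `skill_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  n <- nrow(panel$scores)
  df <- data.frame(
    id = seq_len(n),
    age_group = if (is.null(panel$age_group)) rep("", n) else panel$age_group,
    sex = if (is.null(panel$sex)) rep("", n) else panel$sex,
    panel$scores, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a skill panel from CSV
#'
#' Expects the header `id,age_group,sex,<skill labels>` with the schema's
#' skill columns; rows with missing, non-integer or out-of-range scores are
#' rejected with their row numbers.
#'
#' @param path CSV file path.
#' @param schema Label/community/maxima configuration, as from
#'   [tgmd3_schema()].
#' @return A `skill_panel`.
#' @export
read_panel <- function(path, schema = tgmd3_schema()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(schema$labels, names(df))
  if (length(missing_cols))
    stop("missing skill column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(df), c("id", "age_group", "sex", schema$labels))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  raw <- as.matrix(df[, schema$labels, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                 dimnames = dimnames(raw)))
  offenders <- character()
  for (j in seq_along(schema$labels)) {
    col <- schema$labels[j]
    bad <- which(is.na(num[, j]) | num[, j] != round(num[, j]) |
                   num[, j] < 0 | num[, j] > schema$score_max[[col]])
    if (length(bad))
      offenders <- c(offenders, paste0("row ", bad, ", column '", col, "'"))
  }
  if (length(offenders))
    stop("invalid score(s): ", paste(offenders, collapse = "; "),
         call. = FALSE)
  age <- if ("age_group" %in% names(df) && any(nzchar(df$age_group)))
    df$age_group else NULL
  sex <- if ("sex" %in% names(df) && any(nzchar(df$sex))) df$sex else NULL
  skill_panel(num, schema$labels, schema$community_of, schema$score_max,
              age_group = age, sex = sex)
}
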