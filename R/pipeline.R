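#' Assemble a validated run configuration
#'
#' Defaults follow the study conventions: EBIC `gamma = 0.25`, `B = 1000`
#' nonparametric bootstraps, CS threshold 0.70 at 95% confidence, age
#' stratification. The seed is mandatory: no wall-clock default, so a config
#' fully determines the run.
#'
#' @param seed Integer seed (required).
#' @param input Optional CSV panel path; when `NULL` the synthetic generator
#'   is used.
#' @param synthetic List of overrides for [make_study_panels()]
#'   (`group_sizes`, `connectivity_scales`, `sex_split`).
#' @param stratify_by Subset of `c("age_group", "sex")`.
#' @param gamma,nlambda,min_ratio Estimation controls.
#' @param B Nonparametric bootstrap replicates.
#' @param B_per_level Case-dropping subsamples per proportion.
#' @param drop_proportions Case-dropping grid.
#' @param ci_level CI level.
#' @param cs_threshold,cs_confidence CS coefficient controls.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, input = NULL, synthetic = list(),
                       stratify_by = "age_group",
                       gamma = 0.25, nlambda = 100L, min_ratio = 0.01,
                       B = 1000L, B_per_level = 250L,
                       drop_proportions = seq(0.05, 0.75, by = 0.05),
                       ci_level = 0.95, cs_threshold = 0.70,
                       cs_confidence = 0.95) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory (no wall-clock default)", call. = FALSE)
  stopifnot(gamma >= 0, ci_level > 0, ci_level < 1,
            all(stratify_by %in% c("age_group", "sex")))
  structure(list(seed = as.integer(seed), input = input,
                 synthetic = synthetic, stratify_by = stratify_by,
                 gamma = gamma, nlambda = as.integer(nlambda),
                 min_ratio = min_ratio, B = as.integer(B),
                 B_per_level = as.integer(B_per_level),
                 drop_proportions = drop_proportions,
                 ci_level = ci_level, cs_threshold = cs_threshold,
                 cs_confidence = cs_confidence),
            class = "run_config")
}

#' Read a run configuration file
#'
#' YAML key/value file with an optional nested `synthetic` block. Unknown
#' keys are errors, not warnings.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$synthetic)) {
    syn_known <- c("group_sizes", "connectivity_scales", "sex_split")
    syn_unknown <- setdiff(names(raw$synthetic), syn_known)
    if (length(syn_unknown))
      stop("unknown synthetic config key(s): ",
           paste(syn_unknown, collapse = ", "), call. = FALSE)
    for (f in c("group_sizes", "connectivity_scales"))
      if (!is.null(raw$synthetic[[f]]))
        raw$synthetic[[f]] <- unlist(raw$synthetic[[f]])
  }
  do.call(run_config, raw)
}

log_stage <- function(stage, stratum, t0) {
  message(sprintf("[%s] stratum=%s elapsed=%.1fs", stage, stratum,
                  as.numeric(proc.time()["elapsed"]) - t0))
}

#' Run the full stratified network pipeline
#'
#' For the whole sample and each stratum: network estimation
#' ([select_network()]), centrality ([centrality_table()]), nonparametric
#' bootstrap, case-dropping bootstrap with CS coefficients; then CI-overlap
#' comparisons across age-group pairs (and the sexes when stratified by sex).
#' All artifacts are written as text files under `out_dir` and listed, with
#' content hashes, in `manifest.json`. Re-running with the same config
#' reproduces identical outputs. Strata with too few rows (`n <= p`) are
#' skipped with a warning and the run continues.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return The run report (manifest contents), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(proc.time()["elapsed"])
  files <- character(0)
  emit <- function(name) { files[[length(files) + 1L]] <<- name; file.path(out_dir, name) }

  if (!is.null(config$input)) {
    panel <- read_panel(config$input)
  } else {
    spec <- default_skill_spec()
    args <- c(list(base_spec = spec, seed = config$seed), config$synthetic)
    panels <- do.call(make_study_panels, args)
    panel <- bind_panels(panels)
    write_truth_tsv(spec, emit("truth_edges.tsv"))
    write_panel(panel, emit("panel.csv"))
  }
  p <- length(panel$labels)

  strata <- list(all = seq_len(nrow(panel$scores)))
  if ("age_group" %in% config$stratify_by && !is.null(panel$age_group))
    for (g in unique(panel$age_group))
      strata[[g]] <- which(panel$age_group == g)
  if ("sex" %in% config$stratify_by && !is.null(panel$sex))
    for (g in unique(panel$sex))
      strata[[g]] <- which(panel$sex == g)

  summaries <- list()
  status <- list()
  for (si in seq_along(strata)) {
    sname <- names(strata)[si]
    idx <- strata[[si]]
    if (length(idx) <= p) {
      warning("stratum '", sname, "' has n = ", length(idx),
              " <= p; skipped")
      status[[sname]] <- "skipped"
      next
    }
    sub <- panel_rows(panel, idx)
    sseed <- child_seed(config$seed, si, stream = 7L)
    fit <- select_network(sub, gamma = config$gamma,
                          nlambda = config$nlambda,
                          min_ratio = config$min_ratio)
    G <- network_graph(fit$W, fit$C$labels, sub$community_of)
    write_edge_list(fit, emit(paste0("network_", sname, ".tsv")))
    write_graphml(G, emit(paste0("network_", sname, ".graphml")))
    log_stage("fit", sname, t0)
    write_centrality_tsv(centrality_table(G),
                         emit(paste0("centrality_", sname, ".tsv")))
    log_stage("centrality", sname, t0)
    bs <- nonparametric_bootstrap(sub, B = config$B, gamma = config$gamma,
                                  level = config$ci_level, seed = sseed,
                                  nlambda = config$nlambda,
                                  min_ratio = config$min_ratio)
    write_bootstrap_tsv(bs, emit(paste0("bootstrap_", sname, ".tsv")))
    summaries[[sname]] <- bs
    log_stage("bootstrap", sname, t0)
    prof <- case_drop_bootstrap(sub,
                                drop_proportions = config$drop_proportions,
                                B_per_level = config$B_per_level,
                                gamma = config$gamma, seed = sseed,
                                nlambda = config$nlambda,
                                min_ratio = config$min_ratio,
                                cs_threshold = config$cs_threshold,
                                cs_confidence = config$cs_confidence)
    write_stability_tsv(prof, emit(paste0("stability_", sname, ".tsv")))
    write_cs_tsv(prof$cs, emit(paste0("cs_", sname, ".tsv")))
    status[[sname]] <- "ok"
    log_stage("stability", sname, t0)
  }

  comparisons <- list()
  age_strata <- intersect(c("3-5", "6-8", "9-11"), names(summaries))
  if (length(age_strata) >= 2) {
    comparisons <- compare_all(summaries[age_strata])
    write_comparison_tsv(summaries[age_strata], comparisons,
                         emit("comparison_age.tsv"))
    log_stage("compare", "age", t0)
  }
  if (all(c("M", "F") %in% names(summaries))) {
    sex_cmp <- compare_all(summaries[c("M", "F")], pairs = list(c("M", "F")))
    comparisons <- c(comparisons, sex_cmp)
    write_comparison_tsv(summaries[c("M", "F")], sex_cmp,
                         emit("comparison_sex.tsv"))
    log_stage("compare", "sex", t0)
  }

  cfg <- unclass(config)
  cfg$input <- if (is.null(cfg$input)) NA else cfg$input
  manifest <- list(
    package = "skillnets",
    version = as.character(utils::packageVersion("skillnets")),
    config = cfg,
    strata = status,
    files = lapply(setNames(unlist(files), unlist(files)), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report <- list(manifest = manifest, summaries = summaries,
                 comparisons = comparisons)
  invisible(report)
}
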