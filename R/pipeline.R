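#' Study configuration
#'
#' Collects everything a full simulated study run needs: the cohort
#' specification, protocol options, the variables entering the group
#' comparison tables, and the candidate predictors for the best-subset
#' regression step.
#'
#' @param cohort_spec A `vf_cohort_spec` (or path to a YAML/JSON spec file).
#' @param protocol A [protocol_options()] object.
#' @param compare_vars Numeric columns compared between diagnostic groups.
#' @param candidates Candidate predictors for [best_subset_cpm()] /
#'   [mechanism_scenario()].
#' @param mechanism_bands Age bands on which the mechanism regression is run
#'   (plus the whole sample).
#' @return A `vf_config` list.
#' @export
study_config <- function(cohort_spec = default_cohort_spec(),
                         protocol = protocol_options(),
                         compare_vars = c("age_years", "viq", "piq", "fsiq",
                                          "srs_t", "threshold_g", "az", "c"),
                         candidates = c("az", "c"),
                         mechanism_bands = "child") {
  if (is.character(cohort_spec)) cohort_spec <- read_cohort_spec(cohort_spec)
  structure(list(cohort_spec = cohort_spec, protocol = protocol,
                 compare_vars = compare_vars, candidates = candidates,
                 mechanism_bands = mechanism_bands),
            class = "vf_config")
}

#' Simulate a cohort and its detection sessions, fully scored
#'
#' Convenience wrapper: cohort draw, trial-level simulation of the four-block
#' protocol, and session scoring, returned as one participant-level dataset
#' (covariates plus threshold, SDT counts and metrics).
#'
#' @param config A [study_config()].
#' @param seed Integer master seed; the cohort and protocol stages use
#'   derived child seeds so each stage is independently reproducible.
#' @param keep_trials Also return the tidy trial log.
#' @return A tibble (or, with `keep_trials`, a list `dataset`/`trials`).
#' @export
simulate_study <- function(config = study_config(), seed = 1L,
                           keep_trials = FALSE) {
  seed <- as.integer(seed)
  cohort <- simulate_cohort(config$cohort_spec, seed = seed)
  trials <- simulate_sessions(cohort, config$protocol, seed = seed + 500000L)
  sessions <- score_sessions(trials, config$protocol)
  dataset <- dplyr::left_join(cohort, sessions, by = "id")
  if (keep_trials) list(dataset = dataset, trials = trials) else dataset
}

#' Run the full simulated study pipeline
#'
#' Simulate, score, compare, regress: produces the participant dataset and
#' trial log, descriptive group-comparison tables (whole sample and per age
#' band, Cliff's delta per variable plus a sex chi-square), the block-pooling
#' ICC(3,4) of the four block thresholds, and the mechanism regression
#' summaries (baseline CPM vs baseline + criterion, best-subset search).
#' When `out_dir` is given, all tables are written as tidy CSV (plus a JSON
#' manifest with the seed and config hash); outputs are byte-identical for
#' identical config and seed.
#'
#' @inheritParams simulate_study
#' @param out_dir Optional output directory.
#' @return A `vf_study` list: `dataset`, `trials`, `comparisons`,
#'   `sex_tables`, `icc_blocks`, `mechanism`, `searches`, `seed`.
#' @export
run_study <- function(config = study_config(), seed = 1L, out_dir = NULL) {
  seed <- as.integer(seed)
  sim <- simulate_study(config, seed, keep_trials = TRUE)
  dataset <- sim$dataset
  res <- analyze_dataset(dataset, config)
  blocks <- block_summaries(sim$trials, config$protocol)
  keep <- dataset$id[!dataset$excluded]
  bw <- blocks[blocks$id %in% keep, c("id", "block", "threshold_g")] |>
    tidyr::pivot_wider(names_from = "block", values_from = "threshold_g")
  res$icc_blocks <- icc_consistency(log10(as.matrix(bw[, -1])))
  out <- structure(c(list(dataset = dataset, trials = sim$trials),
                     res, list(seed = seed)), class = "vf_study")
  if (!is.null(out_dir)) write_study(out, config, out_dir)
  out
}

analyze_dataset <- function(dataset, config) {
  bands <- unique(dataset$band)
  scopes <- c(list(whole = dataset),
              stats::setNames(purrr::map(bands, ~ dataset[dataset$band == .x, ]),
                              bands))
  comparisons <- purrr::imap_dfr(scopes, function(d, scope) {
    vars <- intersect(config$compare_vars, names(d))
    dplyr::mutate(compare_groups(d, vars, group = "diagnosis", ref = "NT"),
                  scope = scope, .before = 1)
  })
  sex_tables <- purrr::imap_dfr(scopes, function(d, scope) {
    tab <- table(d$diagnosis, d$sex)
    if (!all(dim(tab) == c(2, 2)) || any(rowSums(tab) == 0) ||
        any(colSums(tab) == 0)) return(NULL)
    dplyr::mutate(chisq_2x2(tab), scope = scope, .before = 1)
  })
  mech_scopes <- intersect(c("whole", config$mechanism_bands), names(scopes))
  mechanism <- purrr::map_dfr(mech_scopes, function(scope) {
    d <- scopes[[scope]]
    m <- tryCatch(
      mechanism_scenario(d, candidates = config$candidates),
      error = function(e) {
        warning("mechanism regression failed for scope '", scope, "': ",
                conditionMessage(e), call. = FALSE)
        failed_mechanism_row(sum(!is.na(d$threshold_g)))
      })
    dplyr::mutate(m, scope = scope, .before = 1)
  })
  list(comparisons = comparisons, sex_tables = sex_tables,
       mechanism = mechanism)
}

#' Analyse an externally collected dataset
#'
#' Runs the statistical battery only (no simulation) on a participant-level
#' table with the documented columns: `threshold_g`, `diagnosis`
#' (`"NT"`/`"ASD"`), `age_years`, `sex` (`"F"`/`"M"`), `counterbalance`,
#' `az`, `c`, and optionally `band` and further covariates. Accepts a data
#' frame or a CSV path.
#'
#' @param data Data frame or path to a CSV file.
#' @param config A [study_config()] (cohort spec and protocol are ignored).
#' @return List with `comparisons`, `sex_tables`, `mechanism`.
#' @export
analyze_external <- function(data, config = study_config()) {
  if (is.character(data)) data <- utils::read.csv(data)
  data <- tibble::as_tibble(data)
  required <- c("threshold_g", "diagnosis", "age_years", "sex",
                "counterbalance", "az", "c")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0)
    stop("dataset lacks required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"band" %in% names(data)) data$band <- "all"
  analyze_dataset(data, config)
}

write_study <- function(study, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wr(study$dataset, "participants")
  wr(study$trials, "trials")
  wr(study$comparisons, "group_comparisons")
  wr(study$sex_tables, "sex_chisq")
  wr(study$mechanism, "mechanism")
  wr(study$icc_blocks, "icc_blocks")
  manifest <- list(seed = study$seed,
                   config_hash = rlang::hash(config),
                   package_version = as.character(utils::packageVersion("vonfrey")),
                   n_participants = nrow(study$dataset))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Replicated mechanism analysis over simulated cohorts
#'
#' Draws `n_reps` independent cohorts from a specification, runs the
#' protocol and scoring for each, and applies [mechanism_scenario()],
#' returning one row per replicate. This is the package's headline
#' experiment: across replicates it measures how often a criterion gap with
#' equal sensitivity produces a significant baseline diagnosis effect that
#' is supplanted once the estimated criterion enters the model.
#'
#' @param n_reps Number of replicate cohorts.
#' @param spec A `vf_cohort_spec` (e.g. child bands only).
#' @param opts A [protocol_options()].
#' @param seed Integer seed; replicate r uses derived seed `seed + r`.
#' @param candidates Candidate predictors for the best-subset step.
#' @return Tibble with one row per replicate (columns of
#'   [mechanism_scenario()] plus `rep`).
#' @export
mechanism_battery <- function(n_reps, spec = default_cohort_spec("child"),
                              opts = protocol_options(), seed = 1L,
                              candidates = c("az", "c")) {
  cfg <- study_config(cohort_spec = spec, protocol = opts,
                      candidates = candidates)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    d <- simulate_study(cfg, seed = as.integer(seed) + r)
    dplyr::mutate(mechanism_scenario(d, candidates = candidates), rep = r,
                  .before = 1)
  })
}
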