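#' Build a pipeline run configuration
#'
#' Exactly one input source must be given: either a synthetic-cohort config
#' (the generator supplies chains, questionnaires, and embeddings) or the
#' three file paths for real data (chain TSV, questionnaire CSV, embedding
#' text file). Per-stage parameters default to desk-scale values; raise
#' `n_repeats`/`n_perm` to 500 for full-scale runs.
#'
#' @param synthetic Optional [synthetic_config()].
#' @param chains_path,questionnaires_path,embeddings_path Optional input
#'   file paths (all three required together).
#' @param n_repeats Classification bootstrap repeats.
#' @param n_perm Permutation-null size.
#' @param cost SVM regularization constant.
#' @param bin_width Time-course bin width in associates.
#' @param k_themes Number of theme words.
#' @param theme_exclusions Tokens excluded from theme selection.
#' @param k_folds Stepwise CV folds.
#' @param min_prevalence,min_abs_bias Bias display-filter thresholds.
#' @param seed Global seed; every stage derives its own stream via
#'   [stage_seed()].
#' @return A `linger_run_config` list.
#' @export
run_config <- function(synthetic = NULL, chains_path = NULL,
                       questionnaires_path = NULL, embeddings_path = NULL,
                       n_repeats = 100, n_perm = 100, cost = 1,
                       bin_width = 10, k_themes = 10,
                       theme_exclusions = character(), k_folds = 10,
                       min_prevalence = 0.16, min_abs_bias = 0.10,
                       seed = 1L) {
  have_files <- !is.null(chains_path) || !is.null(questionnaires_path) ||
    !is.null(embeddings_path)
  if (!is.null(synthetic) && have_files) {
    stop("provide either a synthetic config or input paths, not both",
         call. = FALSE)
  }
  if (is.null(synthetic)) {
    if (is.null(chains_path) || is.null(questionnaires_path) ||
        is.null(embeddings_path)) {
      stop("real-data runs need chains_path, questionnaires_path, ",
           "and embeddings_path", call. = FALSE)
    }
  } else {
    stopifnot(inherits(synthetic, "linger_config"))
  }
  stopifnot(n_repeats >= 1, n_perm >= 1, bin_width >= 1, k_themes >= 1,
            k_folds >= 2)
  structure(list(synthetic = synthetic, chains_path = chains_path,
                 questionnaires_path = questionnaires_path,
                 embeddings_path = embeddings_path,
                 n_repeats = n_repeats, n_perm = n_perm, cost = cost,
                 bin_width = bin_width, k_themes = k_themes,
                 theme_exclusions = theme_exclusions, k_folds = k_folds,
                 min_prevalence = min_prevalence,
                 min_abs_bias = min_abs_bias,
                 seed = as.integer(seed)),
            class = "linger_run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [run_config()]; a `synthetic:` block
#' mirrors [synthetic_config()] (with per-condition `delta`/`lambda`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `linger_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    syn <- do.call(synthetic_config, raw$synthetic)
  }
  args <- raw[setdiff(names(raw), "synthetic")]
  do.call(run_config, c(list(synthetic = syn), args))
}

load_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- stage_seed(config$seed, "simulate")
    generate_cohort(syn)
  } else {
    chains <- read_chains(config$chains_path)
    participants <- read_questionnaires(config$questionnaires_path)
    embeddings <- load_embeddings(config$embeddings_path)
    structure(list(chains = chains, participants = participants,
                   embeddings = embeddings,
                   ground_truth = NULL,
                   config = synthetic_config(
                     conditions = stats::setNames(
                       lapply(unique(participants$condition),
                              function(x) list(delta = 0, lambda = 0)),
                       unique(participants$condition)))),
              class = "linger_cohort")
  }
}

#' Run the full lingering-analysis pipeline
#'
#' Executes, per condition: document-term matrix construction and scaling,
#' leave-one-participant-out classification with bootstrap repeats,
#' permutation null and one-sided p; and, cohort-wide: theme-word selection,
#' per-participant pre/post theme-similarity deltas, the binned time-course
#' with lingering duration, word-level bias tables, condition contrasts of
#' the lingering rating (Kruskal-Wallis + pairwise Mann-Whitney), and
#' cross-validated backward stepwise prediction of lingering and of the
#' theme delta. Every stochastic stage is seeded from the global seed via
#' [stage_seed()], so reports are bit-reproducible.
#'
#' @param config A `linger_run_config`.
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `bias.tsv`, `timecourse.tsv`, `themes.tsv`, and `classification.json`.
#' @return A `linger_report` list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "linger_run_config"))
  cohort <- load_inputs(config)
  conditions <- unique(cohort$participants$condition)

  themes <- select_theme_words(cohort, cohort$embeddings, k = config$k_themes,
                               exclusions = config$theme_exclusions)

  per_condition <- lapply(conditions, function(cond) {
    pids <- cohort$participants$participant_id[
      cohort$participants$condition == cond]
    sub <- cohort$chains[cohort$chains$participant_id %in% pids, ]
    dtm <- scale_dtm(build_dtm(sub))
    cls <- run_classification(dtm, n_repeats = config$n_repeats,
                              seed = stage_seed(config$seed,
                                                paste0("classify:", cond)),
                              cost = config$cost)
    nulls <- permutation_null(dtm, n_perm = config$n_perm,
                              seed = stage_seed(config$seed,
                                                paste0("null:", cond)),
                              cost = config$cost)
    pv <- permutation_pvalue(cls$mean_accuracy, nulls)
    bias <- display_filter(bias_scores(sub), config$min_prevalence,
                           config$min_abs_bias)
    tc <- timecourse(sub, cohort$embeddings, themes,
                     bin_width = config$bin_width,
                     latency_mean_ms = cohort$config$token_latency_mean_ms)
    deltas <- cohort_theme_deltas(sub, cohort$embeddings, themes)
    list(condition = cond, classification = cls, null_accuracies = nulls,
         p_value = pv, bias = bias, timecourse = tc,
         duration = lingering_duration(tc), theme_deltas = deltas)
  })
  names(per_condition) <- conditions

  ratings <- split(as.numeric(cohort$participants$lingering_rating),
                   cohort$participants$condition)
  lingering_tests <- if (length(ratings) >= 2) {
    kw <- kruskal_wallis(ratings)
    pairs <- utils::combn(names(ratings), 2, simplify = FALSE)
    mw <- lapply(pairs, function(pr) {
      c(list(groups = paste(pr, collapse = " vs ")),
        mann_whitney(ratings[[pr[1]]], ratings[[pr[2]]]))
    })
    list(kruskal_wallis = kw, pairwise_mann_whitney = mw)
  } else NULL

  enc <- encode_predictors(cohort, cohort$embeddings, themes)
  stepwise <- list(
    lingering = backward_stepwise_cv(enc$X, enc$y_lingering,
                                     k_folds = config$k_folds,
                                     seed = stage_seed(config$seed,
                                                       "stepwise:lingering")),
    theme_delta = if (!is.null(enc$y_delta) && !anyNA(enc$y_delta))
      backward_stepwise_cv(enc$X, enc$y_delta, k_folds = config$k_folds,
                           seed = stage_seed(config$seed,
                                             "stepwise:delta")) else NULL)

  report <- structure(list(
    schema_version = "1.0",
    seed = config$seed,
    parameters = config[setdiff(names(config), "synthetic")],
    themes = themes,
    per_condition = per_condition,
    lingering_tests = lingering_tests,
    stepwise = stepwise), class = "linger_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

report_json <- function(report) {
  per_cond <- lapply(report$per_condition, function(pc) {
    list(condition = pc$condition,
         mean_accuracy = pc$classification$mean_accuracy,
         n_repeats = pc$classification$n_repeats,
         null_mean = mean(pc$null_accuracies),
         n_perm = length(pc$null_accuracies),
         p_value = pc$p_value$p,
         p_label = pc$p_value$label,
         mean_pre = mean(pc$theme_deltas$pre_mean, na.rm = TRUE),
         mean_post = mean(pc$theme_deltas$post_mean, na.rm = TRUE),
         mean_delta = mean(pc$theme_deltas$delta, na.rm = TRUE),
         n_significant_bins = pc$duration$n_significant_bins,
         lingering_seconds = pc$duration$seconds)
  })
  sw <- lapply(report$stepwise, function(s) {
    if (is.null(s)) return(NULL)
    list(selected = s$selected, r_squared = s$fit$r_squared,
         coefficients = as.list(s$fit$coefficients),
         t = as.list(s$fit$t), df = s$fit$df)
  })
  list(schema_version = report$schema_version,
       seed = report$seed,
       parameters = report$parameters,
       theme_words = report$themes$tokens,
       per_condition = per_cond,
       lingering_tests = report$lingering_tests,
       stepwise = sw)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (full machine-readable summary),
#' `classification.json`, and the TSV tables `bias.tsv`, `timecourse.tsv`,
#' `themes.tsv`.
#'
#' @param report A `linger_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cls <- lapply(report$per_condition, function(pc) {
    list(condition = pc$condition,
         mean_accuracy = pc$classification$mean_accuracy,
         repeat_accuracies = pc$classification$repeat_accuracies,
         null_accuracies = pc$null_accuracies,
         p_value = pc$p_value$p, p_label = pc$p_value$label,
         n_repeats = pc$classification$n_repeats,
         n_perm = length(pc$null_accuracies),
         seed = pc$classification$seed)
  })
  jsonlite::write_json(cls, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bias_all <- do.call(rbind, lapply(report$per_condition, function(pc) {
    cbind(condition = pc$condition, as.data.frame(pc$bias))
  }))
  utils::write.table(bias_all, file.path(out_dir, "bias.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tc_all <- do.call(rbind, lapply(report$per_condition, function(pc) {
    cbind(condition = pc$condition, as.data.frame(pc$timecourse$bins))
  }))
  utils::write.table(tc_all, file.path(out_dir, "timecourse.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  th <- data.frame(rank = seq_along(report$themes$tokens),
                   token = report$themes$tokens)
  utils::write.table(th, file.path(out_dir, "themes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.linger_report <- function(x, ...) {
  cat("<linger_report> seed ", x$seed, "\n", sep = "")
  for (pc in x$per_condition) {
    cat(sprintf("  %-10s accuracy %.1f%% (p %s); delta %+0.4f; %d sig bin(s)\n",
                pc$condition, 100 * pc$classification$mean_accuracy,
                pc$p_value$label, mean(pc$theme_deltas$delta, na.rm = TRUE),
                pc$duration$n_significant_bins))
  }
  invisible(x)
}
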