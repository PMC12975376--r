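#' Assemble the modeled trait table from pipeline artifacts
#'
#' Collects every trait entering twin modeling into one tibble and assigns
#' each its trait class (which fixes the covariate-adjustment set): the 30
#' food-group intakes, total energy, the nutrient intakes, the three diet
#' indices, the three composite taste preferences (mean of the two item
#' ratings per taste class) and the six individual taste-item ratings.
#'
#' @param profiles Intake profiles of the retained participants.
#' @param scores Diet-index scores ([score_diet_indices()] output).
#' @param ffq Imputed answer table (for the taste ratings).
#' @param schema The [ffq_schema()] in use.
#' @return A list: `traits` (tibble `participant_id` + trait columns) and
#'   `classes` (named character vector of trait classes).
#' @export
build_trait_table <- function(profiles, scores, ffq, schema) {
  fg_cols <- paste0("fg_", schema$food_groups)
  nutrient_cols <- setdiff(schema$nutrients, "energy_kcal")
  t_items <- taste_cols(schema)
  ffq_m <- ffq[match(profiles$participant_id, ffq$participant_id), ]
  taste <- tibble::as_tibble(lapply(setNames(t_items, t_items), function(cl) {
    as.numeric(ffq_m[[cl]])
  }))
  for (cls in c("bitter", "sweet", "sour")) {
    members <- paste0("taste_", schema$taste_items$item[schema$taste_items$taste_class == cls])
    taste[[paste0("taste_", cls)]] <- rowMeans(taste[members])
  }
  scores_m <- scores[match(profiles$participant_id, scores$participant_id), ]
  traits <- dplyr::bind_cols(
    tibble::tibble(participant_id = profiles$participant_id),
    profiles[fg_cols],
    profiles["energy_kcal"],
    profiles[nutrient_cols],
    tibble::tibble(
      rmed = scores_m$rmed, hnfi = scores_m$hnfi, pdi = scores_m$pdi
    ),
    taste
  )
  classes <- c(
    setNames(rep("food_group", length(fg_cols)), fg_cols),
    setNames("energy", "energy_kcal"),
    setNames(rep("nutrient", length(nutrient_cols)), nutrient_cols),
    setNames(rep("index", 3), c("rmed", "hnfi", "pdi")),
    setNames(rep("taste", ncol(taste)), names(taste))
  )
  list(traits = traits, classes = classes)
}

#' Configure a pipeline run
#'
#' Bundles every knob of an end-to-end run: the simulation spec of the
#' synthetic cohort (or paths to existing participant/FFQ CSVs), the QC
#' thresholds (defaulting to the plausibility bounds the screen was designed
#' with: 500/6000 kcal, 0.3/4 PAL, 15/140 BMI, 10% missingness), model
#' options and the seed.
#'
#' @param spec A [simulation_spec()], or `NULL` when reading input files.
#' @param participants_file,ffq_file CSV paths, used when `spec` is `NULL`.
#' @param schema An [ffq_schema()].
#' @param thresholds A [qc_thresholds()] list.
#' @param alpha LRT significance level for model selection.
#' @param ci Compute profile-likelihood CIs per trait.
#' @param out_dir Optional directory; when set, every intermediate artifact
#'   and the report are persisted as TSV/markdown.
#' @return A `run_config` list.
#' @export
run_config <- function(spec = NULL, participants_file = NULL, ffq_file = NULL,
                       schema = default_ffq_schema(),
                       thresholds = qc_thresholds(), alpha = 0.05,
                       ci = TRUE, out_dir = NULL) {
  if (is.null(spec) && (is.null(participants_file) || is.null(ffq_file))) {
    abort("Provide either a simulation spec or participant + FFQ file paths.")
  }
  structure(
    list(
      spec = spec, participants_file = participants_file,
      ffq_file = ffq_file, schema = schema, thresholds = thresholds,
      alpha = alpha, ci = ci, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]: an optional `spec` block (a2, c2, e2,
#' n_mz_pairs, n_dz_pairs, missing_rate, implausible_fraction,
#' bmi_outlier_fraction, prop_female, seed), optional `participants_file` /
#' `ffq_file`, optional `thresholds` block, `alpha`, `ci`, `out_dir` and an
#' optional `schema_dir` readable by [read_ffq_schema()]. Every QC
#' threshold is a named key so deviations from the defaults are visible
#' diffs.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$spec)) do.call(simulation_spec, y$spec) else NULL
  thresholds <- do.call(qc_thresholds, y$thresholds %||% list())
  schema <- if (!is.null(y$schema_dir)) read_ffq_schema(y$schema_dir) else default_ffq_schema()
  run_config(
    spec = spec,
    participants_file = y$participants_file,
    ffq_file = y$ffq_file,
    schema = schema,
    thresholds = thresholds,
    alpha = y$alpha %||% 0.05,
    ci = y$ci %||% TRUE,
    out_dir = y$out_dir
  )
}

# Table-1-style cohort summary: counts by zygosity and sex, BMI classes,
# mean/SD energy.
cohort_summary <- function(participants, profiles) {
  pp <- participants[match(profiles$participant_id, participants$participant_id), ]
  bmi_class <- cut(
    profiles$bmi, c(-Inf, 18.5, 25, 30, Inf),
    labels = c("<18.5", "18.5-24.9", "25-29.9", ">=30"), right = FALSE
  )
  tibble::tibble(
    statistic = c(
      "participants", "pairs", "mz_individuals", "dz_individuals",
      "percent_female", "mean_energy_kcal", "sd_energy_kcal",
      "mean_bmi", paste0("bmi_", levels(bmi_class))
    ),
    value = c(
      nrow(pp), nrow(pp) / 2,
      sum(pp$zygosity == "MZ"), sum(pp$zygosity == "DZ"),
      100 * mean(pp$sex == "F"),
      mean(profiles$energy_kcal), sd(profiles$energy_kcal),
      mean(profiles$bmi),
      as.numeric(table(bmi_class))
    )
  )
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> process -> indices -> prepare -> model as
#' one reproducible run: cohort generation or ingestion, intake profiling,
#' quality control with pair completion, diet-index scoring, trait
#' preparation and per-trait twin ACE analysis. Fully deterministic given
#' the config (the only randomness is the simulation spec's seed).
#'
#' @param config A [run_config()].
#' @return An object of class `dietace_report`: cohort summary, QC
#'   waterfall, per-trait variance-component table, selected-model tally,
#'   and the underlying `twin_ace_result`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(
#'   spec = simulation_spec(0.5, 0, 0.5, 60, 120, seed = 5),
#'   ci = FALSE
#' )
#' rep <- run_pipeline(cfg)
#' rep$model_tally
#' }
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  schema <- config$schema
  if (!is.null(config$spec)) {
    cohort <- simulate_ffq_cohort(config$spec, schema)
    participants <- cohort$participants
    ffq <- cohort$ffq
  } else {
    participants <- readr::read_csv(
      config$participants_file, show_col_types = FALSE, progress = FALSE
    )
    ffq <- readr::read_csv(
      config$ffq_file, show_col_types = FALSE, progress = FALSE
    )
    cohort <- NULL
  }
  if (nrow(participants) == 0 || nrow(ffq) == 0) {
    abort("Empty cohort: no participants or no FFQ records; nothing to analyze.")
  }
  validate_ffq(ffq, schema)

  profiles <- intake_profiles(ffq, participants, schema)
  qc <- apply_qc(ffq, participants, profiles, config$thresholds)
  retained_ids <- qc$participant_id[qc$pass]
  if (length(retained_ids) < 40) {
    abort(sprintf(
      "Only %d records survive QC; too few complete pairs to model.",
      length(retained_ids)
    ))
  }
  keep <- profiles$participant_id %in% retained_ids
  profiles_r <- profiles[keep, ]
  ffq_imputed <- impute_missing(ffq, schema)[keep, ]
  participants_r <- participants[participants$participant_id %in% retained_ids, ]

  scores <- score_diet_indices(profiles_r, participants_r)
  tt <- build_trait_table(profiles_r, scores, ffq_imputed, schema)
  prepared <- prepare_traits(
    tt$traits, tt$classes, participants_r, profiles_r$energy_kcal
  )
  result <- twin_ace(
    prepared$values, participants_r,
    alpha = config$alpha, ci = config$ci
  )
  tab <- result$table
  report <- structure(
    list(
      cohort_summary = cohort_summary(participants_r, profiles_r),
      qc_waterfall = qc_waterfall(qc),
      qc = qc,
      trait_table = tab,
      preparation_log = prepared$log,
      model_tally = dplyr::count(
        tab[!is.na(tab$chosen), ], .data$chosen, name = "n_traits"
      ),
      index_scores = scores,
      result = result,
      truth = if (!is.null(cohort)) cohort$truth else NULL
    ),
    class = "dietace_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Persist a pipeline report
#'
#' Writes the cohort summary, QC waterfall, per-trait variance-component
#' table, preparation log and model tally as TSV files plus a human-readable
#' `report.md` into `dir`.
#'
#' @param report A `dietace_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f), progress = FALSE)
  w(report$cohort_summary, "cohort_summary.tsv")
  w(report$qc_waterfall, "qc_waterfall.tsv")
  w(tibble::as_tibble(report$qc), "qc_report.tsv")
  w(report$trait_table, "trait_table.tsv")
  w(report$preparation_log, "preparation_log.tsv")
  w(report$model_tally, "model_tally.tsv")
  w(report$index_scores, "index_scores.tsv")
  md <- c(
    "# Twin ACE dietary analysis report", "",
    "## Cohort", "",
    sprintf("- %s: %.4g", report$cohort_summary$statistic, report$cohort_summary$value),
    "", "## QC waterfall", "",
    sprintf("- %s: %d", report$qc_waterfall$step, report$qc_waterfall$n),
    "", "## Model selection tally", "",
    sprintf("- %s: %d traits", report$model_tally$chosen, report$model_tally$n_traits),
    "", "## Traits (chosen-model heritability)", "",
    sprintf(
      "- %s: %s, a2 = %.3f [%.3f, %.3f], q = %.3g",
      report$trait_table$trait,
      ifelse(is.na(report$trait_table$chosen), "excluded", report$trait_table$chosen),
      report$trait_table$a2, report$trait_table$a2_lower,
      report$trait_table$a2_upper, report$trait_table$fdr_q
    )
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' @export
print.dietace_report <- function(x, ...) {
  cat("<dietace_report>\n\n## Cohort\n")
  print(x$cohort_summary, n = Inf)
  cat("\n## QC waterfall\n")
  print(x$qc_waterfall, n = Inf)
  cat("\n## Model tally\n")
  print(x$model_tally)
  invisible(x)
}
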