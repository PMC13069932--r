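# Orchestration: enrollment filtering and the end-to-end
# simulate -> score -> analyze -> report pipeline.
#
# All tabular interchange is CSV; the analysis summary is JSON. Every output
# directory carries a manifest recording the seed, the configuration echo and
# a configuration hash, so outputs of different runs are distinguishable and
# identical configurations reproduce byte-identical summaries.

#' Apply enrollment exclusions
#'
#' Retains exactly the rows with both completeness flags clear
#' (`missing_clinical` and `missing_slide` both `FALSE`) and reports counts
#' by exclusion reason; a row with both flags set counts once toward the
#' total excluded.
#'
#' @param raw data frame with logical columns `missing_clinical` and
#'   `missing_slide` (e.g. from [generate_raw_enrollment()]).
#' @return list with `cohort` (the eligible rows) and `report` (data frame of
#'   counts: screened, missing clinical only, missing slide only, both,
#'   excluded, eligible).
#' @examples
#' raw <- generate_raw_enrollment(331, 149, seed = 1)
#' apply_exclusions(raw)$report
#' @export
apply_exclusions <- function(raw) {
  if (!is.data.frame(raw) || nrow(raw) == 0)
    stop("raw cohort must be a non-empty data frame")
  check_columns(raw, c("missing_clinical", "missing_slide"), "raw cohort")
  mc <- raw$missing_clinical
  ms <- raw$missing_slide
  eligible <- !mc & !ms
  report <- data.frame(
    reason = c("screened", "missing_clinical_only", "missing_slide_only",
               "missing_both", "excluded", "eligible"),
    n = c(nrow(raw), sum(mc & !ms), sum(!mc & ms), sum(mc & ms),
          sum(!eligible), sum(eligible))
  )
  if (!any(eligible))
    warning("all cases excluded: downstream analyses cannot run")
  cohort <- raw[eligible, , drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort, report = report)
}

#' Pipeline configuration
#'
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed governing every random stage.
#' @param spec a [synthetic_spec()] for the simulated cohort (its own seed is
#'   overridden by `seed`); ignored when `cohort_csv` is given.
#' @param cohort_csv optional path to an existing cohort CSV (columns
#'   `case_id`, `ihc_category`, `fish_status`, `mean_intensity`, `pct_area`,
#'   optional `hscore`); when `NULL` a cohort is simulated.
#' @param n_total,n_incomplete enrollment simulation: cases screened and
#'   cases flagged incomplete before eligibility filtering.
#' @param fields_per_slide fields per slide for image-based stages.
#' @param cutpoint_test test used by the cutpoint scan: `"t"`, `"chisq"` or
#'   `"fisher"`.
#' @param covariates extra predictor columns for the adjusted logistic model.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, spec = synthetic_spec(),
                            cohort_csv = NULL,
                            n_total = 331, n_incomplete = 149,
                            fields_per_slide = 3,
                            cutpoint_test = "t", covariates = character(0)) {
  if (fields_per_slide < 1) stop("fields_per_slide must be at least 1")
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 cohort_csv = cohort_csv, n_total = n_total,
                 n_incomplete = n_incomplete,
                 fields_per_slide = fields_per_slide,
                 cutpoint_test = cutpoint_test, covariates = covariates),
            class = "pipeline_config")
}

read_cohort_csv <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(coh, c("case_id", "ihc_category", "fish_status",
                       "mean_intensity", "pct_area"),
                paste0("cohort file '", path, "'"))
  coh
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, applies enrollment exclusions to a
#' simulated screening table, scores every case, and runs the decision
#' analysis: ROC/AUC with Youden cutoff, logistic association, cutpoint
#' scan, group summaries and (when control categories are present) pairwise
#' group AUCs. Writes the report bundle to `config$out_dir`:
#' `cohort.csv`, `scored.csv`, `exclusions.csv`, `roc.csv`, `summary.json`,
#' `cutpoints.csv`, `groups.csv`, `pairwise_auc.csv` (if applicable) and
#' `manifest.json`. Re-running with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`cohort`, `scored`,
#'   `exclusions`, `roc`, `logistic`, `cutpoints`, `groups`,
#'   `pairwise_auc`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  exclusions <- NULL
  if (is.null(config$cohort_csv)) {
    raw <- generate_raw_enrollment(config$n_total, config$n_incomplete,
                                   seed = config$seed)
    excl <- apply_exclusions(raw)
    exclusions <- excl$report
    spec <- config$spec
    spec$seed <- config$seed + 1L
    cohort <- generate_cohort(spec)
  } else {
    cohort <- read_cohort_csv(config$cohort_csv)
  }

  scored <- score_cohort(cohort)
  analysis <- scored[scored$scoreable &
                       scored$fish_status %in% c("positive", "negative"), ,
                     drop = FALSE]
  if (nrow(analysis) == 0 || length(unique(analysis$fish_status)) < 2)
    stop("analysis set is degenerate: need scoreable cases of both FISH classes")

  roc <- roc_curve(analysis$hscore, analysis$fish_status)
  logistic <- logistic_association(analysis,
                                   predictors = c("hscore", config$covariates))
  cutpoints <- cutpoint_scan(analysis$hscore, analysis$fish_status,
                             test = config$cutpoint_test)
  groups <- group_summary(scored[is.finite(scored$hscore), , drop = FALSE])
  pairwise <- NULL
  if (length(unique(scored$ihc_category[is.finite(scored$hscore)])) >= 2)
    pairwise <- pairwise_group_auc(scored)

  summary_obj <- list(
    n_cases = nrow(analysis),
    n_positive = sum(analysis$fish_status == "positive"),
    n_negative = sum(analysis$fish_status == "negative"),
    mean_hscore = round(mean(analysis$hscore), 10),
    auc = round(roc$auc, 10),
    auc_se = round(roc$auc_se, 10),
    auc_ci95 = round(roc$auc_ci95, 10),
    youden_cutoff = round(roc$youden_cutoff, 10),
    sensitivity = round(roc$sens_at_cutoff, 10),
    specificity = round(roc$spec_at_cutoff, 10),
    best_cutpoint = round(cutpoints$best_cutpoint, 10),
    best_cutpoint_p_adj = round(cutpoints$best_p_adj, 10)
  )

  cfg_echo <- utils::capture.output(utils::str(config, give.attr = FALSE))
  manifest <- list(
    package = "odhscore",
    version = as.character(utils::packageVersion("odhscore")),
    seed = config$seed,
    config_hash = fnv1a_hash(cfg_echo),
    config = cfg_echo
  )

  wcsv <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }
  wcsv(cohort, "cohort.csv")
  wcsv(scored, "scored.csv")
  wcsv(exclusions, "exclusions.csv")
  wcsv(data.frame(cutoff = roc$cutoffs, sensitivity = roc$sensitivity,
                  specificity = roc$specificity), "roc.csv")
  wcsv(cutpoints$table, "cutpoints.csv")
  wcsv(groups, "groups.csv")
  wcsv(pairwise, "pairwise_auc.csv")
  jsonlite::write_json(summary_obj, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, scored = scored, exclusions = exclusions,
                 roc = roc, logistic = logistic, cutpoints = cutpoints,
                 groups = groups, pairwise_auc = pairwise,
                 summary = summary_obj))
}
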