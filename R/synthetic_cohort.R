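# Synthetic cohorts with the group structure the decision analysis assumes.
#
# The two FISH groups of an IHC 2+ cohort are parameterized by mean/SD/range
# of (i) mean stain intensity and (ii) percent area stained; cases are drawn
# from normal distributions truncated to the stated ranges, intensity and
# area independently (the two are treated as uncorrelated). IHC 0/1+/3+
# control groups are generated at the HScore level directly, since controls
# are characterized by their score distribution alone.
#
# Note that truncating a normal to an asymmetric range shifts its mean: the
# long-run sample mean of a group equals truncnorm_moments() applied to its
# parameters, not the parent mean itself.

default_control_groups <- function() {
  list(
    `0` = list(hscore_mean = 3.35, hscore_sd = 0.74, hscore_range = c(2.10, 4.51), n = 10),
    `1` = list(hscore_mean = 2.56, hscore_sd = 0.97, hscore_range = c(1.51, 4.55), n = 10),
    `3` = list(hscore_mean = 4.02, hscore_sd = 1.43, hscore_range = c(2.46, 6.75), n = 10)
  )
}

#' Specification of a synthetic IHC 2+ cohort
#'
#' Defaults describe a cohort of 182 ERBB2 IHC 2+ cases, 169 FISH-negative
#' and 13 FISH-positive, with group-wise intensity and stained-area moments
#' typical of an equivocal ERBB2 series; optional IHC 0/1+/3+ control groups
#' (10 cases each) are specified at the HScore level.
#'
#' @param negative,positive per-group parameters: lists with
#'   `intensity_mean`, `intensity_sd`, `intensity_range` (length-2),
#'   `area_mean`, `area_sd`, `area_range` (percent units), `n`.
#' @param controls named list (`"0"`, `"1"`, `"3"`) of HScore-level control
#'   groups, each with `hscore_mean`, `hscore_sd`, `hscore_range`, `n`; or
#'   `NULL` for none.
#' @param include_controls whether [generate_cohort()] appends the control
#'   groups (default `FALSE`: the 2+ discrimination cohort only).
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    negative = list(intensity_mean = 113.3, intensity_sd = 13.9,
                    intensity_range = c(66.4, 142.8),
                    area_mean = 6.3, area_sd = 1.9, area_range = c(2.6, 13.8),
                    n = 169),
    positive = list(intensity_mean = 103.82, intensity_sd = 20.8,
                    intensity_range = c(59.1, 126.4),
                    area_mean = 6.8, area_sd = 2.1, area_range = c(3.6, 11.9),
                    n = 13),
    controls = default_control_groups(),
    include_controls = FALSE,
    seed = NULL) {
  spec <- structure(list(negative = negative, positive = positive,
                         controls = controls,
                         include_controls = include_controls, seed = seed),
                    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  check_group <- function(g, label) {
    for (f in c("intensity_mean", "intensity_sd", "intensity_range",
                "area_mean", "area_sd", "area_range", "n"))
      if (is.null(g[[f]])) stop(label, " group is missing field ", f)
    if (g$intensity_sd <= 0 || g$area_sd <= 0)
      stop(label, " group: SDs must be positive")
    if (g$intensity_mean < g$intensity_range[1] || g$intensity_mean > g$intensity_range[2])
      stop(label, " group: intensity_range must contain intensity_mean")
    if (g$area_mean < g$area_range[1] || g$area_mean > g$area_range[2])
      stop(label, " group: area_range must contain area_mean")
    if (g$n < 1) stop(label, " group: n must be at least 1")
  }
  check_group(spec$negative, "negative")
  check_group(spec$positive, "positive")
  if (spec$negative$n + spec$positive$n < 2)
    stop("cohort must contain at least 2 cases")
  for (cat in names(spec$controls)) {
    g <- spec$controls[[cat]]
    if (g$hscore_sd <= 0) stop("control ", cat, ": hscore_sd must be positive")
    if (g$hscore_mean < g$hscore_range[1] || g$hscore_mean > g$hscore_range[2])
      stop("control ", cat, ": hscore_range must contain hscore_mean")
    if (g$n < 1) stop("control ", cat, ": n must be at least 1")
  }
  invisible(spec)
}

draw_group <- function(g, fish, offset) {
  data.frame(
    case_id = sprintf("case_%04d", offset + seq_len(g$n)),
    ihc_category = 2L,
    fish_status = fish,
    mean_intensity = rtruncnorm(g$n, g$intensity_mean, g$intensity_sd,
                                g$intensity_range[1], g$intensity_range[2]),
    pct_area = rtruncnorm(g$n, g$area_mean, g$area_sd,
                          g$area_range[1], g$area_range[2]),
    hscore = NA_real_,
    age = round(stats::runif(g$n, 30, 90)), # placeholder covariate
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort
#'
#' Draws each 2+ case's mean intensity and percent stained area independently
#' from the group's truncated normal distributions and labels it with its
#' FISH group; HScores for 2+ cases are left `NA` for [score_cohort()] to
#' fill. Control-group cases (IHC 0/1+/3+, when `include_controls = TRUE`)
#' carry a directly drawn `hscore`, `fish_status = "unavailable"` and no
#' intensity/area measurements. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return data frame with columns `case_id`, `ihc_category`, `fish_status`,
#'   `mean_intensity`, `pct_area`, `hscore`, `age`.
#' @examples
#' coh <- generate_cohort(synthetic_spec(seed = 1))
#' table(coh$fish_status)
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  validate_synthetic_spec(spec)
  with_seed_if(spec$seed, {
    neg <- draw_group(spec$negative, "negative", 0L)
    pos <- draw_group(spec$positive, "positive", spec$negative$n)
    coh <- rbind(neg, pos)
    if (spec$include_controls && length(spec$controls) > 0) {
      offset <- nrow(coh)
      for (cat in names(spec$controls)) {
        g <- spec$controls[[cat]]
        ctrl <- data.frame(
          case_id = sprintf("ctrl%s_%03d", cat, seq_len(g$n)),
          ihc_category = as.integer(cat),
          fish_status = "unavailable",
          mean_intensity = NA_real_,
          pct_area = NA_real_,
          hscore = rtruncnorm(g$n, g$hscore_mean, g$hscore_sd,
                              g$hscore_range[1], g$hscore_range[2]),
          age = round(stats::runif(g$n, 30, 90)),
          stringsAsFactors = FALSE
        )
        coh <- rbind(coh, ctrl)
        offset <- offset + g$n
      }
    }
    rownames(coh) <- NULL
    coh
  })
}

#' Generate a raw enrollment table with completeness flags
#'
#' Emulates the chart-review stage of a retrospective series: `n_total`
#' screened cases of which `n_incomplete` are incomplete (missing clinical
#' data, missing original slide, or both) and will fall to the eligibility
#' filter. Which cases are flagged, and for which reason, is pseudo-random
#' under `seed`.
#'
#' @param n_total number screened.
#' @param n_incomplete number flagged incomplete, `0 <= n_incomplete <= n_total`.
#' @param seed integer seed.
#' @return data frame with columns `case_id`, `missing_clinical`,
#'   `missing_slide` (class `raw_cohort`).
#' @seealso [apply_exclusions()]
#' @export
generate_raw_enrollment <- function(n_total, n_incomplete, seed = NULL) {
  if (n_total < 0 || n_incomplete < 0 || n_incomplete > n_total)
    stop("need 0 <= n_incomplete <= n_total")
  with_seed_if(seed, {
    raw <- data.frame(
      case_id = sprintf("case_%04d", seq_len(n_total)),
      missing_clinical = FALSE,
      missing_slide = FALSE,
      stringsAsFactors = FALSE
    )
    if (n_incomplete > 0) {
      flagged <- sample(n_total, n_incomplete)
      reason <- sample(c("clinical", "slide", "both"), n_incomplete,
                       replace = TRUE, prob = c(0.55, 0.35, 0.10))
      raw$missing_clinical[flagged] <- reason %in% c("clinical", "both")
      raw$missing_slide[flagged] <- reason %in% c("slide", "both")
    }
    class(raw) <- c("raw_cohort", class(raw))
    raw
  })
}
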