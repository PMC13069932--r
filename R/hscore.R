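# The optical-density HScore.
#
# A field's staining is summarized as an optical density,
#   OD = log10(255 / mean_intensity),
# the log-ratio of reference white to the observed mean gray value of the
# stained area (darker stain -> lower mean intensity -> higher OD), and
# scaled by the stained extent:
#   HScore = OD * (pct_area + 1),
# with pct_area in PERCENT units (0-100). The +1 keeps a faint but non-zero
# stain from collapsing the score to 0. The base of the logarithm is 10 and
# the area is in percent; both conventions are pinned down numerically by the
# unit tests (natural log or fractional area give wildly different scales).

#' Optical density of a mean gray value
#'
#' `log10(255 / mean_intensity)`: 0 for reference white (255), increasing as
#' the stained area darkens.
#'
#' @param mean_intensity mean gray value of the stained area, in `(0, 255]`.
#' @return optical density (dimensionless, log10 units).
#' @examples
#' optical_density(255)   # 0
#' optical_density(127.5) # log10(2)
#' @export
optical_density <- function(mean_intensity) {
  if (any(!is.finite(mean_intensity)) || any(mean_intensity <= 0))
    stop("mean_intensity must be positive (gray value in (0, 255])")
  if (any(mean_intensity > WHITE_REF))
    stop("mean_intensity cannot exceed the white reference ", WHITE_REF)
  log10(WHITE_REF / mean_intensity)
}

#' Optical-density HScore
#'
#' `log10(255 / mean_intensity) * (pct_area + 1)`, with the stained-area
#' percentage in percent units. Monotone: decreasing in `mean_intensity`
#' (darker stain scores higher), increasing in `pct_area`.
#'
#' Mean intensities below 1 are clamped to 1 with a warning before the log
#' transform; a gray value of 0 (pure black) would otherwise send the score
#' to infinity, and real 8-bit fields never average below 1 unless the mask
#' has degenerated.
#'
#' @param mean_intensity mean gray value of the stained area, vectorized.
#' @param pct_area percent of area stained, in `[0, 100]`, vectorized.
#' @return numeric HScore value(s), `>= 0`; 0 exactly when the stained area
#'   is reference white.
#' @examples
#' hscore(103.82, 6.8) # ~3.04
#' hscore(113.3, 6.3)  # ~2.57
#' @export
hscore <- function(mean_intensity, pct_area) {
  if (any(!is.finite(pct_area)) || any(pct_area < 0) || any(pct_area > 100))
    stop("pct_area must lie in [0, 100] (percent units)")
  if (any(is.finite(mean_intensity) & mean_intensity < 1)) {
    warning("mean_intensity below 1 clamped to 1 before the optical-density transform")
    mean_intensity <- pmax(mean_intensity, 1)
  }
  optical_density(mean_intensity) * (pct_area + 1)
}

#' Score every case of a cohort
#'
#' Computes `od` and `hscore` per case from `mean_intensity` and `pct_area`.
#' Cases carrying a precomputed `hscore` alongside their inputs are validated
#' against the recomputation (tolerance 1e-9); a mismatch aborts, naming the
#' offending cases. Cases without intensity/area but with an `hscore` already
#' present (e.g. score-level synthetic controls) are kept as-is; cases with
#' neither are flagged `scoreable = FALSE`, excluded from downstream analyses,
#' and reported in a warning.
#'
#' @param cohort data frame with columns `mean_intensity` and `pct_area`
#'   (and optionally `hscore`, `case_id`).
#' @return the cohort with columns `od`, `hscore` and `scoreable` filled.
#' @export
score_cohort <- function(cohort) {
  check_columns(cohort, c("mean_intensity", "pct_area"), "cohort")
  ids <- if ("case_id" %in% names(cohort)) cohort$case_id else seq_len(nrow(cohort))
  has_inputs <- is.finite(cohort$mean_intensity) & is.finite(cohort$pct_area)
  had_hscore <- "hscore" %in% names(cohort)
  prior <- if (had_hscore) cohort$hscore else rep(NA_real_, nrow(cohort))

  od <- rep(NA_real_, nrow(cohort))
  hs <- prior
  if (any(has_inputs)) {
    od[has_inputs] <- optical_density(pmax(cohort$mean_intensity[has_inputs], 1))
    hs[has_inputs] <- hscore(cohort$mean_intensity[has_inputs],
                             cohort$pct_area[has_inputs])
    if (had_hscore) {
      chk <- has_inputs & is.finite(prior)
      bad <- chk & abs(prior - hs) > 1e-9
      if (any(bad))
        stop("precomputed hscore disagrees with recomputation for case(s): ",
             paste(ids[bad], collapse = ", "))
    }
  }
  scoreable <- is.finite(hs)
  if (any(!scoreable))
    warning(sum(!scoreable), " case(s) lack both measurements and a score; ",
            "flagged unscoreable: ",
            paste(utils::head(ids[!scoreable], 5), collapse = ", "))
  cohort$od <- od
  cohort$hscore <- hs
  cohort$scoreable <- scoreable
  cohort
}
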