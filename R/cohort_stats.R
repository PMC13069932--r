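# Cohort-level decision analysis of a continuous score against a binary
# reference standard (FISH status): empirical ROC/AUC with DeLong standard
# errors, Youden-index cutoff selection, a Bonferroni-corrected cutpoint
# scan, pairwise group AUCs across IHC categories, logistic association, and
# descriptive group summaries.
#
# Conventions: the positive call is score >= cutoff (higher score -> positive
# class); candidate ROC cutoffs are the observed score values; tied
# positive/negative scores contribute 1/2 to the AUC (Mann-Whitney with
# midranks).

as_binary_labels <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  labels == positive
}

# DeLong (1988) variance of the empirical AUC via placement values.
delong_variance <- function(pos, neg) {
  m <- length(pos)
  n <- length(neg)
  all <- c(pos, neg)
  r_all <- rank(all)
  r_pos <- rank(pos)
  r_neg <- rank(neg)
  # placement of each positive among negatives, and vice versa
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  if (m > 1) s10 <- stats::var(v10) else s10 <- 0
  if (n > 1) s01 <- stats::var(v01) else s01 <- 0
  s10 / m + s01 / n
}

#' Empirical ROC curve with AUC, DeLong CI and Youden cutoff
#'
#' Builds the empirical ROC of `scores` against binary `labels` using the
#' observed score values as candidate cutoffs (call positive when
#' `score >= cutoff`). The AUC is the Mann-Whitney probability that a random
#' positive outscores a random negative, ties counting one half; its standard
#' error and 95% CI come from DeLong's method (CI clipped to `[0, 1]`). The
#' Youden-optimal cutoff is attached for convenience.
#'
#' @param scores numeric marker values (e.g. HScores).
#' @param labels case labels; compared against `positive`, or a logical
#'   vector.
#' @param positive label value of the positive class (default `"positive"`).
#' @return object of class `roc_summary`: list with `cutoffs`,
#'   `sensitivity`, `specificity` (per cutoff), `auc`, `auc_se`, `auc_ci95`,
#'   `youden_cutoff`, `sens_at_cutoff`, `spec_at_cutoff`, `n_pos`, `n_neg`.
#' @examples
#' r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc
#' @export
roc_curve <- function(scores, labels, positive = "positive") {
  y <- as_binary_labels(labels, positive)
  keep <- is.finite(scores) & !is.na(y)
  scores <- scores[keep]
  y <- y[keep]
  if (!any(y) || all(y))
    stop("ROC analysis needs both classes present in the labels")
  pos <- scores[y]
  neg <- scores[!y]
  m <- length(pos)
  n <- length(neg)

  # Mann-Whitney AUC via midranks (ties count 1/2)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  se <- sqrt(delong_variance(pos, neg))
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)

  cutoffs <- sort(unique(scores))
  sens <- vapply(cutoffs, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cutoffs, function(c) mean(neg < c), numeric(1))

  out <- structure(list(
    cutoffs = cutoffs, sensitivity = sens, specificity = spec,
    auc = auc, auc_se = se, auc_ci95 = ci,
    n_pos = m, n_neg = n
  ), class = "roc_summary")
  yj <- youden_cutoff(out)
  out$youden_cutoff <- yj$cutoff
  out$sens_at_cutoff <- yj$sensitivity
  out$spec_at_cutoff <- yj$specificity
  out
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d positive vs %d negative cases\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f (SE %.3f; 95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_se, x$auc_ci95[1], x$auc_ci95[2]))
  cat(sprintf("  Youden cutoff %.4f: sensitivity %.2f, specificity %.2f\n",
              x$youden_cutoff, x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' @export
plot.roc_summary <- function(x, ...) {
  fpr <- c(1, 1 - x$specificity, 0)
  tpr <- c(1, x$sensitivity, 0)
  plot(fpr, tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "gray")
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' The cutoff maximizing J = sensitivity + specificity - 1 over the ROC's
#' candidate cutoffs; ties are broken toward the smallest cutoff (the
#' sensitivity-favoring choice).
#'
#' @param roc a `roc_summary` from [roc_curve()].
#' @return list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_summary"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)[1] # cutoffs sorted ascending: first = smallest
  list(cutoff = roc$cutoffs[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       j = j[best])
}

#' Logistic association of a score with the binary reference standard
#'
#' Maximum-likelihood binary logistic regression of FISH status on the
#' HScore (and optional covariates). Odds ratios are `exp(coefficient)` with
#' Wald 95% CIs. Predictors dropped by the fit for rank deficiency (e.g. a
#' constant column), and apparent complete separation, are flagged with a
#' warning rather than reported as spuriously precise estimates.
#'
#' @param cohort data frame of cases.
#' @param predictors character vector of predictor column names
#'   (default `"hscore"`).
#' @param outcome name of the binary outcome column (default `"fish_status"`).
#' @param positive outcome value coding the positive class.
#' @return object of class `logistic_fit`: list with `terms` (data frame:
#'   `term`, `estimate`, `or`, `ci_lo`, `ci_hi`, `p`), `log_likelihood`,
#'   `converged`, `n`, and the underlying `glm` fit.
#' @export
logistic_association <- function(cohort, predictors = "hscore",
                                 outcome = "fish_status",
                                 positive = "positive") {
  pred_cols <- setdiff(predictors, "1") # "1" requests an intercept-only fit
  check_columns(cohort, c(outcome, pred_cols), "cohort")
  use <- cohort[cohort[[outcome]] != "unavailable", , drop = FALSE]
  y <- as.integer(as_binary_labels(use[[outcome]], positive))
  if (length(unique(y)) < 2)
    stop("logistic fit needs both outcome classes present")
  dat <- use[, pred_cols, drop = FALSE]
  dat$.y <- y
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  form <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  co <- summary(fit)$coefficients
  dropped <- setdiff(names(stats::coef(fit)), rownames(co))
  if (any(is.na(stats::coef(fit)))) {
    dropped <- union(dropped, names(stats::coef(fit))[is.na(stats::coef(fit))])
    warning("predictor(s) dropped (rank-deficient, e.g. constant): ",
            paste(dropped, collapse = ", "))
  }
  separated <- any(abs(co[, "Estimate"]) > 15) || any(co[, "Std. Error"] > 100)
  if (separated)
    warning("apparent complete separation: odds ratios are unreliable")
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  terms <- data.frame(
    term = rownames(co),
    estimate = est,
    or = exp(est),
    ci_lo = exp(est - stats::qnorm(0.975) * se),
    ci_hi = exp(est + stats::qnorm(0.975) * se),
    p = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(terms = terms,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 converged = fit$converged && !separated,
                 n = nrow(dat), fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Binary logistic fit (n = %d, logLik = %.2f, converged: %s)\n",
              x$n, x$log_likelihood, x$converged))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Cutpoint scan with Bonferroni correction
#'
#' Scans candidate dichotomization points of a continuous score: at each
#' candidate `c` the cases split into `score < c` versus `score >= c`, and
#' the binary outcome (0/1) is compared between the two groups — by default
#' with a Welch two-sample t test on the 0/1 outcome (numerically a
#' two-proportion comparison), alternatively chi-squared or Fisher's exact
#' test on the 2x2 table. Each raw p-value is Bonferroni-multiplied by the
#' number of candidates actually tested. The best cutpoint is the one with
#' the smallest adjusted p, ties broken toward the smallest cutpoint.
#'
#' @param scores numeric score values.
#' @param labels binary labels (see [roc_curve()]).
#' @param grid candidate cutpoints; default: midpoints between consecutive
#'   sorted unique scores.
#' @param test `"t"` (Welch, default), `"chisq"` or `"fisher"`.
#' @param positive label value of the positive class.
#' @param min_group smallest group size a candidate may produce; candidates
#'   splitting off fewer cases are skipped and recorded. Default
#'   `max(5, ceiling(0.1 * n))`, the usual minimum-proportion guard of
#'   cutpoint scans: comparisons against near-empty groups are vacuous and,
#'   for the t variant, badly anticonservative (a handful of identical 0/1
#'   outcomes has zero variance).
#' @return object of class `cutpoint_scan`: list with `table` (data frame:
#'   `cutpoint`, `statistic`, `p_raw`, `p_adj`, `skipped`), `best_cutpoint`,
#'   `best_p_adj`, `n_tested`, `test`.
#' @export
cutpoint_scan <- function(scores, labels, grid = NULL,
                          test = c("t", "chisq", "fisher"),
                          positive = "positive", min_group = NULL) {
  test <- match.arg(test)
  y <- as.integer(as_binary_labels(labels, positive))
  keep <- is.finite(scores) & !is.na(y)
  scores <- scores[keep]
  y <- y[keep]
  su <- sort(unique(scores))
  if (length(su) < 2) stop("cutpoint scan needs at least 2 distinct scores")
  if (is.null(grid)) grid <- (su[-1] + su[-length(su)]) / 2
  if (is.null(min_group)) min_group <- max(5, ceiling(0.1 * length(y)))

  one <- function(c) {
    hi <- scores >= c
    if (sum(hi) < min_group || sum(!hi) < min_group)
      return(c(statistic = NA_real_, p = NA_real_, skipped = 1))
    res <- tryCatch({
      if (test == "t") {
        tt <- stats::t.test(y[hi], y[!hi])
        c(statistic = unname(tt$statistic), p = tt$p.value, skipped = 0)
      } else if (test == "chisq") {
        ct <- suppressWarnings(stats::chisq.test(table(hi, y)))
        c(statistic = unname(ct$statistic), p = ct$p.value, skipped = 0)
      } else {
        ft <- stats::fisher.test(table(hi, y))
        c(statistic = NA_real_, p = ft$p.value, skipped = 0)
      }
    }, error = function(e) {
      if (test == "t") {
        # degenerate Welch case: both groups constant in the 0/1 outcome;
        # identical means carry no evidence, distinct means are a pure split
        if (mean(y[hi]) == mean(y[!hi]))
          c(statistic = 0, p = 1, skipped = 0)
        else
          c(statistic = Inf, p = 0, skipped = 0)
      } else {
        c(statistic = NA_real_, p = NA_real_, skipped = 1)
      }
    })
    res
  }
  res <- t(vapply(grid, one, numeric(3)))
  n_tested <- sum(res[, "skipped"] == 0)
  p_adj <- pmin(1, res[, "p"] * n_tested)
  tab <- data.frame(cutpoint = grid, statistic = res[, "statistic"],
                    p_raw = res[, "p"], p_adj = p_adj,
                    skipped = res[, "skipped"] == 1)
  best <- NA_real_
  best_p <- NA_real_
  if (any(!tab$skipped & is.finite(tab$p_adj))) {
    cand <- tab[!tab$skipped & is.finite(tab$p_adj), ]
    cand <- cand[order(cand$p_adj, cand$cutpoint), ]
    best <- cand$cutpoint[1]
    best_p <- cand$p_adj[1]
  }
  structure(list(table = tab, best_cutpoint = best, best_p_adj = best_p,
                 n_tested = n_tested, test = test),
            class = "cutpoint_scan")
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat(sprintf("Cutpoint scan (%s test, %d candidates tested)\n", x$test, x$n_tested))
  cat(sprintf("  best cutpoint %.4f (Bonferroni-adjusted p = %.4g)\n",
              x$best_cutpoint, x$best_p_adj))
  invisible(x)
}

#' Pairwise group AUCs across IHC categories
#'
#' For every ordered pair of IHC categories present (higher category treated
#' as the positive class), computes the empirical ROC of the score and
#' reports AUC, DeLong SE and 95% CI — one row per pair, in the order
#' 1 vs 0, 2 vs 0, 3 vs 0, 2 vs 1, 3 vs 1, 3 vs 2 when all four categories
#' are present. Pairs in which either category has fewer than 2 scored cases
#' are skipped with a warning.
#'
#' @param cohort data frame with `ihc_category` and the score column.
#' @param score name of the score column (default `"hscore"`).
#' @return data frame: `group` (e.g. `"3 vs 2"`), `auc`, `se`, `ci_lo`,
#'   `ci_hi`, `n_hi`, `n_lo`.
#' @export
pairwise_group_auc <- function(cohort, score = "hscore") {
  check_columns(cohort, c("ihc_category", score), "cohort")
  use <- cohort[is.finite(cohort[[score]]), , drop = FALSE]
  cats <- sort(unique(use$ihc_category))
  rows <- list()
  for (lo in cats) {
    for (hi in cats[cats > lo]) {
      s_hi <- use[[score]][use$ihc_category == hi]
      s_lo <- use[[score]][use$ihc_category == lo]
      label <- sprintf("%d vs %d", hi, lo)
      if (length(s_hi) < 2 || length(s_lo) < 2) {
        warning("pair ", label, " skipped: a category has fewer than 2 cases")
        next
      }
      r <- roc_curve(c(s_hi, s_lo),
                     c(rep(TRUE, length(s_hi)), rep(FALSE, length(s_lo))))
      rows[[label]] <- data.frame(group = label, auc = r$auc, se = r$auc_se,
                                  ci_lo = r$auc_ci95[1], ci_hi = r$auc_ci95[2],
                                  n_hi = length(s_hi), n_lo = length(s_lo),
                                  stringsAsFactors = FALSE)
    }
  }
  # present in "vs 0 first" reading order: by lower category, then higher
  ord <- order(vapply(rows, function(r) {
    p <- as.integer(strsplit(r$group, " vs ")[[1]]); p[2] * 10 + p[1]
  }, numeric(1)))
  out <- do.call(rbind, rows[ord])
  rownames(out) <- NULL
  out
}

#' Descriptive summary by group
#'
#' Mean, SD and range of the scored quantities per group (IHC category by
#' default). Single-case groups report `NA` SD and a collapsed range.
#'
#' @param cohort data frame of cases.
#' @param by grouping column (default `"ihc_category"`).
#' @param vars columns to summarize; defaults to whichever of `hscore`,
#'   `mean_intensity`, `pct_area` are present.
#' @return data frame with one row per group: `group`, `n`, then
#'   `<var>_mean`, `<var>_sd`, `<var>_min`, `<var>_max` per variable.
#' @export
group_summary <- function(cohort, by = "ihc_category",
                          vars = intersect(c("hscore", "mean_intensity", "pct_area"),
                                           names(cohort))) {
  check_columns(cohort, c(by, vars), "cohort")
  groups <- split(cohort, cohort[[by]])
  if (length(groups) == 0) stop("cohort has no groups")
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    row <- data.frame(group = g, n = nrow(d), stringsAsFactors = FALSE)
    for (v in vars) {
      x <- d[[v]][is.finite(d[[v]])]
      row[[paste0(v, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0(v, "_sd")]] <- if (length(x) > 1) stats::sd(x) else NA_real_
      row[[paste0(v, "_min")]] <- if (length(x)) min(x) else NA_real_
      row[[paste0(v, "_max")]] <- if (length(x)) max(x) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
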