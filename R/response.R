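#' Classify the tumour-fraction change between two samples
#'
#' Dual-threshold rule: `decline` when the relative decrease exceeds `rel`
#' (50%) AND the absolute decrease exceeds `abs` (0.03); `increase`
#' symmetrically; otherwise `stable`. Both inequalities are strict, so a
#' change of exactly 0.03 (or exactly 50%) is `stable`. When `pre = 0` the
#' relative change is treated as infinite and the absolute threshold alone
#' decides; `pre = post = 0` is `stable`.
#'
#' @param pre,post Tumour fractions in `[0, 1)`.
#' @param rel Relative-change threshold (default 0.5).
#' @param abs Absolute-change threshold (default 0.03).
#' @return List of class `tfx_change`: `pre`, `post`, `absolute_change`
#'   (post - pre), `relative_change` (`Inf` flagged when `pre = 0`), `group`.
#' @export
classify_tfx_change <- function(pre, post, rel = 0.5, abs = 0.03) {
  if (pre < 0 || pre >= 1 || post < 0 || post >= 1)
    stop("`pre` and `post` must lie in [0, 1)")
  d <- post - pre
  r <- if (pre > 0) d / pre else if (d == 0) 0 else Inf * sign(d)
  group <- if (d < 0 && -r > rel && -d > abs) "decline"
  else if (d > 0 && r > rel && d > abs) "increase"
  else "stable"
  structure(list(pre = pre, post = post, absolute_change = d,
                 relative_change = r, relative_defined = pre > 0,
                 group = group),
            class = "tfx_change")
}

#' @export
print.tfx_change <- function(x, ...) {
  cat(sprintf("TFx %0.4f -> %0.4f (delta %+0.4f): %s\n",
              x$pre, x$post, x$absolute_change, x$group))
  invisible(x)
}

#' Classify the tumour-fraction change on the absolute threshold alone
#'
#' Companion single-threshold classifier: `decrease` when `pre - post > abs`,
#' `increase` when `post - pre > abs`, else `stable`. The dual-threshold
#' [classify_tfx_change()] is the canonical grouping; this one reproduces the
#' simpler three-way split by absolute change only.
#'
#' @inheritParams classify_tfx_change
#' @return One of `"decrease"`, `"stable"`, `"increase"`.
#' @export
classify_tfx_change_abs <- function(pre, post, abs = 0.03) {
  d <- post - pre
  if (d > abs) "increase" else if (-d > abs) "decrease" else "stable"
}

#' Is a tumour fraction detectable?
#'
#' Applies the detectability cut-off of 0.016245 (the ROC-derived threshold
#' separating cancer from non-cancer plasma); the boundary itself counts as
#' detectable.
#'
#' @param tfx Tumour fraction(s) in `[0, 1)`.
#' @param cutoff Detectability threshold.
#' @return Logical vector.
#' @export
detectable <- function(tfx, cutoff = 0.016245) {
  if (any(tfx < 0 | tfx >= 1)) stop("`tfx` must lie in [0, 1)")
  tfx >= cutoff
}

#' mRECIST response category from viable-lesion diameter sums
#'
#' `CR` requires disappearance of all target lesions; `PR` at least a 30%
#' decrease of the diameter sum; `PD` a minimum 20% increase; `SD` lies
#' between PR and PD. Both percentage thresholds are inclusive.
#'
#' @param baseline_sum,followup_sum Sums of viable target lesion diameters.
#' @param all_lesions_gone Logical: complete disappearance of target lesions.
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
mrecist_category <- function(baseline_sum, followup_sum,
                             all_lesions_gone = FALSE) {
  if (baseline_sum < 0 || followup_sum < 0) stop("diameter sums must be >= 0")
  if (all_lesions_gone) return("CR")
  if (baseline_sum == 0)
    stop("zero baseline diameter sum without complete response")
  change <- (followup_sum - baseline_sum) / baseline_sum
  if (change >= 0.2) "PD" else if (change <= -0.3) "PR" else "SD"
}

#' Lipiodol deposition rate and group
#'
#' Rate = lipiodol area / whole-tumour area; the `high` deposition group is
#' defined by rate >= `cutoff` (50%), boundary inclusive.
#'
#' @param lipiodol_area,tumour_area Areas (same units); `lipiodol_area` must
#'   not exceed `tumour_area`.
#' @param cutoff Grouping threshold (default 0.5).
#' @return List with `rate` and `group` (`"high"`/`"low"`).
#' @export
lipiodol_group <- function(lipiodol_area, tumour_area, cutoff = 0.5) {
  if (tumour_area <= 0) stop("`tumour_area` must be positive")
  if (lipiodol_area < 0 || lipiodol_area > tumour_area)
    stop("`lipiodol_area` must lie in [0, tumour_area]")
  rate <- lipiodol_area / tumour_area
  list(rate = rate, group = if (rate >= cutoff) "high" else "low")
}

#' Longitudinal tumour-fraction classification over repeated sessions
#'
#' Applies [classify_tfx_change()] to the pre/post pair of every treatment
#' session: a patient is `any-increase` when any session classifies as
#' increase, else `persistent-nonincrease`. The first-session call is also
#' returned for first-session analyses.
#'
#' @param timeline Data.frame with one row per session, columns `pre_tfx`,
#'   `post_tfx` (ordered by session).
#' @param rel,abs Thresholds passed to [classify_tfx_change()].
#' @return List with `class`, `session_calls` (character vector) and
#'   `first_session_call`.
#' @export
longitudinal_class <- function(timeline, rel = 0.5, abs = 0.03) {
  if (nrow(timeline) < 2)
    stop("longitudinal classification needs >= 2 sessions")
  calls <- vapply(seq_len(nrow(timeline)), function(i)
    classify_tfx_change(timeline$pre_tfx[i], timeline$post_tfx[i],
                        rel = rel, abs = abs)$group, "")
  list(class = if (any(calls == "increase")) "any-increase"
       else "persistent-nonincrease",
       session_calls = calls, first_session_call = calls[1])
}

#' Kaplan-Meier medians and log-rank test
#'
#' Product-limit survival per group with the median defined as the smallest
#' time at which the survival curve drops to 0.5 or below (undefined, `NA`,
#' when the curve stays above 0.5), and the k-group log-rank chi-square test.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels (>= 2 distinct values).
#' @return List with `medians` (named), `statistic`, `df`, `p_value`, and the
#'   underlying `survival::survdiff` fit.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("log-rank needs >= 2 groups")
  if (sum(events) < 1) stop("log-rank needs >= 1 event")
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  tab <- summary(sf)$table
  med <- if (is.matrix(tab)) tab[, "median"] else tab["median"]
  names(med) <- sub("^groups=", "", names(med))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(medians = med, statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       survdiff = sd)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling; hazard ratio with Wald
#' 95% confidence interval and p-value. Monotone-likelihood (perfect
#' separation) is reported through the `separation` flag rather than an
#' error.
#'
#' @param times,events Survival outcome.
#' @param covariate Numeric or two-level covariate.
#' @return List with `hr`, `ci_lower`, `ci_upper`, `p_value`, `beta`, `se`,
#'   `separation`, and the `coxph` fit.
#' @export
cox_univariate <- function(times, events, covariate) {
  if (length(unique(covariate)) < 2)
    stop("covariate must take >= 2 distinct values")
  if (sum(events) < 1) stop("Cox regression needs >= 1 event")
  if (is.character(covariate)) covariate <- as.factor(covariate)
  fit <- survival::coxph(survival::Surv(times, events) ~ covariate,
                         ties = "breslow")
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  separation <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 100
  z <- beta / se
  list(hr = exp(beta), ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se),
       p_value = 2 * stats::pnorm(-abs(z)), beta = beta, se = se,
       separation = separation, fit = fit)
}

#' ROC curve with Youden-optimal cut-off
#'
#' Empirical ROC over all score thresholds, trapezoidal AUC, and the cut-off
#' maximizing Youden's J (sensitivity + specificity - 1).
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (0/1, logical, or two-level factor).
#' @return List with `auc`, `cutoff`, `sensitivity`, `specificity`, and the
#'   `pROC::roc` object.
#' @export
roc_youden <- function(scores, labels) {
  labels <- as.integer(as.factor(labels)) - 1L
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]  # first optimum on exact ties
  list(auc = as.numeric(pROC::auc(r)), cutoff = best$threshold,
       sensitivity = best$sensitivity, specificity = best$specificity,
       roc = r)
}

# sample cross-product odds ratio of a 2x2 table (NA otherwise)
.sample_or <- function(tab) {
  if (!all(dim(tab) == 2)) return(NA_real_)
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Association tests used across the cohort analyses
#'
#' One entry point for the standard battery: `chisq` (Pearson chi-square on a
#' contingency table, falling back to Fisher's exact test automatically when
#' any expected cell is below 5), `fisher`, `pearson` correlation, `ttest`
#' (Student's two-sample t-test, equal variances), and `logistic`
#' (binary-outcome logistic regression via iteratively reweighted least
#' squares, possibly multivariable).
#'
#' @param kind One of `"chisq"`, `"fisher"`, `"pearson"`, `"ttest"`,
#'   `"logistic"`.
#' @param x For `chisq`/`fisher`: a contingency table (matrix) or a factor;
#'   for `pearson`/`ttest`: a numeric vector; for `logistic`: a data.frame of
#'   predictors (or numeric vector).
#' @param y Second factor (`chisq`/`fisher` when `x` is a factor), second
#'   numeric vector (`pearson`), group labels (`ttest`), or binary outcome
#'   (`logistic`).
#' @return List with `kind`, `statistic`, `effect`, `p_value`, plus
#'   kind-specific fields: `method`, the sample cross-product `odds_ratio`
#'   for 2x2 tables, logistic `coefficients` and `converged`.
#' @export
association_tests <- function(x, y = NULL,
                              kind = c("chisq", "fisher", "pearson",
                                       "ttest", "logistic")) {
  kind <- match.arg(kind)
  switch(kind,
    chisq = {
      tab <- if (is.matrix(x) || is.table(x)) as.table(as.matrix(x)) else
        table(x, y)
      if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate contingency table")
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(tab)
        list(kind = "chisq", method = "fisher",
             statistic = NA_real_,
             effect = if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_,
             odds_ratio = .sample_or(tab), p_value = ft$p.value)
      } else {
        ct <- stats::chisq.test(tab, correct = FALSE)
        list(kind = "chisq", method = "pearson",
             statistic = unname(ct$statistic), effect = NA_real_,
             odds_ratio = .sample_or(tab), p_value = ct$p.value)
      }
    },
    fisher = {
      tab <- if (is.matrix(x) || is.table(x)) as.table(as.matrix(x)) else
        table(x, y)
      ft <- stats::fisher.test(tab)
      list(kind = "fisher", statistic = NA_real_,
           effect = if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_,
           odds_ratio = .sample_or(tab), p_value = ft$p.value)
    },
    pearson = {
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("constant vector: correlation undefined")
      ct <- stats::cor.test(x, y, method = "pearson")
      list(kind = "pearson", statistic = unname(ct$statistic),
           effect = unname(ct$estimate), p_value = ct$p.value)
    },
    ttest = {
      g <- as.factor(y)
      if (nlevels(droplevels(g)) != 2) stop("t-test needs exactly 2 groups")
      tt <- stats::t.test(x ~ g, var.equal = TRUE)
      list(kind = "ttest", statistic = unname(tt$statistic),
           effect = unname(diff(rev(tt$estimate))), p_value = tt$p.value)
    },
    logistic = {
      yy <- if (is.logical(y)) as.integer(y) else y
      if (!all(yy %in% c(0, 1))) stop("logistic outcome must be binary")
      dat <- data.frame(.y = yy, x)
      fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
      cf <- summary(fit)$coefficients
      list(kind = "logistic", statistic = unname(cf[-1, "z value"]),
           effect = exp(unname(cf[-1, "Estimate"])),
           p_value = unname(cf[-1, "Pr(>|z|)"]),
           coefficients = cf, converged = fit$converged)
    })
}
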