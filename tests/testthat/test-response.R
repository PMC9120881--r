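test_that("TFx-change classification applies both thresholds strictly", {
  expect_equal(classify_tfx_change(0.20, 0.05)$group, "decline")
  expect_equal(classify_tfx_change(0.10, 0.08)$group, "stable")
  expect_equal(classify_tfx_change(0.02, 0.06)$group, "increase")
  # absolute change of exactly 0.03 fails the strict rule
  expect_equal(classify_tfx_change(0.06, 0.03)$group, "stable")
  # relative change of exactly 50% fails the strict rule
  expect_equal(classify_tfx_change(0.20, 0.10)$group, "stable")

  # pre = 0 conventions: relative change infinite, absolute decides
  z <- classify_tfx_change(0, 0.05)
  expect_equal(z$group, "increase")
  expect_false(z$relative_defined)
  expect_equal(classify_tfx_change(0, 0.02)$group, "stable")
  expect_equal(classify_tfx_change(0, 0)$group, "stable")
  expect_error(classify_tfx_change(1, 0.5), "\\[0, 1\\)")

  # absolute-only companion classifier
  expect_equal(classify_tfx_change_abs(0.10, 0.05), "decrease")
  expect_equal(classify_tfx_change_abs(0.10, 0.12), "stable")
  expect_equal(classify_tfx_change_abs(0.10, 0.14), "increase")
})

test_that("detectability respects the ROC cut-off with >= at the boundary", {
  expect_true(detectable(0.02))
  expect_false(detectable(0))
  expect_true(detectable(0.016245))
  expect_false(detectable(0.016244))
  expect_error(detectable(-0.1), "\\[0, 1\\)")
})

test_that("mRECIST categories follow the diameter-sum rules", {
  expect_equal(mrecist_category(10, 0, all_lesions_gone = TRUE), "CR")
  expect_equal(mrecist_category(10, 6.9), "PR")
  expect_equal(mrecist_category(10, 12.1), "PD")
  expect_equal(mrecist_category(10, 8.5), "SD")
  # inclusive thresholds: exactly -30% is PR, exactly +20% is PD
  expect_equal(mrecist_category(10, 7), "PR")
  expect_equal(mrecist_category(10, 12), "PD")
  expect_error(mrecist_category(0, 1), "zero baseline")
  expect_error(mrecist_category(-1, 1), ">= 0")
})

test_that("lipiodol grouping splits at 50% deposition inclusive", {
  expect_equal(lipiodol_group(5, 10), list(rate = 0.5, group = "high"))
  expect_equal(lipiodol_group(2, 10), list(rate = 0.2, group = "low"))
  expect_equal(lipiodol_group(10, 10), list(rate = 1, group = "high"))
  expect_error(lipiodol_group(1, 0), "positive")
  expect_error(lipiodol_group(11, 10), "tumour_area")
})

test_that("longitudinal classification flags any increasing session", {
  tl <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(pre_tfx = m[, 1], post_tfx = m[, 2])
  }
  a <- longitudinal_class(tl(0.3, 0.1, 0.1, 0.11, 0.1, 0.1))
  expect_equal(a$class, "persistent-nonincrease")
  expect_equal(a$session_calls, c("decline", "stable", "stable"))
  expect_equal(a$first_session_call, "decline")

  b <- longitudinal_class(tl(0.1, 0.1, 0.05, 0.2))
  expect_equal(b$class, "any-increase")
  expect_equal(b$first_session_call,
               classify_tfx_change(0.1, 0.1)$group)
  expect_error(longitudinal_class(tl(0.1, 0.1)), ">= 2 sessions")
})

test_that("log-rank matches hand computation and is zero under symmetry", {
  # identical survival experience in both groups
  sym <- km_logrank(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  # 6 subjects, times 1..6 all events, groups AAABBB: accumulate
  # observed-expected and hypergeometric variance by hand
  times <- 1:6; groups <- rep(c("A", "B"), each = 3)
  atrisk_A <- c(3, 2, 1, 0, 0, 0); atrisk_B <- c(3, 3, 3, 3, 2, 1)
  n <- atrisk_A + atrisk_B
  expected_A <- atrisk_A / n           # one death at each time
  var_A <- atrisk_A * atrisk_B / n^2
  observed_A <- c(1, 1, 1, 0, 0, 0)
  oracle <- sum(observed_A - expected_A)^2 / sum(var_A)
  got <- km_logrank(times, rep(1, 6), groups)
  expect_lt(abs(got$statistic - oracle), 1e-6)
  expect_equal(got$df, 1)

  # product-limit medians: first time survival drops to <= 0.5
  expect_equal(unname(got$medians["A"]), 2)
  expect_equal(unname(got$medians["B"]), 5)

  expect_error(km_logrank(1:3, c(1, 1, 1), rep("A", 3)), ">= 2 groups")
  expect_error(km_logrank(1:4, rep(0, 4), rep(c("A", "B"), 2)), "event")
})

test_that("Cox regression matches a brute-force partial-likelihood oracle", {
  set.seed(11)
  times <- c(3, 5, 6, 8, 10, 12, 15, 18, 21, 25)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  # Breslow partial log-likelihood, maximized directly
  pll <- function(beta) {
    sum(vapply(which(events == 1), function(i) {
      at_risk <- times >= times[i]
      beta * x[i] - log(sum(exp(beta * x[at_risk])))
    }, 0))
  }
  oracle <- stats::optimize(pll, c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  fit <- cox_univariate(times, events, x)
  expect_lt(abs(fit$beta - oracle), 1e-4)
  expect_false(fit$separation)

  # negated covariate gives the reciprocal hazard ratio
  fit_neg <- cox_univariate(times, events, 1 - x)
  expect_equal(fit$hr, 1 / fit_neg$hr, tolerance = 1e-8)

  # perfect separation is flagged, not thrown
  sep <- suppressWarnings(cox_univariate(c(1, 2, 3, 10, 11, 12),
                                         rep(1, 6), c(1, 1, 1, 0, 0, 0)))
  expect_true(sep$separation)
  expect_error(cox_univariate(1:4, rep(1, 4), rep(1, 4)), "distinct")
})

test_that("ROC analysis matches the Mann-Whitney identity and Youden rule", {
  perfect <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  scores <- c(0.1, 0.4, 0.35, 0.8, 0.45, 0.6, 0.2, 0.7)
  labels <- c(0, 0, 1, 1, 0, 1, 0, 1)
  r <- roc_youden(scores, labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- sum(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b))) / (length(pos) * length(neg))
  expect_equal(r$auc, conc)
  # Youden cut-off maximizes sensitivity + specificity - 1 over thresholds
  j <- sapply(sort(unique(scores)), function(th)
    mean(pos >= th) + mean(neg < th) - 1)
  expect_equal(r$sensitivity + r$specificity - 1, max(j))

  # labels independent of scores give chance-level AUC on average
  set.seed(5)
  aucs <- replicate(40, {
    roc_youden(scores, sample(labels))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  expect_error(roc_youden(scores, rep(1, 8)), "both classes")
})

test_that("association tests cover the cohort battery", {
  # symmetric 2x2 table: independence
  sym <- association_tests(matrix(c(10, 10, 10, 10), 2), kind = "chisq")
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$method, "pearson")

  # sample cross-product odds ratio: (12*9)/(2*3) = 18
  or <- association_tests(matrix(c(12, 3, 2, 9), 2), kind = "fisher")
  expect_equal(or$odds_ratio, 18)

  # automatic Fisher fallback when an expected cell drops below 5
  small <- association_tests(matrix(c(2, 1, 1, 8), 2), kind = "chisq")
  expect_equal(small$method, "fisher")
  exact <- stats::fisher.test(matrix(c(2, 1, 1, 8), 2))
  expect_equal(small$p_value, exact$p.value)

  # exact linearity
  x <- 1:20
  pe <- association_tests(x, 2 * x, kind = "pearson")
  expect_equal(pe$effect, 1)
  expect_error(association_tests(rep(1, 5), 1:5, kind = "pearson"),
               "constant")

  # Student's t with equal variances
  tt <- association_tests(c(1, 2, 3, 7, 8, 9),
                          rep(c("a", "b"), each = 3), kind = "ttest")
  ref <- stats::t.test(c(1, 2, 3), c(7, 8, 9), var.equal = TRUE)
  expect_equal(tt$p_value, ref$p.value)
  expect_error(association_tests(1:6, rep("a", 6), kind = "ttest"),
               "2 groups")

  # logistic regression recovers a strong positive effect
  set.seed(2)
  z <- stats::rnorm(200)
  y <- stats::rbinom(200, 1, stats::plogis(1.5 * z))
  lg <- association_tests(data.frame(z = z), y, kind = "logistic")
  expect_true(lg$converged)
  expect_gt(lg$effect, 1)   # odds ratio above 1
  expect_lt(lg$p_value, 1e-6)
  expect_error(association_tests(data.frame(z = z), z, kind = "logistic"),
               "binary")
})

test_that("cohort response analysis assembles classifications and tests", {
  cfg <- cohort_config(n_controls = 2, n_patients = 40, seed = 301)
  co <- simulate_cohort(cfg, counts = FALSE)
  tfx_table <- do.call(rbind, lapply(seq_along(co$tfx_trajectories),
    function(i) data.frame(patient_id = sprintf("P%02d", i),
                           session = co$tfx_trajectories[[i]]$session,
                           pre_tfx = co$tfx_trajectories[[i]]$pre_tfx,
                           post_tfx = co$tfx_trajectories[[i]]$post_tfx)))
  cl <- co$clinical
  cl$amplified_mb <- cl$amplified_mb_true
  res <- analyze_cohort_response(tfx_table, cl, co$outcomes)
  expect_equal(nrow(res$patients), 40)
  expect_equal(sum(res$stats$group_counts), 40)
  expect_identical(res$patients$change_group, co$clinical$change_group)
  expect_true(all(c("km_pfs_change", "cox_pfs_increase",
                    "fisher_pd_increase", "pearson_tfx_size",
                    "ttest_amp_lipiodol") %in% names(res$stats)))
  # simulated concordance: TFx correlates with tumour size
  expect_lt(res$stats$pearson_tfx_size$p_value, 0.05)
})
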