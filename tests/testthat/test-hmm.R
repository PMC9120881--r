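test_that("expected log2 ratio follows the mixture formula", {
  expect_equal(expected_log_ratio(2, 0.7, 2), 0)
  expect_equal(expected_log_ratio(5, 0, 2), 0)
  expect_equal(expected_log_ratio(3, 0.5, 2), log2(2.5 / 2))
  expect_equal(expected_log_ratio(0, 0.5, 2), log2(1 / 2))
  # normalization by average copy content: c = phi maps to zero
  expect_equal(expected_log_ratio(3, 0.4, 3), 0)
  expect_error(expected_log_ratio(-1, 0.1, 2), ">= 0")
  expect_error(expected_log_ratio(2, 1, 2), "\\[0, 1\\)")
  expect_error(expected_log_ratio(2, 0.1, 0), "positive")
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(42)
  cases <- list(
    list(B = 1, max_cn = 2, chroms = "c1"),
    list(B = 6, max_cn = 2, chroms = rep("c1", 6)),
    list(B = 6, max_cn = 3, chroms = rep(c("c1", "c2"), each = 3)),
    list(B = 8, max_cn = 3, chroms = rep("c1", 8)))
  for (cs in cases) {
    for (df in c(4, Inf)) {
      x <- stats::rnorm(cs$B, 0, 0.3)
      p <- hmm_params(max_cn = cs$max_cn, df = df)
      t <- stats::runif(1, 0, 0.6)
      got <- forward_loglik(make_profile(x, cs$chroms), t, 2, 0.25, p)
      want <- brute_force_loglik(x, cs$chroms, t, 2, 0.25, p)
      expect_lt(abs(got - want), 1e-9)
    }
  }
})

test_that("a single bin with equiprobable states gives the mixture density", {
  p <- hmm_params(max_cn = 2, state_prior_decay = 0, df = Inf)
  x <- 0.1
  mu <- expected_log_ratio(0:2, 0.3, 2)
  want <- log(mean(stats::dnorm(x, mu, 0.2)))
  got <- forward_loglik(make_profile(x, "c1"), 0.3, 2, 0.2, p)
  expect_lt(abs(got - want), 1e-12)
})

test_that("masked bins are skipped without breaking chain adjacency", {
  set.seed(7)
  x <- stats::rnorm(6, 0, 0.3)
  p <- hmm_params(max_cn = 3)
  with_gap <- make_profile(c(x[1:3], 99, x[4:6]), rep("c1", 7),
                           masked = c(rep(FALSE, 3), TRUE, rep(FALSE, 3)))
  without <- make_profile(x, rep("c1", 6))
  expect_equal(forward_loglik(with_gap, 0.2, 2, 0.25, p),
               forward_loglik(without, 0.2, 2, 0.25, p))
  expect_error(forward_loglik(make_profile(numeric(0), character(0)),
                              0.2, 2, 0.25, p), "usable")
})

test_that("EM is monotone, posteriors normalized, and fits deterministic", {
  prof <- toy_profile(0.4, toy_gain_truth(), seed = 55)
  fit <- fit_em(prof, toy_params())
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-12))
  expect_true(fit$converged)

  fit2 <- fit_em(prof, toy_params())
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$segments, fit2$segments)
})

test_that("a flat diploid profile collapses to the tumour-free fit", {
  prof <- toy_profile(0, seed = 60)
  fit <- fit_em(prof, toy_params())
  expect_lte(fit$tfx, 0.03)
  expect_true(all(fit$states == 2L))
  segs <- fit$segments
  expect_equal(nrow(segs), length(unique(prof$chrom)))
  expect_true(all(segs$call == "neutral"))
})

test_that("a whole-arm gain at tfx 0.4 is recovered with its segments", {
  prof <- toy_profile(0.4, toy_gain_truth(), seed = 70)
  fit <- fit_em(prof, toy_params())
  expect_lt(abs(fit$tfx - 0.4), 0.05)

  copy <- truth_copy_per_bin(toy_gain_truth(), toy_layout())
  gained_bins <- which(copy[fit$usable] == 3)
  expect_gte(mean(fit$states[gained_bins] == 3), 0.9)

  # segment bin counts partition the usable bins
  expect_equal(sum(fit$segments$n_bins), sum(fit$usable))
  # segments are ordered and non-overlapping within chromosomes
  for (ch in unique(fit$segments$chrom)) {
    s <- fit$segments[fit$segments$chrom == ch, ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("model methods expose the fit consistently", {
  prof <- toy_profile(0.4, toy_gain_truth(), seed = 70)
  fit <- fit_em(prof, toy_params())
  cf <- coef(fit)
  expect_named(cf, c("tumour_fraction", "ploidy", "sigma"))
  expect_equal(unname(cf["tumour_fraction"]), fit$tfx)
  r <- residuals(fit)
  f <- fitted(fit)
  expect_equal(r + f, prof$log2ratio)
  s <- summary(fit)
  expect_s3_class(s, "summary.tfx_fit")
  expect_output(print(fit), "tumour fraction")
})

test_that("the two-pass rule triggers only below the 5% threshold", {
  prof_hi <- toy_profile(0.30, toy_gain_truth(), seed = 81)
  fit_hi <- estimate_tumor_fraction(prof_hi, toy_params(),
                                    hmm_params_low_tfx())
  expect_equal(fit_hi$pass_index, 1L)
  expect_gte(fit_hi$tfx, 0.05)

  prof_lo <- toy_profile(0.02, toy_gain_truth(), seed = 82)
  fit_lo <- estimate_tumor_fraction(prof_lo, toy_params(),
                                    hmm_params_low_tfx())
  expect_equal(fit_lo$pass_index, 2L)
  expect_false(is.null(fit_lo$pass1))
  expect_lt(fit_lo$pass1$tfx, 0.05)
  # pass-2 parameter restrictions are in force
  expect_equal(fit_lo$params$max_cn, 3L)
  expect_equal(fit_lo$params$ploidy, 2)
})
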