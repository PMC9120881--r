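test_that("forced and empty event menus give the expected truths", {
  layout <- make_layout()
  menu <- data.frame(arm = "1q", type = "gain", prob = 1)
  tr <- simulate_truth(layout, menu, seed = 3)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$chrom, "chr1")
  expect_equal(tr$start, 125e6)
  expect_equal(tr$end, 249250621)
  expect_equal(tr$copy, 3L)

  flat <- simulate_truth(layout, menu[0, ], seed = 3)
  expect_equal(nrow(flat), 0)
  expect_true(all(truth_copy_per_bin(flat, layout) == 2L))

  expect_error(simulate_truth(layout, data.frame(arm = "1q", type = "gain",
                                                 prob = 1.2)), "\\[0, 1\\]")
  expect_error(simulate_truth(layout, data.frame(arm = "99z", type = "gain",
                                                 prob = 0.5)), "absent")
})

test_that("arm event frequencies match the menu probabilities over a cohort", {
  layout <- make_layout()
  menu <- default_event_menu()
  draws <- sapply(1:200, function(i) {
    tr <- simulate_truth(layout, menu, seed = i)
    arms <- arm_table(layout)
    vapply(seq_len(nrow(menu)), function(k) {
      a <- arms[arms$arm == menu$arm[k], ]
      want <- if (menu$type[k] == "gain") 3L else 1L
      any(tr$chrom == a$chrom & tr$start == a$start & tr$copy == want)
    }, TRUE)
  })
  freq <- rowMeans(draws)
  half_width <- 4 * sqrt(menu$prob * (1 - menu$prob) / 200)
  expect_true(all(abs(freq - menu$prob) < half_width))
})

test_that("the count model reproduces the tumour/normal mixture means", {
  layout <- toy_layout()
  flat_ann <- data.frame(gc = rep(0.45, nrow(layout$bins)),
                         mappability = rep(1, nrow(layout$bins)))
  truth <- toy_gain_truth()
  # tfx = 0: counts do not depend on the truth at all
  c0a <- simulate_sample_counts(truth, 0, layout, flat_ann, depth = 100,
                                seed = 5, sample_id = "x")
  c0b <- simulate_sample_counts(truth[0, ], 0, layout, flat_ann, depth = 100,
                                seed = 5, sample_id = "x")
  expect_identical(as.integer(c0a), as.integer(c0b))

  # tfx = 0.4, whole-arm gain: mean ratio (0.6*2 + 0.4*3)/2 = 1.2
  cnt <- simulate_sample_counts(truth, 0.4, layout, flat_ann, depth = 10000,
                                dispersion = 0, seed = 8, sample_id = "x")
  copy <- truth_copy_per_bin(truth, layout)
  ratio <- mean(cnt[copy == 3]) / mean(cnt[copy == 2])
  expect_lt(abs(ratio - 1.2), 0.005)

  expect_error(simulate_sample_counts(truth, 1, layout, flat_ann),
               "\\[0, 1\\)")
  expect_error(simulate_sample_counts(truth, -0.1, layout, flat_ann),
               "\\[0, 1\\)")
})

test_that("mean bin ratios are monotone in copy number and tumour fraction", {
  layout <- toy_layout()
  flat_ann <- data.frame(gc = rep(0.45, nrow(layout$bins)),
                         mappability = rep(1, nrow(layout$bins)))
  mk <- function(copy) structure(
    data.frame(chrom = "chrA", start = 25e6, end = 60e6, copy = copy),
    class = c("cn_truth", "data.frame"))
  mean_ratio <- function(copy, tfx) {
    cnt <- simulate_sample_counts(mk(copy), tfx, layout, flat_ann,
                                  depth = 2000, dispersion = 0.002,
                                  seed = 31, sample_id = "m")
    cpb <- truth_copy_per_bin(mk(copy), layout)
    mean(cnt[cpb == copy]) / mean(cnt[cpb == 2])
  }
  by_copy <- sapply(c(0L, 1L, 3L, 4L), mean_ratio, tfx = 0.5)
  expect_true(all(diff(by_copy) > 0))
  by_tfx <- sapply(c(0.1, 0.3, 0.6), function(t) mean_ratio(3L, t))
  expect_true(all(diff(by_tfx) > 0))
})

test_that("at tfx = 0 bins inside and outside truth segments are exchangeable", {
  layout <- toy_layout()
  ann <- toy_annotation()
  truth <- toy_gain_truth()
  flat_ann <- data.frame(gc = rep(0.45, nrow(layout$bins)),
                         mappability = rep(1, nrow(layout$bins)))
  cnt <- simulate_sample_counts(truth, 0, layout, flat_ann, depth = 200,
                                seed = 17, sample_id = "ks")
  copy <- truth_copy_per_bin(truth, layout)
  ks <- suppressWarnings(stats::ks.test(cnt[copy == 3], cnt[copy == 2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort simulation is reproducible and carries provenance", {
  cfg <- cohort_config(n_controls = 4, n_patients = 6, seed = 77)
  a <- simulate_cohort(cfg, counts = TRUE)
  b <- simulate_cohort(cfg, counts = TRUE)
  expect_identical(a$counts, b$counts)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$outcomes, b$outcomes)

  expect_true(all(a$samples$seed == 77))
  expect_true(all(a$clinical$seed == 77))
  expect_true(all(a$samples$true_tfx >= 0 & a$samples$true_tfx < 1))
  expect_equal(length(a$truth), 6)

  # change groups recorded in the clinical table agree with the classifier
  # applied to the true TFx trajectory (ground-truth consistency)
  for (i in seq_len(6)) {
    tr <- a$tfx_trajectories[[i]]
    expect_identical(a$clinical$change_group[i],
                     classify_tfx_change(tr$pre_tfx[1], tr$post_tfx[1])$group)
  }
})

test_that("timeline designs produce pre/post/follow-up sampling", {
  cfg <- cohort_config(n_controls = 2, n_patients = 3, seed = 9,
                       timeline_design = list(n_sessions = 2L,
                                              session_gap_days = 120L,
                                              post_day = 35L,
                                              followup_day = 90L))
  co <- simulate_cohort(cfg, counts = FALSE)
  per <- split(co$samples[co$samples$role == "patient", ],
               co$samples$patient_id[co$samples$role == "patient"])
  for (d in per) {
    expect_gte(nrow(d), 3)
    expect_true(all(c("pre", "post", "follow-up") %in% d$phase))
    expect_true(all(diff(d$day) > 0))
  }
  expect_error(cohort_config(n_controls = 2, n_patients = 2),
               "seed")
})
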