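test_that("the PSP rule encodes the published cutoffs", {
  r <- psp_rule()
  expect_s3_class(r, "combined_rule")
  expect_length(r$components, 2)
  feats <- vapply(r$components, `[[`, character(1), "feature")
  expect_setequal(feats, c("ratio_onl_opl", "mean_inl"))
  ratio_comp <- r$components[[which(feats == "ratio_onl_opl")]]
  inl_comp <- r$components[[which(feats == "mean_inl")]]
  expect_equal(ratio_comp$cutoff, 3.1)
  expect_identical(ratio_comp$direction, "below")
  expect_equal(inl_comp$cutoff, 46)
  expect_identical(inl_comp$direction, "below")
  expect_true(ratio_comp$strict && inl_comp$strict)
})

test_that("the PSP rule classifies the published group means", {
  # group-mean subjects: PSP ratio 93.92/38.21 = 2.458, INL 39.38 -> positive
  # PD ratio 105.8/33.74 = 3.136, INL 46.8 -> negative on both components
  rows <- data.frame(
    subject_id = c("psp-mean", "pd-mean"),
    group = c("PSP", "PD"),
    ratio_onl_opl = c(93.92 / 38.21, 105.8 / 33.74),
    mean_inl = c(39.38, 46.8),
    stringsAsFactors = FALSE
  )
  res <- apply_rule(psp_rule(), rows)
  expect_identical(res, c(TRUE, FALSE))
  # PD fails each component on its own
  expect_false(apply_rule(threshold_rule("ratio_onl_opl", "below", 3.1),
                          rows[2, ]))
  expect_false(apply_rule(threshold_rule("mean_inl", "below", 46), rows[2, ]))
})

test_that("threshold comparisons are strict at the boundary", {
  rows <- data.frame(ratio_onl_opl = c(3.1, 3.0999), mean_inl = c(46, 45.99))
  expect_identical(apply_rule(psp_rule(), rows), c(FALSE, TRUE))
  # non-strict variant includes the boundary
  r <- threshold_rule("mean_inl", "below", 46, strict = FALSE)
  expect_true(apply_rule(r, rows[1, ]))
})

test_that("rule application propagates missingness and rejects unknown
          features", {
  rows <- data.frame(x = c(4, NA, 6), y = c(1, 1, NA))
  r1 <- threshold_rule("x", "below", 5)
  expect_identical(apply_rule(r1, rows), c(TRUE, NA, FALSE))
  r2 <- combined_rule(threshold_rule("x", "below", 7),
                      threshold_rule("y", "below", 2))
  expect_identical(apply_rule(r2, rows), c(TRUE, NA, NA))
  expect_error(apply_rule(threshold_rule("zz", "below", 1), rows),
               "unknown feature")
  # conjunction semantics: one failing component decides
  rows2 <- data.frame(ratio_onl_opl = 2.5, mean_inl = 47)
  expect_false(apply_rule(psp_rule(), rows2))
})

test_that("confusion counts match a hand count and log exclusions", {
  ft <- data.frame(
    subject_id = sprintf("s%d", 1:5),
    group = c("PSP", "PSP", "PSP", "PD", "PD"),
    x = c(1, 2, 3, 10, 12),
    stringsAsFactors = FALSE
  )
  cf <- rule_confusion(threshold_rule("x", "below", 5), ft, "PSP", "PD")
  expect_identical(cf$tp, 3L)
  expect_identical(cf$fn, 0L)
  expect_identical(cf$tn, 2L)
  expect_identical(cf$fp, 0L)

  # always-positive rule: sensitivity 1, specificity 0
  cf2 <- rule_confusion(threshold_rule("x", "below", 1e6), ft, "PSP", "PD")
  m2 <- diagnostic_metrics(cf2)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)

  # a missing positive-class feature value is excluded from the 2x2
  ft$x[1] <- NA
  cf3 <- rule_confusion(threshold_rule("x", "below", 5), ft, "PSP", "PD")
  expect_identical(cf3$tp + cf3$fn, 2L)
  expect_identical(cf3$excluded$subject_id, "s1")

  ft$group <- "PD"
  expect_error(rule_confusion(threshold_rule("x", "below", 5), ft,
                              "PSP", "PD"), "positive class")
})

test_that("metrics implement the likelihood-ratio formulas and rounding", {
  # sensitivity 0.96, specificity 0.70 -> LR- = 0.04/0.70 -> printed 0.06
  m <- diagnostic_metrics(list(tp = 96, fn = 4, fp = 30, tn = 70))
  expect_equal(m$sensitivity, 0.96)
  expect_equal(m$specificity, 0.70)
  expect_equal(m$lr_neg, 0.04 / 0.70)
  expect_equal(m$lr_neg_rounded, 0.06)
  expect_equal(m$lr_pos, 0.96 / 0.30)

  # specificity 0.59 -> LR- = 0.04/0.59 -> printed 0.07
  m2 <- diagnostic_metrics(list(tp = 96, fn = 4, fp = 41, tn = 59))
  expect_equal(m2$lr_neg_rounded, 0.07)

  # perfect sensitivity: LR- = 0
  m3 <- diagnostic_metrics(list(tp = 10, fn = 0, fp = 3, tn = 7))
  expect_equal(m3$lr_neg, 0)

  # boundary specificities are flagged, not infinite/NaN by accident
  m4 <- diagnostic_metrics(list(tp = 9, fn = 1, fp = 0, tn = 10))
  expect_identical(m4$lr_pos, Inf)
  expect_match(m4$flags, "lr_pos infinite", all = FALSE)
  m5 <- diagnostic_metrics(list(tp = 9, fn = 1, fp = 10, tn = 0))
  expect_true(is.na(m5$lr_neg))
  expect_match(m5$flags, "lr_neg undefined", all = FALSE)

  expect_error(diagnostic_metrics(list(tp = 0, fn = 0, fp = 1, tn = 1)),
               "tp\\+fn")
})

test_that("likelihood-ratio bands follow the published cut-points", {
  expect_identical(lr_band(3.4, 0.06),
                   c(band_pos = "fair", band_neg = "good"))
  expect_identical(lr_band(100, 0.04),
                   c(band_pos = "excellent", band_neg = "excellent"))
  expect_identical(lr_band(2.4, 0.07),
                   c(band_pos = "fair", band_neg = "good"))
  expect_identical(lr_band(1.5, 0.5),
                   c(band_pos = "none", band_neg = "none"))
  # band-edge conventions: LR+ half-open [lower, upper); LR- as documented
  expect_identical(lr_band(10, 0.05)[["band_pos"]], "good")
  expect_identical(lr_band(50, 0.1)[["band_pos"]], "excellent")
  expect_identical(lr_band(2, 0.3)[["band_pos"]], "fair")
  expect_identical(lr_band(10, 0.05)[["band_neg"]], "good")
  expect_identical(lr_band(10, 0.1)[["band_neg"]], "fair")
  expect_identical(lr_band(10, 0.3)[["band_neg"]], "fair")
  expect_identical(lr_band(Inf, 0)[["band_pos"]], "excellent")
})

test_that("metrics are invariant to row order and dataset duplication", {
  set.seed(31)
  ft <- data.frame(
    subject_id = sprintf("s%d", 1:40),
    group = rep(c("PSP", "PD"), each = 20),
    x = c(stats::rnorm(20, 2), stats::rnorm(20, 4)),
    stringsAsFactors = FALSE
  )
  r <- threshold_rule("x", "below", 3)
  m1 <- diagnostic_metrics(rule_confusion(r, ft, "PSP", "PD"))
  m2 <- diagnostic_metrics(rule_confusion(r, ft[sample(40), ], "PSP", "PD"))
  ft2 <- rbind(ft, transform(ft, subject_id = paste0(subject_id, "b")))
  m3 <- diagnostic_metrics(rule_confusion(r, ft2, "PSP", "PD"))
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
  expect_equal(m1$sensitivity, m3$sensitivity)
  expect_equal(m1$specificity, m3$specificity)
  expect_equal(m1$lr_pos, m3$lr_pos)
})

test_that("LR+ rises and LR- falls as sensitivity or specificity improve", {
  grid <- expand.grid(tp = c(5, 8, 9), tn = c(5, 8, 9))
  lrp <- function(tp, tn) {
    m <- diagnostic_metrics(list(tp = tp, fn = 10 - tp, fp = 10 - tn,
                                 tn = tn))
    c(m$lr_pos, m$lr_neg)
  }
  for (tn in c(5, 8)) {
    expect_lt(lrp(5, tn)[1], lrp(9, tn)[1])
    expect_gt(lrp(5, tn)[2], lrp(9, tn)[2])
  }
  for (tp in c(5, 8)) {
    expect_lt(lrp(tp, 5)[1], lrp(tp, 8)[1])
    expect_gt(lrp(tp, 5)[2], lrp(tp, 8)[2])
  }
})

test_that("on a degenerate cohort the PSP rule is fully sensitive vs PD", {
  coh <- simulate_cohort(zero_sd_params(), seed = 13)
  ft <- build_feature_table(coh)
  cf <- rule_confusion(psp_rule(), ft, "PSP", "PD")
  m <- diagnostic_metrics(cf)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1) # PD means fail both components
})

test_that("rules serialize to JSON and back", {
  path <- withr::local_tempfile(fileext = ".json")
  write_rule(psp_rule(), path)
  back <- read_rule(path)
  expect_equal(back, psp_rule())
})
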