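test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(21)
  v <- c(stats::rnorm(12, 10), stats::rnorm(15, 11))
  g <- rep(c("A", "B"), c(12, 15))
  a <- anova_oneway(v, g)
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  expect_equal(a$f_statistic, unname(tt$statistic)^2)
  expect_equal(a$p_value, tt$p.value)
})

test_that("ANOVA rejects degenerate or underpopulated input", {
  expect_error(anova_oneway(rep(5, 10), rep(c("A", "B"), 5)), "degenerate")
  expect_error(anova_oneway(stats::rnorm(5), rep("A", 5)), "2 groups")
  expect_error(anova_oneway(c(1, 2, 3), c("A", "A", "B")),
               "at least 2 observations")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(22)
  pvals <- replicate(1000, {
    anova_oneway(stats::rnorm(50), rep(group_labels(), each = 10))$p_value
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Dunnett with one treatment group reduces to the pooled t-test", {
  set.seed(23)
  v <- c(stats::rnorm(10, 0), stats::rnorm(14, 0.8))
  g <- rep(c("Control", "PD"), c(10, 14))
  dn <- dunnett_vs_control(v, g)
  tt <- stats::t.test(v ~ factor(g, c("Control", "PD")), var.equal = TRUE)
  expect_identical(nrow(dn), 1L)
  expect_equal(dn$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_equal(dn$estimate, -unname(diff(rev(tt$estimate))), tolerance = 1e-9)
})

test_that("Dunnett adjusted p matches an independent multivariate-t
          simulation", {
  set.seed(24)
  k <- 4; n <- 20
  v <- stats::rnorm(n * (k + 1))
  v[1:n] <- v[1:n] + 0.6 # shift one treatment group
  g <- rep(c("T1", "Control", "T2", "T3", "T4"), each = n)
  dn <- dunnett_vs_control(v, g)

  # oracle: draw max |T| from the balanced Dunnett multivariate t
  # (correlation 0.5, df = N - k - 1) by direct simulation
  df <- n * (k + 1) - (k + 1)
  B <- 200000
  g0 <- stats::rnorm(B)
  z <- matrix(stats::rnorm(B * k), B, k)
  s <- sqrt(stats::rchisq(B, df) / df)
  maxt <- apply(abs(sqrt(0.5) * g0 + sqrt(0.5) * z) / s, 1, max)
  for (i in seq_len(nrow(dn))) {
    p_mc <- mean(maxt > abs(dn$t_statistic[i]))
    expect_lt(abs(p_mc - dn$p_adjusted[i]), 0.01)
  }
})

test_that("post-hoc adjustment is never anti-conservative", {
  set.seed(25)
  v <- stats::rnorm(60)
  g <- rep(c("Control", "PD", "MSA"), each = 20)
  dn <- dunnett_vs_control(v, g)
  tk <- tukey_all_pairs(v, g)
  for (grp in c("PD", "MSA")) {
    sel <- g %in% c("Control", grp)
    p_raw <- stats::t.test(v[sel] ~ droplevels(factor(g[sel])),
                           var.equal = TRUE)$p.value
    expect_gte(dn$p_adjusted[grepl(grp, dn$comparison)] + 1e-12, p_raw)
  }
  # Tukey vs the unadjusted pairwise t on the same pooled error term
  fit <- stats::aov(v ~ factor(g))
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  means <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  for (i in seq_len(nrow(tk))) {
    pair <- strsplit(tk$comparison[i], "-")[[1]]
    tstat <- (means[pair[1]] - means[pair[2]]) /
      sqrt(s2 * (1 / ns[pair[1]] + 1 / ns[pair[2]]))
    p_raw <- 2 * stats::pt(-abs(tstat), fit$df.residual)
    expect_gte(tk$p_adjusted[i] + 1e-12, p_raw)
  }
})

test_that("group order and location shifts do not change the tests", {
  set.seed(26)
  v <- stats::rnorm(45, 100, 10)
  g <- rep(c("Control", "PSP", "PD"), each = 15)
  perm <- sample(length(v))
  a1 <- anova_oneway(v, g)
  a2 <- anova_oneway(v[perm], g[perm])
  expect_equal(a1$f_statistic, a2$f_statistic)
  d1 <- dunnett_vs_control(v, g)
  d2 <- dunnett_vs_control(v[perm], g[perm])
  expect_equal(d1[order(d1$comparison), ]$p_adjusted,
               d2[order(d2$comparison), ]$p_adjusted, tolerance = 1e-6)
  d3 <- dunnett_vs_control(v + 1000, g)
  expect_equal(d1$p_adjusted, d3$p_adjusted, tolerance = 1e-6)
})

test_that("Tukey reduces to the t-test for two groups and separates
          shifted groups", {
  set.seed(27)
  v <- c(stats::rnorm(12, 0), stats::rnorm(12, 1))
  g <- rep(c("A", "B"), each = 12)
  tk <- tukey_all_pairs(v, g)
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  expect_identical(nrow(tk), 1L)
  expect_equal(tk$p_adjusted, tt$p.value, tolerance = 1e-6)

  v5 <- stats::rnorm(50)
  g5 <- rep(group_labels(), each = 10)
  v5[g5 == "PSP"] <- v5[g5 == "PSP"] + 10 * stats::sd(v5)
  tk5 <- tukey_all_pairs(v5, g5)
  psp_pairs <- grepl("PSP", tk5$comparison)
  expect_true(all(tk5$significant[psp_pairs]))
})

test_that("Spearman correlation handles monotone data, ties and small n", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  set.seed(28)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE) # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(spearman_cor(x, y)$rho, spearman_bruteforce(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_cor(c(1, 2), c(3, 4)), "at least 3")
})

test_that("summary table on a degenerate cohort reports the exact inputs
          without flags", {
  coh <- simulate_cohort(zero_sd_params(), seed = 4)
  expect_warning(summary_table(coh, parameters = "onl_central"), "degenerate")
  st <- suppressWarnings(
    summary_table(coh, parameters = c("onl_central", "mt_total"))
  )
  p <- default_params()
  s <- st$summary
  expect_equal(s$PSP_mean[s$parameter == "onl_central"], 93.92)
  expect_equal(s$Control_mean[s$parameter == "mt_total"], 317.6)
  expect_true(all(is.na(s$PSP_significant)))
})

test_that("summary table flags are exactly adjusted p < alpha", {
  coh <- simulate_cohort(default_params(), seed = 6)
  st <- summary_table(coh, parameters = c("mt_total", "mean_inl",
                                          "onl", "ratio_onl_opl"))
  cmp <- st$comparisons
  for (i in seq_len(nrow(cmp))) {
    grp <- sub(" - .*$", "", cmp$comparison[i])
    flag <- st$summary[st$summary$parameter == cmp$parameter[i],
                       paste0(grp, "_significant")]
    expect_identical(unname(unlist(flag)), cmp$p_adjusted[i] < st$alpha)
  }
})

test_that("summary table supports both eye-handling modes", {
  coh <- simulate_cohort(with_group_n(default_params(), 12), seed = 8)
  st_m <- summary_table(coh, parameters = "onl_central")
  st_d <- summary_table(coh, parameters = "onl_central",
                        eye_mode = "duplicates")
  expect_identical(st_m$eye_mode, "subject_means")
  expect_identical(st_d$eye_mode, "duplicates")
  # duplicates mode halves the SEM denominator roughly (2x rows)
  expect_lt(st_d$summary$Control_sem, st_m$summary$Control_sem * 1.05)
})

test_that("control-only cohorts report means but no comparisons", {
  coh <- simulate_cohort(with_group_n(default_params("Control"), 10),
                         seed = 10)
  st <- summary_table(coh, parameters = "onl_central")
  expect_false(is.na(st$summary$Control_mean))
  expect_null(st$comparisons)
})
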