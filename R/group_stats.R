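# Group-comparison machinery: one-way ANOVA, Dunnett many-to-one and Tukey
# all-pairs post-hoc tests at alpha = 0.05, Spearman correlation, and the
# per-parameter summary table with significance flags.
#
# Dunnett adjusted p-values come from the multivariate-t distribution with
# the exact correlation structure implied by the (possibly unbalanced)
# group sizes (multcomp/mvtnorm); Tukey uses the studentized range (stats).

.drop_na_groups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  list(values = values[keep], groups = factor(as.character(groups[keep])))
}

#' One-way fixed-effects analysis of variance
#'
#' Classical one-way ANOVA F test across diagnostic groups.
#'
#' @param values Numeric response (e.g. one layer feature).
#' @param groups Group labels, same length as `values`.
#' @return A list with `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  d <- .drop_na_groups(values, groups)
  if (nlevels(d$groups) < 2) stop("need at least 2 groups")
  if (any(table(d$groups) < 2)) stop("each group needs at least 2 observations")
  if (stats::var(d$values) == 0) {
    stop("degenerate data: zero total variance")
  }
  fit <- stats::lm(values ~ groups, data = d)
  a <- stats::anova(fit)
  list(
    f_statistic = a[1, "F value"], p_value = a[1, "Pr(>F)"],
    df_between = a[1, "Df"], df_within = a[2, "Df"]
  )
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Compares every non-control group mean to the control group mean with
#' family-wise error controlled at `alpha`, using the multivariate-t
#' reference distribution with the exact correlation structure implied by
#' the observed (possibly unbalanced) group sizes.
#'
#' @param values Numeric response.
#' @param groups Group labels, same length as `values`.
#' @param control Label of the reference group (default `"Control"`).
#' @param alpha Family-wise significance level.
#' @return Data frame with one row per non-control group: `comparison`,
#'   `estimate` (group minus control), `t_statistic`, `p_adjusted`,
#'   `significant`. Groups with fewer than 2 observations are returned as
#'   non-estimable (`NA` statistics).
#' @export
dunnett_vs_control <- function(values, groups, control = "Control",
                               alpha = 0.05) {
  d <- .drop_na_groups(values, groups)
  if (!control %in% levels(d$groups)) {
    stop(sprintf("control group \"%s\" not present", control))
  }
  tab <- table(d$groups)
  small <- names(tab)[tab < 2]
  est_levels <- setdiff(names(tab)[tab >= 2], control)
  out <- data.frame(
    comparison = paste(setdiff(names(tab), control), "-", control),
    group = setdiff(names(tab), control),
    estimate = NA_real_, t_statistic = NA_real_, p_adjusted = NA_real_,
    significant = NA, stringsAsFactors = FALSE
  )
  if (tab[[control]] < 2) stop("control group needs at least 2 observations")
  if (length(est_levels)) {
    keep <- d$groups %in% c(control, est_levels)
    g <- factor(as.character(d$groups[keep]),
                levels = c(control, est_levels))
    v <- d$values[keep]
    if (all(tapply(v, g, stats::var) == 0)) {
      warning("zero within-group variance: comparisons non-estimable")
    } else {
      fit <- stats::aov(v ~ g)
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
      sm <- summary(gl)
      idx <- match(est_levels, out$group)
      out$estimate[idx] <- as.numeric(sm$test$coefficients)
      out$t_statistic[idx] <- as.numeric(sm$test$tstat)
      out$p_adjusted[idx] <- as.numeric(sm$test$pvalues)
      out$significant[idx] <- out$p_adjusted[idx] < alpha
    }
  }
  out$group <- NULL
  out
}

#' Tukey all-pairs comparisons
#'
#' All pairwise group-mean comparisons with family-wise error controlled at
#' `alpha` via the studentized-range distribution (Tukey's honest
#' significant difference).
#'
#' @inheritParams dunnett_vs_control
#' @return Data frame with one row per unordered pair: `comparison`,
#'   `estimate`, `p_adjusted`, `significant`.
#' @export
tukey_all_pairs <- function(values, groups, alpha = 0.05) {
  d <- .drop_na_groups(values, groups)
  if (nlevels(d$groups) < 2) stop("need at least 2 groups")
  if (any(table(d$groups) < 2)) stop("each group needs at least 2 observations")
  if (all(tapply(d$values, d$groups, stats::var) == 0)) {
    stop("degenerate data: zero within-group variance")
  }
  fit <- stats::aov(values ~ groups, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  data.frame(
    comparison = rownames(tk),
    estimate = tk[, "diff"],
    p_adjusted = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' exact permutation distribution for n <= 9 pairs (only available without
#' ties, as in [stats::cor.test()]) and the large-sample approximation
#' otherwise.
#'
#' @param x,y Paired numeric vectors; pairs with a missing member are
#'   dropped.
#' @return List with `rho`, `p_value` and `n` (pairs used).
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 9)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Per-parameter group summary with Dunnett significance flags
#'
#' The study-style results table: for each analysed parameter, the
#' per-group mean and standard error, and a flag for each patient group
#' whose mean differs from the control group (ANOVA + Dunnett post-hoc,
#' adjusted p < `alpha`). Subjects (or eyes) missing a parameter are
#' excluded from that parameter's analysis only.
#'
#' Eye handling is switchable: `"subject_means"` (one eye-averaged row per
#' subject, as in the study's figures) or `"duplicates"` (each eye enters
#' as its own row, statistically dependent duplicates).
#'
#' @param cohort A validated `oct_cohort`.
#' @param parameters Character vector of panel/feature columns to analyse;
#'   defaults to all panel fields plus the derived features.
#' @param control Reference group label.
#' @param alpha Significance level for the Dunnett flags.
#' @param eye_mode `"subject_means"` or `"duplicates"`.
#' @return A list of class `oct_summary_table`: `summary` (data frame:
#'   `parameter`, then `<group>_mean`, `<group>_sem`, `<group>_significant`
#'   per group), `comparisons` (long data frame of every Dunnett contrast),
#'   `eye_mode`, `alpha`, `control`. Parameters with zero variance are
#'   reported with `NA` flags and a warning.
#' @export
summary_table <- function(cohort, parameters = NULL, control = "Control",
                          alpha = 0.05,
                          eye_mode = c("subject_means", "duplicates")) {
  eye_mode <- match.arg(eye_mode)
  cohort <- validate_cohort(cohort)

  if (eye_mode == "subject_means") {
    tbl <- build_feature_table(cohort)
  } else {
    subj_group <- stats::setNames(cohort$subjects$group,
                                  cohort$subjects$subject_id)
    p <- cohort$eyes
    tbl <- data.frame(
      subject_id = p$subject_id,
      group = unname(subj_group[p$subject_id]),
      mean_rgc_ipl = layer_mean_nasal_temporal(p$rgc_ipl_nasal,
                                               p$rgc_ipl_temporal),
      mean_inl = layer_mean_nasal_temporal(p$inl_nasal, p$inl_temporal),
      mean_opl = layer_mean_nasal_temporal(p$opl_nasal, p$opl_temporal),
      onl = onl_value(p$onl_central),
      stringsAsFactors = FALSE
    )
    tbl$ratio_onl_opl <- layer_ratio(tbl$onl, tbl$mean_opl)
    tbl$ratio_inl_opl <- layer_ratio(tbl$mean_inl, tbl$mean_opl)
    tbl <- cbind(tbl, p[, panel_fields(), drop = FALSE])
  }
  if (is.null(parameters)) {
    parameters <- c(
      panel_fields(),
      c("mean_rgc_ipl", "mean_inl", "mean_opl", "onl",
        "ratio_onl_opl", "ratio_inl_opl")
    )
  }
  missing_p <- setdiff(parameters, names(tbl))
  if (length(missing_p)) {
    stop("unknown parameters: ", paste(missing_p, collapse = ", "))
  }

  groups_present <- intersect(group_labels(), unique(tbl$group))
  patient_groups <- setdiff(groups_present, control)
  do_compare <- control %in% groups_present && length(patient_groups) > 0

  rows <- list()
  comp_rows <- list()
  for (par in parameters) {
    v <- tbl[[par]]
    row <- list(parameter = par)
    for (g in groups_present) {
      vg <- v[tbl$group == g & !is.na(v)]
      row[[paste0(g, "_mean")]] <- if (length(vg)) mean(vg) else NA_real_
      row[[paste0(g, "_sem")]] <-
        if (length(vg) > 1) stats::sd(vg) / sqrt(length(vg)) else NA_real_
    }
    flags <- stats::setNames(rep(NA, length(patient_groups)), patient_groups)
    if (do_compare) {
      ok <- !is.na(v)
      enough <- sum(ok & tbl$group == control) >= 2 &&
        any(tapply(v[ok], tbl$group[ok], length) >= 2)
      degenerate <- !enough ||
        isTRUE(all(tapply(v[ok], tbl$group[ok], stats::var) == 0, na.rm = TRUE))
      if (degenerate) {
        warning(sprintf(
          "parameter %s: degenerate (zero-variance or underpopulated) data; no significance flags",
          par
        ))
      } else {
        dn <- dunnett_vs_control(v, tbl$group, control = control,
                                 alpha = alpha)
        dn_group <- sub(" - .*$", "", dn$comparison)
        flags[dn_group[dn_group %in% patient_groups]] <-
          dn$significant[dn_group %in% patient_groups]
        comp_rows[[par]] <- cbind(parameter = par, dn)
      }
    }
    for (g in patient_groups) {
      row[[paste0(g, "_significant")]] <- flags[[g]]
    }
    rows[[par]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }

  structure(
    list(
      summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      comparisons = if (length(comp_rows)) {
        do.call(rbind, c(comp_rows, list(make.row.names = FALSE)))
      },
      eye_mode = eye_mode, alpha = alpha, control = control
    ),
    class = "oct_summary_table"
  )
}

#' @export
print.oct_summary_table <- function(x, ...) {
  cat(sprintf(
    "<oct_summary_table> %d parameters, eye mode \"%s\", alpha %g, control \"%s\"\n",
    nrow(x$summary), x$eye_mode, x$alpha, x$control
  ))
  print(utils::head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("  ...\n")
  invisible(x)
}
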