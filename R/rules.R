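# Threshold diagnostic rules, two-by-two screening metrics, likelihood
# ratios and their qualitative bands.

#' Single threshold rule on a feature
#'
#' A directional cut-off on one feature: a subject is component-positive
#' when its feature value lies below (or above) the cutoff, strictly by
#' default.
#'
#' @param feature Feature column name (must exist in the feature table the
#'   rule is applied to).
#' @param direction `"below"` or `"above"`.
#' @param cutoff Finite cutoff in the feature's units.
#' @param strict Use strict inequality (default `TRUE`); values exactly at
#'   the cutoff then test negative.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(feature, direction = c("below", "above"), cutoff,
                           strict = TRUE) {
  direction <- match.arg(direction)
  stopifnot(is.character(feature), length(feature) == 1,
            is.numeric(cutoff), length(cutoff) == 1, is.finite(cutoff))
  structure(
    list(feature = feature, direction = direction, cutoff = cutoff,
         strict = isTRUE(strict)),
    class = "threshold_rule"
  )
}

#' Conjunction of threshold rules
#'
#' Combines threshold rules on distinct features; a subject is positive
#' when every component is positive.
#'
#' @param ... `threshold_rule` components (at least one).
#' @return An object of class `combined_rule`.
#' @export
combined_rule <- function(...) {
  comps <- list(...)
  if (length(comps) == 1 && is.list(comps[[1]]) &&
      !inherits(comps[[1]], "threshold_rule")) {
    comps <- comps[[1]]
  }
  if (!length(comps)) stop("a combined rule needs at least one component")
  if (!all(vapply(comps, inherits, logical(1), "threshold_rule"))) {
    stop("all components must be threshold_rule objects")
  }
  feats <- vapply(comps, `[[`, character(1), "feature")
  if (anyDuplicated(feats)) stop("component features must be distinct")
  structure(list(components = comps), class = "combined_rule")
}

#' @export
format.threshold_rule <- function(x, ...) {
  sprintf("%s %s %g%s", x$feature,
          if (x$direction == "below") "<" else ">",
          x$cutoff, if (x$strict) "" else " (or equal)")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat("<threshold_rule>", format(x), "\n")
  invisible(x)
}

#' @export
format.combined_rule <- function(x, ...) {
  paste(vapply(x$components, format, character(1)), collapse = "  AND  ")
}

#' @export
print.combined_rule <- function(x, ...) {
  cat("<combined_rule>", format(x), "\n")
  invisible(x)
}

#' The PSP screening rule
#'
#' The combined rule that flags progressive supranuclear palsy: ONL/OPL
#' ratio strictly below 3.1 AND mean INL strictly below 46 micrometres.
#' The "below" direction follows the group-level pattern: PSP shows the
#' thinnest ONL and the thickest OPL of the five groups, hence the lowest
#' ratio, together with a thin INL (whereas the INL is thickened in PD).
#'
#' @return A `combined_rule` over `ratio_onl_opl` and `mean_inl`.
#' @examples
#' psp_rule()
#' @export
psp_rule <- function() {
  combined_rule(
    threshold_rule("ratio_onl_opl", "below", 3.1, strict = TRUE),
    threshold_rule("mean_inl", "below", 46, strict = TRUE)
  )
}

#' Apply a rule to a feature table
#'
#' Evaluates the conjunction per row. A row missing any feature the rule
#' needs yields `NA` (that subject is excluded from the two-by-two table
#' and logged by [rule_confusion()]).
#'
#' @param rule A `threshold_rule` or `combined_rule`.
#' @param features A feature data frame (see [build_feature_table()]).
#' @return Logical vector, one element per row, `NA` where not evaluable.
#' @export
apply_rule <- function(rule, features) {
  if (inherits(rule, "threshold_rule")) rule <- combined_rule(rule)
  if (!inherits(rule, "combined_rule")) {
    stop("`rule` must be a threshold_rule or combined_rule")
  }
  res <- rep(TRUE, nrow(features))
  for (comp in rule$components) {
    if (!comp$feature %in% names(features)) {
      stop(sprintf("unknown feature \"%s\" in rule", comp$feature))
    }
    v <- features[[comp$feature]]
    hit <- switch(paste(comp$direction, comp$strict),
      "below TRUE" = v < comp$cutoff,
      "below FALSE" = v <= comp$cutoff,
      "above TRUE" = v > comp$cutoff,
      "above FALSE" = v >= comp$cutoff
    )
    res <- res & hit
  }
  res
}

#' Two-by-two confusion counts for a rule
#'
#' Counts rule outcomes against the reference diagnosis: subjects of
#' `positive_group` are disease-positive, subjects of `negative_groups`
#' disease-negative; other groups are ignored. Subjects whose rule outcome
#' is `NA` (missing features) are excluded and logged.
#'
#' @param rule A `threshold_rule` or `combined_rule`.
#' @param features Feature data frame with a `group` column.
#' @param positive_group Group label counted as disease-positive.
#' @param negative_groups Group labels counted as disease-negative.
#' @return A list of class `confusion_2x2`: `tp`, `fp`, `tn`, `fn` counts
#'   and `excluded` (data frame `subject_id`, `reason`).
#' @export
rule_confusion <- function(rule, features, positive_group, negative_groups) {
  in_pos <- features$group %in% positive_group
  in_neg <- features$group %in% negative_groups
  res <- apply_rule(rule, features)

  excl <- (in_pos | in_neg) & is.na(res)
  excluded <- data.frame(
    subject_id = features$subject_id[excl],
    reason = rep("missing feature for rule", sum(excl)),
    stringsAsFactors = FALSE
  )
  pos_ok <- in_pos & !is.na(res)
  neg_ok <- in_neg & !is.na(res)
  if (!any(pos_ok)) {
    stop(sprintf("positive class \"%s\" is empty after missing-data exclusion",
                 paste(positive_group, collapse = "/")))
  }
  if (!any(neg_ok)) {
    stop(sprintf("negative class \"%s\" is empty after missing-data exclusion",
                 paste(negative_groups, collapse = "/")))
  }
  structure(
    list(
      tp = sum(res[pos_ok]), fn = sum(!res[pos_ok]),
      fp = sum(res[neg_ok]), tn = sum(!res[neg_ok]),
      excluded = excluded
    ),
    class = "confusion_2x2"
  )
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  cat(sprintf("<confusion_2x2> tp=%d fn=%d fp=%d tn=%d (excluded: %d)\n",
              x$tp, x$fn, x$fp, x$tn, nrow(x$excluded)))
  invisible(x)
}

# Round half away from zero (printed LRs use this convention; base round()
# rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Screening metrics from a two-by-two table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive likelihood
#' ratio `sensitivity/(1-specificity)` and negative likelihood ratio
#' `(1-sensitivity)/specificity`, with the qualitative bands of
#' [lr_band()]. Raw values are retained; `lr_pos_rounded`/`lr_neg_rounded`
#' round half away from zero to 2 decimals, `sensitivity_pct`/
#' `specificity_pct` to whole percent. At specificity 1 the LR+ is `Inf`
#' (flagged); at specificity 0 the LR- is undefined (`NA`, flagged).
#'
#' @param confusion A `confusion_2x2`, or a list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return A list of class `diagnostic_metrics`.
#' @examples
#' m <- diagnostic_metrics(list(tp = 96, fn = 4, fp = 30, tn = 70))
#' m$lr_neg_rounded # 0.06
#' @export
diagnostic_metrics <- function(confusion) {
  tp <- confusion$tp; fp <- confusion$fp
  tn <- confusion$tn; fn <- confusion$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  if (tp + fn == 0 || tn + fp == 0) {
    stop("metric computation needs tp+fn > 0 and tn+fp > 0")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (spec == 0) NA_real_ else (1 - sens) / spec
  flags <- c(
    if (spec == 1) "lr_pos infinite (specificity = 1)",
    if (spec == 0) "lr_neg undefined (specificity = 0)"
  )
  bands <- lr_band(lr_pos, lr_neg)
  structure(
    list(
      sensitivity = sens, specificity = spec,
      lr_pos = lr_pos, lr_neg = lr_neg,
      sensitivity_pct = round_half_away(100 * sens),
      specificity_pct = round_half_away(100 * spec),
      lr_pos_rounded = round_half_away(lr_pos, 2),
      lr_neg_rounded = round_half_away(lr_neg, 2),
      band_pos = bands[["band_pos"]], band_neg = bands[["band_neg"]],
      flags = flags
    ),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf(
    "<diagnostic_metrics> sensitivity %g%%, specificity %g%%\n  LR+ %s (%s), LR- %s (%s)\n",
    x$sensitivity_pct, x$specificity_pct,
    format(x$lr_pos_rounded), x$band_pos,
    format(x$lr_neg_rounded), x$band_neg
  ))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Qualitative likelihood-ratio bands
#'
#' Bands a positive and a negative likelihood ratio: LR+ of 50 or more is
#' excellent, 10 to 50 good, 2 to 10 fair (half-open intervals
#' `[lower, upper)`); LR- below 0.05 is excellent, 0.05 to below 0.1 good,
#' 0.1 to 0.3 (inclusive) fair. Values outside every band are `"none"`.
#'
#' @param lr_pos,lr_neg Likelihood ratios (`NA` allowed).
#' @return Named character vector `c(band_pos =, band_neg =)`.
#' @examples
#' lr_band(3.4, 0.06) # fair / good
#' @export
lr_band <- function(lr_pos, lr_neg) {
  band_pos <- if (is.na(lr_pos)) {
    NA_character_
  } else if (lr_pos >= 50) {
    "excellent"
  } else if (lr_pos >= 10) {
    "good"
  } else if (lr_pos >= 2) {
    "fair"
  } else {
    "none"
  }
  band_neg <- if (is.na(lr_neg)) {
    NA_character_
  } else if (lr_neg < 0.05) {
    "excellent"
  } else if (lr_neg < 0.1) {
    "good"
  } else if (lr_neg <= 0.3) {
    "fair"
  } else {
    "none"
  }
  c(band_pos = band_pos, band_neg = band_neg)
}

#' Rules as JSON documents
#'
#' Writes a rule as a JSON array of components (`feature`, `direction`,
#' `cutoff`, `strict`) and reads such a document back into a
#' `combined_rule`.
#'
#' @param rule A `threshold_rule` or `combined_rule`.
#' @param path JSON file path.
#' @return `write_rule()` returns `path` invisibly; `read_rule()` the
#'   `combined_rule`.
#' @export
write_rule <- function(rule, path) {
  if (inherits(rule, "threshold_rule")) rule <- combined_rule(rule)
  jsonlite::write_json(
    lapply(rule$components, unclass), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  comps <- jsonlite::read_json(path, simplifyVector = FALSE)
  combined_rule(lapply(comps, function(cc) {
    threshold_rule(cc$feature, cc$direction, cc$cutoff,
                   strict = isTRUE(cc$strict))
  }))
}
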