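# End-to-end orchestration: simulate (or read) -> QC -> features -> group
# statistics -> screening metrics -> cutoff search, with a deterministic
# seed and a written report bundle.

#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()].
#'
#' @param seed Integer seed for the synthetic cohort.
#' @param params Generator parameters: an `oct_generator_params`, the
#'   string `"default"`, or a path to a JSON file from [write_params()].
#' @param cohort Optional: an existing `oct_cohort` or
#'   `c(subjects_csv, eyes_csv)` paths; when given, no simulation is done
#'   and `params`/`seed` are ignored for data generation.
#' @param eye_mode `"subject_means"` or `"duplicates"` for the group
#'   statistics (see [summary_table()]).
#' @param alpha Significance level in (0, 1).
#' @param rule Screening rule: a rule object, the string `"psp_default"`,
#'   or a path to a JSON file from [write_rule()].
#' @param positive_group,negative_groups Classes for screening and search.
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `oct_run_config`.
#' @export
run_config <- function(seed = 1L, params = "default", cohort = NULL,
                       eye_mode = c("subject_means", "duplicates"),
                       alpha = 0.05, rule = "psp_default",
                       positive_group = "PSP",
                       negative_groups = c("PD", "MSA", "CBS"),
                       out_dir = tempfile("parkoct_run_")) {
  eye_mode <- match.arg(eye_mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (length(seed) != 1 || is.na(seed) || seed != round(seed)) {
    stop("seed must be a single integer")
  }
  if (is.character(params) && params != "default" && !file.exists(params)) {
    stop("params path does not exist: ", params)
  }
  if (is.character(rule) && rule != "psp_default" && !file.exists(rule)) {
    stop("rule path does not exist: ", rule)
  }
  structure(
    list(seed = as.integer(seed), params = params, cohort = cohort,
         eye_mode = eye_mode, alpha = alpha, rule = rule,
         positive_group = positive_group, negative_groups = negative_groups,
         out_dir = out_dir),
    class = "oct_run_config"
  )
}

.resolve_params <- function(params) {
  if (inherits(params, "oct_generator_params")) return(params)
  if (identical(params, "default")) return(default_params())
  read_params(params)
}

.resolve_rule <- function(rule) {
  if (inherits(rule, c("threshold_rule", "combined_rule"))) return(rule)
  if (identical(rule, "psp_default")) return(psp_rule())
  read_rule(rule)
}

#' Run the full analysis pipeline
#'
#' Composes all stages in order: cohort acquisition (simulation under the
#' configured seed, or reading the supplied CSVs), quality-control
#' filtering, eye averaging and feature construction, the per-parameter
#' group summary with Dunnett flags, screening metrics for the configured
#' rule, and the exhaustive cutoff search. Writes the full bundle to
#' `config$out_dir`: `subjects.csv`, `eyes.csv`, `features.csv`,
#' `summary.csv`, `comparisons.csv`, `metrics.json`, `ranked_rules.csv`
#' and `run.log`. Identical configuration and seed reproduce an identical
#' bundle.
#'
#' @param config An [run_config()] object.
#' @return Invisibly, a list of class `oct_run_bundle` with all in-memory
#'   stage results plus `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "oct_run_config")) {
    stop("config must come from run_config()")
  }
  stage <- "setup"
  log_lines <- c(
    sprintf("parkoct %s | R %s", as.character(utils::packageVersion("parkoct")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed=%d eye_mode=%s alpha=%g positive=%s negatives=%s",
            config$seed, config$eye_mode, config$alpha,
            config$positive_group,
            paste(config$negative_groups, collapse = ","))
  )
  fail <- function(e) {
    stop(sprintf("pipeline stage \"%s\" failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  tryCatch({
    stage <- "cohort"
    if (is.null(config$cohort)) {
      cohort <- simulate_cohort(.resolve_params(config$params), config$seed)
      log_lines <- c(log_lines, sprintf(
        "simulated cohort: %d subjects, %d eyes",
        nrow(cohort$subjects), nrow(cohort$eyes)
      ))
    } else if (inherits(config$cohort, "oct_cohort")) {
      cohort <- validate_cohort(config$cohort)
    } else {
      cohort <- read_cohort(config$cohort[1], config$cohort[2])
    }

    stage <- "qc"
    qc <- qc_filter(cohort)
    for (i in seq_len(nrow(qc$log))) {
      log_lines <- c(log_lines, sprintf(
        "excluded %s%s: %s", qc$log$subject_id[i],
        ifelse(is.na(qc$log$side[i]), "", paste0("/", qc$log$side[i])),
        qc$log$reason[i]
      ))
    }

    stage <- "features"
    features <- build_feature_table(qc$cohort)

    stage <- "group_stats"
    summary_res <- summary_table(qc$cohort, alpha = config$alpha,
                                 eye_mode = config$eye_mode)

    stage <- "screen"
    rule <- .resolve_rule(config$rule)
    conf <- rule_confusion(rule, features, config$positive_group,
                           config$negative_groups)
    metrics <- diagnostic_metrics(conf)
    for (i in seq_len(nrow(conf$excluded))) {
      log_lines <- c(log_lines, sprintf(
        "excluded %s from screening: %s",
        conf$excluded$subject_id[i], conf$excluded$reason[i]
      ))
    }

    stage <- "search"
    ranked <- search_rules(features, config$positive_group,
                           config$negative_groups)
    rule_eval <- evaluate_rule_in_search(rule, features,
                                         config$positive_group,
                                         config$negative_groups, ranked)

    stage <- "write"
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_cohort(qc$cohort, p("subjects.csv"), p("eyes.csv"))
    utils::write.csv(features, p("features.csv"), row.names = FALSE, na = "")
    utils::write.csv(summary_res$summary, p("summary.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(summary_res$comparisons, p("comparisons.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(
      list(
        rule = format(rule),
        confusion = list(tp = conf$tp, fn = conf$fn, fp = conf$fp,
                         tn = conf$tn),
        sensitivity = metrics$sensitivity, specificity = metrics$specificity,
        lr_pos = if (is.finite(metrics$lr_pos)) metrics$lr_pos else "Inf",
        lr_neg = metrics$lr_neg,
        band_pos = metrics$band_pos, band_neg = metrics$band_neg,
        rule_rank_in_search = rule_eval$rank,
        evaluation = "in-sample (resubstitution)"
      ),
      p("metrics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    ranked_out <- as.data.frame(ranked)
    utils::write.csv(utils::head(ranked_out, 1000), p("ranked_rules.csv"),
                     row.names = FALSE, na = "")
    writeLines(log_lines, p("run.log"))
  }, error = fail)

  invisible(structure(
    list(
      config = config, cohort = qc$cohort, qc_log = qc$log,
      features = features, summary = summary_res, confusion = conf,
      metrics = metrics, ranked_rules = ranked, rule_eval = rule_eval,
      rule = rule, out_dir = config$out_dir, log = log_lines
    ),
    class = "oct_run_bundle"
  ))
}

#' Human-readable report for a pipeline bundle
#'
#' Renders a markdown report: group sizes, the parameter summary with
#' significance flags, the screening rule's two-by-two metrics with
#' likelihood-ratio bands, and the top of the cutoff search. All
#' performance figures are in-sample (resubstitution).
#'
#' @param bundle An `oct_run_bundle` from [run_pipeline()], or the path of
#'   a bundle directory written by it.
#' @param top_n Number of search rules to list.
#' @return Character vector of report lines (also usable via
#'   `writeLines()`).
#' @export
pipeline_report <- function(bundle, top_n = 10) {
  if (is.character(bundle)) {
    need <- c("features.csv", "summary.csv", "metrics.json",
              "ranked_rules.csv")
    for (f in need) {
      if (!file.exists(file.path(bundle, f))) {
        stop("bundle is missing file: ", f)
      }
    }
    features <- utils::read.csv(file.path(bundle, "features.csv"))
    summary_df <- utils::read.csv(file.path(bundle, "summary.csv"),
                                  check.names = FALSE)
    metrics <- jsonlite::read_json(file.path(bundle, "metrics.json"),
                                   simplifyVector = TRUE)
    ranked <- utils::read.csv(file.path(bundle, "ranked_rules.csv"))
    rule_txt <- metrics$rule
    sens <- metrics$sensitivity; spec <- metrics$specificity
    band_pos <- metrics$band_pos; band_neg <- metrics$band_neg
    lr_pos <- suppressWarnings(as.numeric(metrics$lr_pos))
    lr_neg <- metrics$lr_neg
  } else {
    if (!inherits(bundle, "oct_run_bundle")) {
      stop("bundle must be an oct_run_bundle or a bundle directory path")
    }
    features <- bundle$features
    summary_df <- bundle$summary$summary
    ranked <- as.data.frame(bundle$ranked_rules)
    rule_txt <- format(bundle$rule)
    sens <- bundle$metrics$sensitivity; spec <- bundle$metrics$specificity
    band_pos <- bundle$metrics$band_pos; band_neg <- bundle$metrics$band_neg
    lr_pos <- bundle$metrics$lr_pos; lr_neg <- bundle$metrics$lr_neg
  }

  lines <- c("# Retinal layer analysis report", "")
  if (!nrow(features)) {
    return(c(lines, "No subjects in cohort after quality control."))
  }
  tab <- table(factor(features$group, levels = group_labels()))
  lines <- c(
    lines,
    "## Cohort",
    paste0("- ", names(tab), ": ", as.integer(tab), " subjects"),
    "",
    "## Group summary (mean ± SEM; * = differs from controls, Dunnett)",
    ""
  )
  sig_cols <- grep("_significant$", names(summary_df), value = TRUE)
  for (i in seq_len(nrow(summary_df))) {
    flagged <- sub("_significant$", "",
                   sig_cols[vapply(sig_cols, function(cc)
                     isTRUE(summary_df[[cc]][i]), logical(1))])
    lines <- c(lines, sprintf(
      "- %s%s", summary_df$parameter[i],
      if (length(flagged)) paste0("  [* ", paste(flagged, collapse = ", "),
                                  "]") else ""
    ))
  }
  lr_fmt <- function(x) {
    if (is.null(x) || length(x) == 0 || is.na(x)) "undefined"
    else if (!is.finite(x)) "Inf"
    else sprintf("%.2f", round_half_away(x, 2))
  }
  lines <- c(
    lines, "",
    "## Screening rule (in-sample, resubstitution)",
    paste0("- rule: ", rule_txt),
    sprintf("- sensitivity %.0f%%, specificity %.0f%%",
            round_half_away(100 * sens), round_half_away(100 * spec)),
    sprintf("- LR+ %s (band: %s); LR- %s (band: %s)",
            lr_fmt(lr_pos), band_pos, lr_fmt(lr_neg), band_neg),
    "",
    sprintf("## Cutoff search: top %d of %d rules (in-sample)",
            min(top_n, nrow(ranked)), nrow(ranked)),
    ""
  )
  top <- utils::head(ranked, top_n)
  for (i in seq_len(nrow(top))) {
    r <- top[i, ]
    spec_txt <- sprintf("%s %s %.3g", r$feature1,
                        ifelse(r$direction1 == "below", "<", ">"), r$cutoff1)
    if (!is.na(r$feature2)) {
      spec_txt <- paste0(spec_txt, sprintf(
        " AND %s %s %.3g", r$feature2,
        ifelse(r$direction2 == "below", "<", ">"), r$cutoff2
      ))
    }
    lines <- c(lines, sprintf(
      "%d. %s  (J=%.3f, sens %.0f%%, spec %.0f%%)",
      r$rank, spec_txt, r$youden, 100 * r$sensitivity, 100 * r$specificity
    ))
  }
  lines
}
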