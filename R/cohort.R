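# Cohort container: per-subject clinical table + per-eye layer panel table,
# CSV readers/writers, quality filtering and eye averaging.

.subject_cols <- c(
  "subject_id", "group", "age", "sex", "duration_months", "followup_months",
  "hy", "updrs_on", "updrs_off", "visual_acuity"
)
.subject_numeric_cols <- setdiff(.subject_cols, c("subject_id", "group", "sex"))

.eye_meta_cols <- c("subject_id", "side", "quality_db")

.eye_cols <- function() c(.eye_meta_cols, panel_fields())

#' Construct a validated OCT cohort
#'
#' A cohort is a pair of tables: one row per subject (diagnostic group and
#' clinical covariates) and one row per scanned eye (scan quality plus the
#' full layer panel). Validation enforces the domain invariants: known
#' group labels, positive age, visual acuity in (0, 2] when present, at
#' most one record per (subject, side), every eye resolving to exactly one
#' subject and at most two eyes per subject, all present thicknesses in
#' (0, 1000) micrometres and volumes in (0, 10) cubic millimetres, and
#' non-negative scan quality.
#'
#' @param subjects Data frame with columns `subject_id`, `group`, `age`,
#'   `sex`, `duration_months`, `followup_months`, `hy`, `updrs_on`,
#'   `updrs_off`, `visual_acuity` (missing clinical values as `NA`).
#' @param eyes Data frame with columns `subject_id`, `side`
#'   (`"left"`/`"right"`), `quality_db`, and one column per
#'   [panel_fields()] entry.
#' @return An object of class `oct_cohort`: `list(subjects =, eyes =)`.
#' @seealso [read_cohort()], [qc_filter()], [subject_eye_means()]
#' @export
oct_cohort <- function(subjects, eyes) {
  validate_cohort(
    structure(list(subjects = subjects, eyes = eyes), class = "oct_cohort")
  )
}

.row_error <- function(tbl, rows, msg) {
  stop(sprintf("%s row %s: %s", tbl, paste(rows, collapse = ", "), msg),
    call. = FALSE
  )
}

#' Validate an OCT cohort
#'
#' @param cohort An `oct_cohort` object (or bare list with `subjects` and
#'   `eyes` data frames).
#' @return The cohort, invisibly classed `oct_cohort`; errors name the
#'   offending table, row and field.
#' @export
validate_cohort <- function(cohort) {
  subjects <- cohort$subjects
  eyes <- cohort$eyes
  if (!is.data.frame(subjects) || !is.data.frame(eyes)) {
    stop("cohort must hold `subjects` and `eyes` data frames")
  }
  missing_s <- setdiff(.subject_cols, names(subjects))
  if (length(missing_s)) {
    stop("subjects table lacks columns: ", paste(missing_s, collapse = ", "))
  }
  missing_e <- setdiff(.eye_cols(), names(eyes))
  if (length(missing_e)) {
    stop("eyes table lacks columns: ", paste(missing_e, collapse = ", "))
  }

  if (nrow(subjects)) {
    bad <- which(!subjects$group %in% group_labels())
    if (length(bad)) {
      .row_error("subjects", bad[1], sprintf(
        "field `group`: unknown label \"%s\"", subjects$group[bad[1]]
      ))
    }
    dup <- which(duplicated(subjects$subject_id))
    if (length(dup)) {
      .row_error("subjects", dup[1], "duplicate subject_id")
    }
    bad <- which(!is.na(subjects$age) & subjects$age <= 0)
    if (length(bad)) .row_error("subjects", bad[1], "field `age`: must be > 0")
    bad <- which(!subjects$sex %in% c("F", "M") & !is.na(subjects$sex))
    if (length(bad)) {
      .row_error("subjects", bad[1], "field `sex`: must be \"F\" or \"M\"")
    }
    va <- subjects$visual_acuity
    bad <- which(!is.na(va) & (va <= 0 | va > 2))
    if (length(bad)) {
      .row_error("subjects", bad[1], "field `visual_acuity`: must be in (0, 2]")
    }
  }

  if (nrow(eyes)) {
    bad <- which(!eyes$side %in% c("left", "right"))
    if (length(bad)) {
      .row_error("eyes", bad[1], sprintf(
        "field `side`: must be \"left\" or \"right\", got \"%s\"",
        eyes$side[bad[1]]
      ))
    }
    dup <- which(duplicated(paste(eyes$subject_id, eyes$side)))
    if (length(dup)) {
      .row_error("eyes", dup[1], "duplicate (subject_id, side)")
    }
    orphan <- which(!eyes$subject_id %in% subjects$subject_id)
    if (length(orphan)) {
      .row_error("eyes", orphan[1], sprintf(
        "field `subject_id`: \"%s\" has no subjects row",
        eyes$subject_id[orphan[1]]
      ))
    }
    bad <- which(!is.na(eyes$quality_db) & eyes$quality_db < 0)
    if (length(bad)) {
      .row_error("eyes", bad[1], "field `quality_db`: must be >= 0")
    }
    for (f in panel_fields("thickness")) {
      v <- eyes[[f]]
      bad <- which(!is.na(v) & (v <= 0 | v >= 1000))
      if (length(bad)) {
        .row_error("eyes", bad[1], sprintf(
          "field `%s`: thickness must lie in (0, 1000) um", f
        ))
      }
    }
    for (f in panel_fields("volume")) {
      v <- eyes[[f]]
      bad <- which(!is.na(v) & (v <= 0 | v >= 10)) # mm^3
      if (length(bad)) {
        .row_error("eyes", bad[1], sprintf(
          "field `%s`: volume must lie in (0, 10) mm^3", f
        ))
      }
    }
  }

  structure(list(subjects = subjects, eyes = eyes), class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf(
    "<oct_cohort> %d subjects, %d eyes\n",
    nrow(x$subjects), nrow(x$eyes)
  ))
  if (nrow(x$subjects)) {
    tab <- table(factor(x$subjects$group, levels = group_labels()))
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n"
    )
  }
  invisible(x)
}

#' Read a cohort from subject and eye CSV files
#'
#' Reads the two-file cohort representation: `subjects.csv` (one row per
#' subject) and `eyes.csv` (one row per scanned eye, joined on
#' `subject_id`). Empty cells become missing values (`NA`), never zeros.
#' The result is validated; violations report the table, row and field.
#'
#' @param subjects_path,eyes_path Paths to the CSV files.
#' @return A validated `oct_cohort`.
#' @export
read_cohort <- function(subjects_path, eyes_path) {
  subjects <- utils::read.csv(
    subjects_path,
    colClasses = c(subject_id = "character", group = "character",
                   sex = "character"),
    na.strings = ""
  )
  eyes <- utils::read.csv(
    eyes_path,
    colClasses = c(subject_id = "character", side = "character"),
    na.strings = ""
  )
  for (col in .subject_numeric_cols) {
    if (col %in% names(subjects)) subjects[[col]] <- as.numeric(subjects[[col]])
  }
  for (col in c("quality_db", panel_fields())) {
    if (col %in% names(eyes)) eyes[[col]] <- as.numeric(eyes[[col]])
  }
  oct_cohort(subjects, eyes)
}

#' Write a cohort to subject and eye CSV files
#'
#' Inverse of [read_cohort()]: writes the two CSV files with a mandatory
#' header row, missing values as empty cells, decimal point `"."`. A
#' written cohort reads back equal.
#'
#' @param cohort A validated `oct_cohort`.
#' @param subjects_path,eyes_path Output CSV paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_cohort <- function(cohort, subjects_path, eyes_path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(
    cohort$subjects[, .subject_cols, drop = FALSE],
    subjects_path, row.names = FALSE, na = ""
  )
  utils::write.csv(
    cohort$eyes[, .eye_cols(), drop = FALSE],
    eyes_path, row.names = FALSE, na = ""
  )
  invisible(c(subjects_path, eyes_path))
}

#' Quality-control filter
#'
#' Applies the study's exclusion rules: eyes whose scan quality is below
#' `min_quality_db` (default 20 dB) are removed, and subjects whose
#' recorded visual acuity is below `min_acuity` (default 0.6, i.e. 6/10 on
#' a decimal chart) are removed together with all their eyes. Subjects
#' with no acuity on record are not excluded on acuity. The filter is
#' idempotent.
#'
#' @param cohort A validated `oct_cohort`.
#' @param min_quality_db Minimum acceptable scan quality in dB.
#' @param min_acuity Minimum acceptable decimal visual acuity.
#' @return A list with elements `cohort` (the filtered `oct_cohort`) and
#'   `log` (data frame with columns `subject_id`, `side`, `reason`; one
#'   row per exclusion, plus a warning entry if the cohort empties).
#' @export
qc_filter <- function(cohort, min_quality_db = 20, min_acuity = 0.6) {
  cohort <- validate_cohort(cohort)
  subjects <- cohort$subjects
  eyes <- cohort$eyes
  log <- data.frame(
    subject_id = character(), side = character(), reason = character(),
    stringsAsFactors = FALSE
  )

  va <- subjects$visual_acuity
  drop_subj <- !is.na(va) & va < min_acuity
  if (any(drop_subj)) {
    log <- rbind(log, data.frame(
      subject_id = subjects$subject_id[drop_subj], side = NA_character_,
      reason = sprintf("acuity<%g", min_acuity), stringsAsFactors = FALSE
    ))
    dropped_ids <- subjects$subject_id[drop_subj]
    acuity_eyes <- eyes$subject_id %in% dropped_ids
    if (any(acuity_eyes)) {
      log <- rbind(log, data.frame(
        subject_id = eyes$subject_id[acuity_eyes],
        side = eyes$side[acuity_eyes],
        reason = "subject excluded on acuity", stringsAsFactors = FALSE
      ))
    }
    subjects <- subjects[!drop_subj, , drop = FALSE]
    eyes <- eyes[!acuity_eyes, , drop = FALSE]
  }

  low_q <- !is.na(eyes$quality_db) & eyes$quality_db < min_quality_db
  if (any(low_q)) {
    log <- rbind(log, data.frame(
      subject_id = eyes$subject_id[low_q], side = eyes$side[low_q],
      reason = sprintf("quality<%gdB", min_quality_db),
      stringsAsFactors = FALSE
    ))
    eyes <- eyes[!low_q, , drop = FALSE]
  }

  out <- validate_cohort(list(subjects = subjects, eyes = eyes))
  if (nrow(cohort$subjects) > 0 && nrow(out$eyes) == 0) {
    warning("qc_filter removed every eye from the cohort")
    log <- rbind(log, data.frame(
      subject_id = NA_character_, side = NA_character_,
      reason = "warning: cohort emptied by QC", stringsAsFactors = FALSE
    ))
  }
  list(cohort = out, log = log)
}

#' Per-subject eye-averaged layer panels
#'
#' Collapses the per-eye table to one row per subject: each panel field is
#' the arithmetic mean of the values present across that subject's eyes
#' (both eyes when both carry the field, the single available value
#' otherwise, `NA` when neither eye has it — those subjects are then
#' excluded from any analysis needing that field). Subjects with no eye
#' record at all are dropped and logged.
#'
#' @param cohort A validated `oct_cohort`, typically after [qc_filter()].
#' @return A list with `panels` (data frame: `subject_id`, `group`, `n_eyes`
#'   and one eye-averaged column per panel field, one row per surviving
#'   subject, in subject-table order) and `log` (exclusion data frame as in
#'   [qc_filter()]).
#' @export
subject_eye_means <- function(cohort) {
  cohort <- validate_cohort(cohort)
  subjects <- cohort$subjects
  eyes <- cohort$eyes
  fields <- panel_fields()

  keep <- subjects$subject_id %in% eyes$subject_id
  log <- data.frame(
    subject_id = subjects$subject_id[!keep],
    side = rep(NA_character_, sum(!keep)),
    reason = rep("no eye record", sum(!keep)),
    stringsAsFactors = FALSE
  )
  surv <- subjects[keep, , drop = FALSE]
  if (!nrow(surv)) {
    empty <- cbind(
      data.frame(subject_id = character(), group = character(),
                 n_eyes = integer(), stringsAsFactors = FALSE),
      as.data.frame(stats::setNames(
        rep(list(numeric()), length(fields)), fields
      ))
    )
    return(list(panels = empty, log = log))
  }

  id <- factor(eyes$subject_id, levels = surv$subject_id)
  vals <- as.matrix(eyes[, fields, drop = FALSE])
  pres <- !is.na(vals)
  vals[!pres] <- 0
  sums <- rowsum(vals, id)                  # per-subject field sums
  counts <- rowsum(pres + 0, id)            # per-subject non-missing counts
  means <- sums / counts                    # 0/0 -> NaN, mapped to NA below
  means[counts == 0] <- NA_real_

  panels <- data.frame(
    subject_id = surv$subject_id,
    group = surv$group,
    n_eyes = as.integer(table(id)[surv$subject_id]),
    stringsAsFactors = FALSE
  )
  panels <- cbind(panels, as.data.frame(means[surv$subject_id, , drop = FALSE]))
  rownames(panels) <- NULL
  list(panels = panels, log = log)
}
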