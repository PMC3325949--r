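# Shared fixtures and independent oracles, built in code at test time.

# Blank eye row(s) with all panel fields NA; fill via `...` (name = value).
make_eyes <- function(subject_id, side, quality_db = 25, ...) {
  n <- max(length(subject_id), length(side))
  df <- data.frame(
    subject_id = rep_len(subject_id, n),
    side = rep_len(side, n),
    quality_db = rep_len(quality_db, n),
    stringsAsFactors = FALSE
  )
  for (f in panel_fields()) df[[f]] <- rep(NA_real_, n)
  fills <- list(...)
  for (nm in names(fills)) df[[nm]] <- rep_len(fills[[nm]], n)
  df
}

make_subjects <- function(subject_id, group, age = 65, sex = "F",
                          visual_acuity = 1) {
  n <- length(subject_id)
  data.frame(
    subject_id = subject_id,
    group = rep_len(group, n),
    age = rep_len(age, n),
    sex = rep_len(sex, n),
    duration_months = rep(NA_real_, n),
    followup_months = rep(NA_real_, n),
    hy = rep(NA_real_, n),
    updrs_on = rep(NA_real_, n),
    updrs_off = rep(NA_real_, n),
    visual_acuity = rep_len(visual_acuity, n),
    stringsAsFactors = FALSE
  )
}

# A small two-group cohort with complete INL/OPL/ONL measurements.
make_toy_cohort <- function() {
  subjects <- make_subjects(
    c("C1", "C2", "P1", "P2", "P3"),
    c("Control", "Control", "PSP", "PSP", "PSP")
  )
  eyes <- rbind(
    make_eyes("C1", c("left", "right"), onl_central = c(100, 110),
              inl_nasal = 44, inl_temporal = 41, opl_nasal = 36,
              opl_temporal = 33, rgc_ipl_nasal = 103, rgc_ipl_temporal = 94),
    make_eyes("C2", "left", onl_central = 104, inl_nasal = 45,
              inl_temporal = 42, opl_nasal = 35, opl_temporal = 34,
              rgc_ipl_nasal = 101, rgc_ipl_temporal = 95),
    make_eyes("P1", c("left", "right"), onl_central = c(92, 96),
              inl_nasal = 40, inl_temporal = 38, opl_nasal = 43,
              opl_temporal = 33, rgc_ipl_nasal = 90, rgc_ipl_temporal = 85),
    make_eyes("P2", "right", onl_central = 95, inl_nasal = 41,
              inl_temporal = 39, opl_nasal = 42, opl_temporal = 34,
              rgc_ipl_nasal = 88, rgc_ipl_temporal = 83),
    make_eyes("P3", c("left", "right"), onl_central = c(90, 94),
              inl_nasal = 39, inl_temporal = 37, opl_nasal = 44,
              opl_temporal = 32, rgc_ipl_nasal = 91, rgc_ipl_temporal = 86)
  )
  oct_cohort(subjects, eyes)
}

# Override per-group sample sizes (SDs stay anchored to the published SEMs).
with_group_n <- function(params, n) {
  for (g in names(params$groups)) params$groups[[g]]$n_subjects <- n
  params
}

# All-zero-variance generator: every subject sits exactly at the group mean.
zero_sd_params <- function(params = default_params()) {
  for (g in names(params$groups)) {
    params$groups[[g]]$sd[] <- 0
    params$groups[[g]]$clinical_sd[] <- 0
  }
  params$quality_db_sd <- 0
  params
}

# Independent Spearman oracle: Pearson correlation of average ranks.
spearman_bruteforce <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# Independent brute-force rule search: nested loops, no shared code with
# search_rules(). Returns one row per rule with sens/spec/J.
search_bruteforce <- function(values, group, positive_group, negative_groups,
                              max_components = 2) {
  feats <- names(values)
  is_pos <- group %in% positive_group
  is_neg <- group %in% negative_groups
  eval_rule <- function(comp_list) {
    hit <- rep(TRUE, length(group))
    ok <- rep(TRUE, length(group))
    for (comp in comp_list) {
      v <- values[[comp$f]]
      ok <- ok & !is.na(v)
      h <- if (comp$d == "below") v < comp$c else v > comp$c
      hit <- hit & h
    }
    tp <- sum(hit[is_pos & ok], na.rm = TRUE)
    fn <- sum(is_pos & ok) - tp
    fp <- sum(hit[is_neg & ok], na.rm = TRUE)
    tn <- sum(is_neg & ok) - fp
    c(tp = tp, fn = fn, fp = fp, tn = tn,
      sens = tp / (tp + fn), spec = tn / (tn + fp))
  }
  cuts <- lapply(values, function(v) {
    s <- sort(unique(v[!is.na(v)]))
    if (length(s) < 2) numeric() else (s[-1] + s[-length(s)]) / 2
  })
  rows <- list()
  for (f in feats) {
    for (cc in cuts[[f]]) {
      for (d in c("below", "above")) {
        r <- eval_rule(list(list(f = f, d = d, c = cc)))
        rows[[length(rows) + 1]] <- data.frame(
          key = paste(f, d, signif(cc, 12), "", "", "", sep = "|"),
          t(r)
        )
      }
    }
  }
  if (max_components >= 2 && length(feats) >= 2) {
    for (a in seq_len(length(feats) - 1)) {
      for (b in (a + 1):length(feats)) {
        for (ca in cuts[[feats[a]]]) {
          for (cb in cuts[[feats[b]]]) {
            for (da in c("below", "above")) {
              for (db in c("below", "above")) {
                r <- eval_rule(list(
                  list(f = feats[a], d = da, c = ca),
                  list(f = feats[b], d = db, c = cb)
                ))
                rows[[length(rows) + 1]] <- data.frame(
                  key = paste(feats[a], da, signif(ca, 12),
                              feats[b], db, signif(cb, 12), sep = "|"),
                  t(r)
                )
              }
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$youden <- out$sens + out$spec - 1
  out
}

# Key for matching search_rules() rows against the brute-force oracle.
ranked_rule_key <- function(rk) {
  paste(rk$feature1, rk$direction1, signif(rk$cutoff1, 12),
        ifelse(is.na(rk$feature2), "", rk$feature2),
        ifelse(is.na(rk$direction2), "", rk$direction2),
        ifelse(is.na(rk$cutoff2), "", as.character(signif(rk$cutoff2, 12))),
        sep = "|")
}
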