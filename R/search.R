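# Exhaustive threshold-rule search: every directional cutoff on every base
# feature and pairwise ratio, and every two-component conjunction on
# distinct features, ranked by a declared criterion. All results are
# in-sample (resubstitution); no optimism correction is applied.

#' Decision-distinct candidate cutoffs
#'
#' Midpoints between consecutive distinct sorted values: the complete set
#' of thresholds that produce distinct classifications of the data.
#'
#' @param values Numeric feature values (`NA` dropped).
#' @return Numeric vector of cutoffs; empty when fewer than 2 distinct
#'   values remain.
#' @examples
#' candidate_cutoffs(c(1, 2, 4)) # 1.5, 3
#' @export
candidate_cutoffs <- function(values) {
  v <- sort(unique(values[!is.na(values)]))
  if (length(v) < 2) return(numeric())
  (v[-1] + v[-length(v)]) / 2
}

#' Define a rule search space
#'
#' @param base_features Feature columns searched directly.
#' @param ratio_pairs List of `c(numerator, denominator)` character pairs;
#'   each adds a derived feature `ratio_<num>_<den>` to the space. A pair
#'   with identical members is rejected.
#' @param max_components 1 (single thresholds only) or 2 (also all
#'   conjunctions of two thresholds on distinct features).
#' @return A list of class `rule_search_space`.
#' @export
rule_search_space <- function(base_features = c("mean_rgc_ipl", "mean_inl",
                                                "mean_opl", "onl"),
                              ratio_pairs = list(c("onl", "mean_opl"),
                                                 c("mean_inl", "mean_opl")),
                              max_components = 2) {
  stopifnot(max_components %in% 1:2, length(base_features) >= 1)
  for (rp in ratio_pairs) {
    if (length(rp) != 2 || rp[1] == rp[2]) {
      stop("each ratio pair must name two distinct features")
    }
  }
  structure(
    list(base_features = base_features, ratio_pairs = ratio_pairs,
         max_components = max_components),
    class = "rule_search_space"
  )
}

# Materialize the search-space feature columns (base + derived ratios).
.space_columns <- function(features, space) {
  missing_f <- setdiff(space$base_features, names(features))
  if (length(missing_f)) {
    stop("features table lacks columns: ", paste(missing_f, collapse = ", "))
  }
  cols <- features[, space$base_features, drop = FALSE]
  for (rp in space$ratio_pairs) {
    if (!all(rp %in% names(features))) {
      stop("ratio pair refers to unknown feature: ", paste(rp, collapse = "/"))
    }
    nm <- paste0("ratio_", rp[1], "_", rp[2])
    cols[[nm]] <- suppressWarnings(layer_ratio(features[[rp[1]]],
                                               features[[rp[2]]]))
  }
  cols
}

.rule_row <- function(f1, d1, c1, f2 = NA, d2 = NA, c2 = NA,
                      tp, fn, fp, tn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  data.frame(
    feature1 = f1, direction1 = d1, cutoff1 = c1,
    feature2 = f2, direction2 = d2, cutoff2 = c2,
    n_components = if (is.na(f2)) 1L else 2L,
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = sens, specificity = spec,
    youden = sens + spec - 1,
    stringsAsFactors = FALSE
  )
}

#' Exhaustive threshold-rule search
#'
#' Evaluates every single directional threshold rule over the
#' decision-distinct cutoff grid of every search-space feature, and (when
#' `max_components = 2`) every conjunction of two such rules on distinct
#' features, against the two-class labelling `positive_group` vs
#' `negative_groups`. Rules are ranked by the criterion; ties break
#' deterministically by fewer components, then feature name(s), then
#' smaller cutoff(s).
#'
#' Subjects missing a feature a rule needs are excluded from that rule's
#' two-by-two table only.
#'
#' @param features Feature data frame with `group` column.
#' @param positive_group,negative_groups Class labels as in
#'   [rule_confusion()].
#' @param space A [rule_search_space()].
#' @param criterion `"youden"` (sensitivity + specificity - 1, default) or
#'   `"lexicographic"` (maximal sensitivity, then maximal specificity).
#' @return Data frame of class `ranked_rules`, one row per searched rule,
#'   ordered best-first, with columns `rank`, rule spec columns
#'   (`feature1`, `direction1`, `cutoff1`, `feature2`, `direction2`,
#'   `cutoff2`, `n_components`), confusion counts, `sensitivity`,
#'   `specificity`, `youden`, `lr_pos`, `lr_neg`, and attribute
#'   `criterion`. All metrics are in-sample (resubstitution).
#' @export
search_rules <- function(features, positive_group, negative_groups,
                         space = rule_search_space(),
                         criterion = c("youden", "lexicographic")) {
  criterion <- match.arg(criterion)
  cols <- .space_columns(features, space)
  is_pos <- features$group %in% positive_group
  is_neg <- features$group %in% negative_groups
  if (!any(is_pos)) stop("positive class is empty")
  if (!any(is_neg)) stop("negative class is empty")

  feats <- names(cols)
  cuts <- lapply(cols, candidate_cutoffs)
  if (all(!lengths(cuts))) stop("empty search space: all features constant")

  # indicator matrices: subjects x cutoffs, TRUE = value < cutoff
  below <- lapply(feats, function(f) {
    outer(cols[[f]], cuts[[f]], `<`)
  })
  names(below) <- feats
  present <- lapply(cols, function(v) !is.na(v))

  res <- list()
  # single-component rules, both directions
  for (f in feats) {
    if (!length(cuts[[f]])) next
    ok <- present[[f]]
    npos <- sum(is_pos & ok)
    nneg <- sum(is_neg & ok)
    if (npos == 0 || nneg == 0) next
    B <- below[[f]]
    B[!ok, ] <- FALSE
    tp_b <- colSums(B[is_pos, , drop = FALSE])
    fp_b <- colSums(B[is_neg, , drop = FALSE])
    for (i in seq_along(cuts[[f]])) {
      res[[length(res) + 1]] <- .rule_row(
        f, "below", cuts[[f]][i],
        tp = tp_b[i], fn = npos - tp_b[i],
        fp = fp_b[i], tn = nneg - fp_b[i]
      )
      res[[length(res) + 1]] <- .rule_row(
        f, "above", cuts[[f]][i],
        tp = npos - tp_b[i], fn = tp_b[i],
        fp = nneg - fp_b[i], tn = fp_b[i]
      )
    }
  }

  # two-component conjunctions on distinct features
  if (space$max_components >= 2 && length(feats) >= 2) {
    for (a in seq_len(length(feats) - 1)) {
      for (b in (a + 1):length(feats)) {
        fa <- feats[a]; fb <- feats[b]
        if (!length(cuts[[fa]]) || !length(cuts[[fb]])) next
        ok <- present[[fa]] & present[[fb]]
        pos_ok <- is_pos & ok
        neg_ok <- is_neg & ok
        npos <- sum(pos_ok)
        nneg <- sum(neg_ok)
        if (npos == 0 || nneg == 0) next
        for (da in c("below", "above")) {
          A <- below[[fa]]
          if (da == "above") A <- !A
          for (db in c("below", "above")) {
            Bm <- below[[fb]]
            if (db == "above") Bm <- !Bm
            # tp[i, j] = #positives with A cutoff i and B cutoff j
            tp <- crossprod(A[pos_ok, , drop = FALSE] + 0,
                            Bm[pos_ok, , drop = FALSE] + 0)
            fp <- crossprod(A[neg_ok, , drop = FALSE] + 0,
                            Bm[neg_ok, , drop = FALSE] + 0)
            grid <- expand.grid(i = seq_along(cuts[[fa]]),
                                j = seq_along(cuts[[fb]]))
            res[[length(res) + 1]] <- .rule_row(
              fa, da, cuts[[fa]][grid$i],
              fb, db, cuts[[fb]][grid$j],
              tp = tp[cbind(grid$i, grid$j)],
              fn = npos - tp[cbind(grid$i, grid$j)],
              fp = fp[cbind(grid$i, grid$j)],
              tn = nneg - fp[cbind(grid$i, grid$j)]
            )
          }
        }
      }
    }
  }

  out <- do.call(rbind, res)
  out$lr_pos <- ifelse(out$specificity == 1, Inf,
                       out$sensitivity / (1 - out$specificity))
  out$lr_neg <- ifelse(out$specificity == 0, NA_real_,
                       (1 - out$sensitivity) / out$specificity)
  ord <- .rank_order(out, criterion)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("rank", setdiff(names(out), "rank"))]
  attr(out, "criterion") <- criterion
  class(out) <- c("ranked_rules", class(out))
  out
}

# Deterministic total order: criterion desc, then fewer components,
# feature names, smaller cutoffs.
.rank_order <- function(out, criterion) {
  key_feat <- paste(out$feature1, ifelse(is.na(out$feature2), "",
                                         out$feature2))
  if (criterion == "youden") {
    order(-out$youden, out$n_components, key_feat,
          out$cutoff1, out$cutoff2, method = "radix", na.last = TRUE)
  } else {
    order(-out$sensitivity, -out$specificity, out$n_components, key_feat,
          out$cutoff1, out$cutoff2, method = "radix", na.last = TRUE)
  }
}

#' Criterion value and rank of a named rule within a search
#'
#' Evaluates a rule (typically [psp_rule()]) on the same data and labelling
#' as a completed [search_rules()] result and reports its criterion value
#' and rank among all searched rules. A rule outside the searched space is
#' ranked by inserting its criterion value into the ranking (rank = 1 +
#' number of searched rules strictly better).
#'
#' @param rule A `threshold_rule` or `combined_rule`.
#' @param features Feature data frame used for the search.
#' @param positive_group,negative_groups Class labels as in the search.
#' @param ranked A `ranked_rules` result from [search_rules()] on the same
#'   data.
#' @return List with `metrics` (the rule's [diagnostic_metrics()]),
#'   `criterion_value`, `rank`, `n_rules_searched` and `n_tied_better`
#'   (searched rules with a strictly better criterion value).
#' @export
evaluate_rule_in_search <- function(rule, features, positive_group,
                                    negative_groups, ranked) {
  criterion <- attr(ranked, "criterion")
  conf <- rule_confusion(rule, features, positive_group, negative_groups)
  m <- diagnostic_metrics(conf)
  if (criterion == "lexicographic") {
    value <- c(m$sensitivity, m$specificity)
    better <- ranked$sensitivity > value[1] |
      (ranked$sensitivity == value[1] & ranked$specificity > value[2])
    crit_val <- value[1]
  } else {
    crit_val <- m$sensitivity + m$specificity - 1
    better <- ranked$youden > crit_val
  }
  n_better <- sum(better)
  list(
    metrics = m,
    criterion_value = crit_val,
    rank = n_better + 1L,
    n_rules_searched = nrow(ranked),
    n_tied_better = n_better
  )
}
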