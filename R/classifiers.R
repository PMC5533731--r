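#' Cut-off classifier for flagging rapid decliners
#'
#' A conjunction of one or two threshold conditions on clinical tests,
#' e.g. `ADAS11 > 10.5 AND ADAS13 > 19.0`.
#'
#' @param conditions data frame with columns `feature`, `relation`
#'   (`">"` or `"<"`) and `threshold`; 1 or 2 rows on distinct features.
#' @return a `cutoff_classifier`.
#' @export
new_cutoff_classifier <- function(conditions) {
  stopifnot(is.data.frame(conditions),
            nrow(conditions) %in% c(1L, 2L),
            all(conditions$relation %in% c(">", "<")),
            all(is.finite(conditions$threshold)))
  if (anyDuplicated(conditions$feature)) {
    stop("conditions must be on distinct tests")
  }
  structure(list(conditions = conditions), class = "cutoff_classifier")
}

#' @export
print.cutoff_classifier <- function(x, ...) {
  cat(paste(x$conditions$feature, x$conditions$relation,
            signif(x$conditions$threshold, 6), collapse = " AND "), "\n")
  invisible(x)
}

#' Serialize a classifier to JSON
#'
#' @param clf a `cutoff_classifier`.
#' @param path file path.
#' @export
write_classifier <- function(clf, path) {
  jsonlite::write_json(clf$conditions, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

classifier_fires <- function(clf, frame) {
  fires <- rep(TRUE, nrow(frame))
  for (k in seq_len(nrow(clf$conditions))) {
    v <- frame[[clf$conditions$feature[k]]]
    fires <- fires & if (clf$conditions$relation[k] == ">")
      v > clf$conditions$threshold[k] else v < clf$conditions$threshold[k]
  }
  fires
}

#' Sensitivity and specificity of a cut-off classifier
#'
#' Subjects missing any tested feature are excluded from the evaluation
#' (count in attribute `"n_excluded"`). Positives are the rapid
#' decliners; unclustered subjects belong to the negative class.
#'
#' @param clf a `cutoff_classifier`.
#' @param frame data frame with the feature columns and a logical/0-1
#'   column `label` (TRUE = rapid).
#' @return list with `sensitivity` and `specificity` in percent, plus the
#'   confusion counts `tp`, `fn`, `tn`, `fp`.
#' @export
evaluate_classifier <- function(clf, frame) {
  stopifnot(inherits(clf, "cutoff_classifier"), "label" %in% names(frame))
  feats <- clf$conditions$feature
  absent <- setdiff(feats, names(frame))
  if (length(absent) > 0L) {
    stop("frame lacks feature(s): ", paste(absent, collapse = ", "))
  }
  complete <- stats::complete.cases(frame[, feats, drop = FALSE]) &
    !is.na(frame$label)
  n_excluded <- sum(!complete)
  frame <- frame[complete, , drop = FALSE]
  y <- as.logical(frame$label)
  if (!any(y) || all(y)) {
    stop("undefined metrics: frame needs both positives and negatives")
  }
  fires <- classifier_fires(clf, frame)
  tp <- sum(fires & y)
  fn <- sum(!fires & y)
  tn <- sum(!fires & !y)
  fp <- sum(fires & !y)
  out <- list(sensitivity = 100 * tp / (tp + fn),
              specificity = 100 * tn / (tn + fp),
              tp = tp, fn = fn, tn = tn, fp = fp)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Candidate cut-offs: midpoints between consecutive observed values
#'
#' Midpoint scanning visits every achievable confusion table: the
#' classifier's decision is a step function of the threshold that can
#' only change between consecutive distinct observed values.
#'
#' @param values numeric feature values (need not be sorted or unique).
#' @return numeric vector of `k - 1` midpoints for `k` distinct values;
#'   empty when all values are equal.
#' @export
candidate_thresholds <- function(values) {
  u <- sort(unique(values[!is.na(values)]))
  if (length(u) < 2L) return(numeric(0L))
  (u[-1L] + u[-length(u)]) / 2
}

# vectorized J over all candidate thresholds of one feature/direction
scan_feature <- function(v, y, direction) {
  thr <- candidate_thresholds(v)
  if (length(thr) == 0L) return(NULL)
  npos <- sum(y)
  nneg <- sum(!y)
  fires_count <- function(t) {
    f <- if (direction == ">") v > t else v < t
    c(tp = sum(f & y), fp = sum(f & !y))
  }
  counts <- vapply(thr, fires_count, numeric(2L))
  sens <- counts["tp", ] / npos
  spec <- (nneg - counts["fp", ]) / nneg
  data.frame(threshold = thr, sensitivity = 100 * sens,
             specificity = 100 * spec, J = sens + spec - 1)
}

#' Best single-test cut-off by exhaustive threshold scan
#'
#' Scans every midpoint between consecutive distinct observed values of
#' the feature and returns the cut-off maximizing Youden's
#' J = sensitivity + specificity - 1 (the quality function; `"wracc"`
#' offers weighted relative accuracy instead). Ties are broken toward
#' higher specificity, then the lower threshold.
#'
#' @param feature feature column name.
#' @param frame labeled data frame (see [evaluate_classifier()]).
#' @param direction `">"` flags high values as rapid, `"<"` low values.
#' @param quality `"youden"` (default) or `"wracc"`.
#' @return a `cutoff_classifier` with attributes `"quality"` (training
#'   value of the quality function), `"sensitivity"`, `"specificity"`.
#' @export
search_univariate <- function(feature, frame, direction = ">",
                              quality = c("youden", "wracc")) {
  quality <- match.arg(quality)
  stopifnot(feature %in% names(frame), direction %in% c(">", "<"))
  ok <- !is.na(frame[[feature]]) & !is.na(frame$label)
  v <- frame[[feature]][ok]
  y <- as.logical(frame$label[ok])
  if (!any(y) || all(y)) stop("undefined: labels are degenerate")
  grid <- scan_feature(v, y, direction)
  if (is.null(grid)) stop("feature has fewer than 2 distinct values")
  q <- quality_values(grid, quality, npos = sum(y), n = length(y))
  best <- order(-q, -grid$specificity, grid$threshold)[1L]
  clf <- new_cutoff_classifier(data.frame(
    feature = feature, relation = direction,
    threshold = grid$threshold[best], stringsAsFactors = FALSE))
  attr(clf, "quality") <- q[best]
  attr(clf, "sensitivity") <- grid$sensitivity[best]
  attr(clf, "specificity") <- grid$specificity[best]
  clf
}

quality_values <- function(grid, quality, npos, n) {
  if (quality == "youden") return(grid$J)
  # WRAcc of the rule as a subgroup description of the positive class
  p_pos <- npos / n
  cov <- (grid$sensitivity / 100 * npos +
            (1 - grid$specificity / 100) * (n - npos)) / n
  prec <- ifelse(cov > 0, grid$sensitivity / 100 * npos / (cov * n), 0)
  cov * (prec - p_pos)
}

#' Best two-test conjunction by exhaustive grid search
#'
#' Grid search over the Cartesian product of both features' candidate
#' midpoint thresholds; maximizes the same quality function as
#' [search_univariate()]. Ties break toward higher specificity, then the
#' lower first threshold, then the lower second.
#'
#' @param f1,f2 feature column names (distinct).
#' @param frame labeled data frame.
#' @param directions length-2 vector of `">"`/`"<"`.
#' @inheritParams search_univariate
#' @return a `cutoff_classifier` with the same attributes as
#'   [search_univariate()].
#' @export
search_conjunction <- function(f1, f2, frame, directions = c(">", ">"),
                               quality = c("youden", "wracc")) {
  quality <- match.arg(quality)
  stopifnot(f1 != f2, all(c(f1, f2) %in% names(frame)),
            length(directions) == 2L)
  ok <- !is.na(frame[[f1]]) & !is.na(frame[[f2]]) & !is.na(frame$label)
  v1 <- frame[[f1]][ok]
  v2 <- frame[[f2]][ok]
  y <- as.logical(frame$label[ok])
  if (!any(y) || all(y)) stop("undefined: labels are degenerate")
  t1 <- candidate_thresholds(v1)
  t2 <- candidate_thresholds(v2)
  if (length(t1) == 0L || length(t2) == 0L) {
    stop("both features need at least 2 distinct values")
  }
  npos <- sum(y)
  nneg <- sum(!y)
  best <- NULL
  for (a in t1) {
    m1 <- if (directions[1L] == ">") v1 > a else v1 < a
    for (b in t2) {
      fires <- m1 & (if (directions[2L] == ">") v2 > b else v2 < b)
      sens <- sum(fires & y) / npos
      spec <- sum(!fires & !y) / nneg
      grid1 <- data.frame(threshold = a, sensitivity = 100 * sens,
                          specificity = 100 * spec, J = sens + spec - 1)
      q <- quality_values(grid1, quality, npos, length(y))
      cand <- c(q, 100 * spec, -a, -b)
      if (is.null(best) || lex_greater(cand, best$key)) {
        best <- list(key = cand, t1 = a, t2 = b,
                     sens = 100 * sens, spec = 100 * spec, q = q)
      }
    }
  }
  clf <- new_cutoff_classifier(data.frame(
    feature = c(f1, f2), relation = directions,
    threshold = c(best$t1, best$t2), stringsAsFactors = FALSE))
  attr(clf, "quality") <- best$q
  attr(clf, "sensitivity") <- best$sens
  attr(clf, "specificity") <- best$spec
  clf
}

lex_greater <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}

#' Train-then-validate a classifier across cohorts
#'
#' Freezes the classifier after training (or accepts a prespecified one)
#' and reports sensitivity/specificity side by side for the training and
#' validation cohorts, the standard replication layout.
#'
#' @param clf a `cutoff_classifier` (e.g. from a search on `train_frame`).
#' @param train_frame,test_frame labeled frames with disjoint `cohort`
#'   tags (checked when both carry a `cohort` column).
#' @return one-row data frame: `classifier`, `train_sensitivity`,
#'   `train_specificity`, `test_sensitivity`, `test_specificity`.
#' @export
cross_cohort_validate <- function(clf, train_frame, test_frame) {
  if ("cohort" %in% names(train_frame) && "cohort" %in% names(test_frame)) {
    overlap <- intersect(unique(train_frame$cohort),
                         unique(test_frame$cohort))
    if (length(overlap) > 0L) {
      stop("validation error: cohorts overlap: ",
           paste(overlap, collapse = ", "))
    }
  }
  tr <- evaluate_classifier(clf, train_frame)
  te <- evaluate_classifier(clf, test_frame)
  data.frame(
    classifier = paste(clf$conditions$feature, clf$conditions$relation,
                       signif(clf$conditions$threshold, 6),
                       collapse = " AND "),
    train_sensitivity = tr$sensitivity, train_specificity = tr$specificity,
    test_sensitivity = te$sensitivity, test_specificity = te$specificity,
    stringsAsFactors = FALSE)
}

#' Build a labeled classifier frame from a cohort and clustering
#'
#' Rapid decliners (the given cluster label) are the positive class; all
#' other subjects, including unclustered ones, form the negative class.
#'
#' @param cohort a `cohort_table`.
#' @param clustering a `clustering`.
#' @param rapid_label label of the rapid-decliner cluster.
#' @param features baseline feature columns to carry.
#' @return data frame with the features, `label` and `cohort`.
#' @export
classifier_frame <- function(cohort, clustering, rapid_label,
                             features = c("ADAS11", "ADAS13", "MMSE",
                                          "RAVLT_immediate")) {
  stopifnot(inherits(cohort, "cohort_table"))
  ids <- cohort$subjects$subject_id
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (f in features) {
    out[[f]] <- cohort$baseline[[f]][match(ids, cohort$baseline$subject_id)]
  }
  out$label <- clustering$label[match(ids, clustering$subject_id)] ==
    rapid_label
  out$cohort <- cohort$subjects$cohort
  out
}
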