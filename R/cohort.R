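#' Default descriptor schema
#'
#' Declares the descriptors used by the default two-layer analysis of an
#' MCI-like longitudinal cohort: 26 baseline descriptors (demographics,
#' cognitive and functional scales, MRI volumes, PET SUVRs, CSF proteins)
#' and 17 longitudinal descriptors whose per-subject slopes form the second
#' (prognostic) layer. Slope descriptors are named by prefixing the base
#' descriptor with `"S"`, e.g. `SADAS13` is the slope of `ADAS13`.
#'
#' @param path optional path to a YAML file overriding any of the fields
#'   `baseline`, `longitudinal`, `binary`, `higher_is_worse`.
#' @return a list with character vectors `baseline`, `longitudinal`,
#'   `slope_names`, `binary` (0/1 descriptors tested by chi-square rather
#'   than rank tests) and `higher_is_worse` (direction of clinical
#'   worsening, used only for reporting).
#' @export
default_schema <- function(path = NULL) {
  schema <- list(
    baseline = c(
      "Age", "Gender", "Education", "APOE4",
      "CDRSB", "ADAS11", "ADAS13", "MMSE", "MOCA", "FAQ",
      "RAVLT_immediate", "RAVLT_learning", "RAVLT_forgetting",
      "RAVLT_pforgetting",
      "Ventricles", "Hippocampus", "WholeBrain", "Entorhinal",
      "Fusiform", "MidTemp", "ICV",
      "FDG", "AV45", "ABETA", "TAU", "PTAU"
    ),
    longitudinal = c(
      "CDRSB", "ADAS11", "ADAS13", "MMSE", "FAQ", "MOCA",
      "RAVLT_immediate", "RAVLT_learning", "RAVLT_forgetting",
      "RAVLT_pforgetting",
      "Ventricles", "Hippocampus", "WholeBrain", "Entorhinal",
      "Fusiform", "MidTemp", "ICV"
    ),
    binary = c("Gender", "APOE4"),
    higher_is_worse = c(
      "CDRSB", "ADAS11", "ADAS13", "FAQ", "RAVLT_forgetting",
      "RAVLT_pforgetting", "Ventricles", "TAU", "PTAU", "AV45"
    )
  )
  if (!is.null(path)) {
    override <- yaml::read_yaml(path)
    for (field in intersect(names(override), names(schema))) {
      schema[[field]] <- as.character(override[[field]])
    }
  }
  schema$slope_names <- paste0("S", schema$longitudinal)
  schema
}

#' Read a long-format subject-visit table into a cohort
#'
#' Expects delimited text with one row per subject-visit: required columns
#' `subject_id`, `month`, `diagnosis`, optional `cohort` and `sex`, plus
#' one numeric column per descriptor named in the schema. Baseline
#' descriptors are taken from each subject's earliest visit (screening or
#' baseline, whichever was recorded first). Subjects failing the inclusion
#' rule -- at least one post-baseline visit with a value for at least one
#' longitudinal descriptor -- are dropped and the drop count reported.
#'
#' @param path CSV file path.
#' @param schema descriptor schema, see [default_schema()].
#' @param max_month follow-up cap in months; visits beyond it are discarded
#'   (default 60, i.e. 5 years).
#' @return a `cohort_table` object: list with data frames `subjects`
#'   (subject_id, cohort, sex), `baseline` (one row per subject) and
#'   `visits` (long format, longitudinal descriptors only).
#' @export
read_cohort <- function(path, schema = default_schema(), max_month = 60) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort_table(raw, schema = schema, max_month = max_month)
}

#' Assemble a cohort from a long-format data frame
#'
#' @param df data frame in the layout accepted by [read_cohort()].
#' @inheritParams read_cohort
#' @return a `cohort_table`.
#' @export
as_cohort_table <- function(df, schema = default_schema(), max_month = 60) {
  required <- c("subject_id", "month", "diagnosis")
  missing_cols <- setdiff(required, names(df))
  if (nrow(df) == 0L || length(missing_cols) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(if (nrow(df) == 0L) required else missing_cols, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)

  numeric_cols <- intersect(
    unique(c("month", schema$baseline, schema$longitudinal)), names(df))
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      v[v == ""] <- NA
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad) > 0L) {
        stop("parse error: non-numeric value in column '", col,
             "' at row ", bad[1L])
      }
      df[[col]] <- parsed
    }
  }
  if (anyNA(df$month) || any(df$month < 0)) {
    stop("parse error: 'month' must be a non-negative number on every row")
  }
  dup <- duplicated(df[, c("subject_id", "month")])
  if (any(dup)) {
    stop("parse error: duplicate (subject, month) rows, first at row ",
         which(dup)[1L])
  }

  df <- df[df$month <= max_month, , drop = FALSE]
  df <- df[order(df$subject_id, df$month), , drop = FALSE]

  long_cols <- intersect(schema$longitudinal, names(df))
  split_rows <- split(seq_len(nrow(df)), df$subject_id)
  keep <- vapply(split_rows, function(idx) {
    sub <- df[idx, , drop = FALSE]
    post <- sub[sub$month > min(sub$month), long_cols, drop = FALSE]
    nrow(post) > 0L && any(!is.na(as.matrix(post)))
  }, logical(1L))
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " subject(s) dropped: no post-baseline visit data")
  }
  ids <- names(split_rows)[keep]
  df <- df[df$subject_id %in% ids, , drop = FALSE]

  first_rows <- df[!duplicated(df$subject_id), , drop = FALSE]
  base_cols <- intersect(schema$baseline, names(df))
  baseline <- data.frame(subject_id = first_rows$subject_id,
                         first_rows[, base_cols, drop = FALSE],
                         check.names = FALSE, row.names = NULL)
  subjects <- data.frame(
    subject_id = first_rows$subject_id,
    cohort = if ("cohort" %in% names(first_rows))
      as.character(first_rows$cohort) else NA_character_,
    sex = if ("sex" %in% names(first_rows))
      as.character(first_rows$sex) else NA_character_,
    stringsAsFactors = FALSE
  )
  visits <- df[, c("subject_id", "month", "diagnosis", long_cols),
               drop = FALSE]
  rownames(visits) <- NULL

  structure(
    list(subjects = subjects, baseline = baseline, visits = visits,
         schema = schema, n_dropped = n_dropped),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$subjects), "subjects,",
      nrow(x$visits), "visits,",
      ncol(x$baseline) - 1L, "baseline descriptors\n")
  invisible(x)
}

#' Write a cohort back to long-format CSV
#'
#' Inverse of [read_cohort()]: one row per subject-visit, baseline-only
#' descriptors recorded on the subject's first visit row.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  long <- cohort$visits
  long$cohort <- cohort$subjects$cohort[
    match(long$subject_id, cohort$subjects$subject_id)]
  long$sex <- cohort$subjects$sex[
    match(long$subject_id, cohort$subjects$subject_id)]
  base_only <- setdiff(names(cohort$baseline),
                       c("subject_id", names(long)))
  first <- !duplicated(long$subject_id)
  for (d in base_only) {
    long[[d]] <- NA_real_
    long[[d]][first] <- cohort$baseline[[d]][
      match(long$subject_id[first], cohort$baseline$subject_id)]
  }
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Longitudinal slope of a measurement series
#'
#' Ordinary least-squares slope of value on visit month, rescaled to the
#' mean change per 6-month period, using all visits with a non-missing
#' value. Returns `NA` (an undefined slope, not an error) when fewer than
#' two complete points remain or all months coincide.
#'
#' @param months visit times in months from baseline.
#' @param values measurements at those visits (may contain `NA`).
#' @return slope per 6 months, or `NA_real_` if undefined.
#' @export
compute_slope <- function(months, values) {
  stopifnot(length(months) == length(values))
  ok <- !is.na(months) & !is.na(values)
  m <- months[ok]
  v <- values[ok]
  if (length(m) < 2L || length(unique(m)) < 2L) return(NA_real_)
  mc <- m - mean(m)
  6 * sum(mc * v) / sum(mc * mc)
}

#' Build the baseline and slope data layers
#'
#' Layer 1 holds the baseline descriptor matrix; layer 2 holds per-subject
#' slopes (per 6 months) of the longitudinal descriptors, estimated with
#' [compute_slope()]. Both layers share the subject (row) order of the
#' cohort. A subject with too few visits for some slope gets a missing cell
#' but keeps its row.
#'
#' @param cohort a `cohort_table`.
#' @param baseline_names baseline descriptors to include (default: schema).
#' @param slope_names slope descriptors (`"S"`-prefixed) to include.
#' @return a list of two `data_layer` objects named `baseline` and `slope`;
#'   each carries `layer_id`, a numeric `matrix` with subject-id rownames,
#'   and `descriptor_names`.
#' @export
build_layers <- function(cohort,
                         baseline_names = cohort$schema$baseline,
                         slope_names = cohort$schema$slope_names) {
  stopifnot(inherits(cohort, "cohort_table"))
  schema <- cohort$schema
  unknown <- setdiff(baseline_names, schema$baseline)
  if (length(unknown) > 0L) {
    stop("configuration error: unknown baseline descriptor(s): ",
         paste(unknown, collapse = ", "))
  }
  bad_slope <- slope_names[!(slope_names %in% paste0("S", schema$longitudinal))]
  if (length(bad_slope) > 0L) {
    stop("configuration error: unknown slope descriptor(s): ",
         paste(bad_slope, collapse = ", "))
  }
  ids <- cohort$subjects$subject_id

  base_avail <- intersect(baseline_names, names(cohort$baseline))
  bmat <- matrix(NA_real_, nrow = length(ids), ncol = length(baseline_names),
                 dimnames = list(ids, baseline_names))
  for (d in base_avail) {
    bmat[, d] <- cohort$baseline[[d]][match(ids, cohort$baseline$subject_id)]
  }

  bases <- substring(slope_names, 2L)
  smat <- matrix(NA_real_, nrow = length(ids), ncol = length(slope_names),
                 dimnames = list(ids, slope_names))
  visit_rows <- split(seq_len(nrow(cohort$visits)), cohort$visits$subject_id)
  for (i in seq_along(ids)) {
    idx <- visit_rows[[ids[i]]]
    if (is.null(idx)) next
    mo <- cohort$visits$month[idx]
    for (k in seq_along(bases)) {
      if (!bases[k] %in% names(cohort$visits)) next
      smat[i, k] <- compute_slope(mo, cohort$visits[[bases[k]]][idx])
    }
  }

  list(
    baseline = new_data_layer("baseline", bmat),
    slope = new_data_layer("slope", smat)
  )
}

new_data_layer <- function(layer_id, matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1L)
  structure(
    list(layer_id = layer_id, matrix = matrix,
         descriptor_names = colnames(matrix)),
    class = "data_layer"
  )
}

#' @export
print.data_layer <- function(x, ...) {
  cat("data_layer '", x$layer_id, "': ", nrow(x$matrix), " x ",
      ncol(x$matrix), " (", sum(is.na(x$matrix)), " missing cells)\n",
      sep = "")
  invisible(x)
}

#' Median-impute a layer for similarity computation
#'
#' Replaces missing cells by the column median of the non-missing values
#' (midpoint of the two central order statistics for an even count).
#' Used only to keep the rule
#' learner and similarity table defined for subjects with block-missing
#' biomarkers; reported statistics always use the raw (unimputed) values.
#' The returned layer carries the logical imputation mask as attribute
#' `"imputed"`.
#'
#' @param layer a `data_layer`.
#' @return an imputed `data_layer`; the input is unchanged.
#' @export
impute_for_similarity <- function(layer) {
  stopifnot(inherits(layer, "data_layer"))
  m <- layer$matrix
  full_miss <- colSums(!is.na(m)) == 0L
  if (any(full_miss)) {
    stop("configuration error: fully-missing descriptor(s): ",
         paste(colnames(m)[full_miss], collapse = ", "))
  }
  mask <- is.na(m)
  for (j in seq_len(ncol(m))) {
    if (!any(mask[, j])) next
    m[mask[, j], j] <- stats::median(m[!mask[, j], j])
  }
  out <- new_data_layer(layer$layer_id, m)
  attr(out, "imputed") <- mask
  out
}
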