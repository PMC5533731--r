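#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test with the tie-corrected normal
#' approximation z-statistic (as reported in cluster-contrast tables).
#' For small samples (`n_a + n_b <= exact_max`) the p-value is computed by
#' exhaustive enumeration of all group assignments of the pooled values,
#' counting permutations at least as extreme (|U - E[U]| symmetric tail),
#' which is exact under ties as well.
#'
#' @param a,b numeric samples; missing values are removed.
#' @param exact_max largest pooled size for which the exact enumeration is
#'   used (default 10).
#' @return list with `U` (for sample `a`), `z`, `p`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, exact_max = 10L) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty after missing-value removal")
  }
  n1 <- length(a)
  n2 <- length(b)
  n <- n1 + n2
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(U = n1 * n2 / 2, z = 0, p = 1, n_a = n1, n_b = n2))
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0

  if (n <= exact_max) {
    picks <- utils::combn(n, n1)
    u_all <- apply(picks, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    eps <- 1e-9
    p <- mean(abs(u_all - mu) >= abs(U - mu) - eps)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, z = z, p = min(p, 1), n_a = n1, n_b = n2)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction), df = 1. A zero row or column
#' margin makes the statistic undefined; this is reported, not raised.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return list with `statistic`, `p`, `undefined`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, undefined = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       undefined = FALSE)
}

# raw (unimputed) descriptor value matrix: baseline columns + slope columns
descriptor_values <- function(cohort) {
  layers <- build_layers(cohort)
  cbind(layers$baseline$matrix, layers$slope$matrix)
}

#' Cluster contrast table
#'
#' Per-descriptor group means and SDs on non-missing values plus a
#' two-group test: Mann-Whitney (reported as |z|) for numeric
#' descriptors, chi-square for binary indicators such as APOE4 carrier
#' status. Restricting to one sex reproduces the sex-stratified design.
#'
#' @param cohort a `cohort_table`.
#' @param clustering a `clustering` from [label_unclustered()].
#' @param descriptors descriptor names (baseline or `"S"`-slopes); default
#'   all schema descriptors.
#' @param labels the two cluster labels to contrast (default `cluster_1`
#'   vs `cluster_2`).
#' @param stratum optional sex value (`"Female"`/`"Male"`) to restrict to.
#' @param adjust add a Benjamini-Hochberg adjusted p column (off by
#'   default, mirroring per-descriptor reporting).
#' @return data frame with one row per descriptor: per-group n, mean, sd,
#'   `test`, `statistic`, `p`.
#' @export
compare_clusters <- function(cohort, clustering, descriptors = NULL,
                             labels = c("cluster_1", "cluster_2"),
                             stratum = NULL, adjust = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"), length(labels) == 2L)
  vals <- descriptor_values(cohort)
  if (is.null(descriptors)) {
    descriptors <- colnames(vals)
  }
  absent <- setdiff(descriptors, colnames(vals))
  if (length(absent) > 0L) {
    warning("skipping unknown descriptor(s): ",
            paste(absent, collapse = ", "))
    descriptors <- intersect(descriptors, colnames(vals))
  }
  lab <- clustering$label[match(rownames(vals), clustering$subject_id)]
  keep <- lab %in% labels
  if (!is.null(stratum)) {
    sex <- cohort$subjects$sex[match(rownames(vals),
                                     cohort$subjects$subject_id)]
    keep <- keep & !is.na(sex) & sex == stratum
  }
  if (length(unique(lab[keep])) < 2L) {
    stop("need at least two named clusters with members")
  }
  binary <- cohort$schema$binary

  rows <- lapply(descriptors, function(d) {
    v <- vals[keep, d]
    g <- lab[keep]
    v1 <- v[g == labels[1L] & !is.na(v)]
    v2 <- v[g == labels[2L] & !is.na(v)]
    row <- data.frame(
      descriptor = d,
      n_1 = length(v1), mean_1 = mean(v1), sd_1 = stats::sd(v1),
      n_2 = length(v2), mean_2 = mean(v2), sd_2 = stats::sd(v2),
      test = NA_character_, statistic = NA_real_, p = NA_real_,
      stringsAsFactors = FALSE)
    if (length(v1) < 2L || length(v2) < 2L) return(row)  # degenerate
    if (d %in% binary) {
      tab <- rbind(c(sum(v1 == 1), sum(v1 != 1)),
                   c(sum(v2 == 1), sum(v2 != 1)))
      ct <- chi_square_2x2(tab)
      row$test <- "chi_square"
      row$statistic <- ct$statistic
      row$p <- ct$p
    } else {
      mw <- mann_whitney(v1, v2)
      row$test <- "mann_whitney"
      row$statistic <- abs(mw$z)
      row$p <- mw$p
    }
    row
  })
  if (length(rows) == 0L) {
    return(data.frame(descriptor = character(), test = character(),
                      statistic = numeric(), p = numeric()))
  }
  out <- do.call(rbind, rows)
  nm <- names(out)
  is1 <- grepl("_1$", nm)
  is2 <- grepl("_2$", nm)
  nm[is1] <- sub("_1$", paste0("_", labels[1L]), nm[is1])
  nm[is2] <- sub("_2$", paste0("_", labels[2L]), nm[is2])
  names(out) <- nm
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Diagnosis transition report
#'
#' Counts, per cluster and overall, subjects who converted (any visit
#' diagnosed Dementia), reverted (any visit Cognitively Normal and none
#' Dementia -- a later dementia diagnosis supersedes reversion) or stayed
#' stable, with rates as percentages. Subjects without any post-baseline
#' diagnosis count as stable.
#'
#' @param cohort a `cohort_table`.
#' @param clustering optional `clustering`; omitted, a single overall row
#'   is returned.
#' @return data frame with columns `group`, `n`, `converted`, `reverted`,
#'   `stable`, `conversion_pct`, `reversion_pct`, `stable_pct`.
#' @export
transition_rates <- function(cohort, clustering = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  ids <- cohort$subjects$subject_id
  dx <- split(cohort$visits$diagnosis, cohort$visits$subject_id)
  state <- vapply(ids, function(id) {
    d <- dx[[id]]
    if (is.null(d)) return("stable")
    if (any(d == "Dementia", na.rm = TRUE)) "converted"
    else if (any(d == "CN", na.rm = TRUE)) "reverted"
    else "stable"
  }, character(1L))
  n_nodx <- sum(vapply(ids, function(id) {
    idx <- cohort$visits$subject_id == id
    mo <- cohort$visits$month[idx]
    all(is.na(cohort$visits$diagnosis[idx][mo > min(mo)]))
  }, logical(1L)))
  if (n_nodx > 0L) {
    message(n_nodx, " subject(s) without post-baseline diagnosis counted ",
            "as stable")
  }

  groups <- if (is.null(clustering)) {
    rep("all", length(ids))
  } else {
    clustering$label[match(ids, clustering$subject_id)]
  }
  tally <- function(sel, name) {
    n <- sum(sel)
    conv <- sum(state[sel] == "converted")
    rev_ <- sum(state[sel] == "reverted")
    data.frame(group = name, n = n, converted = conv, reverted = rev_,
               stable = n - conv - rev_,
               conversion_pct = 100 * conv / n,
               reversion_pct = 100 * rev_ / n,
               stable_pct = 100 * (n - conv - rev_) / n,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g)
    tally(groups == g, g)))
  if (!is.null(clustering)) {
    out <- rbind(out, tally(rep(TRUE, length(ids)), "all"))
  }
  rownames(out) <- NULL
  out
}
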