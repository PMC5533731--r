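#' @name crv
#' @title Clustering-related variability (CRV)
#'
#' @description
#' The clustering objective. For instance `i` in cluster `C`, the
#' within-cluster term is the sum of squared deviations of the
#' similarities `x_ij` (j in C, j != i) around their mean, and the
#' outside-cluster term the same over all j outside C. `CRV_i` is their
#' sum, and the cluster score `CRV_C` adds `CRV_i` over members. A merge
#' of clusters a and b is worth `DIFF_ab = CRV_a + CRV_b - CRV_{a u b}`,
#' positive exactly when merging reduces the variability. Empty index
#' sets contribute zero; in particular a singleton cluster has zero
#' within-cluster variability.
NULL

# normalize a partition to a list of integer member vectors
as_partition <- function(partition, N) {
  if (is.list(partition)) {
    parts <- lapply(partition, function(p) sort(as.integer(p)))
  } else {
    assign <- as.integer(partition)
    stopifnot(length(assign) == N)
    parts <- unname(split(seq_len(N), assign))
  }
  members <- sort(unlist(parts))
  if (!identical(members, seq_len(N))) {
    stop("partition must cover 1..N exactly once")
  }
  if (any(lengths(parts) == 0L)) stop("empty cluster in partition")
  parts
}

# sum of squares around the mean via sums; clamped at zero
ss_term <- function(s1, s2, n) {
  n <- rep_len(n, length(s1))
  out <- numeric(length(s1))
  pos <- n > 0L
  out[pos] <- pmax(s2[pos] - s1[pos] * s1[pos] / n[pos], 0)
  out
}

#' Per-instance CRV terms
#'
#' @param est a `similarity_table` or symmetric matrix.
#' @param partition list of member-index vectors, or an integer cluster
#'   assignment of length N.
#' @param i instance index.
#' @return named numeric `c(wc = , oc = )`.
#' @rdname crv
#' @export
crv_instance <- function(est, partition, i) {
  x <- est_matrix(est)
  N <- nrow(x)
  if (i < 1L || i > N) stop("instance index out of range")
  parts <- as_partition(partition, N)
  C <- parts[[which(vapply(parts, function(p) i %in% p, logical(1L)))]]
  within <- setdiff(C, i)
  outside <- setdiff(seq_len(N), C)
  xw <- x[i, within]
  xo <- x[i, outside]
  c(wc = ss_term(sum(xw), sum(xw^2), length(within)),
    oc = ss_term(sum(xo), sum(xo^2), length(outside)))
}

#' Cluster CRV
#'
#' @param C member-index vector; must equal one cluster of the partition.
#' @rdname crv
#' @export
crv_cluster <- function(est, partition, C) {
  x <- est_matrix(est)
  parts <- as_partition(partition, nrow(x))
  C <- sort(as.integer(C))
  if (!any(vapply(parts, identical, logical(1L), y = C))) {
    stop("unknown cluster: not a member of the partition")
  }
  sum(vapply(C, function(i) sum(crv_instance(x, parts, i)), numeric(1L)))
}

#' Variability reduction of merging two clusters
#'
#' @param a,b member-index vectors of two distinct clusters of the
#'   partition.
#' @rdname crv
#' @export
diff_merge <- function(est, partition, a, b) {
  x <- est_matrix(est)
  parts <- as_partition(partition, nrow(x))
  a <- sort(as.integer(a))
  b <- sort(as.integer(b))
  if (identical(a, b)) stop("cannot merge a cluster with itself")
  ia <- which(vapply(parts, identical, logical(1L), y = a))
  ib <- which(vapply(parts, identical, logical(1L), y = b))
  if (length(ia) != 1L || length(ib) != 1L) {
    stop("unknown cluster: not a member of the partition")
  }
  merged_parts <- c(parts[-c(ia, ib)], list(sort(c(a, b))))
  crv_cluster(x, parts, a) + crv_cluster(x, parts, b) -
    crv_cluster(x, merged_parts, c(a, b))
}

#' Joint (multilayer) merge value: the minimum over layers
#'
#' @param ests list of similarity tables sharing N and subject order.
#' @rdname crv
#' @export
joint_diff <- function(ests, partition, a, b) {
  if (inherits(ests, "similarity_table") || is.matrix(ests)) {
    ests <- list(ests)
  }
  ns <- vapply(ests, function(e) nrow(est_matrix(e)), integer(1L))
  if (length(unique(ns)) != 1L) stop("layers disagree on N")
  min(vapply(ests, diff_merge, numeric(1L),
             partition = partition, a = a, b = b))
}

# ---- fast agglomeration ---------------------------------------------------

# per-layer precomputation for incremental CRV sums
layer_state <- function(x) {
  x0 <- x
  diag(x0) <- 0
  x2 <- x0 * x0
  list(x0 = x0, x2 = x2, t1 = rowSums(x0), t2 = rowSums(x2))
}

# total CRV of cluster A (contribution of its members), one layer
crv_members <- function(st, A, N) {
  s1 <- rowSums(st$x0[A, A, drop = FALSE])
  s2 <- rowSums(st$x2[A, A, drop = FALSE])
  nw <- length(A) - 1L
  no <- N - length(A)
  wc <- ss_term(s1, s2, nw)
  oc <- ss_term(st$t1[A] - s1, st$t2[A] - s2, no)
  sum(wc + oc)
}

pair_diff_fast <- function(st, A, B, N) {
  crv_members(st, A, N) + crv_members(st, B, N) -
    crv_members(st, sort(c(A, B)), N)
}

# joint diff matrix over all singleton pairs, vectorized per layer
singleton_diff_matrix <- function(states, N) {
  layer_mats <- lapply(states, function(st) {
    crv1 <- ss_term(st$t1, st$t2, N - 1L)        # singleton CRV_i
    no <- N - 2L
    s1o <- matrix(st$t1, N, N) - st$x0
    s2o <- matrix(st$t2, N, N) - st$x2
    oc <- if (no > 0L) pmax(s2o - s1o * s1o / no, 0) else
      matrix(0, N, N)
    outer(crv1, crv1, `+`) - (oc + t(oc))
  })
  D <- Reduce(pmin, layer_mats)
  diag(D) <- -Inf
  D
}

#' Multilayer agglomerative clustering by CRV minimization
#'
#' Starts from all-singleton clusters and repeatedly merges the pair of
#' clusters with the largest joint `DIFF` (the minimum across layers of
#' the per-layer variability reduction), while that maximum is strictly
#' positive. Ties are broken toward the pair with the lexicographically
#' smallest cluster ids, ids being the smallest member index, which makes
#' the procedure deterministic. When no merge can reduce variability in
#' every layer the current partition is returned as optimal.
#'
#' @param ests one `similarity_table` (or matrix), or a list of them, one
#'   per data layer, sharing N and subject order.
#' @return a `merge_trace`: list with `merges` (data frame of executed
#'   merges with per-layer and joint DIFF), `partition` (integer cluster
#'   id per subject; id = smallest member index), `subject_ids`, and `N`.
#' @export
mlc_cluster <- function(ests) {
  if (inherits(ests, "similarity_table") || is.matrix(ests)) {
    ests <- list(ests)
  }
  mats <- lapply(ests, est_matrix)
  N <- nrow(mats[[1L]])
  stopifnot(N >= 2L)
  if (any(vapply(mats, nrow, integer(1L)) != N)) {
    stop("layers disagree on N")
  }
  ids <- rownames(mats[[1L]])
  if (is.null(ids)) ids <- as.character(seq_len(N))
  states <- lapply(mats, layer_state)
  L <- length(states)

  members <- lapply(seq_len(N), identity)   # cluster id = min member index
  names(members) <- as.character(seq_len(N))
  D <- singleton_diff_matrix(states, N)
  dimnames(D) <- list(names(members), names(members))
  # per-layer diffs recomputed on demand for the trace
  merges <- list()

  repeat {
    best <- max(D)
    if (!(best > 0)) break
    hits <- which(D == best, arr.ind = TRUE)
    cand_a <- as.integer(rownames(D)[hits[, 1L]])
    cand_b <- as.integer(colnames(D)[hits[, 2L]])
    lo <- pmin(cand_a, cand_b)
    hi <- pmax(cand_a, cand_b)
    pick <- order(lo, hi)[1L]
    a <- min(lo[pick], hi[pick])
    b <- max(lo[pick], hi[pick])

    A <- members[[as.character(a)]]
    B <- members[[as.character(b)]]
    layer_diffs <- vapply(states, pair_diff_fast, numeric(1L),
                          A = A, B = B, N = N)
    merges[[length(merges) + 1L]] <- data.frame(
      step = length(merges) + 1L, id_a = a, id_b = b,
      size_a = length(A), size_b = length(B),
      t(stats::setNames(layer_diffs, paste0("diff_layer", seq_len(L)))),
      joint_diff = min(layer_diffs))

    # merge b into a (a < b), update members and the joint-DIFF matrix
    members[[as.character(a)]] <- sort(c(A, B))
    members[[as.character(b)]] <- NULL
    keep <- rownames(D) != as.character(b)
    D <- D[keep, keep, drop = FALSE]
    if (nrow(D) < 2L) break
    Anew <- members[[as.character(a)]]
    others <- setdiff(rownames(D), as.character(a))
    for (o in others) {
      jd <- min(vapply(states, pair_diff_fast, numeric(1L),
                       A = Anew, B = members[[o]], N = N))
      D[as.character(a), o] <- jd
      D[o, as.character(a)] <- jd
    }
  }

  partition <- integer(N)
  for (id in names(members)) partition[members[[id]]] <- as.integer(id)
  structure(
    list(
      merges = if (length(merges) > 0L) do.call(rbind, merges) else
        data.frame(step = integer(), id_a = integer(), id_b = integer(),
                   size_a = integer(), size_b = integer(),
                   joint_diff = numeric()),
      partition = stats::setNames(partition, ids),
      subject_ids = ids, N = N, n_layers = L,
      best_remaining_diff = if (is.matrix(D) && any(is.finite(D)))
        max(D[is.finite(D)]) else NA_real_
    ),
    class = "merge_trace")
}

#' @export
print.merge_trace <- function(x, ...) {
  k <- length(unique(x$partition))
  cat("merge_trace:", nrow(x$merges), "merges on N =", x$N, "->",
      k, "clusters\n")
  invisible(x)
}

#' Flag small final clusters as unclustered
#'
#' Mirrors the reporting convention in which only sizeable clusters are
#' named and the remaining subjects stay simply unclustered. Named
#' clusters are ranked by decreasing size (`cluster_1` largest).
#'
#' @param trace a `merge_trace` from [mlc_cluster()].
#' @param min_size smallest cluster size that earns a name (default 20).
#' @return a `clustering`: data frame with columns `subject_id`,
#'   `cluster` (numeric id from the trace) and `label` (`cluster_k` or
#'   `"unclustered"`).
#' @export
label_unclustered <- function(trace, min_size = 20L) {
  stopifnot(inherits(trace, "merge_trace"), min_size >= 1L)
  sizes <- table(trace$partition)
  named <- names(sizes)[sizes >= min_size]
  named <- named[order(-sizes[named], as.integer(named))]
  lab <- stats::setNames(rep("unclustered", length(sizes)), names(sizes))
  if (length(named) > 0L) {
    lab[named] <- paste0("cluster_", seq_along(named))
  }
  out <- data.frame(
    subject_id = trace$subject_ids,
    cluster = unname(trace$partition),
    label = unname(lab[as.character(trace$partition)]),
    stringsAsFactors = FALSE)
  class(out) <- c("clustering", "data.frame")
  out
}

#' Persist a merge trace as JSON / a clustering as CSV
#'
#' @param trace a `merge_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  jsonlite::write_json(
    list(N = trace$N, n_layers = trace$n_layers,
         merges = trace$merges,
         partition = as.list(trace$partition)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param clustering a `clustering` data frame.
#' @rdname write_trace
#' @export
write_clustering <- function(clustering, path) {
  utils::write.csv(as.data.frame(clustering), path, row.names = FALSE)
  invisible(path)
}
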