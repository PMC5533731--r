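#' Example similarity table (EST)
#'
#' A symmetric N x N matrix of pairwise subject similarities in `[0, 1]`
#' with unit diagonal, computed as the proportion of induced rules
#' covering both members of a pair (see [compute_est()]).
#'
#' @param x symmetric numeric matrix in `[0, 1]` with unit diagonal.
#' @param layer_id name of the data layer the table was computed from.
#' @return a `similarity_table` object.
#' @export
new_similarity_table <- function(x, layer_id = "layer") {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (!isTRUE(all.equal(x, t(x), tolerance = 0)) && !identical(x, t(x))) {
    stop("similarity table must be exactly symmetric")
  }
  if (any(x < 0) || any(x > 1)) stop("similarities must lie in [0, 1]")
  if (any(diag(x) != 1)) stop("diagonal convention: x_ii = 1")
  structure(list(x = x, N = nrow(x), layer_id = layer_id),
            class = "similarity_table")
}

#' @export
print.similarity_table <- function(x, ...) {
  off <- x$x[upper.tri(x$x)]
  cat("similarity_table '", x$layer_id, "': N = ", x$N,
      ", mean off-diagonal = ", signif(mean(off), 3), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.similarity_table <- function(x, ...) x$x

est_matrix <- function(est) {
  if (inherits(est, "similarity_table")) est$x else as.matrix(est)
}

#' Randomized negative instances for the similarity task
#'
#' Builds `m` artificial instances by sampling every column independently
#' (with replacement) from that column's observed values. This preserves
#' each descriptor's marginal distribution while destroying the
#' between-descriptor correlation structure, yielding the negative class
#' of the original-vs-randomized discrimination task.
#'
#' @param layer an imputed `data_layer` or complete numeric matrix.
#' @param m number of negatives.
#' @param seed RNG seed.
#' @return an `m x d` matrix with the layer's column names.
#' @export
randomize_instances <- function(layer, m, seed = 1L) {
  X <- if (inherits(layer, "data_layer")) layer$matrix else as.matrix(layer)
  if (anyNA(X)) stop("layer must be imputed before randomization")
  if (m <= 0) stop("configuration error: m must be positive")
  withr::with_seed(as.integer(seed), {
    neg <- apply(X, 2, function(col) sample(col, m, replace = TRUE))
    if (m == 1L) neg <- matrix(neg, nrow = 1L)
    colnames(neg) <- colnames(X)
    neg
  })
}

#' Parameters of the rule learner
#'
#' @param n_trees number of bagged trees.
#' @param max_depth maximum tree depth; bounds rule length.
#' @param mtry descriptors sampled per tree (default `ceiling(sqrt(d))`).
#' @param minsplit minimum node size eligible for splitting.
#' @param m number of randomized negatives (default: three per original,
#'   which stabilizes the randomized side of every split; the learner
#'   keeps the task balanced through equal class priors).
#' @return a plain parameter list.
#' @export
est_params <- function(n_trees = 300L, max_depth = 4L, mtry = NULL,
                       minsplit = 20L, m = NULL) {
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       mtry = mtry, minsplit = as.integer(minsplit), m = m)
}

#' Construct a rule
#'
#' An axis-parallel conjunction of threshold conditions. Conditions are a
#' data frame with columns `descriptor`, `relation` (`"<="` or `">"`) and
#' `threshold`; at most one condition per (descriptor, relation) pair, so
#' a rule may bound a descriptor from both sides but never redundantly.
#'
#' @param conditions condition data frame as above.
#' @return a `rule` object.
#' @export
new_rule <- function(conditions) {
  stopifnot(is.data.frame(conditions),
            all(c("descriptor", "relation", "threshold") %in%
                  names(conditions)))
  if (nrow(conditions) < 1L) stop("a rule needs at least one condition")
  if (!all(conditions$relation %in% c("<=", ">"))) {
    stop("relation must be '<=' or '>'")
  }
  if (!all(is.finite(conditions$threshold))) {
    stop("thresholds must be finite")
  }
  key <- paste(conditions$descriptor, conditions$relation)
  if (anyDuplicated(key)) stop("duplicate (descriptor, relation) condition")
  structure(list(conditions = conditions), class = "rule")
}

#' @export
print.rule <- function(x, ...) {
  cat(paste(x$conditions$descriptor, x$conditions$relation,
            signif(x$conditions$threshold, 4), collapse = " AND "), "\n")
  invisible(x)
}

#' Does a rule cover an instance?
#'
#' @param rule a `rule`.
#' @param instance named numeric vector providing every descriptor the
#'   rule tests.
#' @return `TRUE` iff all conditions hold.
#' @export
rule_covers <- function(rule, instance) {
  stopifnot(inherits(rule, "rule"))
  cond <- rule$conditions
  absent <- setdiff(cond$descriptor, names(instance))
  if (length(absent) > 0L) {
    stop("instance lacks descriptor(s): ", paste(absent, collapse = ", "))
  }
  v <- instance[cond$descriptor]
  all(ifelse(cond$relation == "<=", v <= cond$threshold,
             v > cond$threshold))
}

# coverage of one rule over the rows of a matrix -> logical vector
rule_coverage <- function(rule, X) {
  cond <- rule$conditions
  out <- rep(TRUE, nrow(X))
  for (k in seq_len(nrow(cond))) {
    col <- X[, cond$descriptor[k]]
    out <- out & if (cond$relation[k] == "<=") col <= cond$threshold[k]
    else col > cond$threshold[k]
  }
  out
}

# extract the root-to-leaf path conditions of an rpart tree.
# maxcompete = maxsurrogate = 0 ensures fit$splits has exactly one row per
# internal node, in frame order; ncat == -1 sends x < threshold left.
rpart_paths <- function(fit) {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  internal <- which(frame$var != "<leaf>")
  if (length(internal) == 0L) return(list())
  split_row <- integer(max(nodes))
  split_row[nodes[internal]] <- seq_along(internal)
  leaves <- nodes[frame$var == "<leaf>"]
  lapply(leaves, function(leaf) {
    conds <- list()
    nd <- leaf
    while (nd > 1L) {
      parent <- nd %/% 2L
      left <- nd %% 2L == 0L
      r <- split_row[parent]
      thr <- fit$splits[r, "index"]
      goes_left_is_lt <- fit$splits[r, "ncat"] == -1
      rel <- if (left == goes_left_is_lt) "<=" else ">"
      conds[[length(conds) + 1L]] <- data.frame(
        descriptor = as.character(frame$var[nodes == parent]),
        relation = rel, threshold = thr, stringsAsFactors = FALSE)
      nd <- parent
    }
    list(leaf = leaf, conditions = do.call(rbind, rev(conds)))
  })
}

# tighten duplicate conditions: keep min threshold for <=, max for >
collapse_conditions <- function(cond) {
  keep <- logical(nrow(cond))
  for (k in seq_len(nrow(cond))) {
    same <- cond$descriptor == cond$descriptor[k] &
      cond$relation == cond$relation[k]
    thr <- cond$threshold[same]
    best <- if (cond$relation[k] == "<=") min(thr) else max(thr)
    keep[k] <- cond$threshold[k] == best & !any(keep[same])
  }
  cond[keep, , drop = FALSE]
}

#' Induce a rule ensemble discriminating originals from randomized copies
#'
#' Fits `n_trees` bagged, depth-limited classification trees on the task
#' original-vs-randomized (bootstrap rows, random descriptor subset per
#' tree) and emits every root-to-leaf path whose leaf covers a higher
#' fraction of the bag's originals than of its randomized instances as one
#' conjunctive rule. Similar originals end up covered by many common
#' rules, which is what the similarity table counts.
#'
#' @param positives matrix of original instances (complete, named cols).
#' @param negatives matrix of randomized instances.
#' @param params learner parameters, see [est_params()].
#' @param seed RNG seed.
#' @return a `rule_ensemble`: list with `rules`, rule count `R`, and
#'   `provenance` (parameters + seed).
#' @export
induce_rules <- function(positives, negatives, params = est_params(),
                         seed = 1L) {
  positives <- as.matrix(positives)
  negatives <- as.matrix(negatives)
  stopifnot(nrow(positives) >= 2L, nrow(negatives) >= 1L,
            ncol(positives) == ncol(negatives))
  if (isTRUE(all.equal(dim(positives), dim(negatives))) &&
      isTRUE(all.equal(unname(positives), unname(negatives)))) {
    warning("degenerate task: positives identical to negatives")
  }
  d <- ncol(positives)
  feat <- colnames(positives)
  if (is.null(feat)) {
    feat <- paste0("V", seq_len(d))
    colnames(positives) <- colnames(negatives) <- feat
  }
  mtry <- if (is.null(params$mtry)) ceiling(sqrt(d)) else
    min(as.integer(params$mtry), d)
  X <- rbind(positives, negatives)
  y <- factor(rep(c("orig", "rand"), c(nrow(positives), nrow(negatives))),
              levels = c("orig", "rand"))
  ctrl <- rpart::rpart.control(
    maxdepth = params$max_depth, cp = 0, minsplit = params$minsplit,
    xval = 0, maxcompete = 0, maxsurrogate = 0, usesurrogate = 0)

  rules <- withr::with_seed(as.integer(seed), {
    out <- list()
    for (t in seq_len(params$n_trees)) {
      bag <- sample(nrow(X), nrow(X), replace = TRUE)
      cols <- sort(sample(d, mtry))
      df <- data.frame(.y = y[bag], X[bag, cols, drop = FALSE],
                       check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = ctrl,
                          parms = list(prior = c(0.5, 0.5)))
      frame <- fit$frame
      if (all(frame$var == "<leaf>")) next
      # yval2 columns 2:3 hold per-leaf counts of (orig, rand) in the bag
      n_orig <- sum(y[bag] == "orig")
      n_rand <- sum(y[bag] == "rand")
      counts <- frame$yval2
      for (p in rpart_paths(fit)) {
        row <- which(as.integer(rownames(frame)) == p$leaf)
        cover_orig <- counts[row, 2] / n_orig
        cover_rand <- counts[row, 3] / max(n_rand, 1L)
        if (cover_orig > cover_rand) {
          out[[length(out) + 1L]] <-
            new_rule(collapse_conditions(p$conditions))
        }
      }
    }
    out
  })
  structure(
    list(rules = rules, R = length(rules),
         provenance = c(params, list(seed = as.integer(seed), mtry = mtry))),
    class = "rule_ensemble")
}

#' @export
print.rule_ensemble <- function(x, ...) {
  cat("rule_ensemble:", x$R, "rules from", x$provenance$n_trees, "trees\n")
  invisible(x)
}

#' Compute the example similarity table for one data layer
#'
#' Runs the original-vs-randomized similarity construction end to end:
#' draws `m` randomized negatives ([randomize_instances()]), induces a
#' rule ensemble ([induce_rules()]), and sets the similarity of subjects
#' `i` and `j` to the proportion of rules covering both, with unit
#' diagonal.
#'
#' @param layer an imputed `data_layer` (or complete numeric matrix).
#' @param params see [est_params()]; `params$m` defaults to N negatives.
#' @param seed RNG seed controlling both randomization and the learner.
#' @return a `similarity_table` with an attribute `"ensemble"` for audit.
#' @export
compute_est <- function(layer, params = est_params(), seed = 1L) {
  X <- if (inherits(layer, "data_layer")) layer$matrix else as.matrix(layer)
  layer_id <- if (inherits(layer, "data_layer")) layer$layer_id else "layer"
  if (anyNA(X)) stop("layer must be imputed (no missing cells)")
  n <- nrow(X)
  if (n < 2L) stop("configuration error: need at least 2 instances")
  if (n > 1000L) warning("more than 1000 instances; expect long runtimes")
  m <- if (is.null(params$m)) 3L * n else as.integer(params$m)

  seed <- as.integer(seed)
  negatives <- randomize_instances(X, m, seed = seed)
  ensemble <- induce_rules(X, negatives, params = params, seed = seed + 1L)
  if (ensemble$R == 0L) {
    warning("no rules induced; returning zero similarity")
    x <- matrix(0, n, n)
  } else {
    cover <- vapply(ensemble$rules, function(r) rule_coverage(r, X),
                    logical(n))
    if (n == 1L) cover <- matrix(cover, nrow = 1L)
    storage.mode(cover) <- "double"
    x <- (cover %*% t(cover)) / ensemble$R
  }
  diag(x) <- 1
  rownames(x) <- colnames(x) <- rownames(X)
  out <- new_similarity_table(x, layer_id = layer_id)
  attr(out, "ensemble") <- ensemble
  out
}

#' Write / read a similarity table as square CSV
#'
#' @param est a `similarity_table`.
#' @param path file path.
#' @export
write_est <- function(est, path) {
  x <- est_matrix(est)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  df <- data.frame(subject_id = ids, x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_est
#' @export
read_est <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- df[[1L]]
  # guard against asymmetry introduced by decimal serialization
  x <- (x + t(x)) / 2
  new_similarity_table(x, layer_id = "from_file")
}
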