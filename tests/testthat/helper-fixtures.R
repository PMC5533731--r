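# shared fixtures, all built in code

# three-subject long table: S3 has only a baseline visit
toy_long_df <- function() {
  data.frame(
    subject_id = c("S1", "S1", "S1", "S2", "S2", "S3"),
    month = c(0, 6, 12, 0, 12, 0),
    diagnosis = c("MCI", "MCI", "Dementia", "MCI", "MCI", "MCI"),
    ADAS13 = c(20, 22, 25, 12, 13, 15),
    MMSE = c(27, 26, 24, 29, 29, 28),
    stringsAsFactors = FALSE
  )
}

toy_schema <- function() {
  s <- default_schema()
  s$baseline <- c("ADAS13", "MMSE")
  s$longitudinal <- c("ADAS13", "MMSE")
  s$slope_names <- c("SADAS13", "SMMSE")
  s
}

# small two-blob layer: two tight groups `sep` SDs apart on every column
two_blob_layer <- function(n_per = 20, d = 3, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    m <- rbind(
      matrix(rnorm(n_per * d, 0), n_per, d),
      matrix(rnorm(n_per * d, sep), n_per, d)
    )
    colnames(m) <- paste0("V", seq_len(d))
    rownames(m) <- sprintf("B%03d", seq_len(2 * n_per))
    m
  })
}

# independent brute-force CRV implementation straight from the displayed
# formulas, used as the oracle for the fast path
brute_crv_i <- function(x, parts, i) {
  C <- parts[[which(vapply(parts, function(p) i %in% p, logical(1)))]]
  within <- setdiff(C, i)
  outside <- setdiff(seq_len(nrow(x)), C)
  wc <- if (length(within) == 0) 0 else
    sum((x[i, within] - mean(x[i, within]))^2)
  oc <- if (length(outside) == 0) 0 else
    sum((x[i, outside] - mean(x[i, outside]))^2)
  c(wc = wc, oc = oc)
}

brute_crv_C <- function(x, parts, C) {
  sum(vapply(C, function(i) sum(brute_crv_i(x, parts, i)), numeric(1)))
}

brute_diff <- function(x, parts, a, b) {
  ia <- which(vapply(parts, function(p) identical(sort(p), sort(a)),
                     logical(1)))
  ib <- which(vapply(parts, function(p) identical(sort(p), sort(b)),
                     logical(1)))
  merged <- c(parts[-c(ia, ib)], list(sort(c(a, b))))
  brute_crv_C(x, parts, a) + brute_crv_C(x, parts, b) -
    brute_crv_C(x, merged, sort(c(a, b)))
}

random_sym_est <- function(N, seed) {
  withr::with_seed(seed, {
    x <- matrix(runif(N * N), N, N)
    x <- (x + t(x)) / 2
    diag(x) <- 1
    x
  })
}

# exhaustive single-threshold search oracle
brute_univariate <- function(feature, frame, direction) {
  v <- frame[[feature]]
  y <- frame$label
  thr <- candidate_thresholds(v)
  best <- NULL
  for (t in thr) {
    fires <- if (direction == ">") v > t else v < t
    sens <- sum(fires & y) / sum(y)
    spec <- sum(!fires & !y) / sum(!y)
    key <- c(sens + spec - 1, 100 * spec, -t)
    if (is.null(best) || mlclust:::lex_greater(key, best$key)) {
      best <- list(key = key, t = t)
    }
  }
  best
}

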