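test_that("classifier evaluation counts the confusion table", {
  frame <- data.frame(
    ADAS13 = c(seq(21, 29, length.out = 9), 15,        # 10 rapid
               seq(5, 18, length.out = 18), 25, 24),   # 20 non-rapid
    label = rep(c(TRUE, FALSE), c(10, 20)))
  clf <- new_cutoff_classifier(data.frame(
    feature = "ADAS13", relation = ">", threshold = 19))
  m <- evaluate_classifier(clf, frame)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 90)
  expect_equal(m$tp + m$fn, 10)
  expect_equal(m$tn + m$fp, 20)

  always <- new_cutoff_classifier(data.frame(
    feature = "ADAS13", relation = ">", threshold = -1e9))
  m2 <- evaluate_classifier(always, frame)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 0)

  # missing feature values are excluded and counted
  frame$ADAS13[1] <- NA
  m3 <- evaluate_classifier(clf, frame)
  expect_equal(attr(m3, "n_excluded"), 1L)
  expect_equal(m3$tp + m3$fn, 9)

  expect_error(evaluate_classifier(clf, data.frame(ADAS13 = 1:3,
                                                   label = TRUE)),
               "undefined")
  expect_error(new_cutoff_classifier(data.frame(
    feature = c("a", "a"), relation = c(">", ">"), threshold = c(1, 2))),
    "distinct")
})

test_that("candidate thresholds are midpoints of distinct values", {
  expect_equal(candidate_thresholds(c(1, 2, 4)), c(1.5, 3))
  expect_equal(candidate_thresholds(5), numeric(0))
  expect_equal(candidate_thresholds(c(2, 2, 2)), numeric(0))
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_length(candidate_thresholds(v), length(unique(v)) - 1L)
})

test_that("univariate search finds the separating cut-off", {
  frame <- data.frame(f = c(1:10, 21:30),
                      label = rep(c(FALSE, TRUE), each = 10))
  clf <- search_univariate("f", frame, ">")
  expect_equal(attr(clf, "sensitivity"), 100)
  expect_equal(attr(clf, "specificity"), 100)
  expect_gt(clf$conditions$threshold, 10)
  expect_lt(clf$conditions$threshold, 21)

  # reversed direction on negated values performs identically
  frame2 <- data.frame(f = -frame$f, label = frame$label)
  clf2 <- search_univariate("f", frame2, "<")
  expect_equal(attr(clf2, "sensitivity"), 100)
  expect_equal(attr(clf2, "specificity"), 100)

  expect_error(search_univariate("f", data.frame(f = 1:4, label = TRUE)),
               "degenerate")
})

test_that("searches equal exhaustive enumeration on random fixtures", {
  withr::with_seed(23, {
    for (k in 1:5) {
      n <- 120
      frame <- data.frame(
        f = round(rnorm(n, 10, 3), 1),
        g = round(rnorm(n, 5, 2), 1),
        label = sample(c(TRUE, FALSE), n, replace = TRUE))
      clf <- search_univariate("f", frame, ">")
      oracle <- brute_univariate("f", frame, ">")
      expect_equal(clf$conditions$threshold, oracle$t)
      expect_equal(attr(clf, "quality"), unname(oracle$key[1]),
                   tolerance = 1e-12)
    }
    # conjunction vs brute force on a ~50x50 grid
    n <- 60
    frame <- data.frame(
      f = round(rnorm(n, 0, 1), 1),
      g = round(rnorm(n, 0, 1), 1),
      label = sample(c(TRUE, FALSE), n, replace = TRUE))
    clf <- search_conjunction("f", "g", frame)
    t1s <- candidate_thresholds(frame$f)
    t2s <- candidate_thresholds(frame$g)
    best <- NULL
    for (a in t1s) for (b in t2s) {
      fires <- frame$f > a & frame$g > b
      sens <- sum(fires & frame$label) / sum(frame$label)
      spec <- sum(!fires & !frame$label) / sum(!frame$label)
      key <- c(sens + spec - 1, 100 * spec, -a, -b)
      if (is.null(best) || mlclust:::lex_greater(key, best$key)) {
        best <- list(key = key, a = a, b = b)
      }
    }
    expect_equal(clf$conditions$threshold, c(best$a, best$b))
  })
})

test_that("a conjunction separates AND-shaped data no single test can", {
  withr::with_seed(29, {
    # positives in the upper-right quadrant; negatives on both arms
    pos <- cbind(f = runif(30, 6, 10), g = runif(30, 6, 10))
    negA <- cbind(f = runif(30, 6, 10), g = runif(30, 0, 4))
    negB <- cbind(f = runif(30, 0, 4), g = runif(30, 6, 10))
  })
  frame <- data.frame(rbind(pos, negA, negB),
                      label = rep(c(TRUE, FALSE), c(30, 60)))
  u <- search_univariate("f", frame, ">")
  expect_lt(attr(u, "quality"), 1)
  conj <- search_conjunction("f", "g", frame)
  expect_equal(attr(conj, "sensitivity"), 100)
  expect_equal(attr(conj, "specificity"), 100)
  # never worse than the better constituent
  expect_gte(attr(conj, "quality"), attr(u, "quality"))
})

test_that("midpoint scanning misses no achievable confusion table", {
  withr::with_seed(37, {
    v <- sample(seq(1, 30, 0.5), 40, replace = TRUE)
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  })
  conf <- function(t) {
    fires <- v > t
    c(sum(fires & y), sum(fires & !y))
  }
  mid_tables <- unique(t(vapply(candidate_thresholds(v), conf,
                                numeric(2))))
  eps_tables <- unique(t(vapply(c(sort(unique(v)) - 1e-9,
                                  sort(unique(v)) + 1e-9), conf,
                                numeric(2))))
  interior <- eps_tables[eps_tables[, 1] + eps_tables[, 2] > 0 &
                           eps_tables[, 1] + eps_tables[, 2] < 40, ,
                         drop = FALSE]
  expect_true(all(apply(interior, 1, function(r)
    any(mid_tables[, 1] == r[1] & mid_tables[, 2] == r[2]))))
})

test_that("cross-cohort validation freezes the classifier", {
  withr::with_seed(41, {
    make_frame <- function(n, tag) data.frame(
      ADAS13 = c(rnorm(n / 2, 24, 4), rnorm(n / 2, 12, 3)),
      label = rep(c(TRUE, FALSE), each = n / 2),
      cohort = tag)
    train <- make_frame(120, "study1")
    test <- make_frame(120, "study2")
  })
  clf <- search_univariate("ADAS13", train, ">")
  out <- cross_cohort_validate(clf, train, test)
  expect_named(out, c("classifier", "train_sensitivity",
                      "train_specificity", "test_sensitivity",
                      "test_specificity"))
  # same-distribution cohorts: metrics agree within binomial bounds
  p <- out$train_sensitivity / 100
  expect_lt(abs(out$test_sensitivity - out$train_sensitivity),
            100 * (1.96 * sqrt(p * (1 - p) / 60) + 1.96 *
                     sqrt(p * (1 - p) / 60)))

  # flipped labels swap sensitivity and specificity
  flipped <- test
  flipped$label <- !flipped$label
  m <- evaluate_classifier(clf, test)
  mf <- evaluate_classifier(clf, flipped)
  expect_equal(mf$sensitivity, 100 - m$specificity)
  expect_equal(mf$specificity, 100 - m$sensitivity)

  # overlapping cohort tags are rejected
  expect_error(cross_cohort_validate(clf, train, train),
               "validation error")
})
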