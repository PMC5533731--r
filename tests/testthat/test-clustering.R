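two_block4 <- function() generate_two_block_est(2, 2, 1, 0)

test_that("per-instance CRV on the worked 4x4 fixture", {
  est <- two_block4()
  singles <- as.list(1:4)
  v <- crv_instance(est, singles, 1)
  expect_equal(unname(v["wc"]), 0)
  expect_equal(unname(v["oc"]), 2 / 3)

  v2 <- crv_instance(est, list(c(1, 2), 3, 4), 1)
  expect_equal(unname(v2), c(0, 0))

  # constant off-diagonal EST has zero variability everywhere
  xc <- matrix(0.4, 4, 4); diag(xc) <- 1
  for (i in 1:4) {
    expect_equal(unname(crv_instance(xc, singles, i)), c(0, 0))
    expect_equal(unname(crv_instance(xc, list(c(1, 3), c(2, 4)), i)),
                 c(0, 0))
  }
  expect_error(crv_instance(est, singles, 5), "out of range")
})

test_that("cluster CRV and merge DIFF on the worked fixture", {
  est <- two_block4()
  singles <- as.list(1:4)
  expect_equal(crv_cluster(est, singles, 1), 2 / 3)
  expect_equal(crv_cluster(est, list(c(1, 2), 3, 4), c(1, 2)), 0)
  expect_equal(crv_cluster(est, list(1:4), 1:4), 8 / 3)
  expect_error(crv_cluster(est, singles, c(1, 2)), "unknown cluster")

  expect_equal(diff_merge(est, singles, 1, 2), 4 / 3)
  expect_equal(diff_merge(est, list(c(1, 2), c(3, 4)), c(1, 2), c(3, 4)),
               -8 / 3)
  expect_error(diff_merge(est, singles, 2, 2), "itself")
  xc <- matrix(0.4, 4, 4); diag(xc) <- 1
  expect_equal(diff_merge(xc, singles, 1, 3), 0)
})

test_that("joint DIFF is the minimum across layers", {
  est <- two_block4()
  singles <- as.list(1:4)
  # contradictory second layer: blocks {1,3} and {2,4}
  x2 <- matrix(0, 4, 4)
  x2[cbind(c(1, 3), c(3, 1))] <- 1
  x2[cbind(c(2, 4), c(4, 2))] <- 1
  diag(x2) <- 1
  d1 <- diff_merge(est, singles, 1, 2)
  d2 <- diff_merge(x2, singles, 1, 2)
  expect_equal(joint_diff(list(est, x2), singles, 1, 2), min(d1, d2))
  expect_equal(joint_diff(list(est), singles, 1, 2), d1)
  expect_equal(joint_diff(est, singles, 1, 2), d1)
  expect_error(joint_diff(list(est, matrix(1, 3, 3)), singles, 1, 2),
               "disagree")
})

test_that("clustering the two-block fixture runs the documented trace", {
  tr <- mlc_cluster(two_block4())
  expect_equal(nrow(tr$merges), 2L)
  expect_equal(tr$merges$joint_diff, c(4 / 3, 4 / 3))
  expect_equal(tr$best_remaining_diff, -8 / 3)
  parts <- unname(split(seq_len(4), tr$partition))
  expect_equal(parts, list(c(1L, 2L), c(3L, 4L)))
  expect_true(all(tr$merges$joint_diff > 0))
})

test_that("agreeing layers recover the blocks jointly", {
  agree <- list(generate_two_block_est(2, 2, 1, 0),
                generate_two_block_est(2, 2, 0.9, 0.1))
  tr <- mlc_cluster(agree)
  expect_equal(length(unique(tr$partition)), 2L)
  expect_true(all(tr$merges$joint_diff > 0))
})

test_that("contradictory block layers: every pair still offers +1/3", {
  # layer 1 blocks {1,2}|{3,4}, layer 2 blocks {1,3}|{2,4}. Removing a
  # high-similarity column from a row outside-set lowers its variability
  # in one layer without raising it in the other, so, by the formulas,
  # all six singleton pairs tie at joint DIFF = 1/3 (brute-force check)
  # and the deterministic tie-break resolves toward layer 1 blocks.
  x1 <- as.matrix(two_block4())
  x2 <- matrix(0, 4, 4)
  x2[cbind(c(1, 3), c(3, 1))] <- 1
  x2[cbind(c(2, 4), c(4, 2))] <- 1
  diag(x2) <- 1
  singles <- as.list(1:4)
  for (p in combn(4, 2, simplify = FALSE)) {
    expect_equal(joint_diff(list(x1, x2), singles, p[1], p[2]), 1 / 3)
    expect_equal(min(brute_diff(x1, singles, p[1], p[2]),
                     brute_diff(x2, singles, p[1], p[2])), 1 / 3)
  }
  tr2 <- mlc_cluster(list(x1, x2))
  expect_equal(tr2$merges[, c("id_a", "id_b")],
               data.frame(id_a = c(1L, 3L), id_b = c(2L, 4L)))
  expect_equal(tr2$merges$joint_diff, c(1 / 3, 1 / 3))
  expect_equal(length(unique(tr2$partition)), 2L)
})

test_that("CRV and DIFF match the brute-force oracle on random inputs", {
  withr::with_seed(7, {
    checked <- 0L
    while (checked < 120L) {
      N <- sample(4:12, 1)
      x <- random_sym_est(N, seed = sample.int(1e6, 1))
      assign <- sample(seq_len(sample(2:4, 1)), N, replace = TRUE)
      parts <- unname(split(seq_len(N), assign))
      if (length(parts) < 2L) next
      i <- sample(N, 1)
      expect_equal(crv_instance(x, parts, i), brute_crv_i(x, parts, i),
                   tolerance = 1e-9)
      a <- parts[[1]]
      b <- parts[[2]]
      expect_equal(crv_cluster(x, parts, a), brute_crv_C(x, parts, a),
                   tolerance = 1e-9)
      expect_equal(diff_merge(x, parts, a, b), brute_diff(x, parts, a, b),
                   tolerance = 1e-9)
      checked <- checked + 1L
    }
  })
})

test_that("every executed merge reduces variability in the binding layer", {
  # noisy two-block ESTs at N = 100
  withr::with_seed(11, {
    N <- 100
    noisy_block_est <- function() {
      base <- as.matrix(generate_two_block_est(N / 2, N / 2, 0.7, 0.2))
      noise <- matrix(runif(N * N, -0.15, 0.15), N, N)
      noise <- (noise + t(noise)) / 2
      x <- pmin(pmax(base + noise, 0), 1)
      diag(x) <- 1
      x
    }
    layers <- list(noisy_block_est(), noisy_block_est())
    tr <- mlc_cluster(layers)
    expect_lte(nrow(tr$merges), N - 1L)

    # replay the trace: per-layer total CRV before/after each merge
    total_crv <- function(x, parts) {
      sum(vapply(parts, function(C) crv_cluster(x, parts, C), numeric(1)))
    }
    parts <- as.list(seq_len(N))
    ids <- seq_len(N)
    for (k in seq_len(nrow(tr$merges))) {
      a <- tr$merges$id_a[k]
      b <- tr$merges$id_b[k]
      ia <- which(vapply(parts, function(p) a %in% p, logical(1)))
      ib <- which(vapply(parts, function(p) b %in% p, logical(1)))
      expect_gt(tr$merges$joint_diff[k], 0)
      binding <- which.min(unlist(
        tr$merges[k, paste0("diff_layer", 1:2)]))
      before <- total_crv(layers[[binding]], parts)
      merged <- c(parts[-c(ia, ib)],
                  list(sort(c(parts[[ia]], parts[[ib]]))))
      after <- total_crv(layers[[binding]], merged)
      expect_lt(after, before)
      parts <- merged
    }
    # final state: replayed partition matches, all joint DIFFs <= 0
    final <- unname(split(seq_len(N), tr$partition))
    expect_setequal(lapply(final, sort), lapply(parts, sort))
    if (length(final) > 1L) {
      for (i in seq_along(final)[-length(final)]) {
        for (j in seq((i + 1), length(final))) {
          expect_lte(joint_diff(layers, final, final[[i]], final[[j]]), 0)
        }
      }
    }
  })
})

test_that("subject permutation yields the same partition up to labels", {
  x <- as.matrix(generate_two_block_est(3, 4, 0.85, 0.15))
  withr::with_seed(5, {
    noise <- matrix(runif(49, -0.05, 0.05), 7, 7)
    noise <- (noise + t(noise)) / 2
    x <- pmin(pmax(x + noise, 0), 1)
    diag(x) <- 1
    p <- sample(7)
  })
  tr1 <- mlc_cluster(x)
  tr2 <- mlc_cluster(x[p, p])
  part1 <- tr1$partition[p]          # in permuted subject order
  part2 <- tr2$partition
  # same grouping iff the co-membership relations agree
  expect_identical(outer(part1, part1, "=="), outer(part2, part2, "=="),
                   ignore_attr = TRUE)
})

test_that("small final clusters are flagged unclustered", {
  x <- as.matrix(generate_two_block_est(4, 3, 0.9, 0.1))
  tr <- mlc_cluster(x)
  cl0 <- label_unclustered(tr, min_size = 1)
  expect_false(any(cl0$label == "unclustered"))
  cl <- label_unclustered(tr, min_size = 4)
  expect_equal(sum(cl$label == "cluster_1"), 4L)
  expect_equal(sum(cl$label == "unclustered"), 3L)

  # all singletons with min_size 2: everything unclustered
  x2 <- matrix(0, 3, 3); diag(x2) <- 1
  tr2 <- mlc_cluster(x2)
  cl2 <- label_unclustered(tr2, min_size = 2)
  expect_true(all(cl2$label == "unclustered"))
})

test_that("trace and clustering serialize", {
  tr <- mlc_cluster(two_block4())
  tpath <- withr::local_tempfile(fileext = ".json")
  write_trace(tr, tpath)
  back <- jsonlite::read_json(tpath)
  expect_equal(back$N, 4L)
  expect_equal(length(back$merges), 2L)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_clustering(label_unclustered(tr, 2), cpath)
  expect_equal(nrow(read.csv(cpath)), 4L)
})
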