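lab_from <- function(m) labeled_mask(matrix(as.integer(m), nrow(m), ncol(m)))

test_that("the detection F-score follows its closed form", {
  expect_equal(f1_score(2, 1, 1), 2 / 3)
  expect_equal(f1_score(5, 0, 0), 1)
  expect_equal(f1_score(0, 3, 2), 0)
  expect_equal(f1_score(0, 0, 0), 1)   # perfect empty
  expect_error(f1_score(-1, 0, 0), class = "flowseg_invalid_params")
})

test_that("the Jaccard index follows its set definition", {
  a <- matrix(FALSE, 20, 20); a[3:12, 3:12] <- TRUE
  b <- matrix(FALSE, 20, 20); b[3:12, 8:17] <- TRUE
  expect_equal(jaccard_index(binary_mask(a), binary_mask(a)), 1)
  expect_equal(jaccard_index(binary_mask(a), binary_mask(!a)), 0)
  expect_equal(jaccard_index(binary_mask(a), binary_mask(b)), 1 / 3) # 50/150
  e <- binary_mask(matrix(FALSE, 4, 4))
  expect_equal(jaccard_index(e, e), 1)
  expect_error(jaccard_index(binary_mask(a), binary_mask(matrix(FALSE, 5, 5))),
               class = "flowseg_dim_mismatch")
  expect_equal(jaccard_index(binary_mask(b), binary_mask(a)),
               jaccard_index(binary_mask(a), binary_mask(b)))
})

test_that("object matching is greedy, one-to-one, and IoU-thresholded", {
  truth <- matrix(0L, 30, 30)
  truth[2:9, 2:9] <- 1L; truth[15:22, 15:22] <- 2L
  t <- lab_from(truth)
  expect_equal(match_objects(t, t), c(tp = 2L, fp = 0L, fn = 0L))

  pred <- matrix(0L, 30, 30)
  pred[2:9, 2:9] <- 1L          # perfect on truth A
  pred[25:28, 2:5] <- 2L        # spurious, off both truths
  expect_equal(match_objects(lab_from(pred), t), c(tp = 1L, fp = 1L, fn = 1L))

  expect_equal(match_objects(lab_from(matrix(0L, 30, 30)),
                             lab_from(truth + ifelse(truth == 2L, 1L, 0L))),
               c(tp = 0L, fp = 0L, fn = 2L))
  expect_error(match_objects(t, lab_from(matrix(0L, 5, 5))),
               class = "flowseg_dim_mismatch")
  # a 37.5% overlap fails the default 0.5 IoU gate but passes a 0.3 gate
  half <- matrix(0L, 30, 30); half[2:9, 2:4] <- 1L   # IoU = 24/64
  expect_equal(match_objects(lab_from(half), lab_from((truth == 1L) * 1L))[["tp"]], 0L)
  expect_equal(match_objects(lab_from(half), lab_from((truth == 1L) * 1L),
                             iou_match_threshold = 0.3)[["tp"]], 1L)
})

test_that("dataset evaluation micro-averages counts and pools pixels", {
  t1 <- matrix(0L, 20, 20); t1[2:9, 2:9] <- 1L
  p2 <- matrix(0L, 20, 20); p2[2:9, 2:9] <- 1L; p2[14:17, 14:17] <- 2L
  t2 <- matrix(0L, 20, 20); t2[2:9, 2:9] <- 1L; t2[12:19, 2:9] <- 2L
  # image 1: perfect (1,0,0); image 2: (1,1,1) -> pooled F1 = 2/(2+1)
  res <- evaluate_dataset(list(lab_from(t1), lab_from(p2)),
                          list(lab_from(t1), lab_from(t2)))
  expect_equal(res$tp, 2L); expect_equal(res$fp, 1L); expect_equal(res$fn, 1L)
  expect_equal(res$f1, 2 / 3)
  pooled_i <- sum(t1 > 0) + sum(p2 > 0 & t2 > 0)
  pooled_u <- sum(t1 > 0) + sum(p2 > 0 | t2 > 0)
  expect_equal(res$jaccard, pooled_i / pooled_u)
  expect_equal(nrow(tidy(res)), 2L)
  expect_equal(glance(res)$f1, 2 / 3)

  perfect <- evaluate_dataset(list(lab_from(t1), lab_from(t2)),
                              list(lab_from(t1), lab_from(t2)))
  expect_equal(perfect$f1, 1); expect_equal(perfect$jaccard, 1)

  expect_error(evaluate_dataset(list(), list(lab_from(t1))),
               class = "flowseg_invalid_params")
  expect_error(evaluate_dataset(list(lab_from(t1)),
                                list(lab_from(t1), lab_from(t2))),
               class = "flowseg_invalid_params")
})

test_that("pixel-level Eq-3 analogue equals Dice and bounds Jaccard", {
  set.seed(31)
  for (i in 1:10) {
    a <- matrix(runif(900) < 0.4, 30, 30)
    b <- matrix(runif(900) < 0.4, 30, 30)
    tp <- sum(a & b); fp <- sum(b & !a); fn <- sum(a & !b)
    dice <- f1_score(tp, fp, fn)
    expect_equal(dice, 2 * tp / (2 * tp + fp + fn))
    j <- jaccard_index(binary_mask(a), binary_mask(b))
    expect_lte(j, dice + 1e-12)
  }
})

test_that("extra predicted pixels outside the truth strictly lower Jaccard", {
  truth <- matrix(FALSE, 20, 20); truth[5:14, 5:14] <- TRUE
  pred <- truth
  j_prev <- jaccard_index(binary_mask(truth), binary_mask(pred))
  outside <- which(!truth)
  set.seed(4)
  for (k in sample(outside, 5)) {
    pred[k] <- TRUE
    j <- jaccard_index(binary_mask(truth), binary_mask(pred))
    expect_lt(j, j_prev)
    j_prev <- j
  }
})
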