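# Metric correctness against literal oracles and the worked fixtures.

test_that("classification metrics match hand-enumerated one-vs-rest tables", {
  truth <- c(0L, 0L, 1L, 1L, 2L, 2L)
  pred <- c(0L, 1L, 1L, 2L, 2L, 0L)
  r <- cls_metrics(pred, truth)
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$f1, 0.5)
  # per-class: every class has TP=1, FP=1, FN=1 here
  expect_equal(r$per_class$precision, rep(0.5, 3))
  expect_equal(r$per_class$recall, rep(0.5, 3))
  expect_equal(sum(r$confusion), 6L)
  expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
})

test_that("perfect predictions give accuracy and F1 of 1", {
  set.seed(61)
  y <- sample(0:2, 30, replace = TRUE)
  r <- cls_metrics(y, y)
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
})

test_that("a never-predicted class yields zero precision with a warning", {
  truth <- c(0L, 1L, 2L, 2L)
  pred <- c(0L, 1L, 0L, 1L)
  expect_warning(r <- cls_metrics(pred, truth), "zero-division")
  expect_equal(r$per_class$precision[3], 0)
  expect_equal(r$per_class$f1[3], 0)
  expect_error(cls_metrics(0:1, 0:2), "lengths differ")
  expect_error(cls_metrics(c(0, 5), c(0, 1)), "\\{0,1,2\\}")
})

test_that("random classification inputs agree with the independent oracle", {
  set.seed(62)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    truth <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    r <- suppressWarnings(cls_metrics(pred, truth))
    o <- oracle_cls(pred, truth)
    expect_equal(r$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(r$f1, o$f1, tolerance = 1e-12)
    expect_true(r$accuracy >= 0 && r$accuracy <= 1)
  }
})

test_that("the 4x4 worked segmentation fixture is exact", {
  truth <- matrix(0, 4, 4); truth[, 1:2] <- 1
  pred <- matrix(0, 4, 4); pred[, 1:3] <- 1
  r <- seg_metrics(pred, truth)
  expect_equal(r$dice, 0.8)
  expect_equal(r$miou, (8 / 12 + 4 / 8) / 2)
  expect_equal(r$per_image$iou, 7 / 12)
})

test_that("the 3-4-5 Hausdorff fixture and base properties hold", {
  a <- rbind(c(1, 1))
  b <- rbind(c(4, 5))
  expect_equal(hausdorff(a, b), 5)
  expect_equal(hausdorff(a, b, method = "brute"), 5)
  expect_equal(hausdorff(a, a), 0)
  # subset: directed(a -> b) = 0, so the symmetric distance is directed(b -> a)
  b2 <- rbind(c(1, 1), c(7, 9))
  expect_equal(hausdorff(a, b2), 10)
  expect_error(hausdorff(a[0, , drop = FALSE], b), "nonempty")
})

test_that("fast and brute Hausdorff agree exactly on random grids", {
  set.seed(63)
  for (i in 1:60) {
    a <- cbind(sample(1:50, 20, TRUE), sample(1:50, 20, TRUE))
    b <- cbind(sample(1:50, 20, TRUE), sample(1:50, 20, TRUE))
    g <- hausdorff(a, b)
    expect_identical(g, hausdorff(a, b, method = "brute"))
    expect_equal(g, oracle_hausdorff(a, b), tolerance = 1e-12)
    expect_identical(g, hausdorff(b, a))   # symmetry
  }
  # sampled triangle inequality
  for (i in 1:20) {
    a <- cbind(sample(1:30, 8, TRUE), sample(1:30, 8, TRUE))
    b <- cbind(sample(1:30, 8, TRUE), sample(1:30, 8, TRUE))
    c <- cbind(sample(1:30, 8, TRUE), sample(1:30, 8, TRUE))
    expect_lte(hausdorff(a, c), hausdorff(a, b) + hausdorff(b, c) + 1e-9)
  }
})

test_that("identical masks score perfectly; the Dice-IoU identity holds", {
  set.seed(64)
  masks <- lapply(1:5, function(i) random_mask(12, 12))
  r <- seg_metrics(masks, masks)
  expect_equal(r$miou, 1)
  expect_equal(r$dice, 1)
  expect_equal(r$mhd, 0)
  preds <- lapply(1:5, function(i) random_mask(12, 12))
  r2 <- seg_metrics(preds, masks)
  for (i in 1:5) {
    iou_fg <- with(list(p = preds[[i]], t = masks[[i]]), {
      tp <- sum(p == 1 & t == 1)
      tp / (tp + sum(p != t))
    })
    expect_equal(r2$per_image$dice[i], 2 * iou_fg / (1 + iou_fg),
                 tolerance = 1e-12)
  }
})

test_that("degenerate masks follow the stated total-function policy", {
  z <- matrix(0, 6, 6)
  o <- matrix(0, 6, 6); o[3, 3] <- 1
  both_empty <- seg_metrics(z, z)
  expect_equal(both_empty$per_image$iou, 1)
  expect_equal(both_empty$per_image$dice, 1)
  expect_equal(both_empty$per_image$hd, 0)
  one_empty <- seg_metrics(z, o)
  expect_equal(one_empty$per_image$dice, 0)
  expect_equal(one_empty$per_image$hd, sqrt(50))
})

test_that("boundary extraction matches direct neighbour enumeration", {
  set.seed(65)
  for (i in 1:10) {
    m <- random_mask(9, 11)
    got <- ifrcnet:::boundary_points(m)
    want <- oracle_boundary(m)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("the averaged Hausdorff variant is bounded by the max variant", {
  set.seed(66)
  p <- random_mask(16, 16); t <- random_mask(16, 16)
  r_max <- seg_metrics(p, t)
  r_avg <- seg_metrics(p, t, hd_variant = "average")
  expect_lte(r_avg$mhd, r_max$mhd + 1e-12)
})

test_that("reports serialize to JSON and confusion matrices to CSV", {
  r <- cls_metrics(c(0L, 1L, 2L), c(0L, 1L, 2L))
  jp <- withr::local_tempfile(fileext = ".json")
  report_to_json(r, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$accuracy, 1)
  cp <- withr::local_tempfile(fileext = ".csv")
  write_confusion(r, cp)
  expect_true(file.exists(cp))
})
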