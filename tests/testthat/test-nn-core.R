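# Layer-level checks of the network engine against literal oracles and
# finite differences.

fd_grad <- function(f, x, k, eps = 1e-5) {
  e <- array(0, dim(x))
  e[k] <- eps
  (f(x + e) - f(x - e)) / (2 * eps)
}

test_that("convolution matches the nested-loop oracle, plain and dilated", {
  set.seed(11)
  cases <- list(list(k = 3L, pad = 1L, dil = 1L),
                list(k = 3L, pad = 2L, dil = 2L),
                list(k = 3L, pad = 3L, dil = 3L),
                list(k = 1L, pad = 0L, dil = 1L))
  for (cs in cases) {
    x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
    cv <- ifrcnet:::nn_conv2d(3L, 4L, kernel = cs$k, pad = cs$pad,
                              dilation = cs$dil)
    expect_equal(cv$fwd(x),
                 oracle_conv2d(x, cv$par$W, cv$par$b, cs$k, cs$pad, cs$dil),
                 tolerance = 1e-12)
  }
})

test_that("convolution and deconvolution gradients pass finite differences", {
  set.seed(12)
  x <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  cv <- ifrcnet:::nn_conv2d(3L, 5L, kernel = 3L, pad = 1L)
  f <- function(xx) sum(cv$fwd(xx)^2) / 2
  y <- cv$fwd(x)
  g <- cv$bwd(y)
  for (k in c(1L, 40L, 99L)) {
    expect_equal(g[k], fd_grad(f, x, k), tolerance = 1e-5)
  }
  dc <- ifrcnet:::nn_deconv2(3L, 4L)
  fd <- function(xx) sum(dc$fwd(xx)^2) / 2
  yd <- dc$fwd(x)
  gd <- dc$bwd(yd)
  expect_equal(dim(yd), c(2L, 4L, 12L, 12L))
  for (k in c(5L, 77L)) {
    expect_equal(gd[k], fd_grad(fd, x, k), tolerance = 1e-5)
  }
})

test_that("max pooling keeps the maximum and routes gradient to it", {
  x <- array(0, c(1, 1, 4, 4))
  x[1, 1, , ] <- matrix(c(1, 2, 3, 4,
                          5, 6, 7, 8,
                          9, 10, 11, 12,
                          13, 14, 15, 16), 4, 4, byrow = TRUE)
  mp <- ifrcnet:::nn_maxpool2()
  y <- mp$fwd(x)
  expect_equal(as.vector(y[1, 1, , ]), c(6, 14, 8, 16))
  dy <- y * 0 + 1
  dx <- mp$bwd(dy)
  expect_equal(sum(dx), 4)
  expect_equal(dx[1, 1, 2, 2], 1)
})

test_that("batch norm normalizes in training and uses running stats in eval", {
  set.seed(13)
  bn <- ifrcnet:::nn_bn2d(3L)
  x <- array(rnorm(4 * 3 * 5 * 5, mean = 2, sd = 3), c(4, 3, 5, 5))
  y <- bn$fwd(x, training = TRUE)
  m <- 4 * 5 * 5
  for (c in 1:3) {
    expect_equal(mean(y[, c, , ]), 0, tolerance = 1e-8)
    expect_equal(sd(as.vector(y[, c, , ])) * sqrt((m - 1) / m), 1,
                 tolerance = 1e-3)
  }
  # eval mode with running stats is a fixed, repeatable transform
  y2 <- bn$fwd(x, training = FALSE)
  y3 <- bn$fwd(x, training = FALSE)
  expect_identical(y2, y3)
  # training-mode gradient passes a finite-difference check
  f <- function(xx) sum(bn$fwd(xx, training = TRUE)^2) / 2
  yy <- bn$fwd(x, training = TRUE)
  g <- bn$bwd(yy)
  e <- array(0, dim(x)); e[17] <- 1e-5
  expect_equal(g[17], (f(x + e) - f(x - e)) / 2e-5, tolerance = 1e-4)
})

test_that("segmentation loss equals ln 2 on uniform logits and saturates", {
  lg <- array(0, c(2, 2, 3, 3))
  y <- array(c(0, 1), c(2, 3, 3))
  expect_equal(seg_loss(lg, y), log(2), tolerance = 1e-12)
  lg[, 1, , ] <- 20 * (1 - y)
  lg[, 2, , ] <- 20 * y
  expect_lt(seg_loss(lg, y), 0.01)
  expect_error(seg_loss(lg, y + 0.5), "binary")
})

test_that("segmentation loss matches a scalar softmax oracle", {
  set.seed(14)
  lg <- array(rnorm(1 * 2 * 3 * 3), c(1, 2, 3, 3))
  y <- array(as.numeric(runif(9) > 0.5), c(1, 3, 3))
  manual <- 0
  for (i in 1:3) for (j in 1:3) {
    p <- exp(lg[1, , i, j]) / sum(exp(lg[1, , i, j]))
    manual <- manual - log(p[y[1, i, j] + 1])
  }
  expect_equal(seg_loss(lg, y), manual / 9, tolerance = 1e-12)
})

test_that("classification loss equals ln 3 on uniform logits and matches the oracle", {
  lg <- matrix(0, 4, 3)
  expect_equal(cls_loss(lg, c(0L, 1L, 2L, 0L)), log(3), tolerance = 1e-12)
  lg2 <- matrix(c(9, -9, -9, -9, -9, 9), 2, 3, byrow = TRUE)
  expect_lt(cls_loss(lg2, c(0L, 2L)), 0.01)
  set.seed(15)
  lg3 <- matrix(rnorm(6), 2, 3)
  expect_equal(cls_loss(lg3, c(0L, 2L)), oracle_softmax_ce(lg3, c(0L, 2L)),
               tolerance = 1e-12)
  expect_error(cls_loss(lg3, c(0L, 5L)), "labels")
})

test_that("optimizers update parameters and lr = 0 is a null update", {
  set.seed(16)
  fc <- ifrcnet:::nn_fc(4L, 2L)
  w0 <- fc$par$W
  x <- matrix(rnorm(12), 3, 4)
  opt0 <- ifrcnet:::new_optimizer(fc, "adam", lr = 0)
  fc$bwd(fc$fwd(x))
  opt0$step()
  expect_identical(fc$par$W, w0)
  opt <- ifrcnet:::new_optimizer(fc, "adam", lr = 1e-2)
  opt$step()
  expect_false(identical(fc$par$W, w0))
})
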