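# Attention block contracts: shapes, gate bounds, saturation limits, and
# agreement with independent scalar compositions.

# force a CAM block's bottleneck output toward a constant via its last bias
saturate_cam <- function(block, value) {
  block$par$W1[] <- 0; block$par$b1[] <- 0
  block$par$W2[] <- 0; block$par$b2[] <- value / 2 # two paths sum
  block
}

saturate_sam <- function(block, value) {
  block$children$conv$par$W[] <- 0
  block$children$conv$par$b[] <- value
  block
}

test_that("channel attention weights are bounded and match a scalar oracle", {
  set.seed(21)
  x <- array(rnorm(2 * 8 * 4 * 4), c(2, 8, 4, 4))
  blk <- ifrcnet:::nn_cam(8L, reduction = 4L)
  w <- channel_attention(x, blk)
  expect_equal(dim(w), dim(x))
  expect_true(all(w > 0 & w < 1))
  # constant over space per (n, c): the broadcast map is constant too
  expect_equal(w[1, 3, 1, 1], w[1, 3, 4, 2])
  # independent scalar composition: shared MLP on avg and max descriptors
  for (n in 1:2) for (c in 1:8) {
    avg <- vapply(1:8, function(cc) mean(x[n, cc, , ]), 0)
    mx <- vapply(1:8, function(cc) max(x[n, cc, , ]), 0)
    mlp <- function(a) {
      h <- pmax(blk$par$W1 %*% a + blk$par$b1, 0)
      blk$par$W2 %*% h + blk$par$b2
    }
    want <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))[c]))
    expect_equal(w[n, c, 1, 1], want, tolerance = 1e-12)
  }
})

test_that("zeroed channel-attention bottleneck yields uniform weights 0.5", {
  x <- array(0, c(1, 4, 3, 3))
  blk <- saturate_cam(ifrcnet:::nn_cam(4L, 2L), 0)
  expect_true(all(channel_attention(x, blk) == 0.5))
})

test_that("spatial attention matches a dense convolution oracle", {
  set.seed(22)
  x <- array(rnorm(1 * 3 * 5 * 5), c(1, 3, 5, 5))
  blk <- ifrcnet:::nn_sam(kernel = 7L)
  s <- blk$fwd(x)
  expect_equal(dim(s), c(1L, 1L, 5L, 5L))
  expect_true(all(s > 0 & s < 1))
  stack <- array(0, c(1, 2, 5, 5))
  stack[1, 1, , ] <- apply(x[1, , , ], c(2, 3), mean)
  stack[1, 2, , ] <- apply(x[1, , , ], c(2, 3), max)
  z <- oracle_conv2d(stack, blk$children$conv$par$W, blk$children$conv$par$b,
                     7L, 3L, 1L)
  expect_equal(s, 1 / (1 + exp(-z)), tolerance = 1e-12)
  # zero conv weights: uniform 0.5 map
  expect_true(all(saturate_sam(blk, 0)$fwd(x) == 0.5))
  expect_error(ifrcnet:::nn_sam(kernel = 4L), "odd")
})

test_that("single-channel input gives identical mean and max planes", {
  set.seed(23)
  x <- array(rnorm(1 * 1 * 4 * 4), c(1, 1, 4, 4))
  b1 <- ifrcnet:::nn_sam(3L)
  # mean plane == max plane == the channel itself; doubling the weight on one
  # plane and zeroing the other must not change the output
  b1$children$conv$par$W[] <- rnorm(9)
  s1 <- b1$fwd(x)
  W <- b1$children$conv$par$W
  b1$children$conv$par$W[1, 1:9] <- 0
  b1$children$conv$par$W[1, 10:18] <- W[1, 1:9] + W[1, 10:18]
  expect_equal(b1$fwd(x), s1, tolerance = 1e-12)
})

test_that("rcbam saturates to identity and to doubling", {
  set.seed(24)
  x <- array(rnorm(2 * 4 * 6 * 6), c(2, 4, 6, 6))
  closed <- ifrcnet:::nn_rcbam(4L, 2L)
  saturate_cam(closed$children$cam, -50)
  saturate_sam(closed$children$sam, -50)
  expect_equal(closed$fwd(x), x, tolerance = 1e-4)
  open <- ifrcnet:::nn_rcbam(4L, 2L)
  saturate_cam(open$children$cam, 50)
  saturate_sam(open$children$sam, 50)
  expect_equal(open$fwd(x), 2 * x, tolerance = 1e-4)
})

test_that("rcbam equals the element-wise composition of its parts", {
  set.seed(25)
  x <- array(rnorm(1 * 4 * 3 * 3), c(1, 4, 3, 3))
  blk <- ifrcnet:::nn_rcbam(4L, 2L, sa_kernel = 3L)
  y <- blk$fwd(x)
  ca <- blk$children$cam$fwd(x)
  x1 <- x * 0
  for (c in 1:4) x1[1, c, , ] <- x[1, c, , ] * ca[1, c]
  sa <- blk$children$sam$fwd(x1)
  want <- x
  for (c in 1:4) want[1, c, , ] <- x[1, c, , ] + x1[1, c, , ] * sa[1, 1, , ]
  expect_equal(y, want, tolerance = 1e-12)
})

test_that("msag gate limits hold and the gate composition matches an oracle", {
  set.seed(26)
  x <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  blk <- ifrcnet:::nn_msag(4L, dilation = 2L)
  blk$children$vote$par$W[] <- 0
  blk$children$vote$par$b[] <- -50
  expect_equal(blk$fwd(x), x, tolerance = 1e-4)
  blk$children$vote$par$b[] <- 50
  expect_equal(blk$fwd(x), 2 * x, tolerance = 1e-4)

  blk2 <- ifrcnet:::nn_msag(4L, dilation = 2L)
  y <- blk2$fwd(x, training = FALSE)
  # independent composition in eval mode
  b1 <- oracle_conv2d(x, blk2$children$conv1$par$W, blk2$children$conv1$par$b, 1L, 0L, 1L)
  b2 <- oracle_conv2d(x, blk2$children$conv3$par$W, blk2$children$conv3$par$b, 3L, 1L, 1L)
  b3 <- oracle_conv2d(x, blk2$children$convd$par$W, blk2$children$convd$par$b, 3L, 2L, 2L)
  cat3 <- array(0, c(1, 12, 8, 8))
  cat3[, 1:4, , ] <- b1; cat3[, 5:8, , ] <- b2; cat3[, 9:12, , ] <- b3
  bn <- blk2$children$bn
  for (c in 1:12) {
    cat3[, c, , ] <- (cat3[, c, , ] - bn$buf$rmean[c]) /
      sqrt(bn$buf$rvar[c] + 1e-5) * bn$par$gamma[c] + bn$par$beta[c]
  }
  cat3 <- pmax(cat3, 0)
  v <- oracle_conv2d(cat3, blk2$children$vote$par$W, blk2$children$vote$par$b, 1L, 0L, 1L)
  g <- 1 / (1 + exp(-v))
  want <- x
  for (c in 1:4) want[1, c, , ] <- x[1, c, , ] * (1 + g[1, 1, , ])
  expect_equal(y, want, tolerance = 1e-10)
})

test_that("attention blocks preserve arbitrary shapes and keep gates in (0,1)", {
  set.seed(27)
  for (i in 1:12) {
    n <- sample(1:2, 1); c <- sample(c(2, 3, 4, 8), 1)
    h <- sample(c(4, 5, 8), 1); w <- sample(c(4, 6, 7), 1)
    x <- array(rnorm(n * c * h * w), c(n, c, h, w))
    expect_equal(dim(rcbam(x, ifrcnet:::nn_rcbam(c, 2L, 3L))), dim(x))
    expect_equal(dim(msag(x, ifrcnet:::nn_msag(c, 2L))), dim(x))
    g <- spatial_attention(x, ifrcnet:::nn_sam(3L))
    expect_true(all(g > 0 & g < 1))
  }
})

test_that("residual branches carry an identity gradient component", {
  set.seed(28)
  x <- array(rnorm(1 * 2 * 2 * 2), c(1, 2, 2, 2))
  blk <- ifrcnet:::nn_rcbam(2L, 2L, 3L)
  y <- blk$fwd(x)
  dy <- array(0, dim(x)); dy[1, 1, 1, 1] <- 1
  g <- blk$bwd(dy)
  # finite-difference check of the same directional derivative
  e <- array(0, dim(x)); e[1, 1, 1, 1] <- 1e-5
  fd <- (blk$fwd(x + e)[1, 1, 1, 1] - blk$fwd(x - e)[1, 1, 1, 1]) / 2e-5
  expect_equal(g[1, 1, 1, 1], fd, tolerance = 1e-4)
  # the diagonal term exceeds the pure attention contribution: identity passes through
  expect_gt(g[1, 1, 1, 1], 0.5)
})
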