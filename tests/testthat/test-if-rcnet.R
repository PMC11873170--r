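# Nesting contracts: mixed input, feature fusion, build-time config checks,
# and ablation parity with the standalone classifier.

tiny_seg_cfg <- seg_config(base_width = 4L)
tiny_widths <- c(4L, 8L, 8L, 16L, 16L)

fake_seg_output <- function(prob) {
  structure(list(prob = prob, mask = (prob > 0.5) * 1), class = "ifr_seg_output")
}

test_that("mixed input composes image and mask channels as specified", {
  set.seed(51)
  img <- array(runif(1 * 3 * 8 * 8), c(1, 3, 8, 8))
  ones <- array(1, c(1, 8, 8))
  zeros <- array(0, c(1, 8, 8))
  m4 <- mixed_input(img, fake_seg_output(ones), fusion_config("mask_channel"))
  expect_equal(dim(m4), c(1L, 4L, 8L, 8L))
  expect_equal(m4[, 1:3, , , drop = FALSE], img)
  expect_true(all(m4[, 4, , ] == 1))
  m6 <- mixed_input(img, fake_seg_output(zeros),
                    fusion_config("masked_rgb_concat"))
  expect_equal(dim(m6), c(1L, 6L, 8L, 8L))
  expect_true(all(m6[, 1:3, , ] == 0))
  expect_equal(m6[, 4:6, , , drop = FALSE], img, ignore_attr = TRUE)
  expect_identical(mixed_input(img, fake_seg_output(ones),
                               fusion_config("none")), img)
  bad <- fake_seg_output(array(1, c(1, 4, 4)))
  expect_error(mixed_input(img, bad, fusion_config("mask_channel")),
               "misaligned")
})

test_that("masked channels vanish exactly outside the known tongue region", {
  ds <- tiny_dataset()
  s <- ds[[1]]
  img <- ifrcnet:::batch_images(ds, 1L)
  prob <- array(s$mask, c(1, dim(s$mask)))
  m6 <- mixed_input(img, fake_seg_output(prob),
                    fusion_config("masked_rgb_concat", soft_mask = TRUE))
  outside <- s$mask == 0
  for (c in 1:3) {
    plane <- m6[1, c, , ]
    expect_true(all(plane[outside] == 0))
  }
})

test_that("fuse_features pools a projection to the configured width", {
  set.seed(52)
  f <- array(rnorm(2 * 4 * 6 * 6), c(2, 4, 6, 6))
  blk <- ifrcnet:::nn_fusion(4L, 7L)
  v <- fuse_features(list(f), blk, stage = 1L)
  expect_equal(dim(v), c(2L, 7L))
  # constant map: pooled vector equals the 1x1 projection of the constant
  cst <- array(0, c(1, 4, 3, 3))
  for (c in 1:4) cst[1, c, , ] <- c
  vc <- fuse_features(list(cst), blk, stage = 1L)
  Wm <- blk$children$proj$par$W
  want <- as.vector(Wm %*% 1:4 + blk$children$proj$par$b)
  expect_equal(as.vector(vc), want, tolerance = 1e-12)
  expect_error(fuse_features(list(f), blk, stage = 3L), "invalid encoder stage")
})

test_that("incompatible coupling configs fail at build time", {
  expect_error(
    build_if_rcnet(tiny_seg_cfg,
                   cls_config(widths = tiny_widths, in_channels = 3L),
                   fusion_config("mask_channel", use_fusion = FALSE)),
    "4 input channels")
  expect_error(
    build_if_rcnet(tiny_seg_cfg,
                   cls_config(widths = tiny_widths, in_channels = 4L,
                              fusion_width = 16L),
                   fusion_config("mask_channel", use_fusion = TRUE,
                                 fusion_width = 32L)),
    "fusion_width")
})

test_that("the nested forward yields (N, 3) logits deterministically", {
  model <- build_if_rcnet(
    tiny_seg_cfg,
    cls_config(widths = tiny_widths, in_channels = 4L, fusion_width = 8L),
    fusion_config("mask_channel", fusion_width = 8L),
    seed = 53L)
  x <- array(runif(2 * 3 * 32 * 32), c(2, 3, 32, 32))
  lg1 <- ifrcnet_forward(model, x)
  expect_equal(dim(lg1), c(2L, 3L))
  expect_identical(lg1, ifrcnet_forward(model, x))
})

test_that("the degenerate coupling equals the standalone classifier exactly", {
  cls_cfg <- cls_config(widths = tiny_widths, in_channels = 3L)
  nested <- build_if_rcnet(tiny_seg_cfg, cls_cfg,
                           fusion_config("none", use_fusion = FALSE),
                           seed = 54L)
  alone <- build_rca_net(cls_cfg, seed = 54L)
  x <- array(runif(2 * 3 * 32 * 32), c(2, 3, 32, 32))
  expect_identical(ifrcnet_forward(nested, x), cls_forward(alone, x))
  # and the parameters themselves agree
  expect_identical(module_parameters(nested$children$cls),
                   module_parameters(alone))
})

test_that("checkpoints restore every network type bit for bit", {
  x <- array(runif(1 * 3 * 32 * 32), c(1, 3, 32, 32))
  seg <- build_rca_unet(tiny_seg_cfg, seed = 55L)
  p <- withr::local_tempfile(fileext = ".rds")
  ckpt_save(seg, p, extra = list(note = "unit"))
  seg2 <- ckpt_load(p)
  expect_identical(seg_forward(seg, x)$logits, seg_forward(seg2, x)$logits)
  expect_equal(attr(seg2, "extra")$note, "unit")
  nested <- build_if_rcnet(
    tiny_seg_cfg,
    cls_config(widths = tiny_widths, in_channels = 4L, fusion_width = 8L),
    fusion_config("mask_channel", fusion_width = 8L), seed = 56L)
  p2 <- withr::local_tempfile(fileext = ".rds")
  ckpt_save(nested, p2)
  nested2 <- ckpt_load(p2)
  expect_identical(ifrcnet_forward(nested, x), ifrcnet_forward(nested2, x))
  expect_error(ckpt_load(withr::local_tempfile(fileext = ".rds") |>
                           (\(f) { saveRDS(list(format = "x"), f); f })()),
               "not an ifrcnet checkpoint")
})
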