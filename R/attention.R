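# Attention blocks: channel attention (CAM), spatial attention (SAM), the
# residual convolutional block attention module (RCBAM) that composes them,
# and the multiscale attention gate (MSAG) used on U-Net skip connections.

# Channel attention: sigmoid of a shared two-layer bottleneck applied to the
# global-average and global-max pooled channel descriptors, summed. Returns
# per-(batch, channel) weights in (0, 1).
nn_cam <- function(channels, reduction = 16L) {
  self <- new_module("cam")
  cr <- max(1L, channels %/% reduction)
  self$par$W1 <- matrix(rnorm(cr * channels, sd = sqrt(2 / channels)), cr, channels)
  self$par$b1 <- numeric(cr)
  self$par$W2 <- matrix(rnorm(channels * cr, sd = sqrt(2 / cr)), channels, cr)
  self$par$b2 <- numeric(channels)
  self$gr$W1 <- matrix(0, cr, channels); self$gr$b1 <- numeric(cr)
  self$gr$W2 <- matrix(0, channels, cr); self$gr$b2 <- numeric(channels)
  self$meta <- list(channels = channels, reduction = reduction)
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    n <- d[1]
    avg <- global_avg_pool(x)
    mp <- global_max_pool(x)
    path <- function(a) {
      h <- a %*% t(self$par$W1) + rep(self$par$b1, each = n)
      r <- h * (h > 0)
      list(h = h, r = r,
           s = r %*% t(self$par$W2) + rep(self$par$b2, each = n))
    }
    pa <- path(avg)
    pm <- path(mp$y)
    w <- sigmoid(pa$s + pm$s)
    self$cache <- list(dims = d, avg = avg, mx = mp$y, idx = mp$idx,
                       pa = pa, pm = pm, w = w)
    w
  }
  self$bwd <- function(dw) {
    ca <- self$cache
    d <- ca$dims
    dz <- dw * ca$w * (1 - ca$w)
    back_path <- function(p, a) {
      dr <- dz %*% self$par$W2
      self$gr$W2 <- self$gr$W2 + crossprod(dz, p$r)
      self$gr$b2 <- self$gr$b2 + colSums(dz)
      dh <- dr * (p$h > 0)
      self$gr$W1 <- self$gr$W1 + crossprod(dh, a)
      self$gr$b1 <- self$gr$b1 + colSums(dh)
      dh %*% self$par$W1
    }
    davg <- back_path(ca$pa, ca$avg)
    dmx <- back_path(ca$pm, ca$mx)
    global_avg_pool_bwd(davg, d) + global_max_pool_bwd(dmx, ca$idx, d)
  }
  self
}

# Spatial attention: sigmoid of a k x k convolution over the 2-plane stack
# [channel mean, channel max]. Returns a (batch, 1, H, W) map in (0, 1).
nn_sam <- function(kernel = 7L) {
  if (kernel %% 2L == 0L) {
    stop("spatial attention kernel must be odd, got ", kernel, call. = FALSE)
  }
  self <- new_module("sam")
  self$children$conv <- nn_conv2d(2L, 1L, kernel = kernel,
                                  pad = (kernel - 1L) %/% 2L)
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    e <- aperm(x, c(2, 1, 3, 4))
    dim(e) <- c(d[2], d[1] * d[3] * d[4])
    te <- t(e)
    idx <- max.col(te, ties.method = "first")
    mxv <- te[cbind(seq_len(nrow(te)), idx)]
    stack <- array(0, c(d[1], 2L, d[3], d[4]))
    stack[, 1, , ] <- colMeans(e)
    stack[, 2, , ] <- mxv
    z <- self$children$conv$fwd(stack, training)
    s <- sigmoid(z)
    self$cache <- list(dims = d, idx = idx, s = s)
    s
  }
  self$bwd <- function(ds) {
    ca <- self$cache
    d <- ca$dims
    dz <- ds * ca$s * (1 - ca$s)
    dstack <- self$children$conv$bwd(dz)
    dmn <- dstack[, 1, , , drop = FALSE]
    dmx <- dstack[, 2, , , drop = FALSE]
    nhw <- d[1] * d[3] * d[4]
    dte <- matrix(0, nhw, d[2])
    dte[cbind(seq_len(nhw), ca$idx)] <- as.vector(dmx)
    dte <- dte + as.vector(dmn) / d[2]
    de <- t(dte)
    dim(de) <- c(d[2], d[1], d[3], d[4])
    aperm(de, c(2, 1, 3, 4))
  }
  self
}

# RCBAM: y = x + (x * CAM(x)) * SAM(x * CAM(x)). Channel attention first,
# then spatial attention on the channel-reweighted map, one residual around
# the whole composition.
nn_rcbam <- function(channels, reduction = 16L, sa_kernel = 7L) {
  self <- new_module("rcbam")
  self$children$cam <- nn_cam(channels, reduction)
  self$children$sam <- nn_sam(sa_kernel)
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    ca <- self$children$cam$fwd(x, training)
    x1 <- x * as.vector(ca)
    sa <- self$children$sam$fwd(x1, training)
    sb <- bcast_spatial(sa, d)
    self$cache <- list(x = x, ca = ca, x1 = x1, sb = sb, dims = d)
    x + x1 * sb
  }
  self$bwd <- function(dy) {
    cc <- self$cache
    d <- cc$dims
    dx2 <- dy
    dsa <- sum_channels(dx2 * cc$x1)
    dx1 <- dx2 * cc$sb + self$children$sam$bwd(dsa)
    dca <- sum_spatial(dx1 * cc$x)
    dy + dx1 * as.vector(cc$ca) + self$children$cam$bwd(dca)
  }
  self
}

# MSAG: three parallel branches (1x1, 3x3, 3x3 dilated) concatenated,
# batch-normalized and rectified, reduced by a 1x1 "vote" convolution to a
# per-pixel sigmoid gate g; output is x + x * g.
nn_msag <- function(channels, dilation = 2L) {
  self <- new_module("msag")
  C <- channels
  self$children$conv1 <- nn_conv2d(C, C, kernel = 1L)
  self$children$conv3 <- nn_conv2d(C, C, kernel = 3L, pad = 1L)
  self$children$convd <- nn_conv2d(C, C, kernel = 3L, pad = dilation,
                                   dilation = dilation)
  self$children$bn <- nn_bn2d(3L * C)
  self$children$vote <- nn_conv2d(3L * C, 1L, kernel = 1L)
  self$meta <- list(channels = C, dilation = dilation)
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    C <- self$meta$channels
    cat3 <- array(0, c(d[1], 3L * C, d[3], d[4]))
    cat3[, 1:C, , ] <- self$children$conv1$fwd(x, training)
    cat3[, (C + 1L):(2L * C), , ] <- self$children$conv3$fwd(x, training)
    cat3[, (2L * C + 1L):(3L * C), , ] <- self$children$convd$fwd(x, training)
    bn <- self$children$bn$fwd(cat3, training)
    pos <- bn > 0
    r <- bn * pos
    v <- self$children$vote$fwd(r, training)
    g <- sigmoid(v)
    gb <- bcast_spatial(g, d)
    self$cache <- list(x = x, pos = pos, g = g, gb = gb, dims = d)
    x + x * gb
  }
  self$bwd <- function(dy) {
    cc <- self$cache
    d <- cc$dims
    C <- self$meta$channels
    dg <- sum_channels(dy * cc$x)
    dv <- dg * cc$g * (1 - cc$g)
    dr <- self$children$vote$bwd(dv)
    dbn <- dr * cc$pos
    dcat <- self$children$bn$bwd(dbn)
    dx <- dy + dy * cc$gb
    dx <- dx + self$children$conv1$bwd(dcat[, 1:C, , , drop = FALSE])
    dx <- dx + self$children$conv3$bwd(dcat[, (C + 1L):(2L * C), , , drop = FALSE])
    dx + self$children$convd$bwd(dcat[, (2L * C + 1L):(3L * C), , , drop = FALSE])
  }
  self
}

## ---- user-facing functional wrappers ----

#' Channel attention weights, broadcast to the input's shape
#'
#' Computes per-(image, channel) attention weights in (0, 1): the sigmoid of a
#' shared two-layer bottleneck applied to the global-average and global-max
#' pooled channel descriptors, summed. With `block = NULL` a block with
#' freshly initialized weights (drawn from the current RNG) is used.
#'
#' @param x feature map, array (batch, channel, height, width)
#' @param block an existing channel-attention block, or `NULL`
#' @param reduction bottleneck reduction ratio (default 16)
#' @return array shaped like `x` holding the broadcast weights
#' @export
channel_attention <- function(x, block = NULL, reduction = 16L) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  if (is.null(block)) block <- nn_cam(d[2], reduction)
  bcast_channel(block$fwd(x), d)
}

#' Spatial attention weights, broadcast to the input's shape
#'
#' Per-pixel weights in (0, 1): the sigmoid of a `kernel` x `kernel`
#' convolution over the channel-mean and channel-max planes of `x`.
#'
#' @inheritParams channel_attention
#' @param kernel odd convolution kernel size (default 7)
#' @return array shaped like `x` holding the broadcast weights
#' @export
spatial_attention <- function(x, block = NULL, kernel = 7L) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  if (is.null(block)) block <- nn_sam(kernel)
  bcast_spatial(block$fwd(x), d)
}

#' Apply a residual channel+spatial attention block
#'
#' `y = x + (x * CAM(x)) * SAM(x * CAM(x))`: with all attention weights at 1
#' the block doubles its input; with weights at 0 it is the identity.
#'
#' @inheritParams channel_attention
#' @param sa_kernel spatial attention kernel (odd, default 7)
#' @return feature map shaped like `x`
#' @export
rcbam <- function(x, block = NULL, reduction = 16L, sa_kernel = 7L) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  if (is.null(block)) block <- nn_rcbam(d[2], reduction, sa_kernel)
  block$fwd(x)
}

#' Apply a multiscale attention gate
#'
#' Pointwise, ordinary, and dilated 3x3 convolutions are concatenated,
#' batch-normalized and rectified, then reduced by a 1x1 "vote" convolution to
#' a per-pixel sigmoid gate g; the result is `x + x * g`.
#'
#' @inheritParams channel_attention
#' @param dilation dilation factor of the third branch (default 2)
#' @return feature map shaped like `x`
#' @export
msag <- function(x, block = NULL, dilation = 2L) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  if (is.null(block)) block <- nn_msag(d[2], dilation)
  block$fwd(x)
}
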