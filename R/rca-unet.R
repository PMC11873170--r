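# RCA-UNet: 4-stage U-Net for binary tongue segmentation. Each encoder stage
# is a dual 3x3 conv (conv-BN-ReLU twice) followed by a residual
# channel/spatial attention block; skip connections pass through multiscale
# attention gates; the decoder upsamples with 2x2 stride-2 transposed
# convolutions and concatenates the gated skips.

nn_seq <- function(children) {
  self <- new_module("seq")
  self$children <- children
  self$fwd <- function(x, training = FALSE) {
    for (ch in self$children) x <- ch$fwd(x, training)
    x
  }
  self$bwd <- function(dy) {
    for (ch in rev(self$children)) dy <- ch$bwd(dy)
    dy
  }
  self
}

nn_dual_conv <- function(in_ch, out_ch) {
  nn_seq(list(
    conv1 = nn_conv2d(in_ch, out_ch, kernel = 3L, pad = 1L),
    bn1 = nn_bn2d(out_ch),
    relu1 = nn_relu(),
    conv2 = nn_conv2d(out_ch, out_ch, kernel = 3L, pad = 1L),
    bn2 = nn_bn2d(out_ch),
    relu2 = nn_relu()
  ))
}

#' Dual 3x3 convolution block
#'
#' Two successive conv(3x3, padding 1) -> batch-norm -> ReLU stages; the
#' building block of every encoder/decoder stage of the segmentation network.
#' Spatial size is preserved; the channel count becomes `out_channels`.
#'
#' @param x feature map, array (batch, channel, height, width)
#' @param out_channels output channel count
#' @param block an existing block (reused weights), or `NULL` for a freshly
#'   initialized one drawn from the current RNG
#' @param training use batch statistics in the BN layers
#' @return feature map (batch, out_channels, height, width)
#' @export
dual_conv <- function(x, out_channels, block = NULL, training = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  if (is.null(block)) block <- nn_dual_conv(d[2], out_channels)
  block$fwd(x, training)
}

#' Segmentation network configuration
#'
#' @param base_width channels of the first encoder stage; stages use
#'   `base_width * c(1, 2, 4, 8)` and the bottleneck `base_width * 16`
#' @param in_channels input channels (3 for RGB)
#' @param msag_dilation dilation of the gate's third branch
#' @param rcbam_reduction channel-attention bottleneck ratio
#' @param sa_kernel spatial-attention kernel (odd)
#' @return an object of class `ifr_seg_config`
#' @export
seg_config <- function(base_width = 64L, in_channels = 3L, msag_dilation = 2L,
                       rcbam_reduction = 16L, sa_kernel = 7L) {
  cfg <- list(base_width = as.integer(base_width),
              in_channels = as.integer(in_channels),
              depth = 4L,
              msag_dilation = as.integer(msag_dilation),
              rcbam_reduction = as.integer(rcbam_reduction),
              sa_kernel = as.integer(sa_kernel))
  class(cfg) <- "ifr_seg_config"
  cfg
}

#' Build an RCA-UNet segmentation network
#'
#' @param cfg a [seg_config()]
#' @param seed optional integer; when given, `set.seed(seed)` is called before
#'   weight initialization so builds are reproducible
#' @return an `ifr_module` of type `rca_unet`
#' @export
build_rca_unet <- function(cfg = seg_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- cfg$base_width
  w <- b * c(1L, 2L, 4L, 8L)
  self <- new_module("rca_unet")
  self$cfg <- cfg
  ch <- list()
  in_ch <- cfg$in_channels
  for (i in 1:4) {
    ch[[paste0("enc_dual", i)]] <- nn_dual_conv(in_ch, w[i])
    ch[[paste0("enc_att", i)]] <- nn_rcbam(w[i], cfg$rcbam_reduction, cfg$sa_kernel)
    ch[[paste0("pool", i)]] <- nn_maxpool2()
    in_ch <- w[i]
  }
  ch$bottleneck <- nn_dual_conv(w[4], 16L * b)
  for (i in 4:1) {
    up_in <- if (i == 4) 16L * b else w[i + 1]
    ch[[paste0("up", i)]] <- nn_deconv2(up_in, w[i])
    ch[[paste0("gate", i)]] <- nn_msag(w[i], cfg$msag_dilation)
    ch[[paste0("dec_dual", i)]] <- nn_dual_conv(2L * w[i], w[i])
  }
  ch$head <- nn_conv2d(w[1], 2L, kernel = 1L)
  self$children <- ch
  self$widths <- w

  self$fwd <- function(x, training = FALSE) {
    ch <- self$children
    skips <- vector("list", 4)
    cur <- x
    for (i in 1:4) {
      cur <- ch[[paste0("enc_dual", i)]]$fwd(cur, training)
      cur <- ch[[paste0("enc_att", i)]]$fwd(cur, training)
      skips[[i]] <- cur
      cur <- ch[[paste0("pool", i)]]$fwd(cur, training)
    }
    cur <- ch$bottleneck$fwd(cur, training)
    enc <- c(skips, list(cur))
    for (i in 4:1) {
      up <- ch[[paste0("up", i)]]$fwd(cur, training)
      g <- ch[[paste0("gate", i)]]$fwd(skips[[i]], training)
      d <- dim(up)
      cc <- array(0, c(d[1], 2L * d[2], d[3], d[4]))
      cc[, 1:d[2], , ] <- up
      cc[, (d[2] + 1L):(2L * d[2]), , ] <- g
      cur <- ch[[paste0("dec_dual", i)]]$fwd(cc, training)
    }
    logits <- ch$head$fwd(cur, training)
    list(logits = logits, encoder_features = enc)
  }

  # dlogits: gradient w.r.t. the logits; denc: optional list of 5 gradients
  # w.r.t. the encoder features (skips 1..4, bottleneck), used when encoder
  # features feed the classifier (feature fusion) or the mixed input is not
  # frozen.
  self$bwd <- function(dlogits, denc = NULL) {
    ch <- self$children
    w <- self$widths
    dcur <- ch$head$bwd(dlogits)
    dskip <- vector("list", 4)
    for (i in 1:4) {
      dcc <- ch[[paste0("dec_dual", i)]]$bwd(dcur)
      dup <- dcc[, 1:w[i], , , drop = FALSE]
      dsk <- dcc[, (w[i] + 1L):(2L * w[i]), , , drop = FALSE]
      dskip[[i]] <- ch[[paste0("gate", i)]]$bwd(dsk)
      dcur <- ch[[paste0("up", i)]]$bwd(dup)
    }
    if (!is.null(denc) && !is.null(denc[[5]])) dcur <- dcur + denc[[5]]
    dcur <- ch$bottleneck$bwd(dcur)
    for (i in 4:1) {
      dcur <- ch[[paste0("pool", i)]]$bwd(dcur)
      dcur <- dcur + dskip[[i]]
      if (!is.null(denc) && !is.null(denc[[i]])) dcur <- dcur + denc[[i]]
      dcur <- ch[[paste0("enc_att", i)]]$bwd(dcur)
      dcur <- ch[[paste0("enc_dual", i)]]$bwd(dcur)
    }
    dcur
  }
  self
}

#' Run the segmentation network
#'
#' @param net a network from [build_rca_unet()]
#' @param x image batch, array (batch, 3, H, W) with H and W divisible by 16
#' @param training propagate training mode to BN layers
#' @return an `ifr_seg_output` list: `logits` (batch, 2, H, W), `prob`
#'   (batch, H, W) foreground softmax probability, `mask` (batch, H, W)
#'   argmax mask, and `encoder_features` (5 feature maps, deepest last)
#' @export
seg_forward <- function(net, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4) stop("seg_forward: input must be 4-axis", call. = FALSE)
  if (d[3] %% 16L != 0L || d[4] %% 16L != 0L) {
    stop(sprintf("seg_forward: spatial size %dx%d not divisible by 16",
                 d[3], d[4]), call. = FALSE)
  }
  out <- net$fwd(x, training)
  lg <- out$logits
  a <- lg[, 1, , , drop = FALSE]; dim(a) <- dim(lg)[-2]
  b <- lg[, 2, , , drop = FALSE]; dim(b) <- dim(lg)[-2]
  mx <- pmax(a, b)
  lse <- mx + log(exp(a - mx) + exp(b - mx))
  prob <- exp(b - lse)
  res <- list(logits = lg,
              prob = prob,
              mask = (b > a) * 1,
              encoder_features = out$encoder_features)
  class(res) <- "ifr_seg_output"
  res
}
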