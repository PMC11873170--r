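# RCA-Net: the classification backbone. Five conv blocks (3x3 conv -> BN ->
# ReLU -> RCBAM); the first two convolutions are dilated (factors 3 and 2) so
# the stem keeps full resolution while widening its receptive field. A branch
# (RCBAM + max-pool + 1x1 projection) taps the first block's output and is
# added to the main path at the post-block-2 resolution. Adaptive average
# pooling to 1x1 feeds a 512-512-3 fully connected classifier with ReLU and
# dropout between the layers.

nn_conv_block <- function(in_ch, out_ch, dilation = 1L, reduction = 16L,
                          sa_kernel = 7L) {
  nn_seq(list(
    conv = nn_conv2d(in_ch, out_ch, kernel = 3L, pad = dilation,
                     dilation = dilation),
    bn = nn_bn2d(out_ch),
    relu = nn_relu(),
    att = nn_rcbam(out_ch, reduction, sa_kernel)
  ))
}

#' Dilated convolution block of the classification backbone
#'
#' conv(3x3, padding = dilation) -> BN -> ReLU -> RCBAM. Padding equals the
#' dilation factor so spatial size is preserved; the effective receptive-field
#' span of the kernel is `dilation * 2 + 1` pixels.
#'
#' @inheritParams dual_conv
#' @param dilation dilation factor (1 = ordinary convolution)
#' @export
conv_block <- function(x, out_channels, dilation = 1L, block = NULL,
                       training = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  if (is.null(block)) block <- nn_conv_block(d[2], out_channels, dilation)
  block$fwd(x, training)
}

#' Classification network configuration
#'
#' Defaults follow the published architecture: five conv blocks, the first
#' two dilated with factors 3 and 2, and a three-layer 512-512-3 classifier
#' head with dropout.
#'
#' @param widths channel counts of the five conv blocks
#' @param in_channels 3 for plain RGB, 4 for mixed input (mask channel),
#'   6 for the masked-RGB concat variant
#' @param dilations five dilation factors (first two must be 3 and 2)
#' @param fc_nodes sizes of the three fully connected layers (last must be 3)
#' @param dropout_rate dropout probability between FC layers
#' @param fusion_width length of the fused segmentation-feature vector
#'   concatenated before the first FC layer; 0 disables fusion
#' @param rcbam_reduction,sa_kernel attention block parameters
#' @return an object of class `ifr_cls_config`
#' @export
cls_config <- function(widths = c(32L, 64L, 128L, 256L, 512L),
                       in_channels = 3L,
                       dilations = c(3L, 2L, 1L, 1L, 1L),
                       fc_nodes = c(512L, 512L, 3L),
                       dropout_rate = 0.5,
                       fusion_width = 0L,
                       rcbam_reduction = 16L,
                       sa_kernel = 7L) {
  if (length(widths) != 5L) stop("cls_config: exactly 5 conv blocks", call. = FALSE)
  if (length(dilations) != 5L || dilations[1] != 3L || dilations[2] != 2L) {
    stop("cls_config: dilations must have length 5 with first two 3 and 2",
         call. = FALSE)
  }
  if (length(fc_nodes) != 3L || fc_nodes[3] != 3L) {
    stop("cls_config: classifier is 3 FC layers ending in 3 nodes", call. = FALSE)
  }
  cfg <- list(widths = as.integer(widths), in_channels = as.integer(in_channels),
              dilations = as.integer(dilations), fc_nodes = as.integer(fc_nodes),
              dropout_rate = dropout_rate, fusion_width = as.integer(fusion_width),
              rcbam_reduction = as.integer(rcbam_reduction),
              sa_kernel = as.integer(sa_kernel))
  class(cfg) <- "ifr_cls_config"
  cfg
}

#' Build an RCA-Net classification network
#'
#' @param cfg a [cls_config()]
#' @param seed optional integer seed for reproducible initialization
#' @return an `ifr_module` of type `rca_net`
#' @export
build_rca_net <- function(cfg = cls_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- cfg$widths
  self <- new_module("rca_net")
  self$cfg <- cfg
  ch <- list()
  in_ch <- cfg$in_channels
  for (i in 1:5) {
    ch[[paste0("block", i)]] <- nn_conv_block(in_ch, w[i], cfg$dilations[i],
                                              cfg$rcbam_reduction, cfg$sa_kernel)
    in_ch <- w[i]
  }
  ch$branch_att <- nn_rcbam(w[1], cfg$rcbam_reduction, cfg$sa_kernel)
  ch$branch_pool <- nn_maxpool2()
  ch$branch_proj <- nn_conv2d(w[1], w[2], kernel = 1L)
  for (i in 2:5) ch[[paste0("pool", i)]] <- nn_maxpool2()
  fc_in <- w[5] + cfg$fusion_width
  ch$fc1 <- nn_fc(fc_in, cfg$fc_nodes[1])
  ch$relu1 <- nn_relu()
  ch$drop1 <- nn_dropout(cfg$dropout_rate)
  ch$fc2 <- nn_fc(cfg$fc_nodes[1], cfg$fc_nodes[2])
  ch$relu2 <- nn_relu()
  ch$drop2 <- nn_dropout(cfg$dropout_rate)
  ch$fc3 <- nn_fc(cfg$fc_nodes[2], cfg$fc_nodes[3])
  self$children <- ch

  self$fwd <- function(x, training = FALSE, fused = NULL) {
    ch <- self$children
    cfg <- self$cfg
    c1 <- ch$block1$fwd(x, training)
    c2 <- ch$block2$fwd(c1, training)
    m <- ch$pool2$fwd(c2, training)
    br <- ch$branch_att$fwd(c1, training)
    br <- ch$branch_pool$fwd(br, training)
    br <- ch$branch_proj$fwd(br, training)
    m <- m + br
    for (i in 3:5) {
      m <- ch[[paste0("block", i)]]$fwd(m, training)
      m <- ch[[paste0("pool", i)]]$fwd(m, training)
    }
    feat <- global_avg_pool(m)
    self$cache <- list(mdims = dim(m), has_fused = !is.null(fused))
    z <- if (is.null(fused)) feat else cbind(feat, fused)
    h <- ch$fc1$fwd(z, training)
    h <- ch$relu1$fwd(h, training)
    h <- ch$drop1$fwd(h, training)
    h <- ch$fc2$fwd(h, training)
    h <- ch$relu2$fwd(h, training)
    h <- ch$drop2$fwd(h, training)
    ch$fc3$fwd(h, training)
  }

  self$bwd <- function(dlogits) {
    ch <- self$children
    cfg <- self$cfg
    ca <- self$cache
    dh <- ch$fc3$bwd(dlogits)
    dh <- ch$drop2$bwd(dh)
    dh <- ch$relu2$bwd(dh)
    dh <- ch$fc2$bwd(dh)
    dh <- ch$drop1$bwd(dh)
    dh <- ch$relu1$bwd(dh)
    dz <- ch$fc1$bwd(dh)
    nb <- cfg$widths[5]
    dfeat <- dz[, 1:nb, drop = FALSE]
    dfused <- if (ca$has_fused) dz[, (nb + 1L):ncol(dz), drop = FALSE] else NULL
    dm <- global_avg_pool_bwd(dfeat, ca$mdims)
    for (i in 5:3) {
      dm <- ch[[paste0("pool", i)]]$bwd(dm)
      dm <- ch[[paste0("block", i)]]$bwd(dm)
    }
    dbr <- ch$branch_proj$bwd(dm)
    dbr <- ch$branch_pool$bwd(dbr)
    dc1_br <- ch$branch_att$bwd(dbr)
    dc2 <- ch$pool2$bwd(dm)
    dc1 <- ch$block2$bwd(dc2) + dc1_br
    list(dx = ch$block1$bwd(dc1), dfused = dfused)
  }
  self
}

#' Run the classification network
#'
#' @param net a network from [build_rca_net()]
#' @param x input batch (batch, in_channels, H, W); any spatial size whose
#'   four pooling stages stay even is accepted (adaptive pooling handles the
#'   rest)
#' @param fused optional matrix (batch, fusion_width) of fused segmentation
#'   features, concatenated before the first FC layer
#' @param training enables batch statistics and dropout
#' @return logits matrix (batch, 3)
#' @export
cls_forward <- function(net, x, fused = NULL, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[2] != net$cfg$in_channels) {
    stop(sprintf("cls_forward: expected (N, %d, H, W) input", net$cfg$in_channels),
         call. = FALSE)
  }
  fw <- net$cfg$fusion_width
  if (fw > 0L) {
    if (is.null(fused) || !is.matrix(fused) || ncol(fused) != fw ||
        nrow(fused) != d[1]) {
      stop(sprintf("cls_forward: fused features must be a (%d, %d) matrix",
                   d[1], fw), call. = FALSE)
    }
  } else if (!is.null(fused)) {
    stop("cls_forward: fused features supplied but fusion_width is 0",
         call. = FALSE)
  }
  net$fwd(x, training = training, fused = fused)
}
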