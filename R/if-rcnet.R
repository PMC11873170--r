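# IF-RCNet: the two-level nesting of RCA-UNet and RCA-Net. The segmentation
# network contributes (a) a mixed input — the predicted foreground
# probability joined to the original image — and (b) fused features — a
# pooled 1x1 projection of one encoder stage concatenated before the
# classifier's first FC layer.

#' Coupling configuration for the nested network
#'
#' @param mix_mode `"mask_channel"` appends the predicted foreground
#'   probability as a 4th input channel; `"masked_rgb_concat"` concatenates
#'   the masked RGB image with the original (6 channels); `"none"` feeds the
#'   raw image (ablation baseline)
#' @param use_fusion concatenate pooled segmentation encoder features before
#'   the classifier's first FC layer
#' @param fusion_stage encoder stage whose features are fused (1-4 = skip
#'   stages, 5 = bottleneck, the default)
#' @param fusion_width channels after the 1x1 projection
#' @param freeze_seg do not update segmentation weights while training the
#'   classifier (two-phase training, the default)
#' @param soft_mask mix the softmax foreground probability rather than the
#'   hard argmax mask
#' @return an object of class `ifr_fusion_config`
#' @export
fusion_config <- function(mix_mode = c("mask_channel", "masked_rgb_concat", "none"),
                          use_fusion = TRUE,
                          fusion_stage = 5L,
                          fusion_width = 128L,
                          freeze_seg = TRUE,
                          soft_mask = TRUE) {
  mix_mode <- match.arg(mix_mode)
  if (!fusion_stage %in% 1:5) {
    stop("fusion_config: fusion_stage must be in 1..5", call. = FALSE)
  }
  cfg <- list(mix_mode = mix_mode, use_fusion = use_fusion,
              fusion_stage = as.integer(fusion_stage),
              fusion_width = as.integer(fusion_width),
              freeze_seg = freeze_seg, soft_mask = soft_mask)
  class(cfg) <- "ifr_fusion_config"
  cfg
}

mix_in_channels <- function(mix_mode) {
  switch(mix_mode, none = 3L, mask_channel = 4L, masked_rgb_concat = 6L)
}

#' Build the mixed classifier input from a segmentation result
#'
#' @param images image batch (batch, 3, H, W)
#' @param seg an `ifr_seg_output` from [seg_forward()] (spatially aligned)
#' @param cfg a [fusion_config()]
#' @return input batch with 3, 4 or 6 channels depending on `mix_mode`
#' @export
mixed_input <- function(images, seg, cfg) {
  d <- dim(images)
  stopifnot(length(d) == 4, d[2] == 3)
  m <- if (cfg$soft_mask) seg$prob else seg$mask
  if (!identical(as.integer(dim(m)), as.integer(d[-2]))) {
    stop("mixed_input: image and mask shapes are misaligned", call. = FALSE)
  }
  if (cfg$mix_mode == "none") return(images)
  if (cfg$mix_mode == "mask_channel") {
    out <- array(0, c(d[1], 4L, d[3], d[4]))
    out[, 1:3, , ] <- images
    out[, 4, , ] <- m
  } else {
    mb <- bcast_spatial(m, d)
    out <- array(0, c(d[1], 6L, d[3], d[4]))
    out[, 1:3, , ] <- images * mb
    out[, 4:6, , ] <- images
  }
  out
}

# 1x1 projection + global average pooling of one encoder feature map.
nn_fusion <- function(in_ch, width) {
  self <- new_module("fusion")
  self$children$proj <- nn_conv2d(in_ch, width, kernel = 1L)
  self$fwd <- function(x, training = FALSE) {
    y <- self$children$proj$fwd(x, training)
    self$cache <- dim(y)
    global_avg_pool(y)
  }
  self$bwd <- function(dv) {
    self$children$proj$bwd(global_avg_pool_bwd(dv, self$cache))
  }
  self
}

#' Pool segmentation encoder features into a fusion vector
#'
#' Selects one encoder feature map, projects it with a 1x1 convolution to
#' `fusion_width` channels and global-average-pools it to a vector.
#'
#' @param encoder_features list of 5 encoder feature maps (from
#'   [seg_forward()])
#' @param block an existing fusion projection block, or `NULL` for a freshly
#'   initialized one
#' @param stage which encoder stage to fuse (1-5)
#' @param fusion_width projection width used when `block` is `NULL`
#' @return matrix (batch, fusion_width)
#' @export
fuse_features <- function(encoder_features, block = NULL, stage = 5L,
                          fusion_width = 128L) {
  if (!stage %in% seq_along(encoder_features)) {
    stop("fuse_features: invalid encoder stage index ", stage, call. = FALSE)
  }
  f <- encoder_features[[stage]]
  if (is.null(block)) block <- nn_fusion(dim(f)[2], fusion_width)
  block$fwd(f)
}

#' Build the nested IF-RCNet
#'
#' Checks configuration compatibility at build time: the classifier's input
#' channels must match `mix_mode` (3/4/6) and its `fusion_width` must match
#' the coupling config.
#'
#' @param seg_cfg a [seg_config()]
#' @param cls_cfg a [cls_config()]
#' @param fus_cfg a [fusion_config()]
#' @param seed optional integer seed for reproducible initialization
#' @return an `ifr_module` of type `if_rcnet` with children `seg`, `cls` and
#'   (when fusion is enabled) `fusion`
#' @export
build_if_rcnet <- function(seg_cfg = seg_config(), cls_cfg = cls_config(),
                           fus_cfg = fusion_config(), seed = NULL) {
  need_in <- mix_in_channels(fus_cfg$mix_mode)
  if (cls_cfg$in_channels != need_in) {
    stop(sprintf(paste0("build_if_rcnet: mix_mode '%s' needs a classifier with ",
                        "%d input channels, got %d"),
                 fus_cfg$mix_mode, need_in, cls_cfg$in_channels), call. = FALSE)
  }
  need_fw <- if (fus_cfg$use_fusion) fus_cfg$fusion_width else 0L
  if (cls_cfg$fusion_width != need_fw) {
    stop(sprintf("build_if_rcnet: classifier fusion_width %d does not match coupling config (%d)",
                 cls_cfg$fusion_width, need_fw), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  self <- new_module("if_rcnet")
  self$fus_cfg <- fus_cfg
  self$seg_cfg <- seg_cfg
  self$cls_cfg <- cls_cfg
  # the classifier is built first so that, with equal seeds, the ablation
  # baseline is parameter-identical to a standalone classifier network
  self$children$cls <- build_rca_net(cls_cfg)
  self$children$seg <- build_rca_unet(seg_cfg)
  if (fus_cfg$use_fusion) {
    enc_ch <- self$children$seg$widths[min(fus_cfg$fusion_stage, 4L)]
    if (fus_cfg$fusion_stage == 5L) enc_ch <- 16L * seg_cfg$base_width
    self$children$fusion <- nn_fusion(enc_ch, fus_cfg$fusion_width)
  }
  self
}

#' Forward pass of the nested network
#'
#' Runs segmentation, builds the mixed input, fuses encoder features, and
#' classifies. The segmentation part always runs in evaluation mode when
#' `freeze_seg` is set.
#'
#' @param model a network from [build_if_rcnet()]
#' @param x image batch (batch, 3, H, W), spatial size divisible by 16
#' @param training enables batch statistics and dropout in the trainable parts
#' @return logits matrix (batch, 3)
#' @export
ifrcnet_forward <- function(model, x, training = FALSE) {
  fc <- model$fus_cfg
  seg_training <- training && !fc$freeze_seg
  seg <- seg_forward(model$children$seg, x, training = seg_training)
  xin <- mixed_input(x, seg, fc)
  fused <- if (fc$use_fusion) {
    model$children$fusion$fwd(seg$encoder_features[[fc$fusion_stage]], training)
  } else NULL
  logits <- model$children$cls$fwd(xin, training = training, fused = fused)
  model$cache <- list(seg = seg, xdims = dim(x))
  logits
}

# Backward pass for the nested network. Always backpropagates through the
# classifier (and the fusion projection); when freeze_seg is FALSE the
# gradient continues into the segmentation network through both couplings
# (the mixed mask channel via the softmax Jacobian, and the fused encoder
# stage).
ifrcnet_bwd <- function(model, dlogits) {
  fc <- model$fus_cfg
  r <- model$children$cls$bwd(dlogits)
  denc_fuse <- if (fc$use_fusion) model$children$fusion$bwd(r$dfused) else NULL
  if (fc$freeze_seg) return(invisible(NULL))
  seg <- model$cache$seg
  d <- model$cache$xdims
  if (fc$mix_mode == "masked_rgb_concat") {
    stop("joint training through the masked_rgb_concat coupling is not supported; use freeze_seg = TRUE",
         call. = FALSE)
  }
  dprob <- if (fc$mix_mode == "mask_channel") {
    dp <- r$dx[, 4, , , drop = FALSE]
    dim(dp) <- d[-2]
    dp
  } else NULL
  denc <- vector("list", 5)
  if (!is.null(denc_fuse)) denc[[fc$fusion_stage]] <- denc_fuse
  dlog_seg <- array(0, dim(seg$logits))
  if (!is.null(dprob) && fc$soft_mask) {
    s <- seg$prob * (1 - seg$prob) * dprob
    dlog_seg[, 2, , ] <- s
    dlog_seg[, 1, , ] <- -s
  }
  model$children$seg$bwd(dlog_seg, denc)
  invisible(NULL)
}

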