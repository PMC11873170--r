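# Single-file checkpoints with a versioned header. The network is rebuilt
# from its stored configuration and the parameter/buffer state is loaded.

CKPT_FORMAT <- "ifrcnet-checkpoint"
CKPT_VERSION <- 1L

#' Save a network checkpoint
#'
#' @param net an RCA-UNet, RCA-Net or IF-RCNet module
#' @param path output file
#' @param extra optional named list stored alongside (e.g. history)
#' @export
ckpt_save <- function(net, path, extra = list()) {
  cfg <- switch(net$type,
                rca_unet = list(seg_cfg = net$cfg),
                rca_net = list(cls_cfg = net$cfg),
                if_rcnet = list(seg_cfg = net$seg_cfg, cls_cfg = net$cls_cfg,
                                fus_cfg = net$fus_cfg),
                stop("ckpt_save: unsupported module type ", net$type,
                     call. = FALSE))
  saveRDS(list(format = CKPT_FORMAT, version = CKPT_VERSION, type = net$type,
               cfg = cfg, state = module_state(net), extra = extra),
          path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path checkpoint file from [ckpt_save()]
#' @return the rebuilt network with restored parameters; the checkpoint's
#'   `extra` list is attached as attribute `"extra"`
#' @export
ckpt_load <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, CKPT_FORMAT)) {
    stop("ckpt_load: not an ifrcnet checkpoint: ", path, call. = FALSE)
  }
  if (ck$version > CKPT_VERSION) {
    stop("ckpt_load: checkpoint version ", ck$version, " is newer than supported",
         call. = FALSE)
  }
  net <- switch(ck$type,
                rca_unet = build_rca_unet(ck$cfg$seg_cfg),
                rca_net = build_rca_net(ck$cfg$cls_cfg),
                if_rcnet = build_if_rcnet(ck$cfg$seg_cfg, ck$cfg$cls_cfg,
                                          ck$cfg$fus_cfg))
  module_load_state(net, ck$state)
  attr(net, "extra") <- ck$extra
  net
}
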