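# High-level fitting interface: classed fit objects with print / summary /
# predict / plot methods around the training loop.

split_holdout <- function(ids, frac, seed) {
  set.seed(seed)
  n_eval <- max(1L, round(frac * length(ids)))
  eval_ids <- sample(ids, n_eval)
  list(train = setdiff(ids, eval_ids), eval = eval_ids)
}

#' Fit the segmentation network
#'
#' Splits the samples into a training part and a held-out evaluation part,
#' trains an RCA-UNet with best-epoch selection on held-out Dice, and
#' returns a fit object.
#'
#' @param samples dataset list with masks
#' @param cfg a [seg_config()]
#' @param train_cfg a [train_config()]
#' @param holdout fraction of samples held out for model selection
#' @return an object of class `rca_unet_fit`
#' @export
fit_rca_unet <- function(samples, cfg = seg_config(base_width = 16L),
                         train_cfg = train_config(preset = "desk"),
                         holdout = 0.2) {
  sp <- split_holdout(names(samples), holdout, train_cfg$seed)
  net <- build_rca_unet(cfg, seed = train_cfg$seed)
  fit <- train_model(net, samples, sp$train, sp$eval, train_cfg)
  obj <- list(net = net, cfg = cfg, train_cfg = train_cfg,
              history = fit$history, steps = fit$steps,
              holdout_dice = fit$best_metric, eval_ids = sp$eval)
  class(obj) <- "rca_unet_fit"
  obj
}

#' @export
print.rca_unet_fit <- function(x, ...) {
  cat(sprintf("RCA-UNet fit: base width %d, %d steps, held-out Dice %.4f\n",
              x$cfg$base_width, x$steps, x$holdout_dice))
  invisible(x)
}

#' @export
summary.rca_unet_fit <- function(object, ...) {
  print(object)
  print(object$history)
  invisible(object)
}

#' @export
predict.rca_unet_fit <- function(object, newdata, ...) {
  predict_masks(object$net, newdata)
}

#' @export
plot.rca_unet_fit <- function(x, ...) {
  plot(x$history$epoch, x$history$train_loss, type = "b",
       xlab = "epoch", ylab = "training loss", ...)
  invisible(x)
}

#' Fit the nested classification network (two-phase)
#'
#' Phase one trains the segmentation network; phase two freezes it and trains
#' the classifier with mixed input and/or feature fusion per `fus_cfg`.
#'
#' @param samples dataset list with masks and labels
#' @param seg_cfg a [seg_config()]
#' @param cls_cfg a [cls_config()] (channels must match `fus_cfg`)
#' @param fus_cfg a [fusion_config()]
#' @param seg_train,cls_train per-phase [train_config()]s
#' @param holdout fraction held out for model selection
#' @return an object of class `if_rcnet_fit`
#' @export
fit_if_rcnet <- function(samples,
                         seg_cfg = seg_config(base_width = 8L),
                         cls_cfg = cls_config(widths = c(8L, 16L, 32L, 64L, 64L),
                                              in_channels = 4L,
                                              fusion_width = 32L),
                         fus_cfg = fusion_config(fusion_width = 32L),
                         seg_train = train_config(preset = "desk"),
                         cls_train = train_config(preset = "desk"),
                         holdout = 0.2) {
  sp <- split_holdout(names(samples), holdout, cls_train$seed)
  model <- build_if_rcnet(seg_cfg, cls_cfg, fus_cfg, seed = cls_train$seed)
  seg_fit <- train_model(model$children$seg, samples, sp$train, sp$eval, seg_train)
  cls_fit <- train_model(model, samples, sp$train, sp$eval, cls_train)
  obj <- list(model = model, seg_cfg = seg_cfg, cls_cfg = cls_cfg,
              fus_cfg = fus_cfg,
              seg_history = seg_fit$history, history = cls_fit$history,
              holdout_accuracy = cls_fit$best_metric,
              holdout_dice = seg_fit$best_metric, eval_ids = sp$eval)
  class(obj) <- "if_rcnet_fit"
  obj
}

#' @export
print.if_rcnet_fit <- function(x, ...) {
  cat(sprintf(paste0("IF-RCNet fit: mix '%s', fusion %s; held-out Dice %.4f, ",
                     "held-out accuracy %.4f\n"),
              x$fus_cfg$mix_mode,
              if (x$fus_cfg$use_fusion) "on" else "off",
              x$holdout_dice, x$holdout_accuracy))
  invisible(x)
}

#' @export
summary.if_rcnet_fit <- function(object, ...) {
  print(object)
  print(object$history)
  invisible(object)
}

#' @export
predict.if_rcnet_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "class") return(predict_labels(object$model, newdata))
  idx <- seq_along(newdata)
  probs <- matrix(0, length(idx), 3, dimnames = list(names(newdata), CLASS_NAMES))
  for (start in seq(1, length(idx), by = 8L)) {
    chunk <- idx[start:min(start + 7L, length(idx))]
    lg <- ifrcnet_forward(object$model, batch_images(newdata, chunk))
    mx <- pmax(lg[, 1], lg[, 2], lg[, 3])
    p <- exp(lg - mx)
    probs[chunk, ] <- p / rowSums(p)
  }
  probs
}

#' @export
plot.if_rcnet_fit <- function(x, ...) {
  plot(x$history$epoch, x$history$eval_metric, type = "b",
       xlab = "epoch", ylab = "held-out accuracy", ...)
  invisible(x)
}
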