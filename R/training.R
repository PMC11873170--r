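# Optimization loop, five-round cross-validation driver and ablation runner.

#' Training hyperparameters
#'
#' Defaults follow the published protocol: batch size 2, Adam, learning rate
#' 0.0001. The `"desk"` preset (batch 8, lr 0.001, 10 epochs) is the
#' package's scaled-down configuration for CPU-size synthetic runs.
#'
#' @param batch_size minibatch size
#' @param lr learning rate
#' @param optimizer `"adam"` or `"sgd"`
#' @param epochs maximum epochs
#' @param patience early-stopping patience on the evaluation metric
#' @param seed master seed (data order, initialization, dropout)
#' @param max_steps cap on total optimizer steps (`Inf` = none)
#' @param preset `"paper"` (default) or `"desk"`
#' @return an object of class `ifr_train_config`
#' @export
train_config <- function(batch_size = 2L, lr = 1e-4,
                         optimizer = c("adam", "sgd"), epochs = 50L,
                         patience = 10L, seed = 1L, max_steps = Inf,
                         preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  optimizer <- match.arg(optimizer)
  if (preset == "desk") {
    if (missing(batch_size)) batch_size <- 8L
    if (missing(lr)) lr <- 1e-3
    if (missing(epochs)) epochs <- 10L
  }
  cfg <- list(batch_size = as.integer(batch_size), lr = lr,
              optimizer = optimizer, epochs = as.integer(epochs),
              patience = as.integer(patience), seed = as.integer(seed),
              max_steps = max_steps, preset = preset)
  class(cfg) <- "ifr_train_config"
  cfg
}

batch_images <- function(samples, idx) {
  s1 <- samples[[idx[1]]]$image
  x <- array(0, c(length(idx), 3L, dim(s1)[1], dim(s1)[2]))
  for (k in seq_along(idx)) {
    x[k, , , ] <- aperm(samples[[idx[k]]]$image, c(3, 1, 2))
  }
  x
}

batch_masks <- function(samples, idx) {
  s1 <- samples[[idx[1]]]$mask
  y <- array(0, c(length(idx), dim(s1)))
  for (k in seq_along(idx)) y[k, , ] <- samples[[idx[k]]]$mask
  y
}

batch_labels <- function(samples, idx) {
  vapply(samples[idx], `[[`, 0L, "label")
}

model_task <- function(model) {
  if (inherits(model, "ifr_rca_unet")) "seg"
  else if (inherits(model, "ifr_rca_net")) "cls"
  else if (inherits(model, "ifr_if_rcnet")) "nested"
  else stop("unknown model type", call. = FALSE)
}

# forward + loss + backward for one batch; returns the loss
train_step <- function(model, task, samples, idx) {
  x <- batch_images(samples, idx)
  if (task == "seg") {
    y <- batch_masks(samples, idx)
    out <- model$fwd(x, training = TRUE)
    sl <- seg_loss(out$logits, y, with_grad = TRUE)
    if (is.finite(sl$loss)) model$bwd(sl$grad)
    sl$loss
  } else {
    lab <- batch_labels(samples, idx)
    logits <- if (task == "cls") {
      model$fwd(x, training = TRUE)
    } else {
      ifrcnet_forward(model, x, training = TRUE)
    }
    cl <- cls_loss(logits, lab, with_grad = TRUE)
    if (is.finite(cl$loss)) {
      if (task == "cls") model$bwd(cl$grad) else ifrcnet_bwd(model, cl$grad)
    }
    cl$loss
  }
}

#' Predict segmentation masks for a set of samples
#'
#' @param net an RCA-UNet
#' @param samples dataset list
#' @param ids ids (or indices) to predict; default all
#' @param batch_size forward batch size
#' @return named list of binary masks
#' @export
predict_masks <- function(net, samples, ids = names(samples), batch_size = 8L) {
  idx <- if (is.character(ids)) match(ids, names(samples)) else ids
  out <- vector("list", length(idx))
  for (start in seq(1, length(idx), by = batch_size)) {
    chunk <- idx[start:min(start + batch_size - 1L, length(idx))]
    so <- seg_forward(net, batch_images(samples, chunk))
    for (k in seq_along(chunk)) {
      m <- so$mask[k, , , drop = FALSE]
      dim(m) <- dim(so$mask)[-1]
      out[[start + k - 1L]] <- m
    }
  }
  names(out) <- names(samples)[idx]
  out
}

#' Predict class labels
#'
#' @param model an RCA-Net or IF-RCNet
#' @param samples dataset list
#' @param ids ids (or indices) to predict; default all
#' @param batch_size forward batch size
#' @return named integer vector of labels in \{0,1,2\}
#' @export
predict_labels <- function(model, samples, ids = names(samples), batch_size = 8L) {
  task <- model_task(model)
  idx <- if (is.character(ids)) match(ids, names(samples)) else ids
  out <- integer(length(idx))
  for (start in seq(1, length(idx), by = batch_size)) {
    chunk <- idx[start:min(start + batch_size - 1L, length(idx))]
    x <- batch_images(samples, chunk)
    logits <- if (task == "cls") model$fwd(x) else ifrcnet_forward(model, x)
    out[start:(start + length(chunk) - 1L)] <- max.col(logits, "first") - 1L
  }
  names(out) <- names(samples)[idx]
  out
}

eval_metric <- function(model, task, samples, idx) {
  if (task == "seg") {
    pm <- predict_masks(model, samples, idx)
    tm <- lapply(samples[idx], `[[`, "mask")
    mean(vapply(seq_along(pm), function(i) {
      p <- pm[[i]]; t <- tm[[i]]
      tp <- sum(p == 1 & t == 1)
      denom <- sum(p == 1) + sum(t == 1)
      if (denom == 0) 1 else 2 * tp / denom
    }, 0))                                   # mean Dice
  } else {
    pred <- predict_labels(model, samples, idx)
    mean(pred == batch_labels(samples, idx)) # accuracy
  }
}

#' Train a network on one train/eval split
#'
#' Iterates epochs of shuffled minibatches, records the training loss per
#' epoch and the evaluation metric (Dice for segmentation, accuracy for
#' classification), and restores the parameters of the best evaluation epoch
#' before returning. Fully seeded: data order, initialization and dropout
#' all derive from `cfg$seed`. A non-finite loss aborts with a diagnostic
#' naming the epoch and batch.
#'
#' For a nested IF-RCNet with `freeze_seg` set, only the classifier and
#' fusion parameters are optimized.
#'
#' @param model an RCA-UNet, RCA-Net or IF-RCNet module
#' @param samples dataset list
#' @param train_ids,eval_ids sample ids of the two subsets
#' @param cfg a [train_config()]
#' @return list: `history` (per-epoch data frame), `steps`, `best_metric`,
#'   `best_epoch`, `trained_ids`
#' @export
train_model <- function(model, samples, train_ids, eval_ids, cfg = train_config()) {
  task <- model_task(model)
  train_idx <- match(train_ids, names(samples))
  eval_idx <- match(eval_ids, names(samples))
  stopifnot(!anyNA(train_idx), !anyNA(eval_idx))
  opt_target <- if (task == "nested" && model$fus_cfg$freeze_seg) {
    tm <- new_module("trainable")
    tm$children <- model$children[setdiff(names(model$children), "seg")]
    tm
  } else model
  opt <- new_optimizer(opt_target, optimizer = cfg$optimizer, lr = cfg$lr)
  set.seed(cfg$seed)
  steps <- 0L
  best <- -Inf
  best_state <- NULL
  best_epoch <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     eval_metric = numeric())
  wait <- 0L
  for (ep in seq_len(cfg$epochs)) {
    perm <- train_idx[sample.int(length(train_idx))]
    losses <- c()
    bstarts <- seq(1, length(perm), by = cfg$batch_size)
    for (bi in seq_along(bstarts)) {
      if (steps >= cfg$max_steps) break
      idx <- perm[bstarts[bi]:min(bstarts[bi] + cfg$batch_size - 1L, length(perm))]
      zero_grad(opt_target)
      l <- train_step(model, task, samples, idx)
      if (!is.finite(l)) {
        stop(sprintf("train_model: non-finite loss at epoch %d, batch %d", ep, bi),
             call. = FALSE)
      }
      opt$step()
      steps <- steps + 1L
      losses <- c(losses, l)
    }
    em <- eval_metric(model, task, samples, eval_idx)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = mean(losses),
                                   eval_metric = em))
    if (em > best) {
      best <- em
      best_state <- module_state(opt_target)
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (steps >= cfg$max_steps || wait >= cfg$patience) break
  }
  if (!is.null(best_state)) module_load_state(opt_target, best_state)
  list(history = hist, steps = steps, best_metric = best,
       best_epoch = best_epoch, trained_ids = names(samples)[train_idx])
}

#' Five-round cross-validation
#'
#' For each round of the fold plan a fresh model is built, trained on the
#' round's 70% train subset with model selection on the 20% evaluation
#' subset, and scored exactly once on the 10% test subset. Per-round seeds
#' derive from the master seed.
#'
#' @param samples dataset list (labels required for classification models)
#' @param builder `function(seed)` returning a fresh untrained model
#' @param cfg a [train_config()]
#' @param plan optional [make_fold_plan()] result; built from `cfg$seed`
#'   otherwise
#' @param stratify stratify folds by label (default when labels available)
#' @return an `ifr_cv_result`: `per_round` reports, `mean_report`, `plan`
#' @export
cross_validate <- function(samples, builder, cfg = train_config(), plan = NULL,
                           stratify = TRUE) {
  labels <- vapply(samples, `[[`, 0L, "label")
  if (is.null(plan)) {
    plan <- make_fold_plan(names(samples), cfg$seed,
                           labels = if (all(!is.na(labels))) labels else NULL,
                           stratify = stratify && all(!is.na(labels)))
  }
  per_round <- vector("list", 5L)
  for (r in 1:5) {
    rd <- plan$rounds[[r]]
    rseed <- (cfg$seed * 101L + r) %% 2147483647L
    model <- builder(rseed)
    rcfg <- cfg
    rcfg$seed <- rseed
    fit <- train_model(model, samples, rd$train_ids, rd$eval_ids, rcfg)
    task <- model_task(model)
    if (task == "seg") {
      pm <- predict_masks(model, samples, rd$test_ids)
      report <- seg_metrics(pm, lapply(samples[rd$test_ids], `[[`, "mask"))
    } else {
      pred <- predict_labels(model, samples, rd$test_ids)
      report <- cls_metrics(pred, labels[match(rd$test_ids, names(samples))])
    }
    per_round[[r]] <- list(report = report, fit = fit, test_ids = rd$test_ids)
  }
  fields <- if (inherits(per_round[[1]]$report, "ifr_seg_report")) {
    c("miou", "dice", "mhd")
  } else {
    c("accuracy", "f1")
  }
  mean_report <- sapply(fields, function(f) {
    mean(vapply(per_round, function(x) x$report[[f]], 0))
  })
  res <- list(per_round = per_round, mean_report = as.list(mean_report),
              plan = plan)
  class(res) <- "ifr_cv_result"
  res
}

#' @export
print.ifr_cv_result <- function(x, ...) {
  cat("5-round cross-validation\n  mean: ",
      paste(sprintf("%s %.4f", names(x$mean_report), unlist(x$mean_report)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the four-configuration coupling ablation
#'
#' Per cross-validation round, one RCA-UNet is trained on the round's train
#' subset and shared (frozen) by four classifier configurations trained on
#' identical folds and seeds: the plain RCA-Net baseline, +mixed input,
#' +feature fusion, and +both (the full nested network). Reports mean test
#' accuracy and macro F1 per configuration.
#'
#' @param samples dataset list with masks and labels
#' @param seg_cfg segmentation [seg_config()]
#' @param cls_widths classifier conv widths (5 values)
#' @param fusion_width fused feature vector length
#' @param seg_cfg_train [train_config()] for the segmentation phase
#' @param cls_cfg_train [train_config()] for the classifier phase
#' @param plan optional fold plan
#' @return an `ifr_ablation`: `table` (4 x accuracy/F1 data frame),
#'   `per_config` round reports, `plan`
#' @export
run_ablation <- function(samples, seg_cfg = seg_config(base_width = 8L),
                         cls_widths = c(8L, 16L, 32L, 64L, 64L),
                         fusion_width = 32L,
                         seg_cfg_train = train_config(preset = "desk"),
                         cls_cfg_train = train_config(preset = "desk"),
                         plan = NULL) {
  labels <- vapply(samples, `[[`, 0L, "label")
  stopifnot(all(!is.na(labels)))
  if (is.null(plan)) {
    plan <- make_fold_plan(names(samples), cls_cfg_train$seed, labels = labels)
  }
  configs <- list(
    base = list(mix = "none", fuse = FALSE),
    mixed = list(mix = "mask_channel", fuse = FALSE),
    fusion = list(mix = "none", fuse = TRUE),
    both = list(mix = "mask_channel", fuse = TRUE)
  )
  acc <- matrix(0, 5, 4, dimnames = list(NULL, names(configs)))
  f1 <- acc
  per_config <- lapply(configs, function(x) vector("list", 5L))
  for (r in 1:5) {
    rd <- plan$rounds[[r]]
    rseed <- (cls_cfg_train$seed * 101L + r) %% 2147483647L
    seg_net <- build_rca_unet(seg_cfg, seed = rseed)
    scfg <- seg_cfg_train
    scfg$seed <- rseed
    train_model(seg_net, samples, rd$train_ids, rd$eval_ids, scfg)
    seg_state <- module_state(seg_net)
    for (cn in names(configs)) {
      cc <- configs[[cn]]
      fus <- fusion_config(mix_mode = cc$mix, use_fusion = cc$fuse,
                           fusion_width = fusion_width, freeze_seg = TRUE)
      ccfg <- cls_config(widths = cls_widths,
                         in_channels = mix_in_channels(cc$mix),
                         fusion_width = if (cc$fuse) fusion_width else 0L)
      model <- build_if_rcnet(seg_cfg, ccfg, fus, seed = rseed)
      module_load_state(model$children$seg, seg_state)
      tcfg <- cls_cfg_train
      tcfg$seed <- rseed
      fit <- train_model(model, samples, rd$train_ids, rd$eval_ids, tcfg)
      pred <- predict_labels(model, samples, rd$test_ids)
      rep <- cls_metrics(pred, labels[match(rd$test_ids, names(samples))])
      acc[r, cn] <- rep$accuracy
      f1[r, cn] <- rep$f1
      per_config[[cn]][[r]] <- list(report = rep, fit = fit)
    }
  }
  res <- list(
    table = data.frame(config = names(configs),
                       mixed_input = c(FALSE, TRUE, FALSE, TRUE),
                       feature_fusion = c(FALSE, FALSE, TRUE, TRUE),
                       accuracy = colMeans(acc), f1 = colMeans(f1),
                       row.names = NULL),
    accuracy_by_round = acc, f1_by_round = f1,
    per_config = per_config, plan = plan)
  class(res) <- "ifr_ablation"
  res
}

#' @export
print.ifr_ablation <- function(x, ...) {
  cat("coupling ablation (5-round CV means):\n")
  print(transform(x$table, accuracy = round(accuracy, 4), f1 = round(f1, 4)))
  invisible(x)
}
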