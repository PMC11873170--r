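# Evaluation metrics: three-class classification reports (accuracy,
# one-vs-rest precision/recall, macro F1, confusion matrix) and binary
# segmentation reports (mean IoU over background+foreground, Dice, mean
# symmetric Hausdorff distance between mask boundaries).

#' Classification metrics for three-class predictions
#'
#' Accuracy is correct/total; precision and recall are computed one-vs-rest
#' per class (TP/(TP+FP), TP/(TP+FN)); F1 per class is 2PR/(P+R); the
#' reported F1 is the unweighted (macro) mean over the three classes. A
#' zero denominator yields 0 with a warning rather than an error.
#'
#' @param pred predicted labels in \{0,1,2\}
#' @param truth reference labels in \{0,1,2\}, same length
#' @return an `ifr_cls_report`: `accuracy`, `f1`, `per_class` (precision,
#'   recall, f1), `confusion` (3x3, rows = truth, cols = predicted)
#' @export
cls_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("cls_metrics: pred and truth lengths differ", call. = FALSE)
  }
  if (!all(pred %in% 0:2) || !all(truth %in% 0:2)) {
    stop("cls_metrics: labels must lie in {0,1,2}", call. = FALSE)
  }
  conf <- table(factor(truth, levels = 0:2), factor(pred, levels = 0:2))
  conf <- matrix(as.integer(conf), 3, 3,
                 dimnames = list(truth = CLASS_NAMES, pred = CLASS_NAMES))
  per <- data.frame(class = CLASS_NAMES, precision = 0, recall = 0, f1 = 0)
  degenerate <- character(0)
  for (k in 1:3) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    if (tp + fp == 0 || tp + fn == 0) degenerate <- c(degenerate, CLASS_NAMES[k])
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    per$precision[k] <- p
    per$recall[k] <- r
    per$f1[k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  if (length(degenerate)) {
    warning("cls_metrics: zero-division for class(es) ",
            paste(degenerate, collapse = ", "), "; reported as 0",
            call. = FALSE)
  }
  rep <- list(accuracy = sum(diag(conf)) / sum(conf),
              f1 = mean(per$f1),
              per_class = per,
              confusion = conf,
              n = length(truth))
  class(rep) <- "ifr_cls_report"
  rep
}

#' @export
print.ifr_cls_report <- function(x, ...) {
  cat(sprintf("classification report (n = %d): accuracy %.4f, macro F1 %.4f\n",
              x$n, x$accuracy, x$f1))
  print(round(x$per_class[, -1], 4))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

# boundary pixels of a binary mask: foreground pixels with at least one
# 4-neighbour outside the foreground (pixels beyond the frame count as
# background). Returns an n x 2 matrix of (row, col).
boundary_points <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- mask == 1
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- fg
  core <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(fg & !core, arr.ind = TRUE)
}

#' Symmetric Hausdorff distance between two point sets
#'
#' `max(sup_a inf_b d(a,b), sup_b inf_a d(a,b))` with Euclidean `d`. The
#' `"grid"` method uses an exact Euclidean distance transform and requires
#' integer coordinates (it falls back to brute force otherwise); `"brute"`
#' is the O(|a| |b|) reference. Both agree exactly on integer grids.
#'
#' @param a,b nonempty n x 2 matrices of (row, col) coordinates
#' @param method `"grid"` (default) or `"brute"`
#' @return the distance in pixels
#' @export
hausdorff <- function(a, b, method = c("grid", "brute")) {
  method <- match.arg(method)
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("hausdorff: point sets must be nonempty", call. = FALSE)
  }
  if (method == "grid" &&
      all(a == round(a)) && all(b == round(b))) {
    off <- c(min(a[, 1], b[, 1]) - 1L, min(a[, 2], b[, 2]) - 1L)
    H <- max(a[, 1], b[, 1]) - off[1]
    W <- max(a[, 2], b[, 2]) - off[2]
    grid_of <- function(p) {
      g <- matrix(0L, H, W)
      g[cbind(p[, 1] - off[1], p[, 2] - off[2])] <- 1L
      g
    }
    da <- edt_sq_cpp(grid_of(a))   # squared distance to nearest a-point
    db <- edt_sq_cpp(grid_of(b))
    h1 <- max(db[cbind(a[, 1] - off[1], a[, 2] - off[2])])
    h2 <- max(da[cbind(b[, 1] - off[1], b[, 2] - off[2])])
    return(sqrt(max(h1, h2)))
  }
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  h1 <- max(apply(d2, 1, min))
  h2 <- max(apply(d2, 2, min))
  sqrt(max(h1, h2))
}

# directed-mean variant: mean over each boundary's points of the distance to
# the other boundary, averaged over the two directions.
hd_average <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

#' Segmentation metrics over a set of mask pairs
#'
#' Per image: IoU is computed for background and foreground and averaged
#' (two classes for binary masks); Dice is `2 TP / (FN + 2 TP + FP)` on the
#' foreground; the Hausdorff distance is the symmetric sup-inf distance
#' between foreground boundary pixel sets (Euclidean). Dataset MIoU/Dice/MHd
#' are means over images.
#'
#' Degenerate cases: both masks empty gives IoU = Dice = 1 and HD = 0;
#' foreground empty in exactly one mask gives Dice 0 and HD equal to the
#' image diagonal, so the metrics stay total during early training.
#'
#' @param pred_masks list of predicted binary masks (or one matrix)
#' @param truth_masks list of reference binary masks, pairwise same shapes
#' @param hd_variant `"max"` (symmetric Hausdorff, default) or `"average"`
#'   (mean of directed mean boundary distances)
#' @return an `ifr_seg_report`: `miou`, `dice`, `mhd`, `per_image`
#' @export
seg_metrics <- function(pred_masks, truth_masks, hd_variant = c("max", "average")) {
  hd_variant <- match.arg(hd_variant)
  if (is.matrix(pred_masks)) pred_masks <- list(pred_masks)
  if (is.matrix(truth_masks)) truth_masks <- list(truth_masks)
  stopifnot(length(pred_masks) == length(truth_masks))
  n <- length(pred_masks)
  per <- data.frame(iou = numeric(n), dice = numeric(n), hd = numeric(n))
  for (i in seq_len(n)) {
    p <- pred_masks[[i]]; t <- truth_masks[[i]]
    if (!identical(dim(p), dim(t))) {
      stop("seg_metrics: mask pair ", i, " has mismatched shapes", call. = FALSE)
    }
    tp <- sum(p == 1 & t == 1); fp <- sum(p == 1 & t == 0)
    fn <- sum(p == 0 & t == 1); tn <- sum(p == 0 & t == 0)
    iou_fg <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
    iou_bg <- if (tn + fp + fn > 0) tn / (tn + fp + fn) else 1
    per$iou[i] <- (iou_fg + iou_bg) / 2
    per$dice[i] <- if (tp + fp + fn > 0) 2 * tp / (fn + 2 * tp + fp) else 1
    np <- sum(p == 1); nt <- sum(t == 1)
    if (np == 0 && nt == 0) {
      per$hd[i] <- 0
    } else if (np == 0 || nt == 0) {
      per$hd[i] <- sqrt((nrow(p) - 1)^2 + (ncol(p) - 1)^2)
    } else {
      bp <- boundary_points(p); bt <- boundary_points(t)
      per$hd[i] <- if (hd_variant == "max") hausdorff(bp, bt) else hd_average(bp, bt)
    }
  }
  rep <- list(miou = mean(per$iou), dice = mean(per$dice), mhd = mean(per$hd),
              per_image = per, n = n, hd_variant = hd_variant)
  class(rep) <- "ifr_seg_report"
  rep
}

#' @export
print.ifr_seg_report <- function(x, ...) {
  cat(sprintf("segmentation report (n = %d): MIoU %.4f, Dice %.4f, MHd %.3f px\n",
              x$n, x$miou, x$dice, x$mhd))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param report an `ifr_cls_report`, `ifr_seg_report` or plain list
#' @param path output file
#' @export
report_to_json <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$confusion)) x$confusion <- unclass(x$confusion)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Write a confusion matrix as CSV and, optionally, a heat-map PNG
#'
#' @param report an `ifr_cls_report`
#' @param csv output CSV path
#' @param png_path optional heat-map PNG path
#' @export
write_confusion <- function(report, csv, png_path = NULL) {
  write.csv(report$confusion, csv)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 480, height = 480)
    on.exit(grDevices::dev.off())
    m <- report$confusion
    graphics::image(1:3, 1:3, t(m[3:1, ]), axes = FALSE,
                    col = grDevices::hcl.colors(32, "Blues 3", rev = TRUE),
                    xlab = "predicted", ylab = "truth")
    graphics::axis(1, 1:3, colnames(m))
    graphics::axis(2, 1:3, rev(rownames(m)))
    for (i in 1:3) for (j in 1:3) {
      graphics::text(j, 4 - i, m[i, j])
    }
  }
  invisible(csv)
}
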