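# Independent scalar reference implementations used as oracles. These are
# deliberately written in the most literal form possible (nested loops,
# direct set definitions) and share no code with the package internals.

# plain nested-loop 2-D convolution with dilation and zero padding
oracle_conv2d <- function(x, Wm, b, k, pad, dil) {
  d <- dim(x)
  out_ch <- nrow(Wm)
  ho <- d[3] + 2 * pad - dil * (k - 1)
  wo <- d[4] + 2 * pad - dil * (k - 1)
  y <- array(0, c(d[1], out_ch, ho, wo))
  for (n in seq_len(d[1])) for (o in seq_len(out_ch)) {
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      s <- b[o]
      for (c in seq_len(d[2])) for (kh in 0:(k - 1)) for (kw in 0:(k - 1)) {
        h <- i - pad + kh * dil
        w <- j - pad + kw * dil
        if (h >= 1 && h <= d[3] && w >= 1 && w <= d[4]) {
          r <- ((c - 1) * k + kh) * k + kw + 1
          s <- s + Wm[o, r] * x[n, c, h, w]
        }
      }
      y[n, o, i, j] <- s
    }
  }
  y
}

# brute-force symmetric Hausdorff distance between two point matrices
oracle_hausdorff <- function(a, b) {
  da <- apply(a, 1, function(p) min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)))
  db <- apply(b, 1, function(p) min(sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2)))
  max(max(da), max(db))
}

# literal per-image segmentation metrics from the pixel-count definitions
oracle_seg_pair <- function(p, t) {
  tp <- sum(p == 1 & t == 1); fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1); tn <- sum(p == 0 & t == 0)
  iou_fg <- tp / (tp + fp + fn)
  iou_bg <- tn / (tn + fp + fn)
  list(miou = (iou_fg + iou_bg) / 2, dice = 2 * tp / (fn + 2 * tp + fp))
}

# boundary of a binary mask by direct neighbour enumeration
oracle_boundary <- function(mask) {
  pts <- which(mask == 1, arr.ind = TRUE)
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, 1]; c <- pts[i, 2]
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    for (k in 1:4) {
      rr <- nb[k, 1]; cc <- nb[k, 2]
      if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask) ||
          mask[rr, cc] == 0) {
        keep[i] <- TRUE
        break
      }
    }
  }
  pts[keep, , drop = FALSE]
}

# one-vs-rest classification metrics by explicit table enumeration
oracle_cls <- function(pred, truth) {
  acc <- mean(pred == truth)
  f1s <- numeric(3)
  for (k in 0:2) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[k + 1] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  list(accuracy = acc, f1 = mean(f1s))
}

# scalar softmax cross-entropy
oracle_softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  tot <- 0
  for (i in seq_len(n)) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    tot <- tot - log(p[labels[i] + 1])
  }
  tot / n
}

# random binary mask with a blob-ish foreground
random_mask <- function(h, w, p = 0.4) {
  matrix(as.numeric(runif(h * w) < p), h, w)
}
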