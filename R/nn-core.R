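# Minimal define-by-run neural-network engine.
#
# Feature maps are plain R arrays with dim (batch, channel, height, width).
# Because R arrays are column-major, the (n, c) axes are contiguous, so a
# per-(n,c) weight matrix broadcasts over space by simple vector recycling,
# and a per-pixel map broadcasts over channels via `bcast_spatial()`.
#
# Every layer is an environment ("ifr_module") holding parameters (`par`),
# accumulated gradients (`gr`), non-trainable buffers (`buf`), child modules
# (`children`), and two closures: `fwd(x, training)` and `bwd(dy)`. Backward
# passes are hand-derived; convolutions are lowered to matrix products via
# C++ im2col/col2im and executed by BLAS.

new_module <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$par <- list()
  self$gr <- list()
  self$buf <- list()
  self$children <- list()
  class(self) <- c(paste0("ifr_", type), "ifr_module")
  self
}

#' @export
print.ifr_module <- function(x, ...) {
  np <- sum(vapply(module_parameters(x), length, integer(1)))
  cat(sprintf("<%s module: %s parameters>\n", x$type, format(np, big.mark = ",")))
  invisible(x)
}

## ---- broadcasting helpers ----

sigmoid <- function(z) 1 / (1 + exp(-z))

# (N, C) weights -> (N, C, H, W) array (recycled over space)
bcast_channel <- function(w, dims) array(as.vector(w), dims)

# (N, 1, H, W) or (N, H, W) map -> (N, C, H, W)
bcast_spatial <- function(s, dims) {
  a <- array(as.vector(s), c(dims[1], dims[3], dims[4], dims[2]))
  aperm(a, c(1, 4, 2, 3))
}

# sum over channel axis -> (N, 1, H, W)
sum_channels <- function(e) {
  d <- dim(e)
  m <- aperm(e, c(2, 1, 3, 4))
  dim(m) <- c(d[2], d[1] * d[3] * d[4])
  array(colSums(m), c(d[1], 1L, d[3], d[4]))
}

# sum over spatial axes -> (N, C) matrix
sum_spatial <- function(e) {
  d <- dim(e)
  m <- e
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  matrix(rowSums(m), d[1], d[2])
}

## ---- parameter bookkeeping ----

module_leaves <- function(m) {
  if (length(m$children)) {
    do.call(c, lapply(m$children, module_leaves))
  } else {
    list(m)
  }
}

#' Collect all trainable parameter arrays of a network
#' @param m an `ifr_module`
#' @return named-free list of numeric arrays
#' @export
module_parameters <- function(m) {
  do.call(c, lapply(module_leaves(m), function(l) l$par))
}

zero_grad <- function(m) {
  for (l in module_leaves(m)) {
    for (nm in names(l$gr)) l$gr[[nm]][] <- 0
  }
  invisible(m)
}

# Recursive state (parameters + buffers), used by checkpoints and by
# best-epoch snapshots during training.
module_state <- function(m) {
  list(par = m$par, buf = m$buf,
       children = lapply(m$children, module_state))
}

module_load_state <- function(m, s) {
  if (length(s$par)) m$par <- s$par
  if (length(s$buf)) m$buf <- s$buf
  if (length(s$children)) {
    nms <- names(m$children)
    for (i in seq_along(m$children)) {
      module_load_state(m$children[[i]], s$children[[i]])
    }
    names(m$children) <- nms
  }
  invisible(m)
}

## ---- layers ----

conv_out_size <- function(n, k, pad, stride, dilation) {
  (n + 2L * pad - dilation * (k - 1L) - 1L) %/% stride + 1L
}

nn_conv2d <- function(in_ch, out_ch, kernel = 3L, pad = 0L, stride = 1L,
                      dilation = 1L, init_sd = NULL) {
  self <- new_module("conv2d")
  fan_in <- in_ch * kernel * kernel
  if (is.null(init_sd)) init_sd <- sqrt(2 / fan_in)
  self$par$W <- matrix(rnorm(out_ch * fan_in, sd = init_sd), out_ch, fan_in)
  self$par$b <- numeric(out_ch)
  self$gr$W <- matrix(0, out_ch, fan_in)
  self$gr$b <- numeric(out_ch)
  self$meta <- list(in_ch = in_ch, out_ch = out_ch, k = as.integer(kernel),
                    pad = as.integer(pad), stride = as.integer(stride),
                    dilation = as.integer(dilation))
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    md <- self$meta
    stopifnot(d[2] == md$in_ch)
    cols <- im2col_cpp(x, d[1], d[2], d[3], d[4],
                       md$k, md$pad, md$stride, md$dilation)
    ho <- conv_out_size(d[3], md$k, md$pad, md$stride, md$dilation)
    wo <- conv_out_size(d[4], md$k, md$pad, md$stride, md$dilation)
    y <- self$par$W %*% cols + self$par$b
    dim(y) <- c(md$out_ch, d[1], ho, wo)
    self$cache <- list(cols = cols, dims = d)
    aperm(y, c(2, 1, 3, 4))
  }
  self$bwd <- function(dy) {
    md <- self$meta
    ca <- self$cache
    d <- ca$dims
    dym <- aperm(dy, c(2, 1, 3, 4))
    dim(dym) <- c(md$out_ch, length(dym) %/% md$out_ch)
    self$gr$W <- self$gr$W + tcrossprod(dym, ca$cols)
    self$gr$b <- self$gr$b + rowSums(dym)
    dcols <- crossprod(self$par$W, dym)
    col2im_cpp(dcols, d[1], d[2], d[3], d[4],
               md$k, md$pad, md$stride, md$dilation)
  }
  self
}

nn_bn2d <- function(C, momentum = 0.1, eps = 1e-5) {
  self <- new_module("bn2d")
  self$par$gamma <- rep(1, C)
  self$par$beta <- rep(0, C)
  self$gr$gamma <- rep(0, C)
  self$gr$beta <- rep(0, C)
  self$buf$rmean <- rep(0, C)
  self$buf$rvar <- rep(1, C)
  self$meta <- list(C = C, momentum = momentum, eps = eps)
  to_mat <- function(x, d) {
    m <- aperm(x, c(1, 3, 4, 2))
    dim(m) <- c(d[1] * d[3] * d[4], d[2])
    m
  }
  to_arr <- function(m, d) {
    dim(m) <- c(d[1], d[3], d[4], d[2])
    aperm(m, c(1, 4, 2, 3))
  }
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    md <- self$meta
    m <- nrow_m <- d[1] * d[3] * d[4]
    xp <- to_mat(x, d)
    if (training) {
      mu <- colMeans(xp)
      xc <- xp - matrix(mu, m, md$C, byrow = TRUE)
      v <- colMeans(xc * xc)
      ub <- if (m > 1) v * m / (m - 1) else v
      self$buf$rmean <- (1 - md$momentum) * self$buf$rmean + md$momentum * mu
      self$buf$rvar <- (1 - md$momentum) * self$buf$rvar + md$momentum * ub
    } else {
      mu <- self$buf$rmean
      v <- self$buf$rvar
      xc <- xp - matrix(mu, m, md$C, byrow = TRUE)
    }
    istd <- 1 / sqrt(v + md$eps)
    xhat <- xc * matrix(istd, m, md$C, byrow = TRUE)
    y <- xhat * matrix(self$par$gamma, m, md$C, byrow = TRUE) +
      matrix(self$par$beta, m, md$C, byrow = TRUE)
    self$cache <- list(xhat = xhat, istd = istd, dims = d, training = training)
    to_arr(y, d)
  }
  self$bwd <- function(dy) {
    ca <- self$cache
    d <- ca$dims
    md <- self$meta
    m <- d[1] * d[3] * d[4]
    dyp <- to_mat(dy, d)
    self$gr$gamma <- self$gr$gamma + colSums(dyp * ca$xhat)
    self$gr$beta <- self$gr$beta + colSums(dyp)
    dxhat <- dyp * matrix(self$par$gamma, m, md$C, byrow = TRUE)
    if (ca$training) {
      dx <- (dxhat -
               matrix(colMeans(dxhat), m, md$C, byrow = TRUE) -
               ca$xhat * matrix(colMeans(dxhat * ca$xhat), m, md$C, byrow = TRUE)) *
        matrix(ca$istd, m, md$C, byrow = TRUE)
    } else {
      dx <- dxhat * matrix(ca$istd, m, md$C, byrow = TRUE)
    }
    to_arr(dx, d)
  }
  self
}

nn_relu <- function() {
  self <- new_module("relu")
  self$fwd <- function(x, training = FALSE) {
    pos <- x > 0
    self$cache <- pos
    x * pos
  }
  self$bwd <- function(dy) dy * self$cache
  self
}

nn_dropout <- function(p = 0.5) {
  self <- new_module("dropout")
  self$meta <- list(p = p)
  self$fwd <- function(x, training = FALSE) {
    if (training && self$meta$p > 0) {
      mask <- (runif(length(x)) >= self$meta$p) / (1 - self$meta$p)
      dim(mask) <- dim(x)
      self$cache <- mask
      x * mask
    } else {
      self$cache <- NULL
      x
    }
  }
  self$bwd <- function(dy) if (is.null(self$cache)) dy else dy * self$cache
  self
}

# 2x2 max pooling, stride 2; deterministic first-wins tie break in the
# order (top-left, bottom-left, top-right, bottom-right).
nn_maxpool2 <- function() {
  self <- new_module("maxpool2")
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[3] %% 2L != 0L || d[4] %% 2L != 0L) {
      stop("maxpool2: spatial size must be even, got ",
           d[3], "x", d[4], call. = FALSE)
    }
    H2 <- d[3] %/% 2L
    W2 <- d[4] %/% 2L
    xr <- x
    dim(xr) <- c(d[1], d[2], 2L, H2, 2L, W2)
    slice <- function(i, j) {
      s <- xr[, , i, , j, , drop = FALSE]
      dim(s) <- c(d[1], d[2], H2, W2)
      s
    }
    s11 <- slice(1, 1); s21 <- slice(2, 1)
    s12 <- slice(1, 2); s22 <- slice(2, 2)
    mx <- pmax(s11, s21, s12, s22)
    a1 <- s11 == mx
    a2 <- (s21 == mx) & !a1
    a3 <- (s12 == mx) & !(a1 | a2)
    a4 <- !(a1 | a2 | a3)
    self$cache <- list(a = list(a1, a2, a3, a4), dims = d, H2 = H2, W2 = W2)
    mx
  }
  self$bwd <- function(dy) {
    ca <- self$cache
    d <- ca$dims
    dxr <- array(0, c(d[1], d[2], 2L, ca$H2, 2L, ca$W2))
    dxr[, , 1, , 1, ] <- dy * ca$a[[1]]
    dxr[, , 2, , 1, ] <- dy * ca$a[[2]]
    dxr[, , 1, , 2, ] <- dy * ca$a[[3]]
    dxr[, , 2, , 2, ] <- dy * ca$a[[4]]
    dim(dxr) <- d
    dxr
  }
  self
}

# 2x2 stride-2 transposed convolution (non-overlapping tiles), the decoder
# upsampler. Weight matrix is (in_ch, out_ch*4); the 4 columns-per-channel are
# the (i, j) offsets of the 2x2 tile, column-major over (out, i, j).
nn_deconv2 <- function(in_ch, out_ch) {
  self <- new_module("deconv2")
  self$par$W <- matrix(rnorm(in_ch * out_ch * 4L, sd = sqrt(2 / in_ch)),
                       in_ch, out_ch * 4L)
  self$par$b <- numeric(out_ch)
  self$gr$W <- matrix(0, in_ch, out_ch * 4L)
  self$gr$b <- numeric(out_ch)
  self$meta <- list(in_ch = in_ch, out_ch = out_ch)
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    md <- self$meta
    xm <- aperm(x, c(2, 1, 3, 4))
    dim(xm) <- c(md$in_ch, d[1] * d[3] * d[4])
    U <- crossprod(self$par$W, xm)            # (out*4, N*H*W)
    dim(U) <- c(md$out_ch, 2L, 2L, d[1], d[3], d[4])
    yr <- array(0, c(d[1], md$out_ch, 2L, d[3], 2L, d[4]))
    for (i in 1:2) for (j in 1:2) {
      s <- U[, i, j, , , , drop = FALSE]
      dim(s) <- c(md$out_ch, d[1], d[3], d[4])
      yr[, , i, , j, ] <- aperm(s, c(2, 1, 3, 4))
    }
    dim(yr) <- c(d[1], md$out_ch, 2L * d[3], 2L * d[4])
    yr <- yr + rep(self$par$b, each = d[1])
    self$cache <- list(xm = xm, dims = d)
    yr
  }
  self$bwd <- function(dy) {
    md <- self$meta
    ca <- self$cache
    d <- ca$dims
    dyr <- dy
    dim(dyr) <- c(d[1], md$out_ch, 2L, d[3], 2L, d[4])
    dU <- array(0, c(md$out_ch, 2L, 2L, d[1], d[3], d[4]))
    for (i in 1:2) for (j in 1:2) {
      s <- dyr[, , i, , j, , drop = FALSE]
      dim(s) <- c(d[1], md$out_ch, d[3], d[4])
      dU[, i, j, , , ] <- aperm(s, c(2, 1, 3, 4))
    }
    dim(dU) <- c(md$out_ch * 4L, d[1] * d[3] * d[4])
    self$gr$W <- self$gr$W + tcrossprod(ca$xm, dU)
    bsum <- dy
    dim(bsum) <- c(d[1] * md$out_ch, length(dy) %/% (d[1] * md$out_ch))
    self$gr$b <- self$gr$b + colSums(matrix(rowSums(bsum), d[1], md$out_ch))
    dxm <- self$par$W %*% dU
    dim(dxm) <- c(md$in_ch, d[1], d[3], d[4])
    aperm(dxm, c(2, 1, 3, 4))
  }
  self
}

nn_fc <- function(in_features, out_features) {
  self <- new_module("fc")
  self$par$W <- matrix(rnorm(out_features * in_features,
                             sd = sqrt(2 / in_features)),
                       out_features, in_features)
  self$par$b <- numeric(out_features)
  self$gr$W <- matrix(0, out_features, in_features)
  self$gr$b <- numeric(out_features)
  self$fwd <- function(x, training = FALSE) {
    self$cache <- x
    x %*% t(self$par$W) + rep(self$par$b, each = nrow(x))
  }
  self$bwd <- function(dy) {
    self$gr$W <- self$gr$W + crossprod(dy, self$cache)
    self$gr$b <- self$gr$b + colSums(dy)
    dy %*% self$par$W
  }
  self
}

## ---- global pooling (functional; callers handle backward) ----

global_avg_pool <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  matrix(rowMeans(m), d[1], d[2])
}

global_avg_pool_bwd <- function(dy, dims) {
  array(as.vector(dy) / (dims[3] * dims[4]), dims)
}

global_max_pool <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  idx <- max.col(m, ties.method = "first")
  list(y = matrix(m[cbind(seq_len(nrow(m)), idx)], d[1], d[2]), idx = idx)
}

global_max_pool_bwd <- function(dy, idx, dims) {
  dm <- matrix(0, dims[1] * dims[2], dims[3] * dims[4])
  dm[cbind(seq_len(nrow(dm)), idx)] <- as.vector(dy)
  dim(dm) <- dims
  dm
}

## ---- losses ----

#' Pixel-wise two-class cross-entropy for segmentation logits
#'
#' Mean softmax cross-entropy over all pixels and images. Equals `log(2)`
#' when both logit channels are identical everywhere.
#'
#' @param logits array (batch, 2, H, W); channel 1 is background, channel 2
#'   foreground
#' @param target binary array (batch, H, W) with values in \{0, 1\}
#' @param with_grad also return the gradient w.r.t. the logits
#' @return the scalar loss, or `list(loss, grad)` when `with_grad = TRUE`
#' @export
seg_loss <- function(logits, target, with_grad = FALSE) {
  d <- dim(logits)
  stopifnot(length(d) == 4, d[2] == 2)
  if (!all(target %in% c(0, 1))) {
    stop("seg_loss: target mask must be binary {0,1}", call. = FALSE)
  }
  if (!identical(as.integer(dim(target)), as.integer(d[-2]))) {
    stop("seg_loss: logits and target shapes disagree", call. = FALSE)
  }
  a <- logits[, 1, , , drop = FALSE]; dim(a) <- d[-2]
  b <- logits[, 2, , , drop = FALSE]; dim(b) <- d[-2]
  mx <- pmax(a, b)
  lse <- mx + log(exp(a - mx) + exp(b - mx))
  lt <- a * (1 - target) + b * target
  loss <- mean(lse - lt)
  if (!with_grad) return(loss)
  n_el <- prod(d[-2])
  p_fg <- exp(b - lse)
  g <- array(0, d)
  g[, 2, , ] <- (p_fg - target) / n_el
  g[, 1, , ] <- ((1 - p_fg) - (1 - target)) / n_el
  list(loss = loss, grad = g)
}

#' Three-class cross-entropy for shape labels
#'
#' @param logits matrix (batch, 3) of raw scores
#' @param labels integer vector of class ids in \{0, 1, 2\}
#' @param with_grad also return the gradient w.r.t. the logits
#' @return the scalar loss, or `list(loss, grad)` when `with_grad = TRUE`
#' @export
cls_loss <- function(logits, labels, with_grad = FALSE) {
  stopifnot(is.matrix(logits), ncol(logits) == 3)
  if (!all(labels %in% 0:2)) {
    stop("cls_loss: labels must lie in {0,1,2}", call. = FALSE)
  }
  if (length(labels) != nrow(logits)) {
    stop("cls_loss: batch size mismatch", call. = FALSE)
  }
  n <- nrow(logits)
  mx <- pmax(logits[, 1], logits[, 2], logits[, 3])
  lse <- mx + log(rowSums(exp(logits - mx)))
  loss <- mean(lse - logits[cbind(seq_len(n), labels + 1L)])
  if (!with_grad) return(loss)
  p <- exp(logits - lse)
  p[cbind(seq_len(n), labels + 1L)] <- p[cbind(seq_len(n), labels + 1L)] - 1
  list(loss = loss, grad = p / n)
}

## ---- optimizers ----

new_optimizer <- function(model, optimizer = c("adam", "sgd"), lr = 1e-4,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          momentum = 0.9) {
  optimizer <- match.arg(optimizer)
  leaves <- Filter(function(l) length(l$par) > 0, module_leaves(model))
  st <- lapply(leaves, function(l) {
    lapply(l$par, function(p) list(m = p * 0, v = p * 0))
  })
  env <- new.env(parent = emptyenv())
  env$t <- 0L
  env$step <- function() {
    env$t <- env$t + 1L
    for (i in seq_along(leaves)) {
      l <- leaves[[i]]
      for (nm in names(l$par)) {
        g <- l$gr[[nm]]
        if (optimizer == "adam") {
          s <- st[[i]][[nm]]
          s$m <- beta1 * s$m + (1 - beta1) * g
          s$v <- beta2 * s$v + (1 - beta2) * g * g
          st[[i]][[nm]] <<- s
          mhat <- s$m / (1 - beta1^env$t)
          vhat <- s$v / (1 - beta2^env$t)
          l$par[[nm]] <- l$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        } else {
          s <- st[[i]][[nm]]
          s$m <- momentum * s$m + g
          st[[i]][[nm]] <<- s
          l$par[[nm]] <- l$par[[nm]] - lr * s$m
        }
      }
    }
  }
  env
}
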