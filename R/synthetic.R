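# Synthetic tongue scenes: a rotated super-ellipse "tongue" whose lower half
# is stretched by a droop factor, a crescent "lip" distractor hugging the
# upper tongue boundary with a hue deliberately close to the tongue's, smooth
# multiplicative texture and additive Gaussian noise on the image (never the
# mask). Three shape classes differ by tongue width relative to the image:
# thin < normal < bulgy.

CLASS_NAMES <- c("thin", "normal", "bulgy")
SUPER_ELLIPSE_P <- 2.5

#' Scene parameters for the synthetic generator
#'
#' @param image_size square image side in pixels (>= 32)
#' @param lip_thickness lip band thickness in pixels (default ~7% of the side)
#' @param lip_contact if `TRUE` the lip band touches the tongue boundary;
#'   otherwise a 2-pixel gap separates them
#' @param lip_similarity 0-1; how far the lip hue is pulled toward the tongue
#'   hue (high values make the distractor hard)
#' @param texture_scale amplitude of the multiplicative texture field
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units on the 0-1 scale)
#' @param seed integer; fully determines the rendered scene
#' @return an object of class `ifr_scene`
#' @export
synth_scene <- function(image_size = 224L, lip_thickness = NULL,
                        lip_contact = TRUE, lip_similarity = 0.8,
                        texture_scale = 0.15, noise_sd = 0.03, seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.null(lip_thickness)) lip_thickness <- max(3L, round(0.07 * image_size))
  sc <- list(image_size = image_size, lip_thickness = lip_thickness,
             lip_contact = lip_contact, lip_similarity = lip_similarity,
             texture_scale = texture_scale, noise_sd = noise_sd,
             seed = as.integer(seed))
  class(sc) <- "ifr_scene"
  sc
}

#' Draw shape parameters for one tongue of a given class
#'
#' Widths are `class_ratios * image_size` (full width), jittered
#' multiplicatively by up to `jitter`; height, droop, rotation and centre get
#' small random perturbations. Uses the current RNG state.
#'
#' @param class_id 0 = thin, 1 = normal, 2 = bulgy
#' @param image_size image side in pixels
#' @param class_ratios tongue width as a fraction of the image width, one per
#'   class (defaults 0.35, 0.55, 0.80)
#' @param jitter relative jitter applied to width and height (default 0.05)
#' @return an object of class `ifr_shape`
#' @export
synth_shape <- function(class_id, image_size,
                        class_ratios = c(0.35, 0.55, 0.80), jitter = 0.05) {
  stopifnot(class_id %in% 0:2)
  S <- image_size
  hw <- class_ratios[class_id + 1L] * S / 2 * runif(1, 1 - jitter, 1 + jitter)
  hh <- 0.56 * S / 2 * runif(1, 1 - jitter, 1 + jitter)
  sh <- list(class_id = as.integer(class_id),
             center = c(row = 0.51 * S + runif(1, -0.01, 0.01) * S,
                        col = 0.50 * S + runif(1, -0.01, 0.01) * S),
             half_width = hw,
             half_height = hh,
             droop = runif(1, 0.20, 0.40),
             rotation = runif(1, -6, 6))
  class(sh) <- "ifr_shape"
  sh
}

# scaled super-ellipse field: <= 1 inside the tongue. vp > 0 is the lower
# (drooping) half. `grow` expands both semi-axes by a pixel margin.
shape_field <- function(up, vp, shape, grow = 0) {
  b <- shape$half_height * (1 + shape$droop * (vp > 0)) + grow
  a <- shape$half_width + grow
  (abs(up) / a)^SUPER_ELLIPSE_P + (abs(vp) / b)^SUPER_ELLIPSE_P
}

shape_in_frame <- function(shape, S) {
  t <- seq(0, 2 * pi, length.out = 256L)
  p <- 2 / SUPER_ELLIPSE_P
  ct <- cos(t); st <- sin(t)
  up <- shape$half_width * sign(ct) * abs(ct)^p
  vp0 <- sign(st) * abs(st)^p
  vp <- shape$half_height * (1 + shape$droop * (vp0 > 0)) * vp0
  th <- shape$rotation * pi / 180
  row <- shape$center["row"] + (-sin(th) * up + cos(th) * vp)
  col <- shape$center["col"] + (cos(th) * up + sin(th) * vp)
  all(row >= 2, row <= S - 1, col >= 2, col <= S - 1)
}

#' Render one labelled synthetic sample
#'
#' Deterministic in `(shape, scene)`: the scene's seed is set before any
#' random draw, so two calls with equal parameters are pixel-identical.
#' Texture and noise perturb the image only; the mask is the exact rendered
#' tongue region. Intensities are quantized to 8-bit levels on the 0-1 scale.
#'
#' @param shape an [synth_shape()] result
#' @param scene a [synth_scene()]
#' @return list with `image` (H, W, 3 array in 0-1), `mask` (H, W binary
#'   matrix, 1 = tongue), `label` (the shape's class id) and `id` (`NA`,
#'   filled by [make_dataset()])
#' @export
make_sample <- function(shape, scene) {
  S <- scene$image_size
  if (S < 32L) stop("make_sample: image_size must be >= 32", call. = FALSE)
  if (!shape_in_frame(shape, S)) {
    stop("make_sample: shape parameters place the tongue outside the image frame",
         call. = FALSE)
  }
  set.seed(scene$seed)
  th <- shape$rotation * pi / 180
  row <- matrix(seq_len(S), S, S) - shape$center["row"]
  col <- matrix(seq_len(S), S, S, byrow = TRUE) - shape$center["col"]
  up <- col * cos(th) + row * sin(th)
  vp <- -col * sin(th) + row * cos(th)
  f <- shape_field(up, vp, shape)
  mask <- (f <= 1) * 1
  t_in <- if (scene$lip_contact) 0 else 2
  lip <- shape_field(up, vp, shape, grow = scene$lip_thickness + t_in) <= 1 &
    shape_field(up, vp, shape, grow = t_in) > 1 &
    vp < 0.3 * shape$half_height &
    mask == 0
  tongue_col <- c(0.80, 0.45, 0.50)
  bg_col <- c(0.42, 0.40, 0.44)
  lip_base <- c(0.55, 0.28, 0.32)
  lip_col <- (1 - scene$lip_similarity) * lip_base +
    scene$lip_similarity * tongue_col
  img <- array(0, c(S, S, 3L))
  for (k in 1:3) {
    plane <- matrix(bg_col[k], S, S)
    plane[mask == 1] <- tongue_col[k]
    plane[lip] <- lip_col[k]
    img[, , k] <- plane
  }
  # smooth multiplicative texture: a few random low-frequency sinusoids
  amp <- runif(4, 0.5, 1)
  fr <- runif(4, 1, 4); fc <- runif(4, 1, 4); ph <- runif(4, 0, 2 * pi)
  if (scene$texture_scale > 0) {
    rows <- matrix(seq_len(S), S, S) / S
    cols <- matrix(seq_len(S), S, S, byrow = TRUE) / S
    field <- 0
    for (k in 1:4) {
      field <- field + amp[k] * sin(2 * pi * (fr[k] * rows + fc[k] * cols) + ph[k])
    }
    field <- 1 + scene$texture_scale * field / sum(amp)
    for (k in 1:3) img[, , k] <- img[, , k] * field
  }
  if (scene$noise_sd > 0) {
    img <- img + rnorm(length(img), sd = scene$noise_sd)
  }
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255
  list(id = NA_character_, image = img, mask = mask, label = shape$class_id)
}

#' Generate a labelled synthetic dataset
#'
#' Per-sample seeds are derived from the scene's master seed as
#' `(seed * 1e6 + index) mod (2^31 - 1)`, so manifests are reproducible
#' without storing per-sample seeds.
#'
#' @param n_per_class samples per class (>= 1); with `imbalance = "table1"`
#'   the total `3 * n_per_class` is redistributed to mimic the published
#'   clinical class proportions (thin 253 / normal 226 / bulgy 331 of 800)
#' @param scene a [synth_scene()]
#' @param class_ratios per-class tongue width fractions, see [synth_shape()]
#' @param jitter relative shape jitter
#' @param imbalance `NULL` (balanced) or `"table1"`
#' @return list of samples (see [make_sample()]), names = sample ids
#' @export
make_dataset <- function(n_per_class, scene = synth_scene(),
                         class_ratios = c(0.35, 0.55, 0.80), jitter = 0.05,
                         imbalance = NULL) {
  if (n_per_class < 1) stop("make_dataset: n_per_class must be >= 1", call. = FALSE)
  total <- 3L * as.integer(n_per_class)
  if (is.null(imbalance)) {
    counts <- rep(as.integer(n_per_class), 3L)
  } else if (identical(imbalance, "table1")) {
    prop <- c(thin = 253, normal = 226, bulgy = 331) / 800
    counts <- round(total * prop)
    counts[which.max(counts)] <- counts[which.max(counts)] + (total - sum(counts))
    counts <- as.integer(counts)
  } else {
    stop("make_dataset: unknown imbalance scheme '", imbalance, "'", call. = FALSE)
  }
  labels <- rep(0:2, times = counts)
  out <- vector("list", total)
  ids <- character(total)
  for (i in seq_len(total)) {
    sseed <- as.integer((scene$seed * 1e6 + (i - 1)) %% 2147483647)
    set.seed(sseed)
    shape <- synth_shape(labels[i], scene$image_size, class_ratios, jitter)
    sc <- scene
    sc$seed <- sseed
    s <- make_sample(shape, sc)
    s$id <- sprintf("s%05d_%s", i - 1L, CLASS_NAMES[labels[i] + 1L])
    ids[i] <- s$id
    out[[i]] <- s
  }
  names(out) <- ids
  out
}

#' Write a dataset in the on-disk layout
#'
#' Layout: `images/<id>.png` (RGB), `masks/<id>.png` (single channel, 0/255),
#' `labels.csv` (id, class_name, class_id) and, when a scene is given,
#' `manifest.yaml` with the generator parameters.
#'
#' @param samples list of samples from [make_dataset()]
#' @param dir output directory (created if needed)
#' @param scene optional [synth_scene()] recorded in the manifest
#' @return `dir`, invisibly
#' @export
write_dataset <- function(samples, dir, scene = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(s$image, file.path(dir, "images", paste0(s$id, ".png")))
    if (!is.null(s$mask)) {
      png::writePNG(s$mask * 1.0, file.path(dir, "masks", paste0(s$id, ".png")))
    }
  }
  labs <- data.frame(id = vapply(samples, `[[`, "", "id"),
                     class_name = CLASS_NAMES[vapply(samples, `[[`, 0L, "label") + 1L],
                     class_id = vapply(samples, `[[`, 0L, "label"))
  write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(scene)) {
    yaml::write_yaml(unclass(scene), file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}
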