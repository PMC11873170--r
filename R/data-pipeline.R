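# Dataset IO and the five-round cross-validation plan.

#' Load an image/mask/label dataset from disk
#'
#' Expects the layout written by [write_dataset()]: `images/*.png`, optional
#' `masks/*.png`, optional `labels.csv` (id, class_name, class_id). Ids are
#' sorted lexicographically; missing masks or labels are tolerated and
#' recorded as `NULL` / `NA`.
#'
#' @param root dataset directory
#' @return named list of samples (id, image in 0-1, mask in \{0,1\} or
#'   `NULL`, label in \{0,1,2\} or `NA`)
#' @export
load_dataset <- function(root) {
  img_dir <- file.path(root, "images")
  if (!dir.exists(img_dir)) {
    stop("load_dataset: no images/ directory under ", root, call. = FALSE)
  }
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  ids <- sub("\\.png$", "", files)
  labs <- NULL
  lab_path <- file.path(root, "labels.csv")
  if (file.exists(lab_path)) {
    labs <- read.csv(lab_path, stringsAsFactors = FALSE)
    bad <- setdiff(unique(labs$class_name), CLASS_NAMES)
    if (length(bad)) {
      stop("load_dataset: unknown class name(s) in labels.csv: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    img <- png::readPNG(file.path(img_dir, files[k]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    mask <- NULL
    mp <- file.path(root, "masks", paste0(id, ".png"))
    if (file.exists(mp)) {
      m <- png::readPNG(mp)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      if (!identical(dim(m), dim(img)[1:2])) {
        stop(sprintf("load_dataset: image/mask size mismatch for id '%s' (%s vs %s)",
                     id, paste(dim(img)[1:2], collapse = "x"),
                     paste(dim(m), collapse = "x")), call. = FALSE)
      }
      mask <- (m >= 0.5) * 1
    }
    label <- NA_integer_
    if (!is.null(labs)) {
      row <- match(id, labs$id)
      if (!is.na(row)) {
        label <- match(labs$class_name[row], CLASS_NAMES) - 1L
      }
    }
    out[[k]] <- list(id = id, image = img, mask = mask, label = label)
  }
  names(out) <- ids
  out
}

#' Standardize a sample to the network input contract
#'
#' Images are resampled bilinearly to `size` x `size`; masks are resampled
#' nearest-neighbour and re-thresholded at 0.5 so they stay binary.
#' Intensities end up in 0-1. A sample already at the target size is
#' returned unchanged, so the operation is idempotent.
#'
#' @param sample one dataset entry
#' @param size target side in pixels (default 224)
#' @return the standardized sample
#' @export
standardize <- function(sample, size = 224L) {
  d <- dim(sample$image)
  stopifnot(length(d) == 3, d[3] == 3)
  if (d[1] != size || d[2] != size) {
    eb <- EBImage::Image(aperm(sample$image, c(2, 1, 3)), colormode = "Color")
    rs <- EBImage::resize(eb, w = size, h = size, filter = "bilinear")
    sample$image <- aperm(EBImage::imageData(rs), c(2, 1, 3))
    sample$image <- pmin(pmax(sample$image, 0), 1)
  }
  if (!is.null(sample$mask) && !identical(dim(sample$mask), c(size, size))) {
    em <- EBImage::Image(t(sample$mask))
    rm <- EBImage::resize(em, w = size, h = size, filter = "none")
    sample$mask <- (t(EBImage::imageData(rm)) >= 0.5) * 1
  }
  sample
}

#' Build the five-round rotating cross-validation plan
#'
#' Ids are shuffled once under `seed` and partitioned into 10 near-equal
#' shards. Round r (r = 0..4) takes shard 2r as the 10% test subset; the next
#' two shards (cyclically) form the 20% evaluation subset; the remaining
#' seven shards (70%) train. Test shards are therefore pairwise disjoint
#' across the five rounds. With labels given, shard assignment is stratified
#' so every shard has near-equal class composition.
#'
#' @param ids character vector of sample ids (>= 10)
#' @param seed integer shuffle seed
#' @param labels optional class labels aligned with `ids`
#' @param stratify stratify shards by label (default: when labels given)
#' @return an `ifr_fold_plan`: list of 5 rounds, each with `train_ids`,
#'   `test_ids`, `eval_ids`
#' @export
make_fold_plan <- function(ids, seed, labels = NULL,
                           stratify = !is.null(labels)) {
  n <- length(ids)
  if (n < 10L) stop("make_fold_plan: need at least 10 ids", call. = FALSE)
  if (stratify && is.null(labels)) {
    stop("make_fold_plan: stratification needs labels", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  if (stratify) perm <- perm[order(labels[perm])]
  shard <- integer(n)
  shard[perm] <- (seq_len(n) - 1L) %% 10L
  rounds <- vector("list", 5L)
  for (r in 0:4) {
    test_s <- 2L * r
    eval_s <- c((2L * r + 1L) %% 10L, (2L * r + 2L) %% 10L)
    rounds[[r + 1L]] <- list(
      train_ids = ids[!(shard %in% c(test_s, eval_s))],
      test_ids = ids[shard == test_s],
      eval_ids = ids[shard %in% eval_s]
    )
  }
  plan <- list(rounds = rounds, seed = as.integer(seed), n = n,
               stratified = stratify)
  class(plan) <- "ifr_fold_plan"
  plan
}

#' @export
print.ifr_fold_plan <- function(x, ...) {
  cat(sprintf("5-round cross-validation plan over %d ids (seed %d%s)\n",
              x$n, x$seed, if (x$stratified) ", stratified" else ""))
  for (r in seq_along(x$rounds)) {
    rd <- x$rounds[[r]]
    cat(sprintf("  round %d: %d train / %d test / %d eval\n", r,
                length(rd$train_ids), length(rd$test_ids), length(rd$eval_ids)))
  }
  invisible(x)
}

#' Serialize a fold plan to JSON for audit
#'
#' @param plan an `ifr_fold_plan`
#' @param path output file (`folds.json`)
#' @export
fold_plan_to_json <- function(plan, path) {
  jsonlite::write_json(
    list(seed = plan$seed, n = plan$n, stratified = plan$stratified,
         rounds = lapply(plan$rounds, function(r) {
           list(train = r$train_ids, test = r$test_ids, eval = r$eval_ids)
         })),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
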