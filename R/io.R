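# Image file I/O. Rasters are (H, W, C) arrays, [row, col, channel], with
# 8-bit values 0-255 before preprocessing. EBImage stores images as
# (x, y, c) = (col, row, channel) in [0, 1], hence the aperm/scale shims.

read_rgb <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2) stop("grayscale input: expected 3-channel RGB (", path, ")")
  if (d[3] == 4) stop("alpha channel present: expected 3-channel RGB (", path, ")")
  if (d[3] != 3) stop("expected 3-channel RGB, got ", d[3], " channels (", path, ")")
  aperm(img@.Data, c(2, 1, 3)) * 255
}

write_rgb <- function(img, path, quality = 95) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  obj <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
  ok <- try(EBImage::writeImage(obj, path, quality = quality), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write image: ", path)
  invisible(path)
}

#' Crop a raster to a rectangular region
#'
#' Coordinates are 0-based and half-open: `rect = c(top, left, height,
#' width)` selects pixel rows `top .. top+height-1` and columns
#' `left .. left+width-1`.
#'
#' @param raw An `(H, W, C)` raster array.
#' @param rect Integer vector `c(top, left, height, width)`.
#' @return The cropped `(height, width, C)` array, content identical to the
#'   source sub-window.
#' @examples
#' x <- array(seq_len(4 * 4 * 3), c(4, 4, 3))
#' crop_polar_map(x, c(1, 1, 2, 2))
#' @export
crop_polar_map <- function(raw, rect) {
  stopifnot(length(dim(raw)) == 3, length(rect) == 4)
  top <- rect[1]; left <- rect[2]; h <- rect[3]; w <- rect[4]
  if (top < 0) stop("crop rectangle exceeds bounds: top < 0")
  if (left < 0) stop("crop rectangle exceeds bounds: left < 0")
  if (h < 1 || w < 1) stop("crop rectangle must have positive size")
  if (top + h > dim(raw)[1]) stop("crop rectangle exceeds bounds: bottom")
  if (left + w > dim(raw)[2]) stop("crop rectangle exceeds bounds: right")
  raw[top + seq_len(h), left + seq_len(w), , drop = FALSE]
}

#' Preprocess a raster into network input
#'
#' Resizes to `size x size` (coverage-weighted area averaging when
#' shrinking, bilinear when growing) and rescales 8-bit values to `[0, 1]`.
#' All three color channels are retained.
#'
#' @param raster An `(H, W, 3)` array of 8-bit RGB values (0-255).
#' @param size Output side in pixels; default 256.
#' @return A `size x size x 3` array with values in `[0, 1]`.
#' @examples
#' img <- array(255, c(64, 64, 3))
#' max(preprocess(img))  # 1 exactly
#' @export
preprocess <- function(raster, size = 256L) {
  d <- dim(raster)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an (H, W, 3) RGB raster, got dims ",
         paste(d, collapse = "x"))
  if (min(raster) < 0 || max(raster) > 255)
    stop("raster values must be 8-bit (0-255)")
  out <- .resize_rgb_cpp(raster * 1.0, as.integer(size), as.integer(size)) / 255
  pmin(pmax(out, 0), 1)
}

#' Read a one-line label sidecar
#'
#' @param path Path to a text file whose content is `"0"` or `"1"`
#'   (surrounding whitespace tolerated).
#' @return Integer 0 or 1.
#' @export
read_label <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  txt <- trimws(paste(readLines(path, warn = FALSE), collapse = ""))
  if (!txt %in% c("0", "1"))
    stop("cannot parse label '", txt, "' in ", path, ": expected 0 or 1")
  as.integer(txt)
}

#' Load an exported dataset directory
#'
#' Reads every JPEG/PNG with a matching `.txt` label sidecar, applies an
#' optional crop and the standard preprocessing, and returns a dataset
#' ready for training.
#'
#' @param directory Directory containing images and label sidecars.
#' @param crop Optional crop rectangle `c(top, left, height, width)`
#'   (0-based, half-open) applied before resizing.
#' @param size Output image side; default 256.
#' @return A list with `x` (`size x size x 3 x n` array in `[0, 1]`),
#'   `labels` and `case_ids`.
#' @export
load_dataset <- function(directory, crop = NULL, size = 256L) {
  paths <- sort(list.files(directory, pattern = "\\.(jpe?g|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0) stop("no images found in ", directory)
  ids <- sub("\\.[^.]*$", "", basename(paths))
  x <- array(0, dim = c(size, size, 3, length(paths)))
  labels <- integer(length(paths))
  for (i in seq_along(paths)) {
    img <- read_rgb(paths[i])
    if (!is.null(crop)) img <- crop_polar_map(img, crop)
    x[, , , i] <- preprocess(img, size)
    labels[i] <- read_label(file.path(directory, paste0(ids[i], ".txt")))
  }
  list(x = x, labels = labels, case_ids = ids)
}

#' Random train/validation/test partition
#'
#' The test set is drawn first as `floor(n * test_fraction)` cases; of the
#' remainder, the training set takes `floor(n_rest * (1 - val_fraction))`
#' and validation the rest. With 138 cases, a test fraction of 1/3 and a
#' validation fraction of 1/3 this yields the 61/31/46 split sizes.
#'
#' @param case_ids Character vector of case identifiers (or a
#'   `polarmap_dataset`).
#' @param test_fraction Fraction of all cases held out for testing.
#' @param val_fraction Fraction of the non-test pool used for validation.
#' @param seed Integer seed; the partition is a pure function of
#'   `(case_ids, fractions, seed)`.
#' @return An object of class `split_spec`: list with `train_ids`,
#'   `val_ids`, `test_ids`, the fractions and the seed.
#' @examples
#' sp <- split_dataset(sprintf("c%03d", 1:138), seed = 1)
#' lengths(sp[c("train_ids", "val_ids", "test_ids")])  # 61 31 46
#' @export
split_dataset <- function(case_ids, test_fraction = 1 / 3,
                          val_fraction = 1 / 3, seed = 1L) {
  if (inherits(case_ids, "polarmap_dataset")) case_ids <- case_ids$case_ids
  n <- length(case_ids)
  n_test <- floor(n * test_fraction)
  n_rest <- n - n_test
  n_train <- floor(n_rest * (1 - val_fraction))
  n_val <- n_rest - n_train
  if (min(n_train, n_val, n_test) < 3)
    stop("too few cases: splits of ", n_train, "/", n_val, "/", n_test,
         " need at least 3 cases each")
  with_seed(seed, {
    test_ids <- sample(case_ids, n_test)
    rest <- setdiff(case_ids, test_ids)
    train_ids <- sample(rest, n_train)
    val_ids <- setdiff(rest, train_ids)
    structure(list(train_ids = sort(train_ids), val_ids = sort(val_ids),
                   test_ids = sort(test_ids),
                   test_fraction = test_fraction,
                   val_fraction = val_fraction, seed = as.integer(seed)),
              class = "split_spec")
  })
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Train/validation/test split: %d/%d/%d cases (seed %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Chi-squared independence check between split labels
#'
#' Pearson chi-squared test (no continuity correction) on the 2x2
#' split-membership by label contingency table for every pair of splits.
#' Pairs with p <= 0.05 are flagged as label-dependent.
#'
#' @param split A [split_dataset()] result.
#' @param labels Named vector (or bare vector ordered as the union of the
#'   split ids) of 0/1 labels per case.
#' @return A data frame with one row per split pair: `pair`, `statistic`,
#'   `p_value`, `flagged`, `note`.
#' @export
check_split_independence <- function(split, labels) {
  stopifnot(inherits(split, "split_spec"))
  all_ids <- c(split$train_ids, split$val_ids, split$test_ids)
  if (is.null(names(labels))) {
    stopifnot(length(labels) == length(all_ids))
    names(labels) <- sort(all_ids)
  }
  sets <- list(train = split$train_ids, validation = split$val_ids,
               test = split$test_ids)
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0) stop(nm, " split is empty")
  }
  pairs <- utils::combn(names(sets), 2)
  rows <- apply(pairs, 2, function(pr) {
    la <- labels[sets[[pr[1]]]]
    lb <- labels[sets[[pr[2]]]]
    note <- ""
    if (length(unique(c(la, lb))) < 2) {
      return(data.frame(pair = paste(pr, collapse = " vs "),
                        statistic = NA_real_, p_value = NA_real_,
                        flagged = FALSE,
                        note = "single label class in both splits"))
    }
    tab <- rbind(c(sum(la == 1), sum(la == 0)),
                 c(sum(lb == 1), sum(lb == 0)))
    if (length(unique(la)) < 2)
      note <- paste0(pr[1], " split has a single label class")
    if (length(unique(lb)) < 2)
      note <- paste0(pr[2], " split has a single label class")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(pair = paste(pr, collapse = " vs "),
               statistic = unname(ct$statistic),
               p_value = unname(ct$p.value),
               flagged = is.finite(ct$p.value) && ct$p.value <= 0.05,
               note = note)
  })
  do.call(rbind, rows)
}
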