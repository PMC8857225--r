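#' Clinical threshold rule configuration
#'
#' The quantitative reading rule: a case is ischemic when at least
#' `min_defect_segments` contiguous segments have stress MBF strictly
#' below `threshold` ml/g/min.
#'
#' @param threshold Stress-MBF cut-off in ml/g/min; default 2.3.
#' @param min_defect_segments Minimum count of contiguous sub-threshold
#'   segments; default 1 (the bare quantitative cut-off).
#' @param display_scale Display scale the threshold must lie within.
#' @return An object of class `clinical_rule`.
#' @export
clinical_rule <- function(threshold = 2.3, min_defect_segments = 1L,
                          display_scale = c(0, 3.5)) {
  if (threshold <= display_scale[1] || threshold >= display_scale[2])
    stop("threshold must lie strictly inside the display scale")
  stopifnot(min_defect_segments >= 1)
  structure(list(threshold = threshold,
                 min_defect_segments = as.integer(min_defect_segments),
                 display_scale = display_scale),
            class = "clinical_rule")
}

# Longest circular run of TRUE within each ring (angular contiguity).
longest_run <- function(flags) {
  n <- length(flags)
  if (n == 0 || !any(flags)) return(0L)
  if (all(flags)) return(n)
  ext <- c(flags, flags)  # unroll the circle; runs never exceed n here
  r <- rle(ext)
  max(r$lengths[r$values])
}

#' Classify a case from segmental MBF by the clinical threshold
#'
#' Returns 1 (ischemic) when at least `min_defect_segments` angularly
#' contiguous segments in some ring (or in the apical disc) fall strictly
#' below the threshold; a segment exactly at the threshold counts as
#' normal.
#'
#' @param mbf A `segmental_mbf` object, or a numeric vector of per-segment
#'   values paired with `layout`.
#' @param rule A [clinical_rule()].
#' @param layout A [territory_layout()] (only needed for bare vectors).
#' @return Integer 0 or 1.
#' @examples
#' case <- sample_case(synth_config(seed = 3), 11)
#' classify_by_threshold(case) == case$label
#' @export
classify_by_threshold <- function(mbf, rule = clinical_rule(),
                                  layout = NULL) {
  if (inherits(mbf, "segmental_mbf")) {
    if (is.null(layout)) layout <- mbf$layout
    vals <- mbf$values
  } else {
    if (is.null(layout)) layout <- territory_layout()
    vals <- as.numeric(mbf)
  }
  if (length(vals) == 0) stop("empty segment grid")
  seg <- layout$segments
  below <- vals < rule$threshold
  if (rule$min_defect_segments == 1L)
    return(as.integer(any(below)))
  best <- 0L
  for (r in unique(seg$ring)) {
    in_ring <- seg$ring == r
    ord <- order(seg$sector[in_ring])
    best <- max(best, longest_run(below[in_ring][ord]))
  }
  as.integer(best >= rule$min_defect_segments)
}

#' Classify a rendered polar-map image by the clinical threshold
#'
#' Inverts pixel colors back to MBF ([invert_colormap()]), aggregates to a
#' per-segment median (robust to compression artifacts at segment edges),
#' then applies [classify_by_threshold()].
#'
#' @param image A `size x size x 3` image; values in `[0, 1]` (preprocessed)
#'   or 0-255 (raw render).
#' @param layout A [territory_layout()].
#' @param rule A [clinical_rule()].
#' @return Integer 0 or 1.
#' @export
classify_image_by_threshold <- function(image, layout = territory_layout(),
                                        rule = clinical_rule()) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("expected a (H, W, 3) image")
  if (max(image) > 1) image <- image / 255
  seg_mbf <- image_segment_mbf(image, layout, rule$display_scale)
  if (all(is.na(seg_mbf)))
    stop("unrecognized palette: no tissue pixels invert to MBF values")
  # segments with no tissue pixels (should not occur on a full bullseye)
  # are treated as normal
  seg_mbf[is.na(seg_mbf)] <- rule$display_scale[2]
  classify_by_threshold(seg_mbf, rule, layout)
}

# Median inverted MBF per segment of a rendered bullseye image.
image_segment_mbf <- function(image, layout, scale = c(0, 3.5)) {
  size <- dim(image)[1]
  map <- segment_map(layout, size)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  keep <- !is.na(map)
  mbf <- invert_colormap(px[keep, , drop = FALSE], scale)
  seg <- map[keep]
  out <- rep(NA_real_, nrow(layout$segments))
  med <- tapply(mbf, seg, median, na.rm = TRUE)
  out[as.integer(names(med))] <- med
  out
}

# Pixel -> segment-id map for a square render, cached per (layout, size).
segment_map_cache <- new.env(parent = emptyenv())
segment_map <- function(layout, size) {
  key <- paste0(size, "|", layout$apex_radius, "|", layout$n_rings, "|",
                layout$n_sectors, "|", layout$n_apex_sectors)
  if (!is.null(segment_map_cache[[key]])) return(segment_map_cache[[key]])
  cc <- (seq_len(size) - 0.5) / size * 2 - 1
  x <- matrix(cc, size, size, byrow = TRUE)
  y <- matrix(rev(cc), size, size)
  r <- sqrt(x^2 + y^2)
  theta <- (atan2(x, y) * 180 / pi) %% 360
  # keep clear of segment boundaries? no: full assignment; the median
  # aggregation absorbs blended boundary pixels
  map <- matrix(segment_at(layout, as.vector(r), as.vector(theta)),
                size, size)
  segment_map_cache[[key]] <- map
  map
}

#' Apply the threshold rule to a truth table or dataset
#'
#' Convenience wrapper classifying every case of a [synth_dataset()] (from
#' its ground-truth segmental MBF) or of an exported `truth.csv` sidecar.
#'
#' @param truth A `polarmap_dataset`, or a data frame with `case_id`,
#'   `segment_id`, `mbf` columns.
#' @param rule A [clinical_rule()].
#' @param layout A [territory_layout()] (for data-frame input).
#' @return Data frame with `case_id` and `label`.
#' @export
classify_truth <- function(truth, rule = clinical_rule(), layout = NULL) {
  if (inherits(truth, "polarmap_dataset")) {
    labs <- vapply(truth$truth, classify_by_threshold, 0L, rule = rule)
    return(data.frame(case_id = truth$case_ids, label = labs))
  }
  stopifnot(is.data.frame(truth),
            all(c("case_id", "segment_id", "mbf") %in% names(truth)))
  if (is.null(layout)) layout <- territory_layout()
  ids <- unique(truth$case_id)
  labs <- vapply(ids, function(id) {
    sub <- truth[truth$case_id == id, ]
    classify_by_threshold(sub$mbf[order(sub$segment_id)], rule, layout)
  }, 0L)
  data.frame(case_id = ids, label = unname(labs))
}
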