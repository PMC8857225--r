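#' Configuration for the synthetic polar-map generator
#'
#' Defines the statistical conditions under which labelled stress-MBF
#' bullseye maps are generated: class mix, normal and defect MBF ranges
#' relative to the ischemia cut-off, display scale, defect geometry,
#' borderline-case fraction and smooth within-myocardium variation.
#'
#' @param n_cases Number of cases to generate.
#' @param ischemic_fraction Expected fraction of ischemic (label 1) cases.
#' @param normal_mbf_range `c(low, high)` ml/g/min for non-defect myocardium;
#'   `low` must be at or above `ischemia_threshold`.
#' @param defect_mbf_range `c(low, high)` ml/g/min for defect myocardium;
#'   `high` must be strictly below `ischemia_threshold`.
#' @param ischemia_threshold Stress-MBF cut-off (ml/g/min) below which a
#'   segment counts as ischemic; default 2.3.
#' @param display_scale `c(min, max)` ml/g/min of the rainbow display scale;
#'   default 0 to 3.5.
#' @param defect_extent_range `c(min, max)` defect angular extent as a
#'   fraction of one 120-degree territory (values above 1 span into the
#'   adjacent territory).
#' @param borderline_fraction Fraction of cases whose extreme MBF is placed
#'   within 0.2 ml/g/min of the threshold (visually ambiguous cases).
#' @param noise_sd Standard deviation (ml/g/min) of the smooth low-frequency
#'   MBF variation added across segments.
#' @param seed Integer seed; the generated dataset is a pure function of
#'   this configuration object.
#' @return An object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_cases = 10, seed = 1)
#' @export
synth_config <- function(n_cases = 138L,
                         ischemic_fraction = 56 / 138,
                         normal_mbf_range = c(2.4, 3.4),
                         defect_mbf_range = c(0.8, 2.2),
                         ischemia_threshold = 2.3,
                         display_scale = c(0, 3.5),
                         defect_extent_range = c(0.3, 1.0),
                         borderline_fraction = 0.05,
                         noise_sd = 0.15,
                         seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              ischemic_fraction = ischemic_fraction,
              normal_mbf_range = normal_mbf_range,
              defect_mbf_range = defect_mbf_range,
              ischemia_threshold = ischemia_threshold,
              display_scale = display_scale,
              defect_extent_range = defect_extent_range,
              borderline_fraction = borderline_fraction,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$n_cases < 1) stop("n_cases: must be >= 1")
  if (cfg$ischemic_fraction < 0 || cfg$ischemic_fraction > 1)
    stop("ischemic_fraction: must lie in [0, 1]")
  if (cfg$ischemia_threshold <= cfg$display_scale[1] ||
      cfg$ischemia_threshold >= cfg$display_scale[2])
    stop("ischemia_threshold: must lie strictly inside display_scale")
  if (cfg$defect_mbf_range[1] > cfg$defect_mbf_range[2] ||
      cfg$defect_mbf_range[2] >= cfg$ischemia_threshold ||
      cfg$defect_mbf_range[1] < 0)
    stop("defect_mbf_range: must be non-negative and entirely below ischemia_threshold")
  if (cfg$normal_mbf_range[1] > cfg$normal_mbf_range[2] ||
      cfg$normal_mbf_range[1] < cfg$ischemia_threshold)
    stop("normal_mbf_range: must lie entirely at or above ischemia_threshold")
  if (cfg$defect_extent_range[1] <= 0 ||
      cfg$defect_extent_range[1] > cfg$defect_extent_range[2])
    stop("defect_extent_range: must be positive and ordered")
  if (cfg$borderline_fraction < 0 || cfg$borderline_fraction > 1)
    stop("borderline_fraction: must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd: must be >= 0")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic polar-map configuration\n")
  cat(sprintf("  %d cases, ischemic fraction %.3f, seed %d\n",
              x$n_cases, x$ischemic_fraction, x$seed))
  cat(sprintf("  normal MBF %.2f-%.2f, defect MBF %.2f-%.2f, threshold %.2f ml/g/min\n",
              x$normal_mbf_range[1], x$normal_mbf_range[2],
              x$defect_mbf_range[1], x$defect_mbf_range[2],
              x$ischemia_threshold))
  cat(sprintf("  display %.1f-%.1f ml/g/min, defect extent %.2f-%.2f of a territory\n",
              x$display_scale[1], x$display_scale[2],
              x$defect_extent_range[1], x$defect_extent_range[2]))
  cat(sprintf("  borderline fraction %.2f, smooth noise SD %.2f ml/g/min\n",
              x$borderline_fraction, x$noise_sd))
  invisible(x)
}

# Smooth low-frequency field over segment centres (unit SD before scaling):
# low-order circular harmonics in angle plus a radial trend, standardized.
smooth_field <- function(theta_deg, rho) {
  th <- theta_deg * pi / 180
  co <- rnorm(6)
  g <- co[1] * cos(th + runif(1, 0, 2 * pi)) +
    co[2] * cos(2 * th + runif(1, 0, 2 * pi)) +
    co[3] * rho +
    co[4] * cos(th + runif(1, 0, 2 * pi)) * rho
  s <- stats::sd(g)
  if (!is.finite(s) || s < 1e-8) return(rep(0, length(g)))
  (g - mean(g)) / s
}

#' Sample one synthetic segmental-MBF case
#'
#' Draws the ground-truth stress MBF for every segment of the bullseye grid
#' plus its ischemia label. Ischemic cases carry one contiguous angular
#' defect (within one territory or spanning into an adjacent one) with MBF
#' drawn from the defect range; non-ischemic cases are uniformly normal with
#' smooth variation, clipped to stay at or above the threshold. The draw is
#' deterministic given `(config, case_seed)`.
#'
#' @param config A [synth_config()] object.
#' @param case_seed Integer seed for this case.
#' @param layout A [territory_layout()]; defaults to the standard grid.
#' @return A list of class `segmental_mbf` with `values` (named by
#'   segment id), `layout`, `label` (1 ischemic / 0 non-ischemic) and
#'   `defect_segments` (integer ids, empty for label 0).
#' @examples
#' case <- sample_case(synth_config(seed = 7), case_seed = 42)
#' case$label == as.integer(min(case$values) < 2.3)
#' @export
sample_case <- function(config, case_seed, layout = territory_layout()) {
  stopifnot(inherits(config, "synth_config"))
  seg <- layout$segments
  th_c <- (seg$ang_lo + seg$ang_hi) / 2
  rho_c <- (seg$rad_lo + seg$rad_hi) / 2
  thr <- config$ischemia_threshold
  with_seed(case_seed, {
    is_isch <- runif(1) < config$ischemic_fraction
    borderline <- runif(1) < config$borderline_fraction
    g <- smooth_field(th_c, rho_c)
    base <- runif(1, config$normal_mbf_range[1], config$normal_mbf_range[2])
    vals <- base + config$noise_sd * g
    vals <- pmin(pmax(vals, thr), config$display_scale[2])
    defect <- integer(0)
    if (is_isch) {
      centre <- runif(1, 0, 360)
      extent <- runif(1, config$defect_extent_range[1],
                      config$defect_extent_range[2]) * 120
      dlo <- if (borderline) max(thr - 0.2, config$defect_mbf_range[1]) else
        config$defect_mbf_range[1]
      dhi <- if (borderline) thr - 0.01 else config$defect_mbf_range[2]
      dbase <- runif(1, dlo, dhi)
      ang_dist <- abs(((th_c - centre + 180) %% 360) - 180)
      defect <- which(seg$ring > 0 & ang_dist <= extent / 2)
      if (length(defect) == 0)
        defect <- which(seg$ring > 0)[which.min(ang_dist[seg$ring > 0])]
      dv <- dbase + 0.3 * config$noise_sd * g[defect]
      vals[defect] <- pmin(pmax(dv, config$defect_mbf_range[1]),
                           min(config$defect_mbf_range[2], thr - 0.01))
    } else if (borderline) {
      # non-ischemic borderline: one territory dips to just above threshold
      centre <- runif(1, 0, 360)
      extent <- runif(1, config$defect_extent_range[1],
                      config$defect_extent_range[2]) * 120
      nbase <- runif(1, thr, thr + 0.2)
      ang_dist <- abs(((th_c - centre + 180) %% 360) - 180)
      dip <- which(seg$ring > 0 & ang_dist <= extent / 2)
      if (length(dip) > 0) {
        dv <- nbase + 0.3 * config$noise_sd * g[dip]
        vals[dip] <- pmin(pmax(dv, thr), thr + 0.2)
      }
    }
    label <- as.integer(min(vals) < thr)
    stopifnot(label == as.integer(is_isch))  # label rule is by construction
    names(vals) <- seg$segment_id
    structure(list(values = vals, layout = layout, label = label,
                   defect_segments = defect),
              class = "segmental_mbf")
  })
}

#' Render a segmental-MBF field as a bullseye polar-map image
#'
#' Draws the bullseye on a square raster: every pixel inside the unit disc
#' takes the rainbow color of the (clipped) MBF at its segment, with a
#' smooth sigmoidal blend across angular segment boundaries; pixels outside
#' the disc are black. Optional territory boundary overlays use white, a
#' color reserved outside the rainbow sweep.
#'
#' @param mbf A `segmental_mbf` object (or a bare numeric vector of
#'   per-segment values matching `layout$segments`).
#' @param layout A [territory_layout()]; defaults to the layout carried by
#'   `mbf`.
#' @param scale Display scale `c(min, max)` ml/g/min.
#' @param size Output raster side in pixels (>= 64).
#' @param blend_deg Angular width (degrees) of the sigmoidal blend across
#'   segment boundaries; 0 disables blending.
#' @param overlays Draw territory boundary lines (white) if `TRUE`.
#' @return An `size x size x 3` array of 8-bit RGB values (0-255).
#' @examples
#' img <- render_polar_map(sample_case(synth_config(seed = 1), 1), size = 128)
#' @export
render_polar_map <- function(mbf, layout = NULL, scale = c(0, 3.5),
                             size = 1024L, blend_deg = 5, overlays = FALSE) {
  if (inherits(mbf, "segmental_mbf")) {
    if (is.null(layout)) layout <- mbf$layout
    vals <- mbf$values
  } else {
    if (is.null(layout)) layout <- territory_layout()
    vals <- as.numeric(mbf)
  }
  if (length(vals) == 0) stop("empty segment grid")
  if (length(vals) != nrow(layout$segments))
    stop("mbf has ", length(vals), " values but layout has ",
         nrow(layout$segments), " segments")
  size <- as.integer(size)
  stopifnot(size >= 64, scale[1] < scale[2])

  cc <- (seq_len(size) - 0.5) / size * 2 - 1   # [-1, 1] pixel centres
  x <- matrix(cc, size, size, byrow = TRUE)    # x increases rightwards
  y <- matrix(rev(cc), size, size)             # y increases upwards
  r <- sqrt(x^2 + y^2)
  theta <- (atan2(x, y) * 180 / pi) %% 360     # 0 at 12 o'clock, clockwise

  seg_id <- segment_at(layout, as.vector(r), as.vector(theta))
  inside <- !is.na(seg_id)
  v <- rep(NA_real_, length(seg_id))
  v[inside] <- vals[seg_id[inside]]

  if (blend_deg > 0) {
    seg <- layout$segments
    ring <- seg$ring[seg_id[inside]]
    sector <- seg$sector[seg_id[inside]]
    nsec <- ifelse(ring == 0, layout$n_apex_sectors, layout$n_sectors)
    sw <- 360 / nsec
    th_in <- as.vector(theta)[inside]
    frac <- th_in / sw - (sector - 1)          # position within sector [0,1)
    d_lo <- frac * sw                          # deg to the lower boundary
    d_hi <- (1 - frac) * sw
    to_next <- d_hi < d_lo                     # nearest boundary is upper
    nb_sector <- ifelse(to_next, sector %% nsec + 1L,
                        (sector - 2L) %% nsec + 1L)
    ring_offset <- ifelse(ring == 0, 0L,
                          layout$n_apex_sectors +
                            (ring - 1L) * layout$n_sectors)
    nb_id <- ring_offset + nb_sector
    d <- pmin(d_lo, d_hi)
    alpha <- stats::plogis(-d / (blend_deg / 4))
    v[inside] <- (1 - alpha) * v[inside] + alpha * vals[nb_id]
  }

  lut <- rainbow_lut()
  img <- array(0, dim = c(size, size, 3))
  rgbv <- mbf_to_rgb(v[inside], scale, lut) * 255
  for (ch in 1:3) {
    plane <- matrix(0, size, size)
    plane[inside] <- rgbv[, ch]
    img[, , ch] <- plane
  }

  if (overlays) {
    ang <- as.vector(theta)
    rr <- as.vector(r)
    bnd <- c(60, 180, 300)
    wd <- 180 / (pi * size / 2)                # ~1 px at mid radius
    on_line <- inside & rr > layout$apex_radius &
      Reduce(`|`, lapply(bnd, function(b)
        abs(((ang - b + 180) %% 360) - 180) * pmax(rr, 0.2) < wd))
    ring_line <- abs(rr - layout$apex_radius) < 1.5 / size
    sel <- on_line | (ring_line & inside)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- 255
      img[, , ch] <- plane
    }
  }
  round(img)
}

#' Generate a labelled synthetic polar-map dataset
#'
#' Draws `config$n_cases` cases ([sample_case()]) and renders each to an
#' RGB raster. The whole dataset is a pure function of `config`; per-case
#' seeds are derived from `config$seed`.
#'
#' @param config A [synth_config()] object.
#' @param layout A [territory_layout()].
#' @param render_size Raster side in pixels for the rendered images.
#' @param blend_deg Passed to [render_polar_map()].
#' @return An object of class `polarmap_dataset`: list with `images`
#'   (`render_size x render_size x 3 x n` array, 0-255), `labels` (integer
#'   vector), `truth` (list of `segmental_mbf`), `case_ids`, `config`,
#'   `layout`.
#' @examples
#' ds <- synth_dataset(synth_config(n_cases = 4, seed = 1), render_size = 128)
#' ds$labels
#' @export
synth_dataset <- function(config, layout = territory_layout(),
                          render_size = 256L, blend_deg = 5) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_cases
  case_seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, n))
  images <- array(0, dim = c(render_size, render_size, 3, n))
  labels <- integer(n)
  truth <- vector("list", n)
  case_ids <- sprintf("case_%04d", seq_len(n))
  for (i in seq_len(n)) {
    case <- sample_case(config, case_seeds[i], layout)
    truth[[i]] <- case
    labels[i] <- case$label
    images[, , , i] <- render_polar_map(case, layout, config$display_scale,
                                        render_size, blend_deg)
  }
  structure(list(images = images, labels = labels, truth = truth,
                 case_ids = case_ids, config = config, layout = layout,
                 case_seeds = case_seeds),
            class = "polarmap_dataset")
}

#' @export
print.polarmap_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Synthetic polar-map dataset: %d cases (%d ischemic), %dx%d px\n",
              length(x$labels), sum(x$labels), d[1], d[2]))
  invisible(x)
}

#' Export a dataset as JPEG images with label and truth sidecars
#'
#' Writes one JPEG per case plus a one-line label text file (`"1"` or
#' `"0"`) sharing the case-id stem, a CSV truth sidecar of the ground-truth
#' segmental MBF, and a manifest CSV listing every triple.
#'
#' @param dataset A `polarmap_dataset` from [synth_dataset()], or a list of
#'   rendered cases (each with `image`, `label`, `mbf`, `case_id`).
#' @param directory Output directory (created if absent).
#' @param jpeg_quality JPEG quality, 1-100; default 95.
#' @return Invisibly, the manifest data frame (`case_id`, `image`, `label`,
#'   `label_file`, `truth_file`).
#' @export
export_dataset <- function(dataset, directory, jpeg_quality = 95) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  if (inherits(dataset, "polarmap_dataset")) {
    n <- length(dataset$labels)
    getter <- function(i) list(image = dataset$images[, , , i],
                               label = dataset$labels[i],
                               mbf = dataset$truth[[i]],
                               case_id = dataset$case_ids[i])
  } else {
    n <- length(dataset)
    getter <- function(i) dataset[[i]]
  }
  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    case <- getter(i)
    img_path <- file.path(directory, paste0(case$case_id, ".jpg"))
    lab_path <- file.path(directory, paste0(case$case_id, ".txt"))
    write_rgb(case$image, img_path, quality = jpeg_quality)
    writeLines(as.character(case$label), lab_path)
    seg <- case$mbf$layout$segments
    truth_rows[[i]] <- data.frame(case_id = case$case_id,
                                  segment_id = seg$segment_id,
                                  territory = seg$territory,
                                  mbf = unname(case$mbf$values))
    rows[[i]] <- data.frame(case_id = case$case_id,
                            image = basename(img_path),
                            label = case$label,
                            label_file = basename(lab_path),
                            truth_file = "truth.csv")
  }
  truth <- do.call(rbind, truth_rows)
  write.csv(truth, file.path(directory, "truth.csv"), row.names = FALSE)
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(directory, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
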