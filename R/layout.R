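#' Bullseye territory layout
#'
#' Fixed geometric convention for the polar-map segment grid. The bullseye
#' is the unit disc; an apical disc of radius `apex_radius` sits at the
#' centre and the remaining annulus is divided into `n_rings` radial rings
#' and `n_sectors` equal angular sectors. Angles are measured in degrees
#' from 12 o'clock, clockwise, on the rendered image. The three coronary
#' territories occupy fixed 120-degree arcs: LAD anterior/septal (centred
#' at 12 o'clock), LCx lateral (60-180 deg clockwise) and RCA inferior
#' (180-300 deg); the apical disc is its own "apex" territory, split into
#' `n_apex_sectors` sectors for contiguity bookkeeping.
#'
#' @param apex_radius Radius of the central apical disc (fraction of the
#'   bullseye radius).
#' @param n_rings Number of radial rings in the outer annulus.
#' @param n_sectors Number of angular sectors per ring (must be divisible
#'   by 3 so territory boundaries fall on sector boundaries).
#' @param n_apex_sectors Number of angular sectors in the apical disc.
#' @return An object of class `territory_layout`: a list with the grid
#'   parameters and a `segments` data frame (one row per segment) holding
#'   `segment_id`, `territory`, `ring` (0 = apex), `sector`, the angular
#'   span `[ang_lo, ang_hi)` in degrees and the radial span
#'   `(rad_lo, rad_hi]` as fractions of the bullseye radius.
#' @examples
#' lay <- territory_layout()
#' table(lay$segments$territory)
#' @export
territory_layout <- function(apex_radius = 0.25, n_rings = 3L,
                             n_sectors = 12L, n_apex_sectors = 4L) {
  stopifnot(apex_radius > 0, apex_radius < 1, n_rings >= 1,
            n_sectors %% 3L == 0L, n_apex_sectors >= 1)
  # territory spans (degrees from 12 o'clock, clockwise, half-open); the
  # LAD straddles 0 deg, handled by shifting [300, 360) to [-60, 0)
  terr_spans <- data.frame(
    territory = c("LAD", "LCx", "RCA"),
    lo = c(-60, 60, 180),
    hi = c(60, 180, 300)
  )
  sector_width <- 360 / n_sectors
  radii <- seq(apex_radius, 1, length.out = n_rings + 1)
  seg <- list()
  sid <- 0L
  # apex segments, ring 0
  aw <- 360 / n_apex_sectors
  for (s in seq_len(n_apex_sectors)) {
    sid <- sid + 1L
    seg[[sid]] <- data.frame(
      segment_id = sid, territory = "apex", ring = 0L, sector = s,
      ang_lo = (s - 1) * aw, ang_hi = s * aw, rad_lo = 0, rad_hi = apex_radius)
  }
  for (r in seq_len(n_rings)) {
    for (s in seq_len(n_sectors)) {
      sid <- sid + 1L
      lo <- (s - 1) * sector_width
      mid <- lo + sector_width / 2
      mid_shift <- ifelse(mid >= 300, mid - 360, mid)  # LAD straddles 0
      terr <- terr_spans$territory[mid_shift >= terr_spans$lo &
                                     mid_shift < terr_spans$hi]
      seg[[sid]] <- data.frame(
        segment_id = sid, territory = terr, ring = r, sector = s,
        ang_lo = lo, ang_hi = lo + sector_width,
        rad_lo = radii[r], rad_hi = radii[r + 1])
    }
  }
  structure(list(apex_radius = apex_radius, n_rings = n_rings,
                 n_sectors = n_sectors, n_apex_sectors = n_apex_sectors,
                 segments = do.call(rbind, seg)),
            class = "territory_layout")
}

#' @export
print.territory_layout <- function(x, ...) {
  cat("Bullseye territory layout\n")
  cat(sprintf("  apex disc radius %.2f (%d sectors), %d rings x %d sectors\n",
              x$apex_radius, x$n_apex_sectors, x$n_rings, x$n_sectors))
  cat("  segments per territory:\n")
  print(table(x$segments$territory))
  invisible(x)
}

# Segment id for polar coordinates (r in [0,1], theta in [0,360) degrees
# from 12 o'clock, clockwise). Returns NA outside the disc. Vectorized.
segment_at <- function(layout, r, theta) {
  theta <- theta %% 360
  out <- rep(NA_integer_, length(r))
  inside <- r <= 1
  apex <- inside & r <= layout$apex_radius
  aw <- 360 / layout$n_apex_sectors
  out[apex] <- 1L + pmin(floor(theta[apex] / aw), layout$n_apex_sectors - 1)
  ann <- inside & !apex
  ring <- pmin(ceiling((r[ann] - layout$apex_radius) /
                         ((1 - layout$apex_radius) / layout$n_rings)), layout$n_rings)
  ring <- pmax(ring, 1L)
  sw <- 360 / layout$n_sectors
  sec <- 1L + pmin(floor(theta[ann] / sw), layout$n_sectors - 1)
  out[ann] <- layout$n_apex_sectors + (ring - 1L) * layout$n_sectors + sec
  out
}
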