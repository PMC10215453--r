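# Lumen morphometry: widths at three lumen levels and straight-line
# lengths between balloon-derived anatomical points, in pixels with mm
# conversion.

#' Measure lumen widths at the three reference levels
#'
#' Width at a level is the length of the maximal contiguous run of
#' air-classified pixels (partial-volume range) along that image row that
#' contains the seed column, or 0 if the seed pixel itself is not air. The
#' seed column is taken from the longest-ROI center, which acts as the
#' constant locator across ears and states. Levels are the nasopharyngeal
#' opening, the mid-cartilaginous (mid-balloon) level, and the posterior
#' (isthmus) end.
#'
#' @param image numeric gray8 matrix (resliced, rotated so the lumen is
#'   vertical).
#' @param levels named list or vector with integer rows `np_row`,
#'   `mid_row`, `isthmus_row` (0-based).
#' @param ranges a [density_ranges()].
#' @param seed_col 0-based column inside the lumen at each level.
#' @return Named numeric vector `c(np = , mid = , isthmus = )` of widths in
#'   pixels.
#' @export
measure_widths <- function(image, levels, ranges, seed_col) {
  if (!inherits(ranges, "density_ranges"))
    stop("'ranges' must be density_ranges")
  rows <- c(np = levels[["np_row"]], mid = levels[["mid_row"]],
            isthmus = levels[["isthmus_row"]])
  if (any(rows != round(rows))) stop("level rows must be integers")
  if (any(rows < 0 | rows >= nrow(image)))
    stop("level row outside image")
  seed_col <- as.integer(seed_col)
  if (seed_col < 0 || seed_col >= ncol(image))
    stop("seed column outside image")
  rng <- ranges$air_partial
  vapply(rows, function(r) {
    line <- as_gray8_int(image[r + 1L, ])
    air <- line >= rng[1] & line <= rng[2]
    if (!air[seed_col + 1L]) return(0)
    runs <- rle(air)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(starts <= seed_col + 1L & ends >= seed_col + 1L)
    as.numeric(runs$lengths[k])
  }, numeric(1))
}

#' Measure the three lumen lengths from balloon-derived points
#'
#' Straight-line (Euclidean) pixel distances: `total` from the torus tip to
#' the balloon tip (the longest luminal length), `torus_to_widest` from the
#' torus tip to the end of the widest (cylindrical) part of the balloon,
#' and `widest_to_tip` from there to the balloon tip — approximating the
#' cartilaginous and bony portions of the lumen respectively.
#'
#' @param torus_tip_2d,widest_2d,balloon_tip_2d `(row, col)` points in
#'   pixels; must be pairwise distinct.
#' @return Named numeric vector
#'   `c(total = , torus_to_widest = , widest_to_tip = )` in pixels.
#' @export
measure_distances <- function(torus_tip_2d, widest_2d, balloon_tip_2d) {
  pts <- list(torus = as.numeric(torus_tip_2d),
              widest = as.numeric(widest_2d),
              tip = as.numeric(balloon_tip_2d))
  for (nm in names(pts))
    if (length(pts[[nm]]) != 2 || any(!is.finite(pts[[nm]])))
      stop("'", nm, "' must be a finite 2D (row, col) point")
  d <- function(a, b) sqrt(sum((a - b)^2))
  if (d(pts$torus, pts$widest) == 0 || d(pts$widest, pts$tip) == 0 ||
      d(pts$torus, pts$tip) == 0)
    stop("coincident points")
  c(total = d(pts$torus, pts$tip),
    torus_to_widest = d(pts$torus, pts$widest),
    widest_to_tip = d(pts$widest, pts$tip))
}

#' Convert pixel measurements to millimetres
#'
#' Pixel spacing is always an explicit input: resliced images use the
#' isotropic in-plane spacing of their stack.
#'
#' @param value_px measurement in pixels.
#' @param pixel_spacing mm per pixel (> 0).
#' @return Measurement in mm.
#' @export
px_to_mm <- function(value_px, pixel_spacing) {
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("'pixel_spacing' must be positive")
  value_px * pixel_spacing
}
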