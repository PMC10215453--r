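#' CT volume container
#'
#' A `volume` is the package's in-memory representation of a CT scan: a 3D
#' scalar array ordered (axial slice, row, column) together with voxel
#' spacing in mm and the intensity semantics of its values. Coordinates
#' throughout the package are 0-based voxel-center coordinates in
#' `(slice, row, col)` order; the axial slice index increases
#' cranial-to-caudal.
#'
#' @param voxels 3D numeric array, dimensions (slices, rows, columns),
#'   each dimension at least 2.
#' @param spacing numeric length-3, voxel spacing in mm as
#'   (slice, row, column); all components must be positive.
#' @param intensity_kind `"HU"` for calibrated Hounsfield units or
#'   `"gray8"` for 8-bit display gray values in \[0, 255\].
#' @param origin numeric length-3, position of voxel (0,0,0) in mm.
#'
#' @return An object of class `volume`.
#' @examples
#' v <- volume(array(0, dim = c(4, 8, 8)), spacing = c(0.625, 0.3125, 0.3125),
#'             intensity_kind = "gray8")
#' dim(v$voxels)
#' @export
volume <- function(voxels, spacing, intensity_kind = c("HU", "gray8"),
                   origin = c(0, 0, 0)) {
  intensity_kind <- match.arg(intensity_kind)
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("'voxels' must be a 3D array (slices x rows x columns)")
  if (any(dim(voxels) < 2))
    stop("each volume dimension must be at least 2")
  if (!is.numeric(spacing) || length(spacing) != 3 || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("'spacing' must be three positive mm values (slice, row, col)")
  stop_if_not_point3(origin, "origin")
  if (intensity_kind == "gray8") {
    rng <- range(voxels)
    if (rng[1] < 0 || rng[2] > 255)
      stop("gray8 voxels must lie in [0, 255]")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 intensity_kind = intensity_kind,
                 origin = as.numeric(origin)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels (%s), spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$intensity_kind,
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

#' Display window for HU-to-gray conversion
#'
#' A CT display window, given as window level and window width in Hounsfield
#' units. The default soft-tissue window (level 40 HU, width 400 HU) places
#' air at gray value 0 and cortical bone at 255, reproducing the
#' air/tissue/bone separability the densitometry relies on.
#'
#' @param level window center in HU.
#' @param width window width in HU; must be positive.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(level = 40, width = 400) {
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0)
    stop("window 'width' must be a single positive HU value")
  if (!is.numeric(level) || length(level) != 1 || !is.finite(level))
    stop("window 'level' must be a single finite HU value")
  structure(list(level = level, width = width), class = "window_spec")
}

#' Convert an HU volume to 8-bit display gray values
#'
#' Linearly maps the HU interval
#' `[level - width/2, level + width/2]` onto \[0, 255\], clamping values
#' outside the window and rounding half-up to integers. The mapping is
#' monotone non-decreasing; spacing and origin are preserved and the result
#' has `intensity_kind = "gray8"`.
#'
#' @param v a `volume` with `intensity_kind = "HU"`.
#' @param w a [window_spec()]; default soft-tissue window (40/400).
#' @return A gray8 `volume`.
#' @examples
#' hu <- volume(array(c(-1000, 40, 1000, 0), dim = c(2, 2, 2)),
#'              spacing = c(1, 1, 1), intensity_kind = "HU")
#' g <- window_to_gray8(hu)
#' range(g$voxels)
#' @export
window_to_gray8 <- function(v, w = window_spec()) {
  if (!is_volume(v)) stop("'v' must be a volume")
  if (v$intensity_kind != "HU") stop("window_to_gray8 expects an HU volume")
  if (!inherits(w, "window_spec")) w <- do.call(window_spec, as.list(w))
  lo <- w$level - w$width / 2
  g <- 255 * (v$voxels - lo) / w$width
  g <- clamp(round_half_up(g), 0, 255)
  volume(g, v$spacing, "gray8", v$origin)
}
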