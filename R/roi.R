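# Balloon-guided vertical ROI boxes on resliced, rotated images.
#
# Three nested boxes per ear: the "small" box spans the radiopaque marker
# beads bounding the balloon's cylindrical segment (the section under full
# dilation pressure); the "longest" box extends it by an equal pixel
# distance toward the torus tip and the balloon tip without including bone
# or the nasopharyngeal air column; the "long" box retracts the longest box
# by 5 pixels at each end.

#' Axis-aligned rectangular ROI
#'
#' Pixel-index rectangle (0-based, inclusive bounds) on a resliced image,
#' tagged with its construction rule.
#'
#' @param kind one of `"small"`, `"longest"`, `"long"`.
#' @param col_min,col_max,row_min,row_max inclusive 0-based pixel bounds.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(kind = c("small", "longest", "long"),
                    col_min, col_max, row_min, row_max) {
  kind <- match.arg(kind)
  b <- vapply(list(col_min, col_max, row_min, row_max), function(x) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x))
      stop("ROI bounds must be single integers")
    as.integer(x)
  }, integer(1))
  if (b[1] > b[2] || b[3] > b[4]) stop("ROI bounds out of order")
  if (any(b[c(1, 3)] < 0)) stop("ROI bounds must be non-negative")
  structure(list(kind = kind, col_min = b[1], col_max = b[2],
                 row_min = b[3], row_max = b[4]),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("%s ROI: rows [%d, %d], cols [%d, %d] (%d x %d px)\n",
              x$kind, x$row_min, x$row_max, x$col_min, x$col_max,
              roi_height(x), x$col_max - x$col_min + 1L))
  invisible(x)
}

roi_height <- function(roi) roi$row_max - roi$row_min + 1L

roi_area <- function(roi) roi_height(roi) * (roi$col_max - roi$col_min + 1L)

#' Build the small ROI from the balloon marker beads
#'
#' The short sides of the box cross the two radiopaque markers (which, after
#' rotation, sit nearly vertically above one another); the columns span the
#' markers' mean column plus/minus the lumen half width.
#'
#' @param marker_a_2d,marker_b_2d `(row, col)` marker positions (0-based,
#'   may be continuous); their column difference must be at most 2 px.
#' @param lumen_halfwidth_px half width of the box in pixels. The
#'   recommended default is `ceiling(3.5 / pixel_spacing)` — half the 7 mm
#'   maximum balloon diameter — so the box spans the fully inflated body.
#' @return A `"small"` [roi_box()].
#' @export
build_small_roi <- function(marker_a_2d, marker_b_2d, lumen_halfwidth_px) {
  a <- as.numeric(marker_a_2d); b <- as.numeric(marker_b_2d)
  if (length(a) != 2 || length(b) != 2) stop("markers must be 2D (row, col)")
  if (all(a == b)) stop("markers must be distinct")
  if (abs(a[2] - b[2]) > 2)
    stop("rotate first: markers are not vertically aligned")
  if (lumen_halfwidth_px < 1) stop("'lumen_halfwidth_px' must be >= 1")
  rows <- sort(round_half_up(c(a[1], b[1])))
  mc <- round_half_up((a[2] + b[2]) / 2)
  roi_box("small", col_min = mc - lumen_halfwidth_px,
          col_max = mc + lumen_halfwidth_px,
          row_min = rows[1], row_max = rows[2])
}

# does row `r` of `mask` contain TRUE within the ROI columns?
mask_blocks_row <- function(mask, r, col_min, col_max) {
  if (is.null(mask)) return(FALSE)
  if (r < 0 || r >= nrow(mask)) return(TRUE) # outside image: stop extension
  any(mask[r + 1L, (col_min + 1L):(col_max + 1L)])
}

#' Extend the small ROI equally toward the torus and the balloon tip
#'
#' The longest box extends the small box by the same distance `d` at both
#' ends, where `d` is the largest extension that (i) does not pass the
#' torus tip row toward the nasopharynx, (ii) does not pass the balloon tip
#' row toward the middle ear, and (iii) keeps the box clear of the bone and
#' nasopharyngeal-air exclusion masks (strict exclusion, checked row by row
#' within the box columns). Columns are unchanged.
#'
#' @param small the `"small"` [roi_box()].
#' @param torus_row,balloon_tip_row integer rows of the torus tip (above
#'   the box; nasopharynx is up) and balloon tip (below the box).
#' @param exclusion_masks optional named list with logical matrices `bone`
#'   and/or `np_air` (image-shaped, TRUE = excluded).
#' @return A `"longest"` [roi_box()].
#' @section Errors:
#' If no positive extension is possible, `"no room to extend"`.
#' @export
build_longest_roi <- function(small, torus_row, balloon_tip_row,
                              exclusion_masks = list()) {
  if (!inherits(small, "roi_box") || small$kind != "small")
    stop("'small' must be a small roi_box")
  torus_row <- as.integer(torus_row)
  balloon_tip_row <- as.integer(balloon_tip_row)
  if (torus_row >= small$row_min || balloon_tip_row <= small$row_max)
    stop("no room to extend: torus/balloon tip rows do not bracket the box")
  d_max <- min(small$row_min - torus_row, balloon_tip_row - small$row_max)
  d <- 0L
  for (dd in seq_len(d_max)) {
    top <- small$row_min - dd
    bot <- small$row_max + dd
    blocked <- any(vapply(exclusion_masks, mask_blocks_row, logical(1),
                          r = top, col_min = small$col_min,
                          col_max = small$col_max)) ||
               any(vapply(exclusion_masks, mask_blocks_row, logical(1),
                          r = bot, col_min = small$col_min,
                          col_max = small$col_max))
    if (blocked) break
    d <- dd
  }
  if (d <= 0L) stop("no room to extend")
  roi_box("longest", col_min = small$col_min, col_max = small$col_max,
          row_min = small$row_min - d, row_max = small$row_max + d)
}

#' Retract the longest ROI by 5 pixels at each end
#'
#' @param longest the `"longest"` [roi_box()]; its row extent (inclusive
#'   height) must exceed 10 px.
#' @return A `"long"` [roi_box()] with rows
#'   `[row_min + 5, row_max - 5]` and unchanged columns.
#' @export
build_long_roi <- function(longest) {
  if (!inherits(longest, "roi_box") || longest$kind != "longest")
    stop("'longest' must be a longest roi_box")
  if (roi_height(longest) <= 10L)
    stop("longest box too short to retract by 5 px per end")
  roi_box("long", col_min = longest$col_min, col_max = longest$col_max,
          row_min = longest$row_min + 5L, row_max = longest$row_max - 5L)
}

#' Serialize ROI boxes to JSON
#' @param rois named list of [roi_box()] objects.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read ROI boxes from JSON written by [write_rois()]
#' @param path JSON path.
#' @return Named list of [roi_box()] objects.
#' @export
read_rois <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(b)
    roi_box(b$kind, b$col_min, b$col_max, b$row_min, b$row_max))
}

#' Export an image with ROI box outlines for visual QC
#'
#' Writes an RGB PNG of the gray image with the small/longest/long box
#' borders drawn in red, green and blue respectively.
#'
#' @param image numeric gray8 matrix.
#' @param rois named list of [roi_box()] objects.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
export_roi_overlay <- function(image, rois, path) {
  g <- clamp(image, 0, 255) / 255
  rgb <- array(rep(g, 3), dim = c(dim(g), 3))
  cols <- c(small = 1, longest = 2, long = 3)
  for (nm in names(rois)) {
    b <- rois[[nm]]
    ch <- cols[[b$kind]] %||% 1
    rs <- (b$row_min:b$row_max) + 1L
    cs <- (b$col_min:b$col_max) + 1L
    rs <- rs[rs >= 1 & rs <= nrow(g)]
    cs <- cs[cs >= 1 & cs <= ncol(g)]
    if (!length(rs) || !length(cs)) next
    for (chan in 1:3) {
      val <- if (chan == ch) 1 else 0
      rgb[range(rs), cs, chan] <- val
      rgb[rs, range(cs), chan] <- val
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
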