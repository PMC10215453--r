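# Gray-value density calibration and air-pixel quantification.
#
# Air in the 8-bit display images occupies the darkest gray values; the
# partial volume effect at lumen boundaries widens the apparent air range
# (strict range observed in pure air regions, e.g. 0-16; partial-volume
# range extending to a configurable ceiling, e.g. 0-31). Tissue and bone
# occupy disjoint brighter ranges. Air-classified pixel counts inside the
# balloon-guided ROIs, summed over the resliced stack, quantify dilation.

#' Calibrated gray-value density ranges
#'
#' Inclusive integer gray-value intervals for strict air, partial-volume
#' air, soft tissue and bone. Invariants: strict air is contained in
#' partial air; partial air, tissue and bone are disjoint and ordered.
#'
#' @param air_strict,air_partial,tissue,bone length-2 integer vectors
#'   `c(lo, hi)`, inclusive.
#' @return An object of class `density_ranges`.
#' @export
density_ranges <- function(air_strict, air_partial, tissue, bone) {
  rng <- lapply(list(air_strict = air_strict, air_partial = air_partial,
                     tissue = tissue, bone = bone), function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2])
      stop("each range must be c(lo, hi) with lo <= hi")
    if (r[1] < 0 || r[2] > 255) stop("ranges must lie in [0, 255]")
    r
  })
  if (rng$air_strict[1] < rng$air_partial[1] ||
      rng$air_strict[2] > rng$air_partial[2])
    stop("reference regions not separable: strict air not within partial air")
  if (!(rng$air_partial[2] < rng$tissue[1] && rng$tissue[2] < rng$bone[1]))
    stop("reference regions not separable: air/tissue/bone ranges overlap")
  structure(rng, class = "density_ranges")
}

#' @export
print.density_ranges <- function(x, ...) {
  cat(sprintf(
    "density ranges: air %d-%d (partial %d-%d), tissue %d-%d, bone %d-%d\n",
    x$air_strict[1], x$air_strict[2], x$air_partial[1], x$air_partial[2],
    x$tissue[1], x$tissue[2], x$bone[1], x$bone[2]))
  invisible(x)
}

#' Default density ranges
#'
#' The calibrated ranges observed on the cadaver series that established
#' this method: strict air 0-16 (nasopharyngeal space and out-of-frame
#' air), partial-volume air 0-31 (intraluminal air), tissue 42-88, bone
#' 214-255.
#' @return A [density_ranges()].
#' @export
default_density_ranges <- function() {
  density_ranges(c(0, 16), c(0, 31), c(42, 88), c(214, 255))
}

#' Calibrate density ranges from reference pixel samples
#'
#' Each range is the `[min, max]` of its reference sample after discarding
#' gray-value bins holding fewer than `trim_frac` (default 0.1%) of that
#' sample's pixels — the trimming keeps ranges stable against stray pixels
#' without changing clean samples. The partial-volume air range shares the
#' air minimum and extends to `partial_ceiling` (default 31, the
#' intraluminal partial-volume tail).
#'
#' @param air_ref,tissue_ref,bone_ref numeric vectors of reference pixel
#'   values (nasopharyngeal air, surrounding soft tissue, petrous bone).
#' @param partial_ceiling upper bound of the partial-volume air range.
#' @param trim_frac bin-discard fraction per sample.
#' @return A [density_ranges()].
#' @section Errors:
#' Overlapping ranges after trimming raise
#' `"reference regions not separable"`.
#' @export
calibrate_ranges <- function(air_ref, tissue_ref, bone_ref,
                             partial_ceiling = 31, trim_frac = 0.001) {
  trimmed_range <- function(sample, what) {
    if (!length(sample)) stop("empty ", what, " reference sample")
    g <- as_gray8_int(sample)
    counts <- tabulate(g + 1L, nbins = 256L)
    keep <- which(counts >= trim_frac * length(g) & counts > 0L) - 1L
    if (!length(keep)) keep <- which(counts > 0L) - 1L
    c(min(keep), max(keep))
  }
  air <- trimmed_range(air_ref, "air")
  tissue <- trimmed_range(tissue_ref, "tissue")
  bone <- trimmed_range(bone_ref, "bone")
  if (partial_ceiling < air[2])
    stop("partial ceiling below the strict air maximum")
  density_ranges(air, c(air[1], partial_ceiling), tissue, bone)
}

check_roi_in_image <- function(image, roi) {
  if (!inherits(roi, "roi_box")) stop("'roi' must be a roi_box")
  if (roi$row_max >= nrow(image) || roi$col_max >= ncol(image))
    stop("ROI box out of image bounds")
}

roi_pixels <- function(image, roi) {
  check_roi_in_image(image, roi)
  image[(roi$row_min + 1L):(roi$row_max + 1L),
        (roi$col_min + 1L):(roi$col_max + 1L)]
}

#' Gray-value histogram of an ROI
#'
#' Exact 256-bin count of the pixels inside the inclusive box; continuous
#' pixel values are quantized half-up to integers first. The counts always
#' sum to the box area.
#'
#' @param image numeric gray8 matrix.
#' @param roi a [roi_box()] within the image bounds.
#' @param slice_offset optional mm offset label carried through to the
#'   result.
#' @return An object of class `histogram_result` with fields `counts`
#'   (length 256, values 0..255), `roi`, `slice_offset`.
#' @export
roi_histogram <- function(image, roi, slice_offset = NA_real_) {
  px <- as_gray8_int(roi_pixels(image, roi))
  counts <- tabulate(px + 1L, nbins = 256L)
  structure(list(counts = counts, roi = roi, slice_offset = slice_offset),
            class = "histogram_result")
}

#' Write a histogram as a two-column CSV (value, count)
#' @param h a `histogram_result`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_histogram_csv <- function(h, path) {
  utils::write.csv(data.frame(value = 0:255, count = h$counts), path,
                   row.names = FALSE)
  invisible(path)
}

resolve_stack_rois <- function(stack, rois) {
  n <- length(stack$images)
  if (inherits(rois, "roi_box")) rois <- rep(list(rois), n)
  if (!is.list(rois) || length(rois) != n)
    stop("need one ROI per stack image")
  rois
}

#' Count air-classified pixels in ROIs across a slice stack
#'
#' Sums, over all images of the stack, the pixels inside each image's ROI
#' whose quantized gray value falls in the chosen air range (inclusive
#' bounds): `"strict"` uses the pure-air range, `"partial"` the
#' partial-volume range.
#'
#' @param stack a [slice_stack()].
#' @param rois a single [roi_box()] applied to every image, or a list with
#'   one box per image.
#' @param ranges a [density_ranges()].
#' @param mode `"partial"` (headline, includes partial-volume boundary
#'   pixels) or `"strict"`.
#' @return Integer total air-pixel count.
#' @export
air_pixels <- function(stack, rois, ranges,
                       mode = c("partial", "strict")) {
  mode <- match.arg(mode)
  if (!inherits(ranges, "density_ranges"))
    stop("'ranges' must be density_ranges")
  rois <- resolve_stack_rois(stack, rois)
  rng <- if (mode == "strict") ranges$air_strict else ranges$air_partial
  total <- 0L
  for (i in seq_along(stack$images)) {
    g <- as_gray8_int(roi_pixels(stack$images[[i]], rois[[i]]))
    total <- total + sum(g >= rng[1] & g <= rng[2])
  }
  total
}

#' Percent increase of post- versus pre-dilation air counts
#'
#' `100 * (post - pre) / pre`. Reported values are rounded to integers in
#' per-ear tables at report time only.
#'
#' @param pre_count,post_count air-pixel counts; `pre_count` must be
#'   positive.
#' @return Percent increase (may be negative).
#' @export
percent_increase <- function(pre_count, post_count) {
  if (pre_count <= 0) stop("undefined baseline: pre-dilation count is 0")
  100 * (post_count - pre_count) / pre_count
}

#' Mean gray value of the ROI in each stack image
#'
#' Per-image arithmetic mean of the quantized ROI pixel values, ordered by
#' slice offset — the profile used to visualize dilation along the lumen.
#'
#' @inheritParams air_pixels
#' @return Numeric vector, one mean per image (ordered by offset).
#' @export
mean_gray_profile <- function(stack, rois) {
  rois <- resolve_stack_rois(stack, rois)
  vapply(seq_along(stack$images), function(i)
    mean(as_gray8_int(roi_pixels(stack$images[[i]], rois[[i]]))),
    numeric(1))
}

#' Classify bone and nasopharyngeal-air exclusion masks on an image
#'
#' Builds the exclusion masks used when extending the longest ROI: `bone`
#' marks pixels in the bone range; `np_air` marks the connected component
#' of air-classified (partial range) pixels touching the top image rows —
#' the nasopharyngeal air column above the torus.
#'
#' @param image numeric gray8 matrix.
#' @param ranges a [density_ranges()].
#' @param top_rows how many top image rows seed the nasopharyngeal air
#'   component.
#' @param valid optional logical matrix of pixels actually sampled inside
#'   the volume; out-of-volume padding (rendered as 0) is never treated as
#'   air.
#' @return List of logical matrices `bone` and `np_air`.
#' @export
classify_exclusion_masks <- function(image, ranges, top_rows = 1,
                                     valid = NULL) {
  g <- as_gray8_int(image)
  bone <- g >= ranges$bone[1] & g <= ranges$bone[2]
  air <- g >= ranges$air_partial[1] & g <= ranges$air_partial[2]
  if (!is.null(valid)) air <- air & valid
  np <- flood_from_top(air, top_rows)
  list(bone = bone, np_air = np)
}

# connected component (4-neighborhood) of TRUE pixels reachable from the
# top `top_rows` rows
flood_from_top <- function(mask, top_rows = 1) {
  R <- nrow(mask); C <- ncol(mask)
  visited <- matrix(FALSE, R, C)
  seeds <- which(mask[seq_len(min(top_rows, R)), , drop = FALSE])
  if (!length(seeds)) return(visited)
  sr <- (seeds - 1L) %% min(top_rows, R) + 1L
  sc <- (seeds - 1L) %/% min(top_rows, R) + 1L
  queue <- cbind(sr, sc)
  visited[queue] <- TRUE
  while (nrow(queue)) {
    nxt <- rbind(cbind(queue[, 1] - 1L, queue[, 2]),
                 cbind(queue[, 1] + 1L, queue[, 2]),
                 cbind(queue[, 1], queue[, 2] - 1L),
                 cbind(queue[, 1], queue[, 2] + 1L))
    ok <- nxt[, 1] >= 1L & nxt[, 1] <= R & nxt[, 2] >= 1L & nxt[, 2] <= C
    nxt <- nxt[ok, , drop = FALSE]
    keep <- mask[nxt] & !visited[nxt]
    nxt <- nxt[keep, , drop = FALSE]
    if (!nrow(nxt)) break
    nxt <- unique(nxt)
    visited[nxt] <- TRUE
    queue <- nxt
  }
  visited
}
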