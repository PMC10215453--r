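# Landmark-defined oblique reslicing: plane construction, trilinear stack
# extraction, and in-plane rotation so the lumen runs vertically.

#' Oblique viewing-plane frame
#'
#' An orthonormal frame describing a reslicing plane: `origin` (mm),
#' in-plane directions `u` (image columns) and `v` (image rows), the plane
#' `normal`, and the `slice_step` (mm) between sequential resliced images.
#' All direction vectors are unit length and mutually orthogonal to within
#' 1e-9; components are in `(slice, row, col)` mm order.
#'
#' @param origin numeric 3-vector, mm.
#' @param u,v,normal unit direction 3-vectors.
#' @param slice_step positive mm step between stack images.
#' @return An object of class `plane_frame`.
#' @export
plane_frame <- function(origin, u, v, normal, slice_step) {
  stop_if_not_point3(origin, "origin")
  for (nm in c("u", "v", "normal")) {
    vec <- get(nm)
    stop_if_not_point3(vec, nm)
    if (abs(vnorm(vec) - 1) > 1e-9) stop("'", nm, "' must be unit length")
  }
  if (abs(sum(u * v)) > 1e-9 || abs(sum(u * normal)) > 1e-9 ||
      abs(sum(v * normal)) > 1e-9)
    stop("frame directions must be mutually orthogonal")
  if (!is.numeric(slice_step) || slice_step <= 0)
    stop("'slice_step' must be positive")
  structure(list(origin = as.numeric(origin), u = as.numeric(u),
                 v = as.numeric(v), normal = as.numeric(normal),
                 slice_step = slice_step),
            class = "plane_frame")
}

# canonical sign: flip so the first component larger than tol is positive
canonical_sign <- function(vec, prefer = NULL) {
  if (!is.null(prefer)) {
    s <- sum(vec * prefer)
    if (abs(s) > 1e-12) return(if (s < 0) -vec else vec)
  }
  for (comp in vec) {
    if (abs(comp) > 1e-12) return(if (comp < 0) -vec else vec)
  }
  vec
}

#' Build the ET viewing plane from three bony landmarks
#'
#' Constructs the oblique plane through the medial pterygoid plate, the
#' opposite pterygoid plate (hamulus) and the sphenoid spine, after
#' converting voxel coordinates to mm. The frame origin is the landmark
#' centroid. The in-plane "vertical" `v` (image rows, nasopharynx at the
#' top) follows the projected balloon axis when `torus_tip` and
#' `balloon_tip` are annotated, otherwise the longest triangle edge. The
#' normal is oriented cranial-positive (toward decreasing slice index).
#'
#' @param lm a [landmark_set()].
#' @param spacing voxel spacing in mm, `(slice, row, col)`.
#' @param slice_step mm between sequential resliced images; defaults to the
#'   native slice spacing.
#' @return A [plane_frame()] whose plane contains all three landmarks to
#'   within 1e-6 mm.
#' @section Errors:
#' Landmark triangles with area at most 1 mm^2 (collinear or nearly so, an
#' annotation error at CT resolution) raise `"degenerate plane"`.
#' @export
plane_from_landmarks <- function(lm, spacing, slice_step = spacing[1]) {
  if (!inherits(lm, "landmark_set")) stop("'lm' must be a landmark_set")
  spacing <- as.numeric(spacing)
  p1 <- lm$medial_pterygoid_plate * spacing
  p2 <- lm$opposite_pterygoid_plate * spacing
  p3 <- lm$sphenoid_spine * spacing
  n0 <- vcross(p2 - p1, p3 - p1)
  area <- vnorm(n0) / 2
  if (area <= 1) stop("degenerate plane: landmark triangle area <= 1 mm^2")
  normal <- vnormalize(n0)
  origin <- (p1 + p2 + p3) / 3

  v_raw <- NULL
  if (!is.null(lm$torus_tip) && !is.null(lm$balloon_tip)) {
    axis <- (lm$balloon_tip - lm$torus_tip) * spacing
    proj <- axis - sum(axis * normal) * normal
    if (vnorm(proj) > 1e-9) v_raw <- proj
  }
  if (is.null(v_raw)) {
    edges <- list(p2 - p1, p3 - p2, p1 - p3)
    v_raw <- edges[[which.max(vapply(edges, vnorm, numeric(1)))]]
    # longest-edge direction is sign-ambiguous under landmark permutation:
    # canonicalize toward increasing slice index (caudal, lumen runs down)
    v_raw <- canonical_sign(v_raw, prefer = c(1, 0, 0))
  }
  v <- vnormalize(v_raw)
  # cranial-positive normal: slice index grows cranial -> caudal
  normal <- canonical_sign(normal, prefer = c(-1, 0, 0))
  u <- vnormalize(vcross(v, normal))
  plane_frame(origin, u, v, normal, slice_step)
}

#' Axis-aligned frame reproducing native axial slices
#'
#' Convenience frame whose plane coincides with a native axial slice: `u`
#' along image columns, `v` along rows, normal along the slice axis.
#' Extracting a stack with this frame at the native pixel spacing
#' reproduces the stored slices exactly (trilinear interpolation at grid
#' points is exact).
#'
#' @param v a [volume()].
#' @param center_slice 0-based index of the slice at offset 0; defaults to
#'   the middle slice.
#' @return A [plane_frame()].
#' @export
identity_frame <- function(v, center_slice = (dim(v$voxels)[1] - 1) %/% 2) {
  d <- dim(v$voxels)
  origin <- c(center_slice, (d[2] - 1) / 2, (d[3] - 1) / 2) * v$spacing
  plane_frame(origin, u = c(0, 0, 1), v = c(0, 1, 0), normal = c(1, 0, 0),
              slice_step = v$spacing[1])
}

# vectorized trilinear interpolation at continuous voxel coordinates
# (0-based); samples outside the voxel-center bounding box return 0 and
# are flagged invalid in the "valid" attribute
trilinear_sample <- function(voxels, zi, yi, xi) {
  d <- dim(voxels)
  out <- numeric(length(zi))
  ok <- zi >= 0 & zi <= d[1] - 1 & yi >= 0 & yi <= d[2] - 1 &
        xi >= 0 & xi <= d[3] - 1
  if (!any(ok)) return(structure(out, valid = ok))
  zi <- zi[ok]; yi <- yi[ok]; xi <- xi[ok]
  z0 <- floor(zi); y0 <- floor(yi); x0 <- floor(xi)
  wz <- zi - z0; wy <- yi - y0; wx <- xi - x0
  z1 <- pmin(z0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  x1 <- pmin(x0 + 1, d[3] - 1)
  idx <- function(z, y, x) 1 + z + d[1] * (y + d[2] * x)
  vals <-
    voxels[idx(z0, y0, x0)] * (1 - wz) * (1 - wy) * (1 - wx) +
    voxels[idx(z1, y0, x0)] * wz       * (1 - wy) * (1 - wx) +
    voxels[idx(z0, y1, x0)] * (1 - wz) * wy       * (1 - wx) +
    voxels[idx(z0, y0, x1)] * (1 - wz) * (1 - wy) * wx       +
    voxels[idx(z1, y1, x0)] * wz       * wy       * (1 - wx) +
    voxels[idx(z1, y0, x1)] * wz       * (1 - wy) * wx       +
    voxels[idx(z0, y1, x1)] * (1 - wz) * wy       * wx       +
    voxels[idx(z1, y1, x1)] * wz       * wy       * wx
  out[ok] <- vals
  structure(out, valid = ok)
}

#' Resliced image stack
#'
#' Ordered list of resliced 2D images at signed offsets along the plane
#' normal, symmetric about the center image at offset 0, sharing one shape
#' and an isotropic in-plane pixel spacing.
#' @param images list of numeric matrices (one shape).
#' @param offsets signed mm offsets, strictly increasing, symmetric about 0.
#' @param pixel_spacing isotropic in-plane mm per pixel.
#' @param frame the [plane_frame()] the stack was sampled from (optional).
#' @param rotation accumulated in-plane rotation angle (radians).
#' @param valid optional list of logical matrices flagging pixels sampled
#'   inside the source volume (out-of-volume padding is FALSE); defaults
#'   to all-valid.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(images, offsets, pixel_spacing, frame = NULL,
                        rotation = 0, valid = NULL) {
  if (!is.list(images) || !length(images)) stop("'images' must be a list")
  shp <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), shp), logical(1))))
    stop("all stack images must share one shape")
  if (length(offsets) != length(images)) stop("one offset per image required")
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  if (max(abs(offsets + rev(offsets))) > 1e-9)
    stop("offsets must be symmetric about 0")
  if (is.null(valid))
    valid <- lapply(images, function(m) matrix(TRUE, shp[1], shp[2]))
  if (length(valid) != length(images) ||
      !all(vapply(valid, function(m) identical(dim(m), shp), logical(1))))
    stop("'valid' must mirror the image list")
  structure(list(images = images, offsets = as.numeric(offsets),
                 pixel_spacing = pixel_spacing, frame = frame,
                 rotation = rotation, valid = valid),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  shp <- dim(x$images[[1]])
  cat(sprintf("slice stack: %d images of %d x %d px (%.4g mm/px), offsets %.3g..%.3g mm\n",
              length(x$images), shp[1], shp[2], x$pixel_spacing,
              min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Extract a symmetric stack of resliced images
#'
#' Samples `2 * half_count + 1` parallel images from the volume by
#' trilinear interpolation: the center image on the plane itself plus
#' `half_count` sequential images toward each side of the plane at
#' multiples of `frame$slice_step` (with the default 12, the 25-image stack
#' used for whole-lumen coverage). Pixel values are kept continuous;
#' samples outside the volume are 0.
#'
#' @param v a [volume()].
#' @param frame a [plane_frame()].
#' @param half_count images per side of the center image (>= 0).
#' @param size_px `c(rows, cols)` of each resliced image; defaults to a
#'   square covering the volume diagonal.
#' @param pixel_spacing isotropic in-plane mm per pixel; defaults to the
#'   smaller of the native row/column spacings, so in-plane measurements
#'   have no direction-dependent bias.
#' @return A [slice_stack()].
#' @export
extract_stack <- function(v, frame, half_count = 12, size_px = NULL,
                          pixel_spacing = NULL) {
  if (!is_volume(v)) stop("'v' must be a volume")
  if (!inherits(frame, "plane_frame")) stop("'frame' must be a plane_frame")
  if (half_count < 0) stop("'half_count' must be >= 0")
  ps <- pixel_spacing %||% min(v$spacing[2], v$spacing[3])
  if (is.null(size_px)) {
    diag_mm <- sqrt(sum((dim(v$voxels) * v$spacing)^2))
    size_px <- rep(ceiling(diag_mm / ps), 2)
  }
  R <- as.integer(size_px[1]); C <- as.integer(size_px[2])
  rr <- rep(seq_len(R) - 1, times = C) - (R - 1) / 2
  cc <- rep(seq_len(C) - 1, each = R) - (C - 1) / 2
  offsets <- (-half_count:half_count) * frame$slice_step
  sampled <- lapply(offsets, function(off) {
    base <- frame$origin + off * frame$normal
    pz <- base[1] + rr * ps * frame$v[1] + cc * ps * frame$u[1]
    py <- base[2] + rr * ps * frame$v[2] + cc * ps * frame$u[2]
    px <- base[3] + rr * ps * frame$v[3] + cc * ps * frame$u[3]
    vals <- trilinear_sample(v$voxels, pz / v$spacing[1], py / v$spacing[2],
                             px / v$spacing[3])
    list(img = matrix(as.numeric(vals), nrow = R, ncol = C),
         valid = matrix(attr(vals, "valid"), nrow = R, ncol = C))
  })
  slice_stack(lapply(sampled, `[[`, "img"), offsets, ps, frame = frame,
              valid = lapply(sampled, `[[`, "valid"))
}

# rotation angle (radians) taking a 2D (d_row, d_col) axis to the vertical
# (increasing row); positive angles rotate row-toward-column
rotation_angle_to_vertical <- function(axis_2d) {
  if (!is.numeric(axis_2d) || length(axis_2d) != 2 || vnorm(axis_2d) == 0)
    stop("lumen axis must be a nonzero 2D (row, col) vector")
  atan2(-axis_2d[2], axis_2d[1])
}

# rotate points (n x 2 matrix of row, col) about the image center by theta
rotate_points_2d <- function(pts, theta, shape) {
  pts <- matrix(pts, ncol = 2)
  ctr <- (shape - 1) / 2
  dr <- pts[, 1] - ctr[1]; dc <- pts[, 2] - ctr[2]
  cbind(ctr[1] + cos(theta) * dr - sin(theta) * dc,
        ctr[2] + sin(theta) * dr + cos(theta) * dc)
}

# bilinear rotation of one image about its center; zero padding outside
rotate_image <- function(img, theta) {
  if (abs(theta) < 1e-12) return(img)
  shp <- dim(img)
  R <- shp[1]; C <- shp[2]
  rr <- rep(seq_len(R) - 1, times = C)
  cc <- rep(seq_len(C) - 1, each = R)
  src <- rotate_points_2d(cbind(rr, cc), -theta, shp)
  sr <- src[, 1]; sc <- src[, 2]
  out <- numeric(R * C)
  ok <- sr >= 0 & sr <= R - 1 & sc >= 0 & sc <= C - 1
  r0 <- floor(sr[ok]); c0 <- floor(sc[ok])
  wr <- sr[ok] - r0; wc <- sc[ok] - c0
  r1 <- pmin(r0 + 1, R - 1); c1 <- pmin(c0 + 1, C - 1)
  idx <- function(r, c) 1 + r + R * c
  out[ok] <-
    img[idx(r0, c0)] * (1 - wr) * (1 - wc) +
    img[idx(r1, c0)] * wr       * (1 - wc) +
    img[idx(r0, c1)] * (1 - wr) * wc       +
    img[idx(r1, c1)] * wr       * wc
  matrix(out, nrow = R, ncol = C)
}

#' Rotate all stack images so the lumen runs vertically
#'
#' Applies one common in-plane rotation to every image of the stack so that
#' the given 2D lumen-axis direction maps onto the vertical, with the
#' nasopharyngeal end at the top of the images (the axis `(d_row, d_col)`
#' should point torus-to-balloon-tip, i.e. toward increasing rows after
#' rotation). Bilinear interpolation, zero-padded, output shape unchanged.
#'
#' @param stack a [slice_stack()].
#' @param lumen_axis_2d nonzero `(d_row, d_col)` direction of the lumen in
#'   the unrotated images.
#' @return A [slice_stack()] with the accumulated rotation recorded in
#'   `$rotation`.
#' @export
rotate_to_vertical <- function(stack, lumen_axis_2d) {
  if (!inherits(stack, "slice_stack")) stop("'stack' must be a slice_stack")
  theta <- rotation_angle_to_vertical(lumen_axis_2d)
  images <- lapply(stack$images, rotate_image, theta = theta)
  # a rotated pixel is valid only if fully interpolated from valid pixels
  valid <- lapply(stack$valid, function(m)
    rotate_image(matrix(as.numeric(m), nrow(m), ncol(m)), theta) >= 0.999)
  slice_stack(images, stack$offsets, stack$pixel_spacing, frame = stack$frame,
              rotation = stack$rotation + theta, valid = valid)
}

#' Project a voxel-coordinate point into stack image coordinates
#'
#' Maps a 0-based `(slice, row, col)` voxel point into the continuous
#' `(row, col)` pixel coordinates of a stack's images, honoring any
#' rotation already applied to the stack, and reports the signed mm offset
#' of the point from the central plane.
#'
#' @param stack a [slice_stack()] carrying its frame.
#' @param point numeric 3-vector, voxel coordinates.
#' @param spacing voxel spacing of the source volume (mm).
#' @return List with `row`, `col` (continuous, 0-based) and `offset_mm`.
#' @export
project_to_stack <- function(stack, point, spacing) {
  if (is.null(stack$frame)) stop("stack carries no frame")
  stop_if_not_point3(point, "point")
  fr <- stack$frame
  dp <- point * as.numeric(spacing) - fr$origin
  shp <- dim(stack$images[[1]])
  rc <- c((shp[1] - 1) / 2 + sum(dp * fr$v) / stack$pixel_spacing,
          (shp[2] - 1) / 2 + sum(dp * fr$u) / stack$pixel_spacing)
  if (stack$rotation != 0)
    rc <- as.numeric(rotate_points_2d(rc, stack$rotation, shp))
  list(row = rc[1], col = rc[2], offset_mm = sum(dp * fr$normal))
}
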