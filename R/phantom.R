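# Parametric synthetic head phantom.
#
# Emulates the imaging situation of the cadaver series: a soft-tissue
# background containing a nasopharyngeal air pocket, a petrous-bone sleeve
# around the bony portion of the ET, and an obliquely oriented tapering ET
# lumen rendered in pre-, during- (inflated balloon with radiopaque marker
# beads) and post-dilation states, with full geometric ground truth.
# Partial volume is simulated by supersampled rendering followed by block
# averaging; zero-mean Gaussian noise is added per voxel.

#' Phantom specification
#'
#' Parameters of the synthetic ET phantom. Defaults reproduce the study
#' conditions of the cadaver series this method was developed on: 0.625 mm
#' slices with 0.3125 mm in-plane spacing (160 mm field of view on a 512
#' matrix, cropped to a 45 mm region around the ET), a 28 mm lumen with a
#' 0.6 cartilaginous fraction, a 16 mm balloon with 7/3 mm maximum/minimum
#' diameters, tissue intensities inside the calibrated density ranges, and
#' per-level dilation factors concentrated at the mid-cartilaginous level.
#'
#' @param shape volume dimensions `(slices, rows, cols)`.
#' @param spacing voxel spacing mm `(slice, row, col)`.
#' @param lumen_origin_mm 3D mm position of the torus tip (nasopharyngeal
#'   end of the lumen).
#' @param lumen_axis direction of the lumen axis (normalized internally).
#' @param lumen_length_mm total lumen length, torus tip to posterior end.
#' @param cartilaginous_fraction fraction of the length forming the
#'   cartilaginous portion; the widest-balloon level sits at its end.
#' @param lumen_width_pre_mm pre-dilation lumen widths (diameters, mm) at
#'   the nasopharyngeal opening, mid-cartilaginous level and isthmus.
#' @param dilation_factor multiplicative width change post vs pre at the
#'   mid-cartilaginous level (>= 1).
#' @param dilation_factor_np,dilation_factor_isthmus end-level factors
#'   (>= 1, typically smaller than `dilation_factor`).
#' @param balloon list: `length_mm` of the cylindrical segment,
#'   `max_diameter_mm`, `min_diameter_mm` (tip of the distal cone),
#'   `marker_radius_mm` of the radiopaque beads at the cylinder ends.
#' @param np_radius_mm radius of the nasopharyngeal air pocket beyond the
#'   torus tip.
#' @param bone_inner_mm inner radius of the petrous bone sleeve around the
#'   bony lumen portion (the soft-tissue cuff between lumen and bone).
#' @param bone_outer_mm outer radius of the petrous bone sleeve.
#' @param bone_overshoot_mm how far the bone block continues past the
#'   posterior lumen end.
#' @param intensities named mean gray8 values for
#'   air/tissue/bone/balloon/marker; defaults lie inside the calibrated
#'   density ranges (air <= 16, tissue 42-88, bone 214-255).
#' @param noise_sd zero-mean Gaussian noise SD in gray levels (>= 0).
#' @param partial_volume integer supersampling factor (>= 1); 3 reproduces
#'   the partial-volume tail of boundary voxels.
#' @param seed integer RNG seed (required; rendering is deterministic
#'   given the spec).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(25, 144, 144),
                         spacing = c(0.625, 0.3125, 0.3125),
                         lumen_origin_mm = c(4.5, 7, 16),
                         lumen_axis = c(6, 24, 10),
                         lumen_length_mm = 28,
                         cartilaginous_fraction = 0.6,
                         lumen_width_pre_mm = c(np = 2.0, mid = 1.6,
                                                isthmus = 1.0),
                         dilation_factor = 1.72,
                         dilation_factor_np = 1.08,
                         dilation_factor_isthmus = 1.38,
                         balloon = list(length_mm = 16, max_diameter_mm = 7,
                                        min_diameter_mm = 3,
                                        marker_radius_mm = 0.8),
                         np_radius_mm = 5,
                         bone_inner_mm = 4.5,
                         bone_outer_mm = 7.5,
                         bone_overshoot_mm = 3,
                         intensities = c(air = 6, tissue = 65, bone = 235,
                                         balloon = 120, marker = 245),
                         noise_sd = 5,
                         partial_volume = 3,
                         seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1)
    stop("'seed' is required and must be a single integer")
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 2)) stop("invalid 'shape'")
  if (any(spacing <= 0)) stop("'spacing' must be positive")
  w <- as.numeric(lumen_width_pre_mm)
  if (length(w) != 3 || any(w <= 0)) stop("lumen widths must be 3 positive mm")
  names(w) <- c("np", "mid", "isthmus")
  for (f in c(dilation_factor, dilation_factor_np, dilation_factor_isthmus))
    if (f < 1) stop("dilation factors must be >= 1")
  if (cartilaginous_fraction <= 0 || cartilaginous_fraction >= 1)
    stop("'cartilaginous_fraction' must be in (0, 1)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  partial_volume <- as.integer(partial_volume)
  if (partial_volume < 1) stop("'partial_volume' must be >= 1")
  need <- c("air", "tissue", "bone", "balloon", "marker")
  if (!all(need %in% names(intensities))) stop("missing intensity entries")
  if (any(intensities < 0 | intensities > 255))
    stop("intensities must lie in [0, 255]")
  if (balloon$length_mm <= 0 || balloon$max_diameter_mm <= 0 ||
      balloon$min_diameter_mm <= 0 ||
      balloon$min_diameter_mm > balloon$max_diameter_mm)
    stop("invalid balloon geometry")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 lumen_origin_mm = as.numeric(lumen_origin_mm),
                 lumen_axis = vnormalize(as.numeric(lumen_axis)),
                 lumen_length_mm = lumen_length_mm,
                 cartilaginous_fraction = cartilaginous_fraction,
                 lumen_width_pre_mm = w,
                 dilation_factor = dilation_factor,
                 dilation_factor_np = dilation_factor_np,
                 dilation_factor_isthmus = dilation_factor_isthmus,
                 balloon = balloon, np_radius_mm = np_radius_mm,
                 bone_inner_mm = bone_inner_mm,
                 bone_outer_mm = bone_outer_mm,
                 bone_overshoot_mm = bone_overshoot_mm,
                 intensities = intensities[need], noise_sd = noise_sd,
                 partial_volume = partial_volume, seed = as.integer(seed)),
            class = "phantom_spec")
}

# piecewise-linear lumen width (diameter, mm) at axial position s (mm)
lumen_width_at <- function(s, L, cart, widths) {
  t <- s / L
  w <- ifelse(t <= cart,
              widths[1] + (widths[2] - widths[1]) * (t / cart),
              widths[2] + (widths[3] - widths[2]) * ((t - cart) / (1 - cart)))
  w[t < 0 | t > 1] <- 0
  w
}

phantom_geometry <- function(spec) {
  d <- spec$lumen_axis
  A <- spec$lumen_origin_mm
  L <- spec$lumen_length_mm
  cart <- spec$cartilaginous_fraction
  s_mid <- cart * L
  B <- A + L * d
  widths_post <- spec$lumen_width_pre_mm *
    c(spec$dilation_factor_np, spec$dilation_factor,
      spec$dilation_factor_isthmus)
  # in-plane basis of the lumen plane: m is the plane normal, e the
  # in-plane direction perpendicular to the axis
  m <- vnormalize(vcross(d, c(1, 0, 0)))
  e <- vnormalize(vcross(m, d))
  # landmark analogues placed in the lumen plane, offsets scaling with the
  # lumen so reduced-size phantoms keep them inside the volume
  landmarks_mm <- list(
    medial_pterygoid_plate = A + 5 * e - 0.07 * L * d,
    opposite_pterygoid_plate = A - 4 * e + 0.035 * L * d,
    sphenoid_spine = A + 4 * e + 0.7 * L * d)
  marker_a_mm <- A + (s_mid - spec$balloon$length_mm) * d
  marker_b_mm <- A + s_mid * d
  list(d = d, A = A, B = B, L = L, cart = cart, s_mid = s_mid,
       e = e, m = m,
       widths_pre = spec$lumen_width_pre_mm, widths_post = widths_post,
       landmarks_mm = landmarks_mm,
       marker_a_mm = marker_a_mm, marker_b_mm = marker_b_mm,
       torus_tip_mm = A, widest_mm = marker_b_mm, balloon_tip_mm = B,
       ref_mm = list(
         air = A - (spec$np_radius_mm / 2) * d,
         tissue = A + 0.3 * L * d + 3 * e,
         bone = A + 0.8 * L * d -
           ((spec$bone_inner_mm + spec$bone_outer_mm) / 2) * e))
}

# evaluate material intensity and air-class indicators on one supersampled
# z layer; yy/xx/q/syx are precomputed in-plane vectors relative to A
phantom_layer <- function(spec, geo, state, z, pre) {
  dz <- z - geo$A[1]
  s <- dz * geo$d[1] + pre$syx
  dist2 <- dz^2 + pre$q
  rad2 <- pmax(dist2 - s^2, 0)
  ints <- spec$intensities
  n <- length(s)
  inten <- rep(ints[["tissue"]], n)
  # petrous bone sleeve around the bony lumen portion, outside a
  # soft-tissue cuff so the lumen is never directly walled by bone
  bone_sel <- s >= geo$s_mid & s <= geo$L + spec$bone_overshoot_mm &
    rad2 >= spec$bone_inner_mm^2 & rad2 <= spec$bone_outer_mm^2
  inten[bone_sel] <- ints[["bone"]]
  # nasopharyngeal air pocket beyond the torus tip
  np_sel <- s < 0 & dist2 < spec$np_radius_mm^2
  inten[np_sel] <- ints[["air"]]
  # tapering lumen
  widths <- if (state == "post") geo$widths_post else geo$widths_pre
  half <- lumen_width_at(pmax(pmin(s, geo$L), 0), geo$L, geo$cart, widths) / 2
  lum_sel <- s >= 0 & s <= geo$L & rad2 <= half^2
  inten[lum_sel] <- ints[["air"]]
  if (state == "during") {
    bmax <- spec$balloon$max_diameter_mm / 2
    bmin <- spec$balloon$min_diameter_mm / 2
    body <- s >= geo$s_mid - spec$balloon$length_mm & s <= geo$s_mid &
      rad2 <= bmax^2
    taper <- bmax + (bmin - bmax) * (s - geo$s_mid) / (geo$L - geo$s_mid)
    cone <- s > geo$s_mid & s <= geo$L & rad2 <= pmax(taper, 0)^2
    balloon_sel <- body | cone
    inten[balloon_sel] <- ints[["balloon"]]
    lum_sel <- lum_sel & !balloon_sel
    marker_z <- c(da2_a = geo$marker_a_mm[1], da2_b = geo$marker_b_mm[1])
    for (mk in c("da2_a", "da2_b")) {
      d2 <- (z - marker_z[[mk]])^2 + pre[[mk]]
      marker_sel <- d2 <= spec$balloon$marker_radius_mm^2
      inten[marker_sel] <- ints[["marker"]]
      lum_sel <- lum_sel & !marker_sel
      balloon_sel <- balloon_sel & !marker_sel
    }
  }
  list(inten = inten, lumen = lum_sel, np = np_sel & !lum_sel)
}

render_phantom_state <- function(spec, geo, state) {
  S <- spec$shape[1]; R <- spec$shape[2]; C <- spec$shape[3]
  pv <- spec$partial_volume
  sp <- spec$spacing
  Rs <- R * pv; Cs <- C * pv
  ys <- ((seq_len(Rs) - 0.5) / pv - 0.5) * sp[2]
  xs <- ((seq_len(Cs) - 0.5) / pv - 0.5) * sp[3]
  yy <- rep(ys, times = Cs) - geo$A[2]
  xx <- rep(xs, each = Rs) - geo$A[3]
  pre <- list(q = yy^2 + xx^2,
              syx = yy * geo$d[2] + xx * geo$d[3])
  if (state == "during") {
    pre$da2_a <- (rep(ys, times = Cs) - geo$marker_a_mm[2])^2 +
      (rep(xs, each = Rs) - geo$marker_a_mm[3])^2
    pre$da2_b <- (rep(ys, times = Cs) - geo$marker_b_mm[2])^2 +
      (rep(xs, each = Rs) - geo$marker_b_mm[3])^2
  }
  block_mean <- function(mvec) {
    if (pv == 1) return(matrix(mvec, R, C))
    a <- array(mvec, dim = c(pv, R, pv, C))
    t1 <- colMeans(a)                       # (R, pv, C)
    colMeans(aperm(t1, c(2, 1, 3)))         # (R, C)
  }
  vox <- array(0, dim = c(S, R, C))
  lum_frac <- array(0, dim = c(S, R, C))
  np_frac <- array(0, dim = c(S, R, C))
  for (j in seq_len(S * pv) - 1L) {
    z <- ((j + 0.5) / pv - 0.5) * sp[1]
    lay <- phantom_layer(spec, geo, state, z, pre)
    i <- j %/% pv + 1L
    vox[i, , ] <- vox[i, , ] + block_mean(lay$inten) / pv
    lum_frac[i, , ] <- lum_frac[i, , ] + block_mean(as.numeric(lay$lumen)) / pv
    np_frac[i, , ] <- np_frac[i, , ] + block_mean(as.numeric(lay$np)) / pv
  }
  # per-state noise stream: rendering any subset of states is deterministic
  set.seed(spec$seed + match(state, c("pre", "during", "post")) - 1L)
  if (spec$noise_sd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, spec$noise_sd)
  list(volume = volume(clamp(round_half_up(vox), 0, 255), sp, "gray8"),
       lumen_mask = lum_frac >= 0.5, np_mask = np_frac >= 0.5)
}

#' Generate the synthetic phantom in its three dilation states
#'
#' Renders pre-, during- and post-dilation gray8 volumes sharing one
#' geometry, plus ground truth. Rendering supersamples each voxel
#' `partial_volume^3` times, block-averages (producing the intermediate
#' boundary values of the partial volume effect), then adds zero-mean
#' Gaussian noise; the result is bit-reproducible for a given spec.
#'
#' Ground-truth lumen masks mark voxels whose supersampled air fraction is
#' at least one half; with `partial_volume = 1` this is exactly the set of
#' voxels rendered at the air intensity.
#'
#' @param spec a [phantom_spec()].
#' @param include_during render the during-dilation (inflated balloon)
#'   state as well; set `FALSE` to save time when only the pre/post
#'   comparison is needed.
#' @return List with elements `pre`, `during` (`NULL` when skipped),
#'   `post` ([volume()]s) and `truth` (class `phantom_truth`):
#'   landmark/marker/level coordinates (0-based voxel coordinates), lumen
#'   and nasopharyngeal-air masks and air-voxel counts per state, and true
#'   widths/lengths in px and mm.
#' @export
generate_phantom <- function(spec, include_during = TRUE) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  geo <- phantom_geometry(spec)
  extent <- (spec$shape - 1) * spec$spacing
  margin <- max(geo$widths_post) / 2
  for (p in list(geo$A, geo$B)) {
    if (any(p < margin) || any(p > extent - margin))
      stop("lumen exceeds volume bounds")
  }
  for (lm in geo$landmarks_mm)
    if (any(lm < 0) || any(lm > extent))
      stop("lumen exceeds volume bounds: landmarks outside the volume")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  pre_state <- render_phantom_state(spec, geo, "pre")
  during_state <- if (include_during)
    render_phantom_state(spec, geo, "during") else NULL
  post_state <- render_phantom_state(spec, geo, "post")

  sp <- spec$spacing
  ps <- min(sp[2], sp[3])
  to_vox <- function(p) p / sp
  level_mm <- list(
    np = geo$A + 0.5 * geo$d,
    mid = geo$widest_mm,
    isthmus = geo$A + (geo$L - 0.5) * geo$d)
  dist_mm <- c(total = geo$L, torus_to_widest = geo$s_mid,
               widest_to_tip = geo$L - geo$s_mid)
  truth <- structure(list(
    landmarks = lapply(geo$landmarks_mm, to_vox),
    marker_a = to_vox(geo$marker_a_mm),
    marker_b = to_vox(geo$marker_b_mm),
    torus_tip = to_vox(geo$torus_tip_mm),
    widest = to_vox(geo$widest_mm),
    balloon_tip = to_vox(geo$balloon_tip_mm),
    levels = lapply(level_mm, to_vox),
    ref_points = lapply(geo$ref_mm, to_vox),
    lumen_mask_pre = pre_state$lumen_mask,
    lumen_mask_post = post_state$lumen_mask,
    np_mask = pre_state$np_mask,
    air_count_pre = sum(pre_state$lumen_mask),
    air_count_post = sum(post_state$lumen_mask),
    widths_pre_mm = geo$widths_pre,
    widths_post_mm = geo$widths_post,
    widths_pre_px = geo$widths_pre / ps,
    widths_post_px = geo$widths_post / ps,
    distances_mm = dist_mm,
    distances_px = dist_mm / ps,
    pixel_spacing = ps,
    spec = spec), class = "phantom_truth")
  list(pre = pre_state$volume,
       during = if (include_during) during_state$volume else NULL,
       post = post_state$volume, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom ground truth: air voxels pre %d, post %d (+%.1f%%); mid width %.2f -> %.2f mm\n",
    x$air_count_pre, x$air_count_post,
    100 * (x$air_count_post - x$air_count_pre) / x$air_count_pre,
    x$widths_pre_mm[["mid"]], x$widths_post_mm[["mid"]]))
  invisible(x)
}

#' True relative air increase of a phantom
#' @param truth a `phantom_truth`.
#' @return Ground-truth percent increase in lumen air voxels post vs pre.
#' @export
truth_percent_increase <- function(truth) {
  percent_increase(truth$air_count_pre, truth$air_count_post)
}

#' Write a phantom volume to disk
#'
#' Writes either a single-frame DICOM series or the raw+sidecar fallback,
#' both readable back into an identical [volume()].
#'
#' @param v a [volume()].
#' @param directory output directory.
#' @param format `"dicom"` (default) or `"raw"`.
#' @return Invisibly, the directory.
#' @export
write_phantom_series <- function(v, directory, format = c("dicom", "raw")) {
  format <- match.arg(format)
  if (format == "dicom") {
    write_dicom_series(v, directory)
  } else {
    if (!dir.exists(directory) &&
        !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
      stop("unwritable directory: ", directory)
    write_raw_volume(v, file.path(directory, "volume.raw"))
  }
  invisible(directory)
}

#' Write phantom ground truth (without masks) as JSON
#' @param truth a `phantom_truth`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  keep <- setdiff(names(truth),
                  c("lumen_mask_pre", "lumen_mask_post", "np_mask", "spec"))
  jsonlite::write_json(unclass(truth)[keep], path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
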