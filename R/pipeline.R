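# End-to-end quantification: reslice -> rotate -> ROI -> densitometry ->
# morphometry for one ear, and a multi-ear pipeline driver with report
# aggregation.

#' Build pipeline annotations from phantom ground truth
#'
#' Packages the landmark set, balloon-derived points, width-level points
#' and calibration reference points of a phantom's ground truth in the
#' annotation layout [quantify_ear()] expects. On real scans the same
#' structure is supplied from manual annotation files.
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @return Annotation list with `landmarks`, `points`, `levels`,
#'   `ref_points`.
#' @export
phantom_annotations <- function(truth) {
  if (!inherits(truth, "phantom_truth")) stop("'truth' must be phantom_truth")
  lm <- landmark_set(
    medial_pterygoid_plate = truth$landmarks$medial_pterygoid_plate,
    opposite_pterygoid_plate = truth$landmarks$opposite_pterygoid_plate,
    sphenoid_spine = truth$landmarks$sphenoid_spine,
    balloon_tip = truth$balloon_tip, torus_tip = truth$torus_tip,
    marker_a = truth$marker_a, marker_b = truth$marker_b)
  list(landmarks = lm,
       points = list(torus_tip = truth$torus_tip, widest = truth$widest,
                     balloon_tip = truth$balloon_tip,
                     marker_a = truth$marker_a, marker_b = truth$marker_b),
       levels = truth$levels,
       ref_points = truth$ref_points)
}

#' Read pipeline annotations from a JSON landmark file
#'
#' The file uses the package's landmark dialect ([write_landmarks()]) and
#' must name, besides the three plane landmarks, the points `torus_tip`,
#' `widest`, `balloon_tip`, `marker_a`, `marker_b`, the width-level points
#' `level_np`, `level_mid`, `level_isthmus`, and optionally reference
#' points `ref_air`, `ref_tissue`, `ref_bone`.
#'
#' @param path JSON annotation file.
#' @return Annotation list as for [phantom_annotations()].
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$coordinate_convention))
    stop("annotation file lacks a coordinate_convention field")
  if (!identical(obj$coordinate_convention, LANDMARK_CONVENTION))
    stop("unsupported coordinate convention: ", obj$coordinate_convention)
  p <- lapply(obj$points, as.numeric)
  need <- c("medial_pterygoid_plate", "opposite_pterygoid_plate",
            "sphenoid_spine", "torus_tip", "widest", "balloon_tip",
            "marker_a", "marker_b", "level_np", "level_mid", "level_isthmus")
  missing_pts <- setdiff(need, names(p))
  if (length(missing_pts))
    stop("annotation file misses points: ", paste(missing_pts, collapse = ", "))
  lm <- landmark_set(p$medial_pterygoid_plate, p$opposite_pterygoid_plate,
                     p$sphenoid_spine, balloon_tip = p$balloon_tip,
                     torus_tip = p$torus_tip, marker_a = p$marker_a,
                     marker_b = p$marker_b)
  refs <- NULL
  if (all(c("ref_air", "ref_tissue", "ref_bone") %in% names(p)))
    refs <- list(air = p$ref_air, tissue = p$ref_tissue, bone = p$ref_bone)
  list(landmarks = lm,
       points = p[c("torus_tip", "widest", "balloon_tip", "marker_a",
                    "marker_b")],
       levels = list(np = p$level_np, mid = p$level_mid,
                     isthmus = p$level_isthmus),
       ref_points = refs)
}

#' Write pipeline annotations to a JSON file readable by
#' [read_annotations()]
#' @param ann annotation list.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path) {
  lmpts <- unclass(ann$landmarks)[c("medial_pterygoid_plate",
                                    "opposite_pterygoid_plate",
                                    "sphenoid_spine")]
  pts <- c(lmpts, ann$points,
           list(level_np = ann$levels$np, level_mid = ann$levels$mid,
                level_isthmus = ann$levels$isthmus))
  if (!is.null(ann$ref_points))
    pts <- c(pts, list(ref_air = ann$ref_points$air,
                       ref_tissue = ann$ref_points$tissue,
                       ref_bone = ann$ref_points$bone))
  jsonlite::write_json(list(coordinate_convention = LANDMARK_CONVENTION,
                            points = pts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# square pixel sample around a projected point on an image
sample_around <- function(image, row, col, halfwidth) {
  r0 <- max(0L, round_half_up(row) - halfwidth)
  r1 <- min(nrow(image) - 1L, round_half_up(row) + halfwidth)
  c0 <- max(0L, round_half_up(col) - halfwidth)
  c1 <- min(ncol(image) - 1L, round_half_up(col) + halfwidth)
  as.vector(image[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)])
}

#' Quantify balloon dilation for one ear
#'
#' Runs the full measurement chain on a matched pre-/post-dilation volume
#' pair: builds the landmark plane, extracts geometrically identical
#' 25-image stacks from both volumes, rotates them so the lumen is
#' vertical, constructs the small/longest/long ROI boxes from the balloon
#' markers, calibrates density ranges from the annotated reference regions
#' (or uses supplied/default ranges), counts air pixels in both states and
#' modes, and measures widths and lengths.
#'
#' @param vol_pre,vol_post gray8 [volume()]s sharing geometry.
#' @param ann annotations ([phantom_annotations()] or
#'   [read_annotations()]).
#' @param ranges optional [density_ranges()]; if `NULL`, calibrated from
#'   `ann$ref_points` when present, else [default_density_ranges()].
#' @param half_count images per side of the center image (default 12,
#'   giving the 25-image stack).
#' @param size_px resliced image size `c(rows, cols)`.
#' @param lumen_halfwidth_px small-box half width; default
#'   `ceiling(3.5 / pixel_spacing)` (half the 7 mm balloon diameter).
#' @param ref_halfwidth_px half widths of the square reference samples,
#'   named `c(air = , tissue = , bone = )` (a scalar is recycled). The air
#'   sample defaults to a larger box: the nasopharyngeal air pocket is
#'   large, and the air range's lower bound must reach the darkest noise
#'   floor, whereas tissue and bone reference regions are geometrically
#'   narrow.
#' @return List of class `ear_quantification` with `record` (named numeric
#'   results), `rois`, `ranges`, `stacks`, `profiles` (mean-gray profiles,
#'   small ROI, pre and post).
#' @export
quantify_ear <- function(vol_pre, vol_post, ann, ranges = NULL,
                         half_count = 12, size_px = c(176, 176),
                         lumen_halfwidth_px = NULL,
                         ref_halfwidth_px = c(air = 4, tissue = 2,
                                              bone = 2)) {
  if (!is_volume(vol_pre) || !is_volume(vol_post))
    stop("volumes required")
  if (!identical(dim(vol_pre$voxels), dim(vol_post$voxels)) ||
      any(vol_pre$spacing != vol_post$spacing))
    stop("pre/post volumes must share geometry")
  for (v in list(vol_pre, vol_post))
    if (v$intensity_kind != "gray8")
      stop("pipeline expects gray8 volumes; window HU volumes first")
  sp <- vol_pre$spacing

  frame <- plane_from_landmarks(ann$landmarks, sp)
  stack_pre <- extract_stack(vol_pre, frame, half_count, size_px)
  stack_post <- extract_stack(vol_post, frame, half_count, size_px)

  # common rotation from the projected marker axis (torus end up)
  pa <- project_to_stack(stack_pre, ann$points$marker_a, sp)
  pb <- project_to_stack(stack_pre, ann$points$marker_b, sp)
  axis2d <- c(pb$row - pa$row, pb$col - pa$col)
  stack_pre <- rotate_to_vertical(stack_pre, axis2d)
  stack_post <- rotate_to_vertical(stack_post, axis2d)

  prj <- function(pt) {
    p <- project_to_stack(stack_pre, pt, sp)
    c(p$row, p$col)
  }
  m_a <- prj(ann$points$marker_a); m_b <- prj(ann$points$marker_b)
  torus <- prj(ann$points$torus_tip); widest <- prj(ann$points$widest)
  tip <- prj(ann$points$balloon_tip)
  center_pre <- stack_pre$images[[half_count + 1]]

  if (length(ref_halfwidth_px) == 1)
    ref_halfwidth_px <- c(air = ref_halfwidth_px, tissue = ref_halfwidth_px,
                          bone = ref_halfwidth_px)
  if (is.null(ranges)) {
    ranges <- if (!is.null(ann$ref_points)) {
      rp <- lapply(ann$ref_points, prj)
      calibrate_ranges(
        air_ref = sample_around(center_pre, rp$air[1], rp$air[2],
                                ref_halfwidth_px[["air"]]),
        tissue_ref = sample_around(center_pre, rp$tissue[1], rp$tissue[2],
                                   ref_halfwidth_px[["tissue"]]),
        bone_ref = sample_around(center_pre, rp$bone[1], rp$bone[2],
                                 ref_halfwidth_px[["bone"]]))
    } else default_density_ranges()
  }

  masks <- classify_exclusion_masks(center_pre, ranges,
                                    valid = stack_pre$valid[[half_count + 1]])
  hw <- lumen_halfwidth_px %||% ceiling(3.5 / stack_pre$pixel_spacing)
  small <- build_small_roi(m_a, m_b, hw)
  longest <- build_longest_roi(small, round_half_up(torus[1]),
                               round_half_up(tip[1]), masks)
  long <- build_long_roi(longest)
  rois <- list(small = small, longest = longest, long = long)

  rec <- list(pixel_spacing = stack_pre$pixel_spacing)
  for (kind in names(rois)) {
    for (mode in c("strict", "partial")) {
      pre_n <- air_pixels(stack_pre, rois[[kind]], ranges, mode)
      post_n <- air_pixels(stack_post, rois[[kind]], ranges, mode)
      rec[[paste0("air_pre_", kind, "_", mode)]] <- pre_n
      rec[[paste0("air_post_", kind, "_", mode)]] <- post_n
      rec[[paste0("pct_", kind, "_", mode)]] <-
        percent_increase(pre_n, post_n)
    }
  }

  levels_2d <- lapply(ann$levels, prj)
  level_rows <- list(np_row = round_half_up(levels_2d$np[1]),
                     mid_row = round_half_up(levels_2d$mid[1]),
                     isthmus_row = round_half_up(levels_2d$isthmus[1]))
  seed_col <- (long$col_min + long$col_max) %/% 2L
  center_post <- stack_post$images[[half_count + 1]]
  w_pre <- measure_widths(center_pre, level_rows, ranges, seed_col)
  w_post <- measure_widths(center_post, level_rows, ranges, seed_col)
  for (lv in names(w_pre)) {
    rec[[paste0("width_", lv, "_pre_px")]] <- w_pre[[lv]]
    rec[[paste0("width_", lv, "_post_px")]] <- w_post[[lv]]
    rec[[paste0("width_pct_", lv)]] <-
      if (w_pre[[lv]] > 0) percent_increase(w_pre[[lv]], w_post[[lv]])
      else NA_real_
  }

  dists <- measure_distances(torus, widest, tip)
  rec$dist_total_px <- dists[["total"]]
  rec$dist_torus_widest_px <- dists[["torus_to_widest"]]
  rec$dist_widest_tip_px <- dists[["widest_to_tip"]]
  rec$dist_total_mm <- px_to_mm(dists[["total"]], stack_pre$pixel_spacing)

  structure(list(record = rec, rois = rois, ranges = ranges,
                 stacks = list(pre = stack_pre, post = stack_post),
                 profiles = list(
                   pre = mean_gray_profile(stack_pre, small),
                   post = mean_gray_profile(stack_post, small))),
            class = "ear_quantification")
}

#' Ground-truth air counts inside the pipeline's measurement region
#'
#' Reslices a phantom's ground-truth lumen masks with exactly the geometry
#' (frame, rotation, stack layout) of a quantification result and counts
#' mask pixels inside a ROI — the oracle against which the pipeline's
#' air-pixel counts and percent increase are judged.
#'
#' @param truth a `phantom_truth`.
#' @param eq an `ear_quantification` from [quantify_ear()].
#' @param roi_kind which ROI box to restrict to (default `"small"`).
#' @return List with `pre`, `post` resliced mask pixel counts and
#'   `pct_increase`.
#' @export
truth_roi_counts <- function(truth, eq, roi_kind = "small") {
  st <- eq$stacks$pre
  roi <- eq$rois[[roi_kind]]
  sp <- truth$spec$spacing
  count_mask <- function(mask) {
    mv <- volume(array(as.numeric(mask), dim = dim(mask)), sp, "gray8")
    ms <- extract_stack(mv, st$frame,
                        half_count = (length(st$images) - 1) %/% 2,
                        size_px = dim(st$images[[1]]),
                        pixel_spacing = st$pixel_spacing)
    if (st$rotation != 0)
      ms$images <- lapply(ms$images, rotate_image, theta = st$rotation)
    sum(vapply(ms$images, function(img)
      sum(roi_pixels(img, roi) >= 0.5), numeric(1)))
  }
  pre_n <- count_mask(truth$lumen_mask_pre)
  post_n <- count_mask(truth$lumen_mask_post)
  list(pre = pre_n, post = post_n,
       pct_increase = percent_increase(pre_n, post_n))
}

#' Run the multi-ear dilation pipeline
#'
#' Executes the full chain for every configured ear and aggregates a
#' [dilation_report()]. Each ear is either a phantom specification
#' (generated on the fly, with ground-truth comparison columns) or a pair
#' of on-disk volumes with an annotation file.
#'
#' @param config a list, or path to a JSON/YAML configuration file, with
#'   elements:
#'   \describe{
#'     \item{seed}{integer; seeds phantom ears that do not set their own.}
#'     \item{ears}{list; each entry has `id` and either `phantom` (a list
#'       of [phantom_spec()] argument overrides) or `pre`, `post`
#'       (directories; DICOM series or raw format per `format`) and
#'       `annotations` (JSON path).}
#'     \item{half_count, size_px, air_mode}{optional pipeline settings.}
#'     \item{out_dir}{optional; when set, the report and QC overlay PNGs
#'       are written there.}
#'   }
#' @return A [dilation_report()].
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$ears) || !length(config$ears))
    stop("config must list at least one ear")
  seed <- config$seed %||% 1L
  half_count <- config$half_count %||% 12
  size_px <- config$size_px %||% c(176, 176)
  air_mode <- config$air_mode %||% "partial"
  # calibrate ranges from annotated reference regions (default), or use
  # the package's default ranges when config$calibrate is FALSE
  ranges_arg <- if (isFALSE(config$calibrate)) default_density_ranges()
                else NULL

  rows <- list()
  quals <- list()
  for (i in seq_along(config$ears)) {
    ear <- config$ears[[i]]
    ear_id <- ear$id %||% paste0("ear", i)
    res <- tryCatch({
      if (!is.null(ear$phantom)) {
        args <- ear$phantom
        if (is.null(args$seed)) args$seed <- seed + i
        ph <- generate_phantom(do.call(phantom_spec, args),
                               include_during = FALSE)
        eq <- quantify_ear(ph$pre, ph$post, phantom_annotations(ph$truth),
                           ranges = ranges_arg,
                           half_count = half_count, size_px = size_px)
        tr <- truth_roi_counts(ph$truth, eq, roi_kind = "small")
        eq$record$truth_pct_small <- tr$pct_increase
        eq$record$truth_pct_global <- truth_percent_increase(ph$truth)
        eq$record$truth_width_ratio_mid <-
          ph$truth$widths_post_mm[["mid"]] / ph$truth$widths_pre_mm[["mid"]]
        eq
      } else {
        reader <- if (identical(ear$format, "raw"))
          function(d) read_raw_volume(file.path(d, "volume.raw"))
        else read_dicom_series
        quantify_ear(reader(ear$pre), reader(ear$post),
                     read_annotations(ear$annotations),
                     ranges = ranges_arg,
                     half_count = half_count, size_px = size_px)
      }
    }, error = function(e)
      stop(sprintf("[%s] %s", ear_id, conditionMessage(e)), call. = FALSE))
    rows[[ear_id]] <- c(list(ear_id = ear_id), res$record)
    quals[[ear_id]] <- res
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      hc <- (length(res$stacks$pre$images) - 1) %/% 2
      export_roi_overlay(res$stacks$pre$images[[hc + 1]], res$rois,
                         file.path(config$out_dir,
                                   paste0(ear_id, "_qc_pre.png")))
      export_roi_overlay(res$stacks$post$images[[hc + 1]], res$rois,
                         file.path(config$out_dir,
                                   paste0(ear_id, "_qc_post.png")))
    }
  }
  per_ear <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(per_ear) <- NULL
  report <- dilation_report(per_ear, config = config, air_mode = air_mode)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
}
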