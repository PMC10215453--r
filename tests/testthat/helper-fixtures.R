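# Shared fixtures, all generated in code.

# reduced-size phantom for fast unit tests (10 mm z extent, 37.2 mm
# in-plane, 18 mm lumen); geometry scaled so all structures fit
small_phantom_spec <- function(seed, ...) {
  args <- list(shape = c(17, 120, 120),
               lumen_origin_mm = c(4.2, 5, 10),
               lumen_axis = c(3, 24, 10),
               lumen_length_mm = 18,
               np_radius_mm = 4,
               balloon = list(length_mm = 8, max_diameter_mm = 7,
                              min_diameter_mm = 3, marker_radius_mm = 0.8),
               seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(phantom_spec, args)
}

# deterministic gray8 test volume with a distinctive pattern
pattern_volume <- function(shape = c(5, 8, 9), spacing = c(1, 0.5, 0.5)) {
  n <- prod(shape)
  vox <- array((seq_len(n) * 37) %% 256, dim = shape)
  volume(vox, spacing, "gray8")
}

# nested-loop oracle for ROI histograms (independent of roi_histogram)
brute_histogram <- function(image, roi) {
  counts <- integer(256)
  for (r in roi$row_min:roi$row_max) {
    for (cl in roi$col_min:roi$col_max) {
      g <- floor(image[r + 1, cl + 1] + 0.5)
      g <- min(max(g, 0), 255)
      counts[g + 1] <- counts[g + 1] + 1L
    }
  }
  counts
}

# brute-force air count in one image (inclusive range)
brute_air_count <- function(image, roi, lo, hi) {
  n <- 0L
  for (r in roi$row_min:roi$row_max) {
    for (cl in roi$col_min:roi$col_max) {
      g <- min(max(floor(image[r + 1, cl + 1] + 0.5), 0), 255)
      if (g >= lo && g <= hi) n <- n + 1L
    }
  }
  n
}

# two-pass mean / sample SD oracle
brute_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  c(mean = m,
    sd = if (length(x) >= 2) sqrt(sum((x - m)^2) / (length(x) - 1))
         else NA_real_)
}

random_roi <- function(nrow_img, ncol_img, kind = "small") {
  r <- sort(sample(0:(nrow_img - 1), 2))
  cl <- sort(sample(0:(ncol_img - 1), 2))
  roi_box(kind, col_min = cl[1], col_max = cl[2],
          row_min = r[1], row_max = r[2])
}
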