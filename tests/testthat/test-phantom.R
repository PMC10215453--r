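test_that("phantom rendering is bit-reproducible for a fixed seed", {
  s1 <- small_phantom_spec(seed = 99, partial_volume = 1)
  s2 <- small_phantom_spec(seed = 99, partial_volume = 1)
  a <- generate_phantom(s1, include_during = FALSE)
  b <- generate_phantom(s2, include_during = FALSE)
  expect_identical(a$pre$voxels, b$pre$voxels)
  expect_identical(a$post$voxels, b$post$voxels)
  c3 <- generate_phantom(small_phantom_spec(seed = 100, partial_volume = 1),
                         include_during = FALSE)
  expect_false(identical(a$pre$voxels, c3$pre$voxels))
})

test_that("unit dilation factors leave the lumen unchanged", {
  spec <- small_phantom_spec(seed = 4, dilation_factor = 1,
                             dilation_factor_np = 1,
                             dilation_factor_isthmus = 1,
                             noise_sd = 0, partial_volume = 1)
  ph <- generate_phantom(spec, include_during = FALSE)
  expect_equal(ph$truth$air_count_pre, ph$truth$air_count_post)
  expect_identical(ph$pre$voxels, ph$post$voxels)
})

test_that("noiseless rendering uses exactly the configured intensities", {
  spec <- small_phantom_spec(seed = 8, noise_sd = 0, partial_volume = 1)
  ph <- generate_phantom(spec)
  ints <- spec$intensities
  expect_true(all(ph$pre$voxels %in% ints[c("air", "tissue", "bone")]))
  expect_true(all(ph$during$voxels %in% ints))
  expect_true(all(ph$pre$voxels[ph$truth$lumen_mask_pre] == ints[["air"]]))
  expect_true(all(ph$post$voxels[ph$truth$lumen_mask_post] == ints[["air"]]))
  expect_true(all(ph$pre$voxels[ph$truth$np_mask] == ints[["air"]]))
  # ground-truth counts equal mask cardinalities
  expect_equal(ph$truth$air_count_pre, sum(ph$truth$lumen_mask_pre))
  expect_equal(ph$truth$air_count_post, sum(ph$truth$lumen_mask_post))
})

test_that("dilation factors pass through to ground-truth widths", {
  spec <- small_phantom_spec(seed = 3, dilation_factor = 2,
                             lumen_width_pre_mm = c(np = 2.4, mid = 2,
                                                    isthmus = 1.2),
                             noise_sd = 0, partial_volume = 1)
  ph <- generate_phantom(spec, include_during = FALSE)
  expect_equal(ph$truth$widths_pre_mm[["mid"]], 2)
  expect_equal(ph$truth$widths_post_mm[["mid"]], 4)
  expect_equal(ph$truth$widths_post_px[["mid"]], 4 / 0.3125)
})

test_that("true air gain grows monotonically with the dilation factor", {
  counts <- vapply(c(1, 1.4, 1.8), function(f) {
    ph <- generate_phantom(
      small_phantom_spec(seed = 12, dilation_factor = f, noise_sd = 0,
                         partial_volume = 1),
      include_during = FALSE)
    ph$truth$air_count_post
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("supersampling produces the partial-volume boundary tail", {
  ph <- generate_phantom(small_phantom_spec(seed = 6, noise_sd = 0,
                                            partial_volume = 3),
                         include_during = FALSE)
  vals <- ph$pre$voxels
  ints <- ph$truth$spec$intensities
  boundary <- vals > ints[["air"]] & vals < ints[["tissue"]]
  expect_gt(sum(boundary), 0)
})

test_that("the during state renders balloon and radiopaque markers", {
  spec <- small_phantom_spec(seed = 5, noise_sd = 0, partial_volume = 1)
  ph <- generate_phantom(spec)
  ints <- spec$intensities
  expect_gt(sum(ph$during$voxels == ints[["marker"]]), 0)
  expect_gt(sum(ph$during$voxels == ints[["balloon"]]), 0)
  expect_equal(sum(ph$pre$voxels == ints[["marker"]]), 0)
  # marker voxels concentrate around the ground-truth marker positions
  mk <- which(ph$during$voxels == ints[["marker"]], arr.ind = TRUE) - 1
  ctrs <- rbind(ph$truth$marker_a, ph$truth$marker_b)
  sp <- spec$spacing
  d_mm <- apply(mk, 1, function(p) {
    min(sqrt(sum(((p - ctrs[1, ]) * sp)^2)),
        sqrt(sum(((p - ctrs[2, ]) * sp)^2)))
  })
  expect_lt(max(d_mm), spec$balloon$marker_radius_mm + max(sp))
})

test_that("a lumen that does not fit the volume is refused", {
  expect_error(
    generate_phantom(small_phantom_spec(seed = 1, lumen_length_mm = 60)),
    "exceeds volume bounds")
})

test_that("phantom series round trip through both on-disk formats", {
  ph <- generate_phantom(small_phantom_spec(seed = 44, partial_volume = 1),
                         include_during = FALSE)
  for (fmt in c("dicom", "raw")) {
    d <- withr::local_tempdir()
    write_phantom_series(ph$pre, d, format = fmt)
    back <- if (fmt == "dicom") read_dicom_series(d)
            else read_raw_volume(file.path(d, "volume.raw"))
    expect_equal(back$voxels, ph$pre$voxels)
    expect_equal(back$spacing, ph$pre$spacing, tolerance = 1e-9)
  }
  d <- withr::local_tempdir()
  write_phantom_series(ph$pre, d, format = "dicom")
  expect_length(list.files(d), dim(ph$pre$voxels)[1])
  gt_path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(ph$truth, gt_path)
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  expect_equal(gt$air_count_pre, ph$truth$air_count_pre)
  expect_equal(as.numeric(gt$landmarks$sphenoid_spine),
               ph$truth$landmarks$sphenoid_spine)
})
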