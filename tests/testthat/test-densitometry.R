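test_that("clean reference samples calibrate to their exact ranges", {
  set.seed(5)
  air <- sample(0:16, 4000, replace = TRUE)
  tissue <- sample(42:88, 4000, replace = TRUE)
  bone <- sample(214:255, 4000, replace = TRUE)
  rng <- calibrate_ranges(air, tissue, bone)
  expect_equal(rng$air_strict, c(0L, 16L))
  expect_equal(rng$air_partial, c(0L, 31L))
  expect_equal(rng$tissue, c(42L, 88L))
  expect_equal(rng$bone, c(214L, 255L))

  rng1 <- calibrate_ranges(5, 60, 230)
  expect_equal(rng1$air_strict, c(5L, 5L))
  expect_equal(rng1$tissue, c(60L, 60L))
  expect_equal(rng1$bone, c(230L, 230L))

  expect_error(calibrate_ranges(0:16, 42:220, 214:255),
               "not separable")
})

test_that("trimming discards sparse stray bins without moving clean ranges", {
  air <- c(rep(3:12, each = 500), 200) # one stray bright pixel
  rng <- calibrate_ranges(air, 42:88, 214:255)
  expect_equal(rng$air_strict, c(3L, 12L))
})

test_that("ROI histograms count exactly and conserve box area", {
  img <- matrix(7, 30, 40)
  roi <- roi_box("small", 5, 24, 10, 19) # 10 x 20 box
  h <- roi_histogram(img, roi)
  expect_equal(h$counts[8], 200)
  expect_equal(sum(h$counts), 200)
  expect_equal(sum(h$counts != 0), 1)

  ramp <- matrix(rep(0:255, length.out = 50 * 60), 50, 60)
  for (box in list(roi_box("small", 0, 59, 0, 49),
                   roi_box("small", 10, 20, 5, 5))) {
    expect_equal(sum(roi_histogram(ramp, box)$counts), roi_area(box))
  }
  expect_error(roi_histogram(img, roi_box("small", 0, 40, 0, 5)),
               "out of image bounds")
})

test_that("histograms and air counts match the nested-loop oracle", {
  set.seed(77)
  for (rep in 1:10) {
    img <- matrix(stats::runif(48 * 48, -3, 260), 48, 48)
    roi <- random_roi(48, 48)
    expect_equal(roi_histogram(img, roi)$counts, brute_histogram(img, roi))
    st <- slice_stack(list(img), 0, 0.3125)
    rng <- default_density_ranges()
    expect_equal(air_pixels(st, roi, rng, "strict"),
                 brute_air_count(img, roi, 0, 16))
    expect_equal(air_pixels(st, roi, rng, "partial"),
                 brute_air_count(img, roi, 0, 31))
  }
})

test_that("air counting sums across slices and strict <= partial", {
  tissue_img <- matrix(60, 20, 20)
  st_tissue <- slice_stack(rep(list(tissue_img), 5),
                           (-2:2) * 0.625, 0.3125)
  roi <- roi_box("small", 2, 17, 2, 17)
  rng <- default_density_ranges()
  expect_equal(air_pixels(st_tissue, roi, rng, "partial"), 0)

  air_img <- matrix(60, 20, 20)
  air_img[5 + 1:10, 8] <- 3 # 10 air pixels per slice
  st_air <- slice_stack(rep(list(air_img), 25), (-12:12) * 0.625, 0.3125)
  expect_equal(air_pixels(st_air, roi_box("small", 0, 19, 0, 19), rng,
                          "strict"), 250)

  set.seed(13)
  for (rep in 1:10) {
    imgs <- lapply(1:5, function(i) matrix(stats::runif(400, 0, 255), 20, 20))
    st <- slice_stack(imgs, (-2:2) * 0.625, 0.3125)
    roi_r <- random_roi(20, 20)
    expect_lte(air_pixels(st, roi_r, rng, "strict"),
               air_pixels(st, roi_r, rng, "partial"))
  }
  expect_error(air_pixels(st_air, rep(list(roi), 3), rng), "one ROI per")
})

test_that("percent increase follows its definition and guards the baseline", {
  expect_equal(percent_increase(100, 164), 64)
  expect_equal(percent_increase(250, 250), 0)
  expect_equal(percent_increase(200, 150), -25)
  # invariant under uniform scaling of both counts
  expect_equal(percent_increase(37, 91), percent_increase(37 * 8, 91 * 8))
  expect_error(percent_increase(0, 50), "undefined baseline")
})

test_that("mean gray profile equals the histogram-weighted mean", {
  expect_equal(
    mean_gray_profile(slice_stack(list(matrix(50, 10, 10)), 0, 1),
                      roi_box("small", 0, 9, 0, 9)),
    50)
  set.seed(21)
  imgs <- lapply(1:3, function(i) matrix(stats::runif(900, 0, 255), 30, 30))
  st <- slice_stack(imgs, -1:1, 1)
  roi <- roi_box("small", 4, 25, 6, 27)
  means <- mean_gray_profile(st, roi)
  for (i in 1:3) {
    h <- roi_histogram(imgs[[i]], roi)
    expect_equal(means[i], sum((0:255) * h$counts) / sum(h$counts))
  }
})

test_that("exclusion classification finds bone and top-connected air", {
  img <- matrix(60, 30, 30)
  img[, 25:30] <- 230                 # bone slab (cols 24..29, 0-based)
  img[1:10, 5] <- 3                   # air column touching the top
  img[20:24, 10] <- 3                 # interior air pocket, not connected
  masks <- classify_exclusion_masks(img, default_density_ranges())
  expect_true(all(masks$bone[, 25:30]))
  expect_false(any(masks$bone[, 1:24]))
  expect_true(all(masks$np_air[1:10, 5]))
  expect_false(any(masks$np_air[20:24, 10]))
})
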