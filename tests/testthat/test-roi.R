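test_that("small ROI spans the markers and is symmetric in marker order", {
  box <- build_small_roi(c(40, 60), c(80, 60), lumen_halfwidth_px = 10)
  expect_equal(c(box$row_min, box$row_max), c(40, 80))
  expect_equal(c(box$col_min, box$col_max), c(50, 70))
  swapped <- build_small_roi(c(80, 60), c(40, 60), lumen_halfwidth_px = 10)
  expect_equal(unclass(box), unclass(swapped))
  expect_error(build_small_roi(c(40, 60), c(80, 66), 10), "rotate first")
  expect_error(build_small_roi(c(40, 60), c(40, 60), 10), "distinct")
})

test_that("longest ROI extends equally and respects the rule arithmetic", {
  small <- roi_box("small", 50, 70, 40, 80)
  longest <- build_longest_roi(small, torus_row = 20, balloon_tip_row = 110)
  expect_equal(c(longest$row_min, longest$row_max), c(20, 100))
  expect_equal(c(longest$col_min, longest$col_max), c(50, 70))
  expect_error(build_longest_roi(small, torus_row = 40, balloon_tip_row = 110),
               "no room to extend")
})

test_that("exclusion masks cap the extension where the mask begins", {
  small <- roi_box("small", 50, 70, 40, 80)
  bone <- matrix(FALSE, 150, 120)
  bone[(15:24) + 1, (50:70) + 1] <- TRUE # rows 15..24 within the columns
  longest <- build_longest_roi(small, 10, 140, list(bone = bone))
  expect_equal(longest$row_min, 25)
  expect_equal(longest$row_max, 95) # equal extension d = 15 at both ends
  # mask outside the columns does not block
  bone2 <- matrix(FALSE, 150, 120)
  bone2[(15:24) + 1, (90:100) + 1] <- TRUE
  longest2 <- build_longest_roi(small, 10, 140, list(bone = bone2))
  expect_equal(c(longest2$row_min, longest2$row_max), c(10, 110))
})

test_that("long ROI retracts 5 px per end and refuses short boxes", {
  longest <- roi_box("longest", 50, 70, 20, 100)
  long <- build_long_roi(longest)
  expect_equal(c(long$row_min, long$row_max), c(25, 95))
  expect_equal(long$row_max - long$row_min + 1, 71) # 81 px becomes 71 px
  expect_error(build_long_roi(roi_box("longest", 50, 70, 20, 29)),
               "too short")
})

test_that("box nesting and shared columns hold over random configurations", {
  set.seed(33)
  for (rep in 1:50) {
    row_min <- sample(30:60, 1)
    height <- sample(10:40, 1)
    small <- build_small_roi(c(row_min, 60), c(row_min + height, 60),
                             lumen_halfwidth_px = sample(5:15, 1))
    gap_top <- sample(1:20, 1)
    gap_bot <- sample(1:20, 1)
    mask <- matrix(FALSE, 200, 120)
    if (stats::runif(1) < 0.5) {
      blk <- sample(0:(small$row_min - 1), 1)
      mask[blk + 1, (small$col_min:small$col_max) + 1] <- TRUE
    }
    longest <- tryCatch(
      build_longest_roi(small, small$row_min - gap_top,
                        small$row_max + gap_bot, list(bone = mask)),
      error = function(e) NULL)
    if (is.null(longest)) next
    d <- small$row_min - longest$row_min
    # equal extension at both ends
    expect_equal(longest$row_max - small$row_max, d)
    expect_gte(d, 1)
    # brute-force verification of the chosen extension distance
    d_brute <- 0
    for (dd in seq_len(min(gap_top, gap_bot))) {
      rows <- c(small$row_min - dd, small$row_max + dd)
      if (any(mask[rows + 1, (small$col_min:small$col_max) + 1])) break
      d_brute <- dd
    }
    expect_equal(d, d_brute)
    expect_equal(c(longest$col_min, longest$col_max),
                 c(small$col_min, small$col_max))
    if (d >= 5 && roi_height(longest) > 10) {
      long <- build_long_roi(longest)
      # nesting small within long within longest
      expect_true(long$row_min >= longest$row_min + 5 &&
                  long$row_max <= longest$row_max - 5)
      expect_true(small$row_min >= long$row_min &&
                  small$row_max <= long$row_max)
    }
  }
})

test_that("ROI boxes serialize to JSON and back unchanged", {
  rois <- list(small = roi_box("small", 50, 70, 40, 80),
               longest = roi_box("longest", 50, 70, 20, 100),
               long = roi_box("long", 50, 70, 25, 95))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_equal(lapply(back, unclass), lapply(rois, unclass))
})
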