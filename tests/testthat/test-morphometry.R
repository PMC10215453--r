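test_that("width is the seeded air run length, zero when the lumen is closed", {
  img <- matrix(60, 100, 120)
  img[41, (50:59) + 1] <- 5 # air run cols 50..59 on row 40 (0-based)
  rng <- default_density_ranges()
  w <- measure_widths(img, list(np_row = 40, mid_row = 40, isthmus_row = 60),
                      rng, seed_col = 55)
  expect_equal(unname(w), c(10, 10, 0))
  # seed outside the run: width 0 even though air exists on the row
  w2 <- measure_widths(img, list(np_row = 40, mid_row = 40, isthmus_row = 40),
                       rng, seed_col = 80)
  expect_equal(unname(w2), c(0, 0, 0))
  expect_error(measure_widths(img, list(np_row = 200, mid_row = 40,
                                        isthmus_row = 40), rng, 55),
               "outside image")
})

test_that("widths are monotone under morphological widening of the air run", {
  rng <- default_density_ranges()
  set.seed(9)
  for (rep in 1:10) {
    img <- matrix(60, 50, 80)
    start <- sample(20:40, 1); len <- sample(3:20, 1)
    img[26, start:(start + len - 1)] <- 4
    wide <- img
    wide[26, (start - 2):(start + len + 1)] <- 4
    lv <- list(np_row = 25, mid_row = 25, isthmus_row = 25)
    seed_col <- start + len %/% 2 - 1
    expect_gte(measure_widths(wide, lv, rng, seed_col)[["mid"]],
               measure_widths(img, lv, rng, seed_col)[["mid"]])
  }
})

test_that("distances are Euclidean with the expected symmetries", {
  d <- measure_distances(c(0, 30), c(45, 30), c(76, 30))
  expect_equal(unname(d), c(76, 45, 31))
  # traversing tip-to-torus swaps the two partial lengths, total unchanged
  d2 <- measure_distances(c(76, 30), c(45, 30), c(0, 30))
  expect_equal(d2[["total"]], d[["total"]])
  expect_equal(d2[["torus_to_widest"]], d[["widest_to_tip"]])
  expect_equal(d2[["widest_to_tip"]], d[["torus_to_widest"]])
  set.seed(14)
  for (rep in 1:20) {
    pts <- matrix(stats::runif(6, 0, 100), 3, 2)
    dd <- tryCatch(measure_distances(pts[1, ], pts[2, ], pts[3, ]),
                   error = function(e) NULL)
    if (is.null(dd)) next
    # triangle inequality: the two segments bound the total length
    expect_gte(dd[["torus_to_widest"]] + dd[["widest_to_tip"]],
               dd[["total"]] - 1e-9)
    # translation invariance
    shift <- stats::runif(2, -50, 50)
    dd2 <- measure_distances(pts[1, ] + shift, pts[2, ] + shift,
                             pts[3, ] + shift)
    expect_equal(dd2, dd, tolerance = 1e-9)
  }
  expect_error(measure_distances(c(1, 1), c(1, 1), c(2, 2)), "coincident")
})

test_that("pixel-to-mm conversion is linear in the supplied spacing", {
  expect_equal(px_to_mm(0, 0.3125), 0)
  expect_equal(px_to_mm(100, 160 / 512), 31.25)
  # spacing back-computed from a known px/mm pair reproduces the mm value
  implied <- 16.8 / 45.26
  expect_equal(px_to_mm(45.26, implied), 16.8, tolerance = 1e-12)
  expect_equal(px_to_mm(31.26, implied), 11.3, tolerance = 0.31)
  expect_error(px_to_mm(10, 0), "positive")
})
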