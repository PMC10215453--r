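random_landmarks <- function() {
  repeat {
    pts <- lapply(1:3, function(i) stats::runif(3, 0, 40))
    lm <- landmark_set(pts[[1]], pts[[2]], pts[[3]])
    area <- vnorm_test(cross_test(pts[[2]] - pts[[1]],
                                  pts[[3]] - pts[[1]])) / 2
    if (area > 2) return(lm)
  }
}
cross_test <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                               a[3] * b[1] - a[1] * b[3],
                               a[1] * b[2] - a[2] * b[1])
vnorm_test <- function(x) sqrt(sum(x^2))

test_that("axis-aligned landmarks give an axis-aligned plane normal", {
  lm <- landmark_set(c(0, 0, 0), c(0, 10, 0), c(0, 0, 10))
  fr <- plane_from_landmarks(lm, spacing = c(1, 1, 1))
  expect_equal(abs(fr$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_error(
    plane_from_landmarks(landmark_set(c(0, 0, 0), c(0, 5, 5), c(0, 10, 10)),
                         spacing = c(1, 1, 1)),
    "degenerate plane")
})

test_that("planes contain their landmarks and frames are orthonormal", {
  set.seed(101)
  for (rep in 1:25) {
    lm <- random_landmarks()
    spacing <- stats::runif(3, 0.3, 1.2)
    fr <- plane_from_landmarks(lm, spacing)
    for (p in list(lm$medial_pterygoid_plate, lm$opposite_pterygoid_plate,
                   lm$sphenoid_spine)) {
      dist <- abs(sum((p * spacing - fr$origin) * fr$normal))
      expect_lt(dist, 1e-6)
    }
    for (pair in list(c("u", "v"), c("u", "normal"), c("v", "normal")))
      expect_lt(abs(sum(fr[[pair[1]]] * fr[[pair[2]]])), 1e-9)
    for (nm in c("u", "v", "normal"))
      expect_equal(vnorm_test(fr[[nm]]), 1, tolerance = 1e-9)
  }
})

test_that("the plane is invariant under landmark permutation", {
  set.seed(202)
  for (rep in 1:10) {
    lm <- random_landmarks()
    spacing <- c(0.625, 0.3125, 0.3125)
    fr0 <- plane_from_landmarks(lm, spacing)
    pts <- list(lm$medial_pterygoid_plate, lm$opposite_pterygoid_plate,
                lm$sphenoid_spine)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2))) {
      fr <- plane_from_landmarks(
        landmark_set(pts[[perm[1]]], pts[[perm[2]]], pts[[perm[3]]]), spacing)
      expect_equal(fr$origin, fr0$origin, tolerance = 1e-9)
      # same plane up to sign of the normal
      expect_equal(abs(sum(fr$normal * fr0$normal)), 1, tolerance = 1e-9)
    }
  }
})

test_that("identity-frame extraction reproduces native slices bit-exactly", {
  v <- pattern_volume(shape = c(7, 20, 20), spacing = c(0.625, 0.4, 0.4))
  fr <- identity_frame(v, center_slice = 3)
  st <- extract_stack(v, fr, half_count = 3, size_px = c(20, 20))
  expect_length(st$images, 7)
  for (k in 1:7) expect_equal(st$images[[k]], v$voxels[k, , ])
})

test_that("stack layout matches the acquisition protocol", {
  v <- pattern_volume(shape = c(30, 12, 12), spacing = c(0.625, 0.3, 0.3))
  fr <- identity_frame(v, center_slice = 14)
  st <- extract_stack(v, fr, half_count = 12, size_px = c(12, 12))
  expect_length(st$images, 25)
  expect_equal(st$offsets, (-12:12) * 0.625)
  st1 <- extract_stack(v, fr, half_count = 0, size_px = c(12, 12))
  expect_length(st1$images, 1)
  expect_equal(st1$offsets, 0)
  expect_equal(st$pixel_spacing, 0.3)
})

test_that("out-of-volume samples are zero", {
  v <- volume(array(200, dim = c(4, 6, 6)), c(1, 1, 1), "gray8")
  fr <- identity_frame(v, center_slice = 1)
  st <- extract_stack(v, fr, half_count = 3, size_px = c(6, 6))
  expect_true(all(st$images[[1]] == 0))   # offset -3: slice index -2
  expect_true(all(st$images[[5]] == 200)) # offset +1: inside
})

test_that("rotation brings a bar to vertical and a vertical axis is a no-op", {
  img <- matrix(0, 21, 21)
  img[11, 4:18] <- 200 # horizontal bar through the center
  st <- slice_stack(list(img), 0, 1)
  same <- rotate_to_vertical(st, c(1, 0))
  expect_equal(same$images[[1]], img)
  rot <- rotate_to_vertical(st, c(0, 1))
  expect_equal(rot$rotation, -pi / 2, tolerance = 1e-12)
  # the bar is now vertical: column 11 holds the mass
  col_sums <- colSums(rot$images[[1]])
  row_sums <- rowSums(rot$images[[1]])
  expect_equal(which.max(col_sums), 11)
  expect_gt(max(row_sums) / max(col_sums), 0) # bar spread across rows
  expect_equal(sort(which(row_sums > 100)), 4:18)
  expect_error(rotate_to_vertical(st, c(0, 0)), "nonzero")
})

test_that("rotating by the lumen axis straightens an oblique mask", {
  # oblique band; after rotation its per-row centroid variance shrinks
  img <- matrix(0, 41, 41)
  for (r in 5:35) {
    cc <- 5 + round(0.8 * (r - 5))
    img[r + 1, (cc - 1):(cc + 1) + 1] <- 1
  }
  centroid_var <- function(m) {
    cents <- apply(m, 1, function(row)
      if (sum(row) > 0) sum(seq_along(row) * row) / sum(row) else NA)
    stats::var(cents[!is.na(cents)])
  }
  st <- slice_stack(list(img), 0, 1)
  rot <- rotate_to_vertical(st, c(1, 0.8))
  expect_lt(centroid_var(rot$images[[1]] > 0.5), centroid_var(img))
})

test_that("projected points land where their pixels were sampled", {
  v <- pattern_volume(shape = c(9, 24, 24), spacing = c(0.625, 0.5, 0.5))
  fr <- identity_frame(v, center_slice = 4)
  st <- extract_stack(v, fr, half_count = 2, size_px = c(24, 24))
  p <- project_to_stack(st, c(4, 7, 13), v$spacing)
  expect_equal(p$row, 7)
  expect_equal(p$col, 13)
  expect_equal(p$offset_mm, 0)
  p2 <- project_to_stack(st, c(6, 7, 13), v$spacing)
  expect_equal(p2$offset_mm, 2 * 0.625)
})

test_that("pre and post stacks from one landmark set share geometry", {
  spec <- small_phantom_spec(seed = 7, noise_sd = 0, partial_volume = 1)
  ph <- generate_phantom(spec, include_during = FALSE)
  ann <- phantom_annotations(ph$truth)
  fr <- plane_from_landmarks(ann$landmarks, ph$pre$spacing)
  st_pre <- extract_stack(ph$pre, fr, half_count = 4, size_px = c(60, 60))
  st_post <- extract_stack(ph$post, fr, half_count = 4, size_px = c(60, 60))
  expect_equal(st_pre$offsets, st_post$offsets)
  expect_equal(st_pre$pixel_spacing, st_post$pixel_spacing)
  expect_equal(dim(st_pre$images[[1]]), dim(st_post$images[[1]]))
})
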