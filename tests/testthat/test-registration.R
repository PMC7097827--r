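make_plain_pair <- function(n = 101, roi = NULL) {
  img <- const_img(n, n, c(100, 70, 75))
  c0 <- (n + 1) / 2
  if (is.null(roi)) roi <- matrix(TRUE, n, n)
  fid <- fiducial_set(center = c(c0, c0), os_a = c(c0 - 20, c0),
                      os_b = c(c0 + 20, c0))
  register_pair(img, img, fid, fid, roi_pre = roi, roi_post = roi)
}

test_that("an already-horizontal centered pair maps through unchanged", {
  n <- 101
  set.seed(7)
  img <- array(runif(n * n * 3, 0, 255), dim = c(n, n, 3))
  c0 <- (n + 1) / 2
  fid <- fiducial_set(c(c0, c0), c(c0 - 20, c0), c(c0 + 20, c0))
  pair <- register_pair(img, img, fid, fid,
                        roi_pre = matrix(TRUE, n, n),
                        roi_post = matrix(TRUE, n, n))
  expect_equal(pair$pre, img, tolerance = 1e-12)
  expect_equal(unname(pair$angles), c(0, 0))
  expect_equal(pair$fiducials$os_a[2], pair$fiducials$os_b[2])
})

test_that("a 45-degree os line induces a -45-degree rotation", {
  n <- 51
  img <- const_img(n, n, c(100, 70, 75))
  fid <- fiducial_set(center = c(25, 25), os_a = c(20, 20), os_b = c(30, 30))
  pair <- register_pair(img, img, fid, fid,
                        roi_pre = matrix(TRUE, n, n),
                        roi_post = matrix(TRUE, n, n))
  expect_equal(unname(pair$angles), c(-45, -45))
})

test_that("a marked point lands where the rigid transform predicts", {
  n <- 101
  img <- const_img(n, n, c(100, 70, 75))
  img[30, 70, ] <- c(250, 250, 250)  # dot at (x=70, y=30)
  fid <- fiducial_set(center = c(45, 55), os_a = c(35, 45), os_b = c(55, 65))
  pair <- register_pair(img, img, fid, fid,
                        roi_pre = matrix(TRUE, n, n),
                        roi_post = matrix(TRUE, n, n))
  # forward transform: rotate dot offset by -45 deg about (45,55), then move
  # the center to the canvas center (51,51)
  a <- -45 * pi / 180
  dx <- 70 - 45; dy <- 30 - 55
  expect_x <- 51 + cos(a) * dx - sin(a) * dy
  expect_y <- 51 + sin(a) * dx + cos(a) * dy
  bright <- which(pair$pre[, , 1] > 150, arr.ind = TRUE)
  got_y <- mean(bright[, 1]); got_x <- mean(bright[, 2])
  expect_lt(abs(got_x - expect_x), 1)
  expect_lt(abs(got_y - expect_y), 1)
})

test_that("coincident os endpoints are rejected", {
  expect_error(fiducial_set(c(5, 5), c(3, 3), c(3, 3)), "distinct")
})

test_that("registration is idempotent", {
  sc <- generate_scene(small_spec(os_angle_deg = 25, noise_sd = 0,
                                  n_specular_spots = 0, seed = 31))
  pair <- register_pair(sc$pre, sc$post, sc$fiducials, sc$fiducials)
  pair2 <- register_pair(pair$pre, pair$post, pair$fiducials, pair$fiducials,
                         roi_pre = pair$roi, roi_post = pair$roi)
  expect_lt(max(abs(pair2$angles)), 0.5)
  expect_lt(max(abs(pair2$fiducials$center - pair$fiducials$center)), 0.5)
})

test_that("clock slicing partitions the ROI pixel-exactly", {
  sc <- generate_scene(small_spec(os_angle_deg = -18, seed = 8))
  pp_pre <- preprocess_image(sc$pre); pp_post <- preprocess_image(sc$post)
  pair <- register_pair(pp_pre$image, pp_post$image, sc$fiducials,
                        sc$fiducials, roi_pre = pp_pre$roi,
                        roi_post = pp_post$roi)
  slices <- slice_clock(pair)
  expect_length(slices, 12)
  acc <- matrix(0L, nrow(pair$roi), ncol(pair$roi))
  for (s in slices) {
    expect_true(all(pair$roi[s$mask]))  # mask subset of roi
    acc <- acc + s$mask
  }
  expect_true(all(acc[pair$roi] == 1L))   # each ROI pixel in exactly one
  expect_true(all(acc[!pair$roi] == 0L))  # and nothing outside
})

test_that("pixels above and right of center fall in sectors 12 and 3", {
  pair <- make_plain_pair(101)
  slices <- slice_clock(pair)
  expect_true(slices[[12]]$mask[51 - 20, 51])  # straight up
  expect_true(slices[[3]]$mask[51, 51 + 20])   # straight right
  expect_true(slices[[6]]$mask[51 + 20, 51])   # straight down
  expect_true(slices[[9]]$mask[51, 51 - 20])   # straight left
})

test_that("rotating a pair by 30 degrees shifts every sector by one hour", {
  # exact coordinate rotation: sector assignment must be equivariant, i.e.
  # a point rotated clockwise by one hour lands in the next sector
  n <- 151
  c0 <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n); col <- matrix(seq_len(n), n, n, byrow = TRUE)
  disk <- (col - c0)^2 + (row - c0)^2 <= 60^2
  pair <- make_plain_pair(n, roi = disk)
  slices <- slice_clock(pair)
  b <- 30 * pi / 180
  for (k in 1:12) {
    idx <- which(slices[[k]]$mask, arr.ind = TRUE)
    dx <- idx[, 2] - c0; dy <- idx[, 1] - c0
    rx <- cos(b) * dx - sin(b) * dy   # clockwise on screen (y down)
    ry <- sin(b) * dx + cos(b) * dy
    shifted <- expected_sector(rx, ry)
    # lattice points sitting exactly on a sector boundary land exactly on
    # the next boundary, where float rounding may tip them either way;
    # away from that measure-zero set the shift must be exact
    theta <- (atan2(dx, -dy) * 180 / pi) %% 360
    off_boundary <- abs((theta + 15) %% 30 - 15) < 14.75 &
                    (dx != 0 | dy != 0)  # the center pixel has no angle
    expect_true(all(shifted[off_boundary] == (k %% 12) + 1))
    expect_gte(mean(shifted == (k %% 12) + 1), 0.95)
  }
})

test_that("histopathology grades map onto slice labels", {
  pair <- make_plain_pair(101)
  slices <- slice_clock(pair)

  all_cin1 <- attach_labels(slices, rep("CIN1", 12))
  expect_true(all(vapply(all_cin1, `[[`, "", "label") == "VIA_NEG"))

  grades <- rep("NORMAL", 12); grades[3] <- "CIN2PLUS"; grades[7] <- NA
  lab <- attach_labels(slices, grades)
  labels <- vapply(lab, `[[`, "", "label")
  expect_identical(labels[3], "VIA_POS")
  expect_identical(labels[7], "UNKNOWN")
  expect_true(all(labels[-c(3, 7)] == "VIA_NEG"))

  expect_error(attach_labels(slices, rep("NORMAL", 11)), "length 12")
  expect_error(attach_labels(slices, c(rep("NORMAL", 11), "CIN9")), "grade")
})

test_that("an empty ROI flags all slices invalid", {
  pair <- make_plain_pair(101, roi = matrix(FALSE, 101, 101))
  slices <- slice_clock(pair)
  expect_true(all(vapply(slices, `[[`, TRUE, "empty_roi")))
  expect_false(any(vapply(slices, `[[`, TRUE, "valid")))
})
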