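# motion core: grayscale conversion, background model, distance, mask, A

test_that("to_grayscale handles 1- and 3-channel input and rejects others", {
  gray <- matrix(100, 4, 4)
  expect_identical(to_grayscale(gray), gray)

  rgb_flat <- array(100, dim = c(4, 4, 3))
  expect_equal(to_grayscale(rgb_flat), matrix(100, 4, 4))

  green <- array(0, dim = c(2, 3, 3)); green[, , 2] <- 255
  expect_equal(to_grayscale(green), matrix(round(0.587 * 255), 2, 3))
  expect_equal(to_grayscale(green)[1, 1], 150)

  expect_error(to_grayscale(array(0, dim = c(2, 2, 4))), "channel")
  expect_error(to_grayscale(matrix(300, 2, 2)), "bit depth")
  expect_error(to_grayscale(matrix(-1, 2, 2)), "bit depth")
})

test_that("update_background gives windowed mean/SD with floor, population convention", {
  static <- replicate(28, matrix(100, 8, 8), simplify = FALSE)
  bm <- update_background(static)
  expect_equal(bm$mean, matrix(100, 8, 8))
  expect_equal(bm$sd, matrix(2, 8, 8))  # zero variance hits the floor

  alt <- rep(list(matrix(0, 8, 8), matrix(255, 8, 8)), 14)
  bm <- update_background(alt)
  expect_equal(bm$mean, matrix(127.5, 8, 8))
  expect_equal(bm$sd, matrix(127.5, 8, 8))  # population SD, not n-1

  expect_error(update_background(static[1:27]), "warm-up")
  expect_error(update_background(static, window_size = 28, sd_floor = 0))
})

test_that("mahalanobis_map is |x - mean| / sd and checks geometry", {
  bm <- update_background(replicate(28, matrix(100, 4, 4), simplify = FALSE),
                          sd_floor = 10)
  expect_equal(mahalanobis_map(matrix(100, 4, 4), bm), matrix(0, 4, 4))
  expect_equal(mahalanobis_map(matrix(130, 4, 4), bm)[2, 2], 3.0)
  expect_error(mahalanobis_map(matrix(100, 5, 4), bm), "geometry")

  # elementwise oracle on random input
  set.seed(42)
  win <- random_video(28)
  bm <- update_background(win)
  fr <- random_video(1)[[1]]
  d <- mahalanobis_map(fr, bm)
  for (i in sample(16, 4)) for (j in sample(16, 4))
    expect_equal(d[i, j], abs(fr[i, j] - bm$mean[i, j]) / bm$sd[i, j])
  expect_true(all(d >= 0))
})

test_that("threshold_mask uses a strict inequality and validates k", {
  d <- matrix(0, 10, 10)
  expect_equal(sum(threshold_mask(d, 3)), 0)

  d[1:5] <- 4  # exactly 5 pixels above k = 3
  expect_equal(sum(threshold_mask(d, 3)), 5)

  expect_equal(sum(threshold_mask(matrix(3, 10, 10), 3)), 0)  # d == k -> 0
  expect_error(threshold_mask(d, 0), "k")
  expect_error(threshold_mask(d, -1), "k")
})

test_that("frame_A is the white-pixel fraction", {
  expect_equal(frame_A(matrix(0L, 10, 10)), 0)
  expect_equal(frame_A(matrix(1L, 10, 10)), 1)
  m <- matrix(0L, 576, 704)
  m[seq_len(4055)] <- 1L
  expect_equal(frame_A(m), 4055 / 405504)
  expect_error(frame_A(matrix(0L, 0, 0)), "empty")
})

test_that("compute_A_series: static video scores A = 0, warm-up enforced", {
  static <- replicate(40, matrix(77, 12, 12), simplify = FALSE)
  As <- compute_A_series(static)
  expect_equal(nrow(As), 40 - 28)
  expect_true(all(As$A == 0))
  expect_error(compute_A_series(static[1:28]), "warm-up")
})

test_that("full-inversion video: per-pixel distance is exactly 1, so A = 1 iff k < 1", {
  # alternating full inversions give window mean 127.5 and population SD
  # 127.5 at every pixel: the distance is exactly 1, independent of the
  # inversion amplitude, so the full-change property holds for any k < 1
  # (and provably cannot hold for k >= 1 under this background model)
  set.seed(7)
  base <- matrix(sample(c(40, 215), 144, TRUE), 12, 12)
  inv <- lapply(seq_len(40), function(t) if (t %% 2) base else 255 - base)
  As_low <- compute_A_series(inv, k = 0.5)
  expect_true(all(As_low$A == 1))
  expect_equal(As_low$A, naive_A_series(inv, k = 0.5))  # oracle agreement
  As_high <- compute_A_series(inv, k = 3)
  expect_true(all(As_high$A == 0))
})

test_that("known moving-blob video: A tracks the changed-pixel fraction", {
  vid <- sweep_blob_video(60)
  f_changed <- 2 * 64 / 128^2  # vacated + newly covered square
  As <- compute_A_series(vid)
  expect_true(all(abs(As$A - f_changed) <= 0.005))
})

test_that("sliding-window chain matches the naive per-pixel oracle exactly", {
  set.seed(101)
  for (rep in 1:5) {
    vid <- random_video(60)
    expect_identical(compute_A_series(vid)$A, naive_A_series(vid))
  }
})
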