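test_that("the 2 mm^2 window side follows the slide geometry", {
  expect_identical(window_patches_for_area(2, 0.2525, 512), 11L)
  # area whose side equals exactly one patch
  unit_area <- (0.2525 * 512 / 1000)^2
  expect_identical(window_patches_for_area(unit_area, 0.2525, 512), 1L)
  expect_identical(window_patches_for_area(2, 0.2525, 1024),
                   as.integer(round(sqrt(2) * 1000 / (0.2525 * 1024))))
  expect_error(window_patches_for_area(0, 0.2525, 512), "positive")
})

test_that("detections quantise onto half-open patch cells", {
  grid <- patch_grid(4, 5, patch_size_px = 512)
  expect_true(all(quantize_detections(NULL, grid) == 0))
  one <- tibble::tibble(x = 0, y = 0, score = 1)
  counts <- quantize_detections(one, grid, score_threshold = 0)
  expect_identical(counts[1, 1], 1L)
  expect_identical(sum(counts), 1L)
  # boundary: x = 512 belongs to the second column
  edge <- tibble::tibble(x = 512, y = 0, score = 1)
  expect_identical(quantize_detections(edge, grid)[1, 2], 1L)
})

test_that("quantisation agrees with a brute-force tally and conserves detections", {
  set.seed(17)
  grid <- patch_grid(6, 8, patch_size_px = 512)
  det <- tibble::tibble(x = runif(500, 0, 8 * 512),
                        y = runif(500, 0, 6 * 512),
                        score = runif(500))
  counts <- quantize_detections(det, grid, score_threshold = 0.5)
  keep <- det[det$score >= 0.5, ]
  expect_identical(sum(counts), nrow(keep))
  brute <- matrix(0L, 6, 8)
  for (i in seq_len(nrow(keep))) {
    r <- floor(keep$y[i] / 512) + 1; c <- floor(keep$x[i] / 512) + 1
    brute[r, c] <- brute[r, c] + 1L
  }
  expect_identical(counts, brute)
})

test_that("out-of-bounds detections are dropped with a warning", {
  grid <- patch_grid(2, 2, patch_size_px = 100)
  det <- tibble::tibble(x = c(50, 500), y = c(50, 50), score = 1)
  expect_warning(counts <- quantize_detections(det, grid, 0), "dropped 1")
  expect_identical(sum(counts), 1L)
})

test_that("sliding sums match the double-loop oracle", {
  counts <- matrix(rpois(30 * 40, 1), 30, 40)
  expect_equal(sliding_sum(counts, 1)$values, counts + 0)
  set.seed(23)
  for (i in 1:5) {
    m <- matrix(rpois(30 * 40, 0.7), 30, 40)
    expect_equal(sliding_sum(m, 11, "same")$values, oracle_window_sum(m, 11))
  }
})

test_that("a single detection spreads over exactly window^2 positions", {
  m <- matrix(0, 31, 31); m[16, 16] <- 1
  out <- sliding_sum(m, 11, "same")$values
  expect_identical(sum(out == 1), 121L)
  expect_identical(sum(out), 121)
})

test_that("valid mode equals the interior of same mode", {
  set.seed(29)
  m <- matrix(rpois(25 * 18, 1), 25, 18)
  same <- sliding_sum(m, 5, "same")$values
  valid <- sliding_sum(m, 5, "valid")$values
  expect_equal(valid, same[3:23, 3:16])
  expect_error(sliding_sum(m, 26, "valid"), "larger")
  expect_error(sliding_sum(m, 4, "same"), "odd")
})

test_that("tumour-masked cells contribute zero and come back missing", {
  m <- matrix(1, 9, 9)
  mask <- matrix(TRUE, 9, 9); mask[5, 5] <- FALSE
  out <- sliding_sum(m, 3, "same", mask = mask)$values
  expect_true(is.na(out[5, 5]))
  expect_identical(out[5, 4], 8)   # window covers the masked cell
  expect_identical(out[1, 1], 4)
})

test_that("translation by one patch shifts the count array by one cell", {
  set.seed(41)
  grid <- patch_grid(10, 10, patch_size_px = 100)
  det <- tibble::tibble(x = runif(200, 100, 800), y = runif(200, 100, 800),
                        score = 1)
  a <- quantize_detections(det, grid, 0)
  b <- quantize_detections(dplyr::mutate(det, x = x + 100), grid, 0)
  expect_identical(a[, 2:9], b[, 3:10])
})

test_that("hotspot returns the row-major-first maximum", {
  zero <- sliding_sum(matrix(0, 4, 4), 1)
  expect_equal(hotspot(zero), tibble::tibble(value = 0, row = 1L, col = 1L))
  m <- matrix(0, 4, 4); m[2, 3] <- 7; m[3, 1] <- 7
  hs <- hotspot(sliding_sum(m, 1))
  expect_identical(c(hs$row, hs$col), c(2L, 3L))
  allna <- sliding_sum(matrix(1, 3, 3), 1, mask = matrix(FALSE, 3, 3))
  expect_error(hotspot(allna), "non-missing")
})

test_that("hotspot of the sliding map equals the brute-force window max", {
  set.seed(47)
  for (i in 1:50) {
    m <- matrix(rpois(20 * 22, 0.8), 20, 22)
    expect_identical(hotspot(sliding_sum(m, 5, "same"))$value,
                     max(oracle_window_sum(m, 5)))
  }
})

test_that("Ki-67 index maps carry missing values at unqualified patches", {
  grid <- patch_grid(3, 3, patch_size_px = 1536)
  pp <- tibble::tibble(grid_row = c(0, 0, 1), grid_col = c(0, 1, 2),
                       index_pct = c(10, 20, 30),
                       qualifies = c(TRUE, FALSE, TRUE))
  map <- ki67_index_map(pp, grid)
  expect_identical(map$kind, "ki67_index")
  expect_identical(map$window_patches, 1L)
  expect_equal(map$values[1, 1], 10)
  expect_true(is.na(map$values[1, 2]))
  expect_equal(map$values[2, 3], 30)
  expect_identical(sum(!is.na(map$values)), 2L)
  # all-unqualified map is unrepresentable downstream
  pp$qualifies <- FALSE
  expect_error(build_histogram(ki67_index_map(pp, grid),
                               histogram_config("ki67")), "unrepresentable")
  # duplicate coordinates are rejected
  expect_error(ki67_index_map(dplyr::mutate(pp, grid_col = c(0, 0, 2)), grid),
               "duplicate")
})
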