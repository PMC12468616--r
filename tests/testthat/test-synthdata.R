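test_that("patch generation honours exact cell and positive counts", {
  p <- gen_ihc_patch(ihc_patch_spec(n_cells = 700, positive_fraction = 0.3,
                                    seed = 1))
  expect_identical(nrow(p$truth), 700L)
  expect_identical(sum(p$truth$positive), 210L)
  # pairwise separation respected
  dmin <- min(dist(cbind(p$truth$center_x, p$truth$center_y)))
  expect_gte(dmin, 44 - 1e-9)
})

test_that("patch generation is seed-deterministic and seed-sensitive", {
  a <- gen_ihc_patch(small_patch_spec(n_cells = 25, seed = 3))
  b <- gen_ihc_patch(small_patch_spec(n_cells = 25, seed = 3))
  c <- gen_ihc_patch(small_patch_spec(n_cells = 25, seed = 4))
  expect_identical(a, b)
  expect_false(identical(a$truth, c$truth))
})

test_that("a zero-positive patch contains no DAB-dominant pixels", {
  p <- gen_ihc_patch(small_patch_spec(n_cells = 40, positive_fraction = 0,
                                      seed = 5))
  planes <- separate_stains(p$image)
  expect_lt(max(planes$dab), 0.05)
})

test_that("impossible packings fail loudly", {
  expect_error(gen_ihc_patch(ihc_patch_spec(n_cells = 500,
                                            patch_size_px = 256, seed = 1)),
               "cannot place")
})

test_that("a silent detection field produces no detections", {
  f <- gen_detection_field(hotspot_field_spec(background_rate = 0,
                                              hotspot_rate = 0, seed = 2))
  expect_identical(nrow(f$detections), 0L)
  expect_equal(f$truth$value, 0)
})

test_that("pipeline hotspot value always equals the generator's brute-force truth", {
  for (s in 1:10) {
    f <- gen_detection_field(hotspot_field_spec(seed = s))
    grid <- patch_grid(40, 40, patch_size_px = 512)
    counts <- quantize_detections(f$detections, grid, score_threshold = 0.5)
    expect_identical(sum(counts), nrow(f$detections))  # conservation
    hs <- hotspot(sliding_sum(counts, 11, "same"))
    expect_equal(hs$value, f$truth$value)
  }
})

test_that("generated detection fields round-trip through the readers", {
  f <- gen_detection_field(hotspot_field_spec(seed = 9))
  dir <- withr::local_tempdir()
  for (ext in c("csv", "json")) {
    path <- file.path(dir, paste0("d.", ext))
    write_detections(f$detections, path)
    back <- read_detections(path)
    expect_equal(as.data.frame(back), as.data.frame(f$detections),
                 tolerance = 1e-9)
  }
})

test_that("cohort grade mix stays inside the multinomial band", {
  ch <- gen_cohort(cohort_spec(n_patients = 186, seed = 7))
  counts <- tabulate(ch$cohort$grade, 3)
  expected <- 186 * c(0.59, 0.30, 0.11)
  band <- 1.96 * sqrt(expected * (1 - c(0.59, 0.30, 0.11)))
  expect_true(all(abs(counts - expected) <= band + 1))
  expect_identical(nrow(ch$features), 186L)
  expect_length(setdiff(feature_names_for_test(), names(ch$features)), 0)
})

test_that("a degenerate cohort is perfectly WHO-gradable from its hotspots", {
  ch <- gen_cohort(cohort_spec(n_patients = 80, background_rate = 0,
                               seed = 17))$cohort
  who <- pmax(who_grade_mitotic(ch$hotspot_count),
              who_grade_ki67(ch$ki67_hotspot_pct))
  expect_identical(who, ch$grade)
})

test_that("survival scales order the per-grade KM medians", {
  ch <- gen_cohort(cohort_spec(n_patients = 400, seed = 23))$cohort
  med <- vapply(1:3, function(g)
    median_survival(km_estimate(ch[ch$grade == g, ])), numeric(1))
  expect_true(all(diff(med) < 0))
  # censoring close to its target rate
  expect_lt(abs(mean(ch$event == 0) - 0.3), 0.08)
})
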