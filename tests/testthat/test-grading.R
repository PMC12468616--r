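test_that("WHO mitotic thresholds honour the inclusive 2-20 band", {
  expect_identical(who_grade_mitotic(c(0, 1.9, 2, 10, 20, 20.5, 21)),
                   c(1L, 1L, 2L, 2L, 2L, 3L, 3L))
  expect_error(who_grade_mitotic(-1), "non-negative")
})

test_that("WHO Ki-67 thresholds honour the inclusive 3-20 band", {
  expect_identical(who_grade_ki67(c(0, 2.9, 3, 10, 20, 25, 100)),
                   c(1L, 1L, 2L, 2L, 2L, 3L, 3L))
  expect_error(who_grade_ki67(101), "\\[0, 100\\]")
})

test_that("the highest grade takes precedence when measures disagree", {
  expect_identical(combined_grade(c(1, 3)), 3L)
  expect_identical(combined_grade(2), 2L)
  expect_error(combined_grade(integer()), "no grades")
  set.seed(67)
  for (i in 1:50) {
    g <- sample(1:3, sample(1:6, 1), replace = TRUE)
    expect_identical(combined_grade(g), max(g))
    expect_identical(combined_grade(rev(g)), combined_grade(g)) # commutative
    expect_identical(combined_grade(rep(g, 2)), combined_grade(g)) # idempotent
  }
})

test_that("WHO grades are monotone in their measure", {
  counts <- sort(runif(50, 0, 40))
  expect_true(all(diff(who_grade_mitotic(counts)) >= 0))
  idx <- sort(runif(50, 0, 100))
  expect_true(all(diff(who_grade_ki67(idx)) >= 0))
})

test_that("naive combinations take the max of their component grades", {
  expect_identical(naive_combination_1(1L, 25), 3L)
  expect_identical(naive_combination_1(3L, 1), 3L)
  expect_identical(naive_combination_1(2L, 10), 2L)
  expect_identical(naive_combination_2(1L, 2L), 2L)
  expect_identical(naive_combination_2(3L, 1L), 3L)
  set.seed(71)
  a <- sample(1:3, 100, TRUE); b <- sample(1:3, 100, TRUE)
  expect_identical(naive_combination_2(a, b), pmax(a, b))
})

test_that("patient grade dominates every slide grade", {
  expect_identical(patient_grade(c(1, 2)), 2L)
  expect_identical(patient_grade(1), 1L)
  set.seed(73)
  for (i in 1:20) {
    g <- sample(1:3, sample(1:5, 1), TRUE)
    expect_true(all(patient_grade(g) >= g))
  }
})

test_that("stratified folds balance grades and are reproducible", {
  nine <- tibble::tibble(patient_id = letters[1:9], grade = rep(1:3, each = 3))
  s <- stratified_folds(nine, k = 3, seed = 5)
  per_fold <- table(s$fold, s$grade)
  expect_true(all(per_fold == 1))
  expect_identical(s, stratified_folds(nine, k = 3, seed = 5))

  big <- tibble::tibble(patient_id = sprintf("p%03d", 1:186),
                        grade = rep(1:3, c(109, 56, 21)))
  sb <- stratified_folds(big, k = 3, seed = 11)
  sb12 <- stratified_folds(big, k = 3, seed = 12)
  expect_false(identical(sb$fold[order(sb$patient_id)],
                         sb12$fold[order(sb12$patient_id)]))
  tab <- table(sb$fold, sb$grade)
  for (g in 1:3) expect_lte(diff(range(tab[, g])), 1)
  # held-out roles split each fold about evenly
  roles <- table(sb$fold, sb$heldout_role)
  expect_true(all(abs(roles[, "test"] - roles[, "val"]) <= 3))

  expect_error(stratified_folds(tibble::tibble(patient_id = 1:5,
                                               grade = c(1, 1, 1, 2, 3)),
                                k = 3, seed = 1), "fewer than")
})

test_that("balanced accuracy is the mean per-class recall", {
  expect_equal(balanced_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- rep(1:3, each = 10)
  expect_equal(balanced_accuracy(y, rep(2, 30)), 1 / 3)
  # confusion: class1 8/10, class2 5/10, class3 9/10
  pred <- c(rep(1, 8), 2, 2, rep(2, 5), rep(3, 5), rep(3, 9), 1)
  expect_equal(balanced_accuracy(y, pred), (0.8 + 0.5 + 0.9) / 3)
  expect_error(balanced_accuracy(c(1, 2), c(1, 2, 3)), "equal length")
})
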