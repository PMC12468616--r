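test_that("histogram supports match the two stains", {
  expect_length(build_histogram(rep(0, 5), histogram_config("mitotic"))$frequencies, 49)
  expect_length(build_histogram(rep(0, 5), histogram_config("ki67"))$frequencies, 101)
})

test_that("an all-zero map concentrates mass at bin 0", {
  h <- build_histogram(sliding_sum(matrix(0, 6, 6), 3), histogram_config("mitotic"))
  expect_equal(unname(h$frequencies[1]), 1)
  expect_equal(sum(h$frequencies), 1)
})

test_that("values above the support clip into the top bin", {
  m <- matrix(0, 5, 5); m[3, 3] <- 60
  h <- build_histogram(sliding_sum(m, 1), histogram_config("mitotic"))
  occupied <- which(h$frequencies > 0) - 1  # bins are 0-based
  expect_identical(max(occupied), 48)
})

test_that("histograms equal a brute-force tally and normalise exactly", {
  set.seed(53)
  v <- rpois(400, 6)
  h <- build_histogram(v, histogram_config("mitotic"))
  brute <- vapply(0:48, function(b) sum(pmin(v, 48) == b), numeric(1)) / 400
  expect_equal(unname(h$frequencies), brute)
  expect_lt(abs(sum(h$frequencies) - 1), 1e-12)
  # permutation invariance
  h2 <- build_histogram(sample(v), histogram_config("mitotic"))
  expect_identical(h$frequencies, h2$frequencies)
})

test_that("rounding is half-up and increasing a value never moves mass down", {
  h <- build_histogram(c(0.5, 1.49, 2.5), histogram_config("mitotic"))
  expect_equal(unname(h$frequencies[c(2, 4)]), c(2 / 3, 1 / 3))
  set.seed(59)
  v <- runif(100, 0, 50)
  for (i in 1:10) {
    j <- sample(100, 1)
    v2 <- v; v2[j] <- v2[j] + runif(1, 0, 10)
    cum1 <- cumsum(build_histogram(v, histogram_config("mitotic"))$frequencies)
    cum2 <- cumsum(build_histogram(v2, histogram_config("mitotic"))$frequencies)
    expect_true(all(cum2 <= cum1 + 1e-12))
  }
})

test_that("mismatched map and histogram kinds are rejected", {
  m <- sliding_sum(matrix(0, 4, 4), 3)
  expect_error(build_histogram(m, histogram_config("ki67")), "kind")
})

test_that("dual-stain features concatenate mitotic then ki67", {
  hm <- build_histogram(c(0, 3, 7), histogram_config("mitotic"))
  hk <- build_histogram(c(10, 25), histogram_config("ki67"))
  f <- concat_features(hm, hk)
  expect_length(f, 150)
  expect_equal(unname(f[1:49]), unname(hm$frequencies))
  expect_equal(sum(f[1:49]), 1)
  expect_equal(sum(f[50:150]), 1)
  expect_error(concat_features(hk, hm), "order|mitotic")
  expect_error(concat_features(NULL, hk), "both")
  # degenerate histograms at bin 0 give exactly two unit entries
  f0 <- concat_features(build_histogram(0, histogram_config("mitotic")),
                        build_histogram(0, histogram_config("ki67")))
  expect_identical(sum(f0 == 1), 2L)
})

test_that("majority vote takes the mode with ties toward the higher grade", {
  expect_identical(majority_vote(c(1, 1, 2)), 1L)
  expect_identical(majority_vote(c(2, 3)), 3L)
  expect_error(majority_vote(integer()), "no patch grades")
  set.seed(61)
  for (i in 1:20) {
    g <- sample(1:3, 1000, replace = TRUE)
    counts <- table(factor(g, levels = 1:3))
    expect_identical(majority_vote(g),
                     max(as.integer(names(counts)[counts == max(counts)])))
  }
})

test_that("tidied histograms expose bins and frequencies", {
  h <- build_histogram(c(1, 1, 4), histogram_config("mitotic"))
  d <- tidy(h)
  expect_identical(nrow(d), 49L)
  expect_equal(d$frequency[d$bin == 1], 2 / 3)
})
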