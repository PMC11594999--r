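test_that("uniformity counts circular transitions including the wrap", {
  expect_equal(uniformity(rep(1, 24)), 0)
  expect_equal(uniformity(rep(0, 24)), 0)
  expect_equal(uniformity(rep(c(1, 0), 12)), 24)
  expect_equal(uniformity(c(rep(1, 3), rep(0, 21))), 2)
  expect_equal(uniformity(c(0, 1, 1, 0, 0, 1, 0, 0)), 4)
  expect_error(uniformity(c(0, 2, 1)), "0/1")
})

test_that("riu2 coding maps uniform patterns to popcount, rest to P+1", {
  expect_equal(riu2_code(rep(1, 24)), 24)
  expect_equal(riu2_code(rep(0, 24)), 0)
  expect_equal(riu2_code(c(rep(1, 7), rep(0, 17))), 7)
  expect_equal(riu2_code(c(0, 1, 1, 0, 0, 1, rep(0, 18))), 25)  # U = 4
  expect_equal(n_riu2_codes(24), 26L)
})

test_that("the riu2 alphabet has exactly P+2 attainable codes", {
  # exhaustive enumeration for small P
  for (P in c(4L, 6L, 8L, 10L)) {
    codes <- integer(0)
    for (v in 0:(2^P - 1)) {
      bits <- as.integer(intToBits(v))[1:P]
      codes <- union(codes, riu2_code(bits))
    }
    expect_setequal(codes, 0:(P + 1))
    expect_length(codes, P + 2L)
  }
  # constructive check for the study configuration P = 24:
  # the runs 1^k 0^(24-k) realize codes 0..24, one alternating pattern gives 25
  realized <- vapply(0:24, function(k)
    riu2_code(c(rep(1, k), rep(0, 24 - k))), integer(1))
  expect_equal(realized, 0:24)
  expect_equal(riu2_code(rep(c(1, 0), 12)), 25)
})

test_that("circular sampling interpolates bilinearly and hits pixel centers", {
  m <- matrix(7.5, 9, 9)
  expect_equal(sample_neighbors(m, 4, 4, lbp_params(P = 24, R = 3)),
               rep(7.5, 24))
  # P=4, R=1: samples fall on the 4-neighborhood exactly
  m2 <- matrix(runif(25), 5, 5)
  s <- sample_neighbors(m2, 2, 2, lbp_params(P = 4, R = 1))
  expect_identical(s, c(m2[3, 4], m2[2, 3], m2[3, 2], m2[4, 3]))
  # bilinear interpolation of an affine ramp is exact everywhere
  ramp <- outer(0:9, 0:9, function(y, x) 3 + 2 * x + 5 * y)
  p8 <- lbp_params(P = 8, R = 1)
  s <- sample_neighbors(ramp, 4, 4, p8)
  ang <- 2 * pi * (0:7) / 8
  expect_equal(s, 3 + 2 * (4 + cos(ang)) + 5 * (4 - sin(ang)),
               tolerance = 1e-12)
  expect_error(sample_neighbors(ramp, 0, 0, p8), "exits")
})

test_that("lbp_transform matches the brute-force oracle pixel-exactly", {
  for (cfg in list(c(4, 1), c(8, 1))) {
    for (seed in 1:5) {
      m <- random_roi(16, seed = seed * 10 + cfg[1])
      got <- lbp_transform(m, lbp_params(P = cfg[1], R = cfg[2]))
      expect_identical(got$codes, oracle_lbp_codes(m, cfg[1], cfg[2]))
    }
  }
  # and for the study configuration on a smaller image
  m <- random_roi(14, seed = 99)
  got <- lbp_transform(m, lbp_params(P = 24, R = 3))
  expect_identical(got$codes, oracle_lbp_codes(m, 24, 3))
})

test_that("degenerate neighborhoods produce the forced codes", {
  p <- lbp_params(P = 8, R = 1)
  m <- matrix(5, 7, 7)
  cm <- lbp_transform(m, p)
  expect_true(all(cm$codes == 8L))          # s(0) = 1 for all neighbors
  m[4, 4] <- 6                              # strict local maximum
  cm <- lbp_transform(m, p)
  expect_equal(cm$codes[3, 3], 0L)
  expect_error(lbp_transform(matrix(1, 6, 6), lbp_params(P = 24, R = 3)),
               "too small")
})

test_that("code matrix geometry and histogram conservation hold", {
  set.seed(31)
  m <- matrix(runif(30 * 22, 100, 400), 30, 22)
  p <- lbp_params(P = 24, R = 3)
  cm <- lbp_transform(m, p)
  expect_equal(dim(cm$codes), c(30 - 6, 22 - 6))
  expect_true(all(cm$codes >= 0 & cm$codes <= 25))
  h <- lbp_histogram(cm)
  expect_length(h$counts, 26)
  expect_equal(sum(h$counts), length(cm$codes))
  expect_equal(sum(h$normalized), 1)
  s <- lbp_stats(cm)
  expect_gte(s$lbp_mean, 0); expect_lte(s$lbp_mean, 25)
  expect_lte(s$lbp_entropy, log(26))
  # constant ROI: all mass at code P, zero entropy
  cm0 <- lbp_transform(matrix(1, 10, 10), p)
  expect_equal(unname(lbp_histogram(cm0)$normalized[25]), 1) # code 24 bin
  expect_equal(lbp_stats(cm0)$lbp_entropy, 0)
})

test_that("riu2 histograms are invariant under 90-degree rotation", {
  p24 <- lbp_params(P = 24, R = 3)
  p8 <- lbp_params(P = 8, R = 1)
  for (seed in 1:5) {
    m <- random_roi(18, seed = 40 + seed)
    for (p in list(p8, p24)) {
      h0 <- lbp_histogram(lbp_transform(m, p))$counts
      h1 <- lbp_histogram(lbp_transform(rotate90(m), p))$counts
      expect_identical(h0, h1)
    }
  }
})

test_that("codes are invariant under monotone intensity transforms", {
  # arbitrary strictly increasing transforms: exact for on-grid sampling
  p4 <- lbp_params(P = 4, R = 1)
  for (seed in 1:5) {
    m <- random_roi(16, seed = 50 + seed)
    c0 <- lbp_transform(m, p4)$codes
    expect_identical(lbp_transform(exp(m / 100), p4)$codes, c0)
    expect_identical(lbp_transform(m^3, p4)$codes, c0)
    expect_identical(lbp_transform(log(m), p4)$codes, c0)
  }
  # affine transforms commute with bilinear interpolation: exact at P=24, R=3
  p24 <- lbp_params(P = 24, R = 3)
  for (seed in 1:5) {
    m <- random_roi(16, seed = 60 + seed)
    c0 <- lbp_transform(m, p24)$codes
    expect_identical(lbp_transform(2.5 * m + 40, p24)$codes, c0)
  }
})

test_that("lbp parameter validation rejects bad configurations", {
  expect_error(lbp_params(P = 3), "P must")
  expect_error(lbp_params(R = 0), "R must")
  expect_error(lbp_transform(matrix(c(1, NaN, 3, 4), 2, 2), lbp_params(4, 1)),
               "NaN")
})
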