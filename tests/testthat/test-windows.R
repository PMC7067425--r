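test_that("1-D profiles match their closed forms under the periodic convention", {
  expect_equal(makeWindow1D("hann", 4), c(0, 0.5, 1, 0.5))
  expect_equal(makeWindow1D("triangular", 6)[4], 1)  # w(3) at I = 6
  expect_equal(makeWindow1D("average", 8), rep(0.5, 8))
  # tapering profiles vanish at index 0 (periodic sample)
  for (kind in c("hann", "bartlett_hann", "triangular"))
    for (I in c(4, 8, 128))
      expect_equal(makeWindow1D(kind, I)[1], 0,
                   info = paste(kind, I), tolerance = 1e-12)
  # closed form of bartlett-hann at a non-trivial sample
  I <- 8; i <- 3
  expect_equal(makeWindow1D("bartlett_hann", I)[i + 1],
               0.62 - 0.48 * abs(i / I - 0.5) - 0.38 * cos(2 * pi * i / I))
})

test_that("invalid 1-D window requests are rejected with the half-stride reason", {
  expect_error(makeWindow1D("hann", 5), "half")
  expect_error(makeWindow1D("hann", 1), "half")
  expect_error(makeWindow1D("pyramidal", 8))  # not separable
  expect_error(makeBorderWindow("pyramidal", "up", 8, 8))
  expect_error(makeCornerWindow("pyramidal", "up_left", 8, 8))
})

test_that("half-stride shifted copies of every separable profile sum to 1", {
  for (kind in c("average", "hann", "bartlett_hann", "triangular"))
    for (I in c(4, 6, 16, 128)) {
      w <- makeWindow1D(kind, I)
      h <- I / 2
      expect_lt(max(abs(w[1:h] + w[(h + 1):I] - 1)), 1e-9)
    }
  # the printed symmetric variants do not
  for (kind in c("hann", "bartlett_hann")) {
    w <- makeWindow1D(kind, 16, strictPaper = TRUE)
    expect_gt(max(abs(w[1:8] + w[9:16] - 1)), 1e-3)
  }
})

test_that("separable 2-D windows are exact outer products and symmetric", {
  for (kind in c("average", "hann", "bartlett_hann", "triangular")) {
    W <- windowWeights(makeWindow2D(kind, 8, 12))
    expect_identical(W, outer(makeWindow1D(kind, 8), makeWindow1D(kind, 12)))
    expect_true(all(W >= 0))
    expect_lte(max(W), 1)
    # flip symmetry away from the periodic sample at index 0
    Ws <- windowWeights(makeWindow2D(kind, 8, 8))[2:8, 2:8]
    expect_equal(Ws, Ws[7:1, ], tolerance = 1e-12)
    expect_equal(Ws, Ws[, 7:1], tolerance = 1e-12)
  }
  expect_equal(windowWeights(makeWindow2D("hann", 4, 4))[3, 3], 1)
  expect_true(all(windowWeights(makeWindow2D("average", 6, 10)) == 0.25))
})

test_that("pyramidal window has a zero border ring, mean exactly 1, and is not separable", {
  W <- windowWeights(makeWindow2D("pyramidal", 8, 8))
  expect_true(all(W[1, ] == 0) && all(W[8, ] == 0) &&
              all(W[, 1] == 0) && all(W[, 8] == 0))
  for (d in list(c(8, 8), c(12, 16), c(128, 128))) {
    W <- windowWeights(makeWindow2D("pyramidal", d[1], d[2]))
    expect_equal(mean(W), 1, tolerance = 1e-9)
    expect_true(all(W >= 0))
  }
  # rank > 1: no outer product of two vectors can reproduce it
  sv <- svd(windowWeights(makeWindow2D("pyramidal", 16, 16)))$d
  expect_gt(sv[2] / sv[1], 1e-3)
  # alpha is the stated mean normalizer and De vanishes only on the ring
  p <- pyramidalParts(8, 8)
  inner <- p$edgeDistance[2:7, 2:7]
  expect_true(all(inner > 0))
  expect_equal(p$alpha,
               64 / sum(p$edgeDistance /
                        (p$centerDistance + p$edgeDistance), na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("border windows flatten the half facing the image border", {
  up <- windowWeights(makeBorderWindow("hann", "up", 4, 4))
  w <- makeWindow1D("hann", 4)
  # W(i, j) = w(i) on the flat rows j < J/2, w(i) w(j) below
  expect_equal(up[1, ], w)
  expect_equal(up[2, ], w)
  expect_equal(up[3, ], w * w[3])
  expect_equal(up[1, 3], 1)        # W(2, 0) = w(2) = 1
  expect_true(all(up[, 1] == 0))   # W(0, j) = 0: w(0) multiplies all rows
  left <- windowWeights(makeBorderWindow("hann", "left", 4, 4))
  expect_identical(left, t(up))
  down <- windowWeights(makeBorderWindow("hann", "down", 4, 4))
  expect_equal(down[3, ], w)
  expect_equal(down[4, ], w)
})

test_that("corner windows carry a constant-1 quadrant and tapered remainder", {
  w <- makeWindow1D("hann", 8)
  ul <- windowWeights(makeCornerWindow("hann", "up_left", 8, 8))
  expect_true(all(ul[1:4, 1:4] == 1))       # flat quadrant at the corner
  expect_equal(ul[8, 8], w[8] * w[8])       # W(7,7) = w(7) w(7)
  expect_equal(ul[1, 8], w[8])              # border row: W(7,0) = w(7)
  ur <- windowWeights(makeCornerWindow("hann", "up_right", 8, 8))
  expect_true(all(ur[1:4, 5:8] == 1))
  dr <- windowWeights(makeCornerWindow("hann", "down_right", 8, 8))
  expect_true(all(dr[5:8, 5:8] == 1))
  # mirror structure: the tapered quadrant of down_right matches up_left's,
  # with the taper running in the opposite direction
  expect_equal(dr[1:4, 1:4], outer(w[1:4], w[1:4]))
  expect_equal(ul[5:8, 5:8], outer(w[5:8], w[5:8]))
})

test_that("tiled windows form a partition of unity for every separable kind", {
  geoms <- list(c(256, 256, 128), c(192, 320, 64), c(128, 128, 128),
                c(96, 160, 32))
  for (kind in c("average", "hann", "bartlett_hann", "triangular"))
    for (g in geoms) {
      f <- assembleWindowField(kind, g[1], g[2], g[3])
      expect_lt(max(abs(f - 1)), 1e-6,
                label = paste(kind, paste(g, collapse = "x")))
    }
  # the paper-printed symmetric forms break the property
  fs <- assembleWindowField("hann", 256, 256, 128, strictPaper = TRUE)
  expect_gt(max(abs(fs - 1)), 1e-3)
  # the pyramidal field is non-constant, hence the extra normalization step
  fp <- assembleWindowField("pyramidal", 256, 256, 128)
  expect_gt(max(fp) / min(fp[fp > 0]), 1)
})

test_that("windows validate their contents", {
  expect_error(new("Window2D", weights = matrix(-1, 2, 2), kind = "hann",
                   role = "interior"), "non-negative")
  expect_error(makeWindow2D("hann", 7, 8), "even")
})
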