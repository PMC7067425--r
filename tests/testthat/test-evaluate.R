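test_that("ssim matches a brute-force sliding-window oracle", {
  set.seed(31)
  for (trial in 1:4) {
    x <- matrix(runif(24 * 24), 24, 24)
    y <- pmin(pmax(x + rnorm(24 * 24, sd = 0.2), 0), 1)
    expect_equal(ssim(x, y), ssimOracle(x, y), tolerance = 1e-10)
  }
  x <- matrix(runif(20 * 20), 20, 20)
  expect_equal(ssim(x, x), 1)
  # constant (zero variance) images are stabilized, not divided by zero
  expect_equal(ssim(matrix(0.4, 10, 10), matrix(0.4, 10, 10)), 1)
  # anticorrelated structure scores negative
  chk <- matrix(rep_len(c(0, 1), 64 * 64), 64, 64)
  expect_lt(ssim(chk, 1 - chk), 0)
})

test_that("class-wise ssim is the arithmetic mean over channels", {
  set.seed(32)
  v1 <- array(runif(32 * 32 * 3), c(32, 32, 3))
  v2 <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p1 <- ProbabilityMap(v1); p2 <- ProbabilityMap(v2)
  per <- vapply(1:3, function(ch) ssim(v1[, , ch], v2[, , ch]), numeric(1))
  expect_equal(ssimClasswise(p1, p2), mean(per))
  expect_equal(ssimClasswise(p1, p1), 1)
})

test_that("the edge-vicinity mask matches a per-pixel oracle and partitions the image", {
  for (patch in c(32, 64, 128)) {
    m <- makeGridMask(256, 256, patch, 5)
    expect_equal(m, gridMaskOracle(256, 256, patch, 5),
                 ignore_attr = TRUE)
  }
  m <- makeGridMask(1024, 1024, 128, 5)
  # 7 interior lines per axis, 10-pixel band each, minus the intersections
  expect_equal(sum(m), 2 * 7 * 10 * 1024 - (7 * 10)^2)
  expect_false(any(makeGridMask(256, 256, 128, 0)))
  expect_false(any(makeGridMask(128, 128, 128, 5)))  # no interior lines
  expect_error(makeGridMask(256, 256, 128, 64))
})

test_that("micro and macro Dice match an exhaustive confusion-matrix oracle", {
  set.seed(33)
  for (trial in 1:200) {
    pred <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
    truth <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
    d <- diceScores(pred, truth, nClasses = 3L)
    o <- diceOracle(as.vector(pred), as.vector(truth), 3)
    expect_equal(d$dice_micro, o$micro, tolerance = 1e-12)
    expect_equal(d$dice_macro, o$macro, tolerance = 1e-12)
  }
})

test_that("Dice handles perfect, disjoint and absent-class cases", {
  truth <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  expect_equal(diceScores(truth, truth, nClasses = 2L)$dice_micro, 1)
  expect_equal(diceScores(truth, truth, nClasses = 2L)$dice_macro, 1)
  # disjoint single-class masks
  pred <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  d <- diceScores(pred, truth, nClasses = 2L)
  expect_equal(d$dice_micro, 0)
  expect_equal(d$dice_macro, 0)
  # class 2 absent from both: contributes 1 by default, dropped with "skip"
  dAbs <- diceScores(truth, truth, nClasses = 3L)
  expect_equal(dAbs$dice_macro, 1)
  pred2 <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  dOne <- diceScores(pred2, truth, nClasses = 3L, absentClass = "one")
  dSkip <- diceScores(pred2, truth, nClasses = 3L, absentClass = "skip")
  perClass <- c(2 * 2 / (2 * 2 + 1), 2 * 1 / (2 * 1 + 1))
  expect_equal(dOne$dice_macro, mean(c(perClass, 1)))
  expect_equal(dSkip$dice_macro, mean(perClass))
  # split by mask region
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  dm <- diceScores(pred, truth, mask, nClasses = 2L)
  expect_setequal(dm$region, c("centre", "edge_vicinity"))
})

test_that("baseline adjustment subtracts the no-overlap score per image/metric/region", {
  tab <- data.frame(
    image_id = rep(1:2, each = 2),
    method = rep(c("no_overlap", "hann"), 2),
    metric = "ssim", region = "all",
    raw = c(0.93, 0.95, 0.90, 0.91))
  adj <- adjustedScores(tab)
  expect_equal(adj$adjusted[adj$method == "no_overlap"], c(0, 0))
  expect_equal(adj$adjusted[adj$method == "hann" & adj$image_id == 1],
               0.02)
  # a monotone shift: per-image ordering of adjusted equals ordering of raw
  sub <- adj[adj$image_id == 1, ]
  expect_equal(order(sub$adjusted), order(sub$raw))
  expect_error(adjustedScores(tab[tab$method != "no_overlap", ]),
               "baseline")
})

test_that("the paired t-test reports df = n - 1 and survives degenerate input", {
  set.seed(34)
  r <- pairedTTest(rnorm(14) + 0.5)
  expect_equal(r$df, 13)
  expect_false(r$degenerate)
  # textbook oracle on a tiny fixed sample
  d <- c(1, 1, 1, 2)
  r2 <- pairedTTest(d)
  tOracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(r2$statistic, tOracle, tolerance = 1e-12)
  expect_equal(r2$p.value, 2 * pt(-abs(tOracle), df = 3), tolerance = 1e-12)
  # zero variance
  z <- pairedTTest(rep(0, 5))
  expect_true(z$degenerate)
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
  c5 <- pairedTTest(rep(0.3, 5))
  expect_true(c5$degenerate)
  expect_equal(c5$p.value, 0)
  expect_error(pairedTTest(1), "at least two")
})

test_that("the exact sign test is the two-sided binomial tail with ties dropped", {
  r <- exactSignTest(rep(1, 14))
  expect_equal(r$positive, 14)
  expect_equal(r$p.value, 2 * 0.5^14, tolerance = 1e-12)
  expect_equal(exactSignTest(c(rep(1, 7), rep(-1, 7)))$p.value, 1)
  rt <- exactSignTest(c(rep(1, 5), 0, 0))
  expect_equal(rt$ties, 2)
  expect_equal(rt$p.value, 2 * 0.5^5, tolerance = 1e-12)
  expect_error(exactSignTest(c(0, 0, 0)), "ties")
})

test_that("a small zero-noise benchmark yields identical methods and zero adjustments", {
  bm <- runBenchmark(nSeeds = 2,
                     scene = SceneSpec(height = 256, width = 256,
                                       nBlobs = 8, seed = 50),
                     profile = ArtefactProfile(baseNoise = 0,
                                               edgeNoise = 0),
                     methods = c("no_overlap", "hann", "average"),
                     patch = 128, maskHalfWidth = 5)
  expect_true(all(abs(bm$scores$adjusted) < 1e-9))
  expect_setequal(unique(bm$scores$method),
                  c("no_overlap", "hann", "average"))
  expect_setequal(unique(bm$scores$metric),
                  c("ssim", "dice_micro", "dice_macro"))
  # degenerate pairwise tests are reported, not NaN
  expect_true(all(bm$tests$t_p[!is.na(bm$tests$t_p)] >= 0))
})

test_that("pairwise test matrices are consistent with direct per-pair tests", {
  set.seed(35)
  scores <- expand.grid(image_id = 1:6,
                        method = c("no_overlap", "hann", "average"),
                        metric = "ssim", region = "all",
                        stringsAsFactors = FALSE)
  scores$raw <- runif(nrow(scores))
  scores <- adjustedScores(scores)
  tests <- pairwiseTests(scores)
  wide <- matrix(scores$raw[order(scores$method, scores$image_id)], ncol = 3)
  colnames(wide) <- sort(c("no_overlap", "hann", "average"))
  d <- wide[, "hann"] - wide[, "average"]
  expect_equal(tests$t_p["hann", "average"], pairedTTest(d)$p.value)
  expect_equal(tests$sign_p["hann", "average"], exactSignTest(d)$p.value)
  expect_equal(tests$mean_diff["hann", "average"], mean(d))
  expect_equal(tests$mean_diff["average", "hann"], -mean(d))
})
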