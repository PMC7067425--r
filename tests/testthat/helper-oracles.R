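# Independent brute-force oracles used to cross-check the implementation.
# Each is deliberately written as plain per-element loops, sharing no code
# with the package internals.

# SSIM by direct evaluation of every fully-interior sliding window.
ssimOracle <- function(x, y, dataRange = 1, win = 7) {
  H <- nrow(x); W <- ncol(x)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  vals <- c()
  for (r in 1:(H - win + 1)) for (cc in 1:(W - win + 1)) {
    px <- x[r:(r + win - 1), cc:(cc + win - 1)]
    py <- y[r:(r + win - 1), cc:(cc + win - 1)]
    ux <- mean(px); uy <- mean(py)
    vx <- stats::var(as.vector(px)); vy <- stats::var(as.vector(py))
    vxy <- stats::cov(as.vector(px), as.vector(py))
    vals <- c(vals, ((2 * ux * uy + C1) * (2 * vxy + C2)) /
                    ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# Micro/macro Dice from an explicitly tallied confusion matrix.
diceOracle <- function(pred, truth, nClasses, absentOne = TRUE) {
  conf <- matrix(0, nClasses, nClasses)
  for (k in seq_along(pred))
    conf[truth[k] + 1, pred[k] + 1] <- conf[truth[k] + 1, pred[k] + 1] + 1
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  per <- numeric(0)
  for (c0 in 1:nClasses) {
    denom <- 2 * tp[c0] + fp[c0] + fn[c0]
    if (denom == 0) {
      if (absentOne) per <- c(per, 1)
    } else per <- c(per, 2 * tp[c0] / denom)
  }
  list(micro = 2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn)),
       macro = mean(per))
}

# Patch origins by naive stepping, independent of planGrid's arithmetic.
originsOracle <- function(H, W, patch) {
  s <- patch / 2
  out <- NULL
  r <- 0
  while (r + patch <= H) {
    cc <- 0
    while (cc + patch <= W) {
      out <- rbind(out, c(r, cc))
      cc <- cc + s
    }
    r <- r + s
  }
  out
}

# Edge-vicinity mask by per-pixel distance check against every grid line.
gridMaskOracle <- function(H, W, patch, hw) {
  m <- matrix(FALSE, H, W)
  lines <- seq(patch, max(H, W) - 1, by = patch)
  for (r in 1:H) for (cc in 1:W) {
    p <- r - 1; q <- cc - 1
    near <- function(pos, n) any(lines < n & pos >= lines - hw &
                                 pos <= lines + hw - 1)
    if (hw > 0 && (near(p, H) || near(q, W))) m[r, cc] <- TRUE
  }
  m
}

# A predictor that slices patches out of fixed global maps (one per
# channel): patchwise-consistent by construction.
globalMapPredictor <- function(maps) {
  if (is.matrix(maps)) maps <- list(maps)
  function(patch, origin) {
    I <- nrow(if (is.matrix(patch)) patch else patch[, , 1])
    r <- origin[1]; cc <- origin[2]
    out <- array(0, c(I, I, length(maps)))
    for (ch in seq_along(maps))
      out[, , ch] <- maps[[ch]][(r + 1):(r + I), (cc + 1):(cc + I)]
    out
  }
}
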