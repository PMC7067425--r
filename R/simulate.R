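# Synthetic benchmark fixtures: a three-class nuclei-like scene and a
# predictor whose error is localized at patch borders. Together they let the
# whole reconstruction/evaluation pipeline run without any dataset or
# trained network.

# Evaluate each random draw under its own seed and restore the caller's RNG
# state afterwards, so predictors are pure functions of (seed, origin).
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-origin substream seed, kept within 32-bit integer range.
.originSeed <- function(seed, origin) {
  as.integer((as.double(seed) * 2654435761 + as.double(origin[1]) * 7919 +
              as.double(origin[2]) * 104729) %% 2147483647)
}

#' Generate a synthetic three-class scene
#'
#' Places random non-overlapping ellipses (random semi-axes within
#' `radiusRange`, random orientation) on a background and classifies every
#' pixel as `background`, `object` (inside the ellipse shrunk by
#' `edgeBand`), or `object_edge` (the remaining ring of width `edgeBand`
#' just inside the ellipse boundary). The rendered image assigns each class
#' a distinct intensity (0.15 / 0.75 / 0.45) plus mild i.i.d. Gaussian noise
#' (sd 0.03), clipped to `[0, 1]`.
#'
#' Placement is rejection-sampled: each blob gets a bounded number of
#' attempts to avoid overlapping previously placed blobs, and impossible
#' packings are rejected with an error.
#'
#' @param spec a [SceneSpec-class].
#' @return List with `image` (numeric matrix), `truth` (one-hot 3-class
#'   [ProbabilityMap-class]), `labels` (integer matrix, 0 = background,
#'   1 = object, 2 = object_edge) and `blobs` (`data.frame` of the placed
#'   ellipse parameters: centre `row`/`col` (0-based), semi-axes `a`/`b`,
#'   orientation `theta`).
#' @examples
#' sc <- generateScene(SceneSpec(height = 128, width = 128, nBlobs = 4,
#'                               seed = 7))
#' table(sc$labels)
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  H <- spec@height; W <- spec@width
  .withSeed(spec@seed, {
    labels <- matrix(0L, H, W)
    rr <- row(labels) - 1; cc <- col(labels) - 1
    placed <- matrix(numeric(0), 0, 3)  # row, col, radius (max semi-axis)
    blobs <- list()
    maxAttempts <- 200L
    for (b in seq_len(spec@nBlobs)) {
      ok <- FALSE
      for (att in seq_len(maxAttempts)) {
        a <- stats::runif(1, spec@radiusRange[1], spec@radiusRange[2])
        bx <- stats::runif(1, spec@radiusRange[1], spec@radiusRange[2])
        rmax <- max(a, bx)
        cy <- stats::runif(1, rmax + 1, H - rmax - 2)
        cx <- stats::runif(1, rmax + 1, W - rmax - 2)
        theta <- stats::runif(1, 0, pi)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >
                placed[, 3] + rmax + spec@edgeBand + 1)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place blob ", b, " after ", maxAttempts,
             " attempts; reduce nBlobs or radiusRange", call. = FALSE)
      placed <- rbind(placed, c(cy, cx, rmax))
      blobs[[b]] <- data.frame(row = cy, col = cx, a = a, b = bx,
                               theta = theta)
      dy <- rr - cy; dx <- cc - cx
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      inside <- (u / a)^2 + (v / bx)^2 <= 1
      ai <- max(a - spec@edgeBand, 0.5)
      bi <- max(bx - spec@edgeBand, 0.5)
      core <- (u / ai)^2 + (v / bi)^2 <= 1
      labels[inside & !core] <- 2L
      labels[core] <- 1L
    }
    intens <- c(0.15, 0.75, 0.45)[labels + 1L]
    image <- matrix(pmin(pmax(intens + stats::rnorm(H * W, sd = 0.03), 0), 1),
                    H, W)
    onehot <- array(0, c(H, W, 3L))
    for (k in 0:2) onehot[, , k + 1L] <- (labels == k) * 1
    list(image = image,
         truth = ProbabilityMap(onehot),
         labels = labels,
         blobs = if (length(blobs)) do.call(rbind, blobs)
                 else data.frame(row = numeric(0), col = numeric(0),
                                 a = numeric(0), b = numeric(0),
                                 theta = numeric(0)))
  })
}

#' A simulated predictor with border-localized error
#'
#' Builds a predictor (`function(patch, origin)`) that looks up the
#' ground-truth one-hot classes of the patch at the given origin, optionally
#' softens them toward the uniform distribution, adds zero-mean Gaussian
#' noise whose standard deviation follows the artefact profile — largest on
#' the patch border ring, smallest at the patch centre — and renormalizes
#' each pixel back onto the probability simplex (negative values clipped to
#' zero). Noise is drawn independently per patch origin, so overlapping
#' patches disagree near their borders: exactly the regime in which border
#' tapering helps and plain averaging accumulates artefacts.
#'
#' The returned predictor is deterministic in (profile seed, origin) and
#' leaves the caller's RNG state untouched.
#'
#' @param truth the ground-truth [ProbabilityMap-class] (one-hot).
#' @param profile an [ArtefactProfile-class].
#' @return A predictor closure suitable for the `predictor` argument of the
#'   reconstruction functions.
#' @export
noisyEdgePredictor <- function(truth, profile) {
  stopifnot(is(truth, "ProbabilityMap"), is(profile, "ArtefactProfile"))
  tv <- probValues(truth)
  C <- dim(tv)[3]
  sigmaCache <- new.env(parent = emptyenv())
  sigmaFor <- function(I) {
    key <- as.character(I)
    if (is.null(sigmaCache[[key]])) {
      i <- 0:(I - 1L)
      de <- pmin(i, I - 1L - i)
      De <- outer(de, de, pmin)                # Chebyshev distance to border
      dnorm <- De / max(De)                    # 0 on border ring, 1 centre
      sigmaCache[[key]] <-
        profile@baseNoise +
        profile@edgeNoise * matrix(vapply(dnorm, profile@profile,
                                          numeric(1)), I, I)
    }
    sigmaCache[[key]]
  }
  function(patch, origin) {
    I <- dim(.asChannels(patch))[1]
    r <- origin[1]; cc <- origin[2]
    if (r + I > dim(tv)[1] || cc + I > dim(tv)[2])
      stop("patch at origin (", r, ", ", cc,
           ") falls outside the ground truth", call. = FALSE)
    gt <- tv[(r + 1L):(r + I), (cc + 1L):(cc + I), , drop = FALSE]
    out <- (1 - profile@softness) * gt + profile@softness / C
    if (profile@baseNoise > 0 || profile@edgeNoise > 0) {
      sigma <- sigmaFor(I)
      noise <- .withSeed(.originSeed(profile@seed, origin), {
        array(stats::rnorm(I * I * C), c(I, I, C)) *
          array(rep(sigma, C), c(I, I, C))
      })
      out <- pmax(out + noise, 0)
      tot <- apply(out, c(1, 2), sum)
      flat <- tot <= 0
      if (any(flat)) for (ch in seq_len(C)) {
        pl <- out[, , ch]; pl[flat] <- 1 / C; out[, , ch] <- pl
      }
      tot[flat] <- 1
      for (ch in seq_len(C)) out[, , ch] <- out[, , ch] / tot
    }
    out
  }
}
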