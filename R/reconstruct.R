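# Overlap-add reconstruction. A predictor is a callable contract
# f(patch, origin) -> patch-sized array of per-class scores; the windows are
# applied to the predictor OUTPUT only (input patches are fed unweighted).
# Accumulation is into a double-precision buffer, so the result is
# independent of patch order.

.asChannels <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

.callPredictor <- function(predictor, patch, origin, patchSize) {
  out <- if (length(formals(predictor)) >= 2L) predictor(patch, origin)
         else predictor(patch)
  out <- .asChannels(out)
  d <- dim(out)
  if (length(d) != 3L || d[1] != patchSize || d[2] != patchSize)
    stop("predictor output has shape ", paste(d, collapse = " x "),
         " instead of ", patchSize, " x ", patchSize,
         " at origin (", origin[1], ", ", origin[2], ")", call. = FALSE)
  if (any(!is.finite(out)))
    stop("predictor output contains non-finite values at origin (",
         origin[1], ", ", origin[2], ")", call. = FALSE)
  out
}

#' The identity predictor
#'
#' Returns its input patch unchanged (a single-channel probability patch for
#' matrix input). Useful for validating that a reconstruction method is
#' weight-preserving: with a predictor whose patches agree with one global
#' map, every method must return that map.
#'
#' @param patch the input patch.
#' @param origin ignored.
#' @return The patch as a `patch x patch x C` array.
#' @export
identityPredictor <- function(patch, origin = NULL) .asChannels(patch)

# Shared driver for the overlapping (windowed) reconstructions.
.reconstructOverlap <- function(image, predictor, patch, windows,
                                classNames = NULL) {
  image <- .asChannels(image)
  padded <- padToGrid(image, patch)
  img <- padded$image
  grid <- planGrid(dim(img)[1], dim(img)[2], patch)
  I <- grid@patch
  out <- NULL
  calls <- 0L
  for (k in seq_len(nPatches(grid))) {
    r <- grid@origins[k, 1L]; cc <- grid@origins[k, 2L]
    p <- img[(r + 1L):(r + I), (cc + 1L):(cc + I), , drop = FALSE]
    pred <- .callPredictor(predictor, p, c(r, cc), I)
    calls <- calls + 1L
    if (is.null(out)) out <- array(0, c(dim(img)[1:2], dim(pred)[3]))
    w <- windows[[paste(grid@rowRoles[k], grid@colRoles[k], sep = ".")]]
    for (ch in seq_len(dim(pred)[3]))
      out[(r + 1L):(r + I), (cc + 1L):(cc + I), ch] <-
        out[(r + 1L):(r + I), (cc + 1L):(cc + I), ch] + w * pred[, , ch]
  }
  pm <- ProbabilityMap(out, classNames)
  pm <- cropToRecord(pm, padded$crop)
  attr(pm, "predictorCalls") <- calls
  attr(pm, "grid") <- grid
  pm
}

#' Windowed overlap-add reconstruction
#'
#' The full pipeline: extract overlapping patches at half-patch stride, run
#' the predictor on each, multiply each prediction by the window appropriate
#' to its absolute location (interior, border or corner variant), and sum
#' the weighted patches at their absolute positions. Because the tiled
#' windows of the separable kinds sum to exactly 1 at every pixel, no
#' post-hoc division is needed and a patchwise-consistent predictor is
#' reproduced exactly.
#'
#' Images whose extent is not a multiple of the patch size are
#' reflect-padded internally and cropped back afterwards.
#'
#' @param image numeric matrix or `H x W x C` array.
#' @param predictor `function(patch, origin)` (or `function(patch)`)
#'   returning a `patch x patch x C` array of class scores; see
#'   [identityPredictor()] and [noisyEdgePredictor()].
#' @param kind a separable window kind (`"hann"`, `"bartlett_hann"`,
#'   `"triangular"`, `"average"`); the pyramidal window has its own path,
#'   [reconstructPyramidal()].
#' @param patch patch side in pixels (even); 128 is typical for
#'   1024 x 1024 pixel-classification output.
#' @param classNames optional channel names for the result.
#' @param strictPaper see [makeWindow1D()].
#' @return A [ProbabilityMap-class]. Attribute `predictorCalls` records the
#'   number of predictor invocations (`(2n-1)(2m-1)` for an `n x m`-patch
#'   image).
#' @examples
#' img <- matrix(runif(256 * 256), 256, 256)
#' rec <- reconstructWindowed(img, identityPredictor, "hann", 128)
#' max(abs(probValues(rec)[, , 1] - img))  # ~1e-16
#' @export
reconstructWindowed <- function(image, predictor,
                                kind = .SEPARABLE_KINDS, patch,
                                classNames = NULL, strictPaper = FALSE) {
  kind <- match.arg(kind)
  patch <- .checkEven(patch)
  .reconstructOverlap(image, predictor, patch,
                      .windowSet(kind, patch, strictPaper), classNames)
}

#' No-overlap baseline reconstruction
#'
#' Straight concatenation of non-overlapping patch predictions at stride
#' equal to the patch size: `n*m` predictor calls for an `n x m`-patch
#' image, and the baseline against which the windowed methods are adjusted.
#' Patch-border prediction errors remain untouched, producing the familiar
#' grid artefact.
#'
#' @inheritParams reconstructWindowed
#' @return A [ProbabilityMap-class] with attribute `predictorCalls`.
#' @export
reconstructNoOverlap <- function(image, predictor, patch,
                                 classNames = NULL) {
  patch <- .checkEven(patch)
  image <- .asChannels(image)
  padded <- padToGrid(image, patch)
  img <- padded$image
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- NULL
  calls <- 0L
  for (r in seq.int(0L, H - patch, by = patch))
    for (cc in seq.int(0L, W - patch, by = patch)) {
      p <- img[(r + 1L):(r + patch), (cc + 1L):(cc + patch), , drop = FALSE]
      pred <- .callPredictor(predictor, p, c(r, cc), patch)
      calls <- calls + 1L
      if (is.null(out)) out <- array(0, c(H, W, dim(pred)[3]))
      out[(r + 1L):(r + patch), (cc + 1L):(cc + patch), ] <- pred
    }
  pm <- cropToRecord(ProbabilityMap(out, classNames), padded$crop)
  attr(pm, "predictorCalls") <- calls
  pm
}

#' Average-window reconstruction
#'
#' Overlap-add with the constant interior window 1/4 and its flat border
#' (1/2) and corner (1) variants, i.e. the plain mean of all predictions
#' covering each pixel. Equivalent to `reconstructWindowed(kind =
#' "average")`.
#'
#' @inheritParams reconstructWindowed
#' @return A [ProbabilityMap-class].
#' @export
reconstructAverage <- function(image, predictor, patch, classNames = NULL) {
  reconstructWindowed(image, predictor, "average", patch, classNames)
}

#' Pyramidal-window reconstruction
#'
#' Overlap-add with the distance-ratio pyramidal window at every origin,
#' followed by pixel-wise division by the assembled window field (the
#' pyramidal window does not tile to a constant, so this extra
#' normalization step is required). The window is zero on every patch's
#' outermost pixel ring, so the one-pixel image border receives zero total
#' weight; those pixels are filled from the nearest pixel with positive
#' weight and a message is emitted (disable the guard with
#' `guardZeros = FALSE` to get an error instead).
#'
#' @inheritParams reconstructWindowed
#' @param guardZeros fill zero-divisor pixels from their nearest covered
#'   neighbour (default) instead of failing.
#' @return A [ProbabilityMap-class].
#' @export
reconstructPyramidal <- function(image, predictor, patch,
                                 classNames = NULL, guardZeros = TRUE) {
  patch <- .checkEven(patch)
  wins <- .windowSet("pyramidal", patch)
  pm <- .reconstructOverlap(image, predictor, patch, wins, classNames)
  d0 <- dim(.asChannels(image))
  field <- assembleWindowField("pyramidal", ceiling(d0[1] / patch) * patch,
                               ceiling(d0[2] / patch) * patch, patch)
  field <- field[seq_len(d0[1]), seq_len(d0[2]), drop = FALSE]
  zero <- field < .Machine$double.eps * patch
  vals <- pm@values
  for (ch in seq_len(dim(vals)[3]))
    vals[, , ch] <- vals[, , ch] / pmax(field, .Machine$double.eps)
  if (any(zero)) {
    if (!guardZeros)
      stop(sum(zero), " pixels received zero total window weight ",
           "(pyramidal windows vanish on the patch border ring)",
           call. = FALSE)
    message("reconstructPyramidal: filling ", sum(zero),
            " zero-weight border pixels from their nearest covered ",
            "neighbour")
    H <- dim(vals)[1]; W <- dim(vals)[2]
    zi <- which(zero, arr.ind = TRUE)
    src <- cbind(pmin(pmax(zi[, 1], 2L), H - 1L),
                 pmin(pmax(zi[, 2], 2L), W - 1L))
    for (ch in seq_len(dim(vals)[3]))
      vals[, , ch][zi] <- vals[, , ch][src]
  }
  out <- new("ProbabilityMap", values = vals, classNames = pm@classNames)
  attr(out, "predictorCalls") <- attr(pm, "predictorCalls")
  out
}

#' Reconstruct with any of the six benchmark methods
#'
#' Dispatch by method name: the no-overlap baseline, the average window,
#' the pyramidal window (with renormalization), or one of the tapering
#' separable windows.
#'
#' @inheritParams reconstructWindowed
#' @param method one of [reconstructionMethods()].
#' @return A [ProbabilityMap-class].
#' @export
reconstructWith <- function(image, predictor, method = .METHODS, patch,
                            classNames = NULL) {
  method <- match.arg(method)
  switch(method,
    no_overlap = reconstructNoOverlap(image, predictor, patch, classNames),
    pyramidal = reconstructPyramidal(image, predictor, patch, classNames),
    reconstructWindowed(image, predictor, method, patch, classNames))
}

#' Per-pixel most-probable class
#'
#' Collapses a probability map to integer labels `0..C-1` by taking the
#' per-pixel argmax; ties are broken deterministically toward the lowest
#' class index.
#'
#' @param pm a [ProbabilityMap-class].
#' @return Integer matrix of class labels.
#' @export
asLabelMask <- function(pm) {
  v <- probValues(pm)
  d <- dim(v)
  flat <- matrix(v, d[1] * d[2], d[3])
  matrix(max.col(flat, ties.method = "first") - 1L, d[1], d[2])
}
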