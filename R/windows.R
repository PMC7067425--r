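# Window construction. All windows use the periodic convention (denominator
# I, not I - 1): only the periodic forms tile to an exact constant at
# half-window stride, which is what makes the reconstruction
# renormalization-free. Indices are 0-based in the formulas; matrices are
# indexed [row j + 1, column i + 1].

.checkEven <- function(size, what = "patch size") {
  if (length(size) != 1L || !is.finite(size) || size != round(size))
    stop(what, " must be a single integer", call. = FALSE)
  if (size < 2 || size %% 2 != 0)
    stop(what, " must be even and >= 2: half-patch stride tiling needs an ",
         "integral half size (", size, "/2)", call. = FALSE)
  as.integer(size)
}

#' 1-D window profiles
#'
#' The 1-D factor `w(i)`, `i = 0..I-1`, of a separable 2-D window:
#' \describe{
#'   \item{hann}{`w(i) = (1 - cos(2*pi*i/I)) / 2`}
#'   \item{bartlett_hann}{`w(i) = a0 - a1*|i/I - 1/2| - a2*cos(2*pi*i/I)`
#'     with `a0 = 0.62`, `a1 = 0.48`, `a2 = 0.38`}
#'   \item{triangular}{`w(i) = 1 - |2*i/I - 1|`}
#'   \item{average}{`w(i) = 1/2`, so the 2-D product is the constant 1/4}
#' }
#' All use the periodic convention (denominator `I`): two copies of any of
#' these profiles offset by `I/2` sum to exactly 1, which is the property
#' that makes half-stride overlap-add reconstruction weight-preserving.
#' The symmetric convention (`I - 1`) and the `+a1` Bartlett-Hann sign
#' variant are available via `strictPaper = TRUE` for comparison; neither
#' tiles to 1.
#'
#' @param kind one of the separable kinds: `"average"`, `"hann"`,
#'   `"bartlett_hann"`, `"triangular"`. The pyramidal window has no 1-D
#'   factor (it is not separable) and is rejected here.
#' @param size patch side `I` in pixels; must be even and at least 2.
#' @param strictPaper if `TRUE`, use the symmetric denominator `I - 1` and
#'   the `+a1` Bartlett-Hann sign. These variants break the partition of
#'   unity and are provided only for comparison.
#' @return Numeric vector of length `size`: `w(0), ..., w(I-1)`.
#' @examples
#' makeWindow1D("hann", 4)        # 0.0 0.5 1.0 0.5
#' makeWindow1D("triangular", 6)[4] # w(3) = 1
#' @export
makeWindow1D <- function(kind = .SEPARABLE_KINDS, size,
                         strictPaper = FALSE) {
  kind <- match.arg(kind)
  I <- .checkEven(size)
  i <- 0:(I - 1L)
  denom <- if (strictPaper) I - 1L else I
  switch(kind,
    average = rep(0.5, I),
    hann = 0.5 * (1 - cos(2 * pi * i / denom)),
    bartlett_hann = {
      a0 <- 0.62; a1 <- 0.48; a2 <- 0.38
      s <- if (strictPaper) +1 else -1
      a0 + s * a1 * abs(i / denom - 0.5) - a2 * cos(2 * pi * i / denom)
    },
    triangular = 1 - abs(2 * i / denom - 1))
}

# Axis profile used at a given image position: "interior" is the plain 1-D
# window; "begin"/"end" replace the half facing the image border by the
# constant 1 (no neighbouring patch contributes context there); "both" is
# the single-patch-per-axis case, identically 1. Half-open convention: the
# flat region of "begin" covers indices 0..I/2-1, of "end" covers I/2..I-1.
.axisProfile <- function(w, side = c("interior", "begin", "end", "both")) {
  side <- match.arg(side)
  I <- length(w)
  h <- I %/% 2L
  switch(side,
    interior = w,
    begin = c(rep(1, h), w[(h + 1L):I]),
    end = c(w[seq_len(h)], rep(1, h)),
    both = rep(1, I))
}

.rolesFromLabel <- function(role) {
  rowRole <- if (grepl("up", role)) "begin" else if (grepl("down", role))
    "end" else "interior"
  colRole <- if (grepl("left", role)) "begin" else if (grepl("right", role))
    "end" else "interior"
  list(row = rowRole, col = colRole)
}

# Build the weight matrix for the given axis roles.
.windowMatrix <- function(kind, height, width, rowRole, colRole,
                          strictPaper = FALSE) {
  wr <- .axisProfile(makeWindow1D(kind, height, strictPaper), rowRole)
  wc <- .axisProfile(makeWindow1D(kind, width, strictPaper), colRole)
  outer(wr, wc)
}

#' Construct a 2-D window
#'
#' For separable kinds the 2-D window is the outer product
#' `W(i, j) = w(i) * w(j)` of the 1-D profile with itself. The pyramidal
#' window is the distance-ratio window `W(i, j) = alpha * De / (Dc + De)`
#' where `De` is the distance from the patch edge (zero on the outermost
#' pixel ring), `Dc` the distance from the patch centre, and `alpha`
#' normalizes the mean weight to exactly 1; it is not separable and, unlike
#' the other kinds, its tiled sum is not constant, so reconstruction with it
#' requires division by the assembled window field afterwards.
#'
#' @param kind one of [windowKinds()].
#' @param height,width patch extent `J`, `I` in pixels; even, at least 2.
#' @param edgeMetric,centerMetric distance metrics for the pyramidal window:
#'   `De` defaults to the Chebyshev (chessboard) distance to the nearest
#'   patch border and `Dc` to the Euclidean distance to the patch centre at
#'   `((I-1)/2, (J-1)/2)`.
#' @param strictPaper see [makeWindow1D()].
#' @return A [Window2D-class] with role `"interior"`.
#' @examples
#' W <- makeWindow2D("hann", 4, 4)
#' windowWeights(W)[3, 3]  # w(2)^2 = 1
#' mean(windowWeights(makeWindow2D("pyramidal", 8, 8)))  # exactly 1
#' @export
makeWindow2D <- function(kind = .WINDOW_KINDS, height, width = height,
                         edgeMetric = c("chebyshev", "manhattan"),
                         centerMetric = c("euclidean", "chebyshev"),
                         strictPaper = FALSE) {
  kind <- match.arg(kind)
  J <- .checkEven(height, "patch height")
  I <- .checkEven(width, "patch width")
  if (kind == "pyramidal") {
    w <- .pyramidalWeights(J, I, match.arg(edgeMetric),
                           match.arg(centerMetric))
  } else {
    w <- .windowMatrix(kind, J, I, "interior", "interior", strictPaper)
  }
  new("Window2D", weights = w, kind = kind, role = "interior")
}

# De, Dc and alpha for the pyramidal window.
.pyramidalParts <- function(height, width, edgeMetric = "chebyshev",
                            centerMetric = "euclidean") {
  J <- height; I <- width
  j <- 0:(J - 1L); i <- 0:(I - 1L)
  dj <- pmin(j, J - 1L - j)  # distance to the nearest horizontal border row
  di <- pmin(i, I - 1L - i)
  De <- switch(edgeMetric,
    chebyshev = outer(dj, di, pmin),
    manhattan = outer(dj, di, pmin))  # nearest-border distance coincides
  cj <- (J - 1) / 2; ci <- (I - 1) / 2
  Dc <- switch(centerMetric,
    euclidean = sqrt(outer((j - cj)^2, (i - ci)^2, `+`)),
    chebyshev = outer(abs(j - cj), abs(i - ci), pmax))
  base <- De / (Dc + De)
  base[De == 0] <- 0  # guard 0/0 when a corner pixel coincides with centre
  alpha <- (I * J) / sum(base)
  list(edgeDistance = De, centerDistance = Dc, alpha = alpha, base = base)
}

.pyramidalWeights <- function(height, width, edgeMetric = "chebyshev",
                              centerMetric = "euclidean") {
  p <- .pyramidalParts(height, width, edgeMetric, centerMetric)
  p$alpha * p$base
}

#' Pyramidal window components
#'
#' Exposes the building blocks of the pyramidal window: the edge-distance
#' grid `De` (zero on the outermost pixel ring), the centre-distance grid
#' `Dc`, and the normalizer `alpha = I*J / sum(De / (Dc + De))` which makes
#' the mean weight exactly 1.
#'
#' @inheritParams makeWindow2D
#' @return List with elements `edgeDistance`, `centerDistance`, `alpha`.
#' @export
pyramidalParts <- function(height, width = height,
                           edgeMetric = c("chebyshev", "manhattan"),
                           centerMetric = c("euclidean", "chebyshev")) {
  J <- .checkEven(height, "patch height")
  I <- .checkEven(width, "patch width")
  p <- .pyramidalParts(J, I, match.arg(edgeMetric), match.arg(centerMetric))
  p[c("edgeDistance", "centerDistance", "alpha")]
}

#' Border and corner window variants
#'
#' Patches on the image border have no neighbouring patch contributing
#' context on one side, so the window is flattened to 1 on the half facing
#' that border: e.g. the `"up"` window is `w(i)` for rows in the top half
#' and `w(i) * w(j)` below, and the `"up_left"` corner window is constant 1
#' on the quadrant facing the image corner, `w(i)` or `w(j)` along the two
#' adjacent borders, and `w(i) * w(j)` in the remaining quadrant. The other
#' corners are axis flips of `"up_left"`. With these variants every pixel's
#' total window weight over all covering patches is exactly 1.
#'
#' Only separable kinds are supported: the border construction is defined
#' from a 1-D window, which the pyramidal window does not have.
#'
#' @param kind a separable window kind.
#' @param role which border (`"up"`, `"down"`, `"left"`, `"right"`) or
#'   corner (`"up_left"`, `"up_right"`, `"down_left"`, `"down_right"`).
#' @inheritParams makeWindow2D
#' @return A [Window2D-class] with the requested role.
#' @examples
#' up <- makeBorderWindow("hann", "up", 4, 4)
#' windowWeights(up)[1, ]  # top row: w(i), maximal at the centre column
#' @export
makeBorderWindow <- function(kind = .SEPARABLE_KINDS,
                             role = .EDGE_ROLES, height, width = height,
                             strictPaper = FALSE) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  J <- .checkEven(height, "patch height")
  I <- .checkEven(width, "patch width")
  ax <- .rolesFromLabel(role)
  new("Window2D",
      weights = .windowMatrix(kind, J, I, ax$row, ax$col, strictPaper),
      kind = kind, role = role)
}

#' @rdname makeBorderWindow
#' @export
makeCornerWindow <- function(kind = .SEPARABLE_KINDS,
                             role = .CORNER_ROLES, height, width = height,
                             strictPaper = FALSE) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  J <- .checkEven(height, "patch height")
  I <- .checkEven(width, "patch width")
  ax <- .rolesFromLabel(role)
  new("Window2D",
      weights = .windowMatrix(kind, J, I, ax$row, ax$col, strictPaper),
      kind = kind, role = role)
}

# All role-specific windows needed by a grid, keyed by "rowRole.colRole".
.windowSet <- function(kind, patch, strictPaper = FALSE) {
  sides <- c("interior", "begin", "end", "both")
  out <- list()
  if (kind == "pyramidal") {
    w <- .pyramidalWeights(patch, patch)
    for (r in sides) for (cc in sides) out[[paste(r, cc, sep = ".")]] <- w
    return(out)
  }
  w1 <- makeWindow1D(kind, patch, strictPaper)
  profs <- lapply(stats::setNames(sides, sides),
                  function(s) .axisProfile(w1, s))
  for (r in sides) for (cc in sides)
    out[[paste(r, cc, sep = ".")]] <- outer(profs[[r]], profs[[cc]])
  out
}

#' Accumulate all tiled windows into an image-sized field
#'
#' Places the interior window and its border/corner variants at every patch
#' origin of the half-stride tiling and sums them. For the separable kinds
#' this field is identically 1 (partition of unity), which is why windowed
#' reconstruction needs no renormalization; for the pyramidal window the
#' field is non-constant and serves as the divisor of
#' [reconstructPyramidal()].
#'
#' @param kind one of [windowKinds()].
#' @param imageHeight,imageWidth image extent; positive multiples of
#'   `patch/2`, at least `patch`.
#' @param patch patch side in pixels (even).
#' @param strictPaper see [makeWindow1D()].
#' @return Numeric `imageHeight x imageWidth` matrix of summed weights.
#' @examples
#' f <- assembleWindowField("hann", 256, 256, 128)
#' range(f)  # 1 1 (within 1e-6)
#' @export
assembleWindowField <- function(kind = .WINDOW_KINDS, imageHeight,
                                imageWidth, patch, strictPaper = FALSE) {
  kind <- match.arg(kind)
  grid <- planGrid(imageHeight, imageWidth, patch)
  wins <- .windowSet(kind, grid@patch, strictPaper)
  field <- matrix(0, grid@imageHeight, grid@imageWidth)
  I <- grid@patch
  for (k in seq_len(nPatches(grid))) {
    r <- grid@origins[k, 1L]; cc <- grid@origins[k, 2L]
    w <- wins[[paste(grid@rowRoles[k], grid@colRoles[k], sep = ".")]]
    field[(r + 1L):(r + I), (cc + 1L):(cc + I)] <-
      field[(r + 1L):(r + I), (cc + 1L):(cc + I)] + w
  }
  field
}
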