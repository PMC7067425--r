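#' @import methods
NULL

.WINDOW_KINDS <- c("average", "hann", "bartlett_hann", "triangular", "pyramidal")
.SEPARABLE_KINDS <- c("average", "hann", "bartlett_hann", "triangular")
.TAPERING_KINDS <- c("hann", "bartlett_hann", "triangular")
.EDGE_ROLES <- c("up", "down", "left", "right")
.CORNER_ROLES <- c("up_left", "up_right", "down_left", "down_right")
.ALL_ROLES <- c("interior", .EDGE_ROLES, .CORNER_ROLES)
.METHODS <- c("no_overlap", "average", "pyramidal", "hann", "bartlett_hann",
              "triangular")

#' Window kinds and reconstruction methods
#'
#' `windowKinds()` lists the supported 2-D window functions. The first four
#' are separable (the 2-D window is an outer product of a 1-D profile with
#' itself); the pyramidal window is a non-separable distance-ratio window and
#' requires a renormalization step after reconstruction.
#' `reconstructionMethods()` lists the six recombination strategies compared
#' by [runBenchmark()]: the no-overlap baseline plus the five windows.
#'
#' @return Character vector of kind / method names.
#' @export
windowKinds <- function() .WINDOW_KINDS

#' @rdname windowKinds
#' @export
reconstructionMethods <- function() .METHODS

#' Window2D: a patch-sized grid of recombination weights
#'
#' A 2-D window to be multiplied onto a per-patch prediction before
#' overlap-add recombination. The `role` records which variant this is:
#' `"interior"` for patches fully surrounded by neighbours, one of
#' `"up"/"down"/"left"/"right"` for patches on an image border (flat, weight
#' preserving, toward the side with no neighbour), and `"up_left"` etc. for
#' the four corners (a constant-1 quadrant toward the image corner). Weights
#' are stored as a numeric matrix indexed `[row, column]`.
#'
#' @slot weights numeric matrix of non-negative weights, patch-sized.
#' @slot kind one of [windowKinds()].
#' @slot role one of `"interior"`, the four edges, the four corners, or a
#'   degenerate combination such as `"up_down"` when a single patch spans the
#'   whole image along an axis.
#' @export
setClass("Window2D",
  representation(weights = "matrix", kind = "character", role = "character"),
  validity = function(object) {
    w <- object@weights
    if (!is.numeric(w)) return("weights must be numeric")
    if (any(!is.finite(w))) return("weights must be finite")
    if (any(w < 0)) return("weights must be non-negative")
    if (!object@kind %in% .WINDOW_KINDS)
      return(sprintf("unknown window kind '%s'", object@kind))
    TRUE
  })

#' PatchGrid: half-stride tiling geometry
#'
#' The tiling used for overlap-add reconstruction: square patches of side
#' `patch` placed at a stride of exactly `patch/2`, so that adjacent patches
#' overlap by half a patch and interior pixels are covered by exactly four
#' patches. For an image of `n` by `m` whole patches the grid holds
#' `(2n-1)(2m-1)` patch origins.
#'
#' @slot imageHeight,imageWidth image extent in pixels.
#' @slot patch patch side in pixels (even).
#' @slot stride always `patch/2`.
#' @slot origins integer matrix with columns `row`, `col`: 0-based top-left
#'   corners, enumerated row-major.
#' @slot rowRoles,colRoles per-origin axis position: `"begin"`, `"interior"`,
#'   `"end"`, or `"both"` (single patch spanning the axis).
#' @export
setClass("PatchGrid",
  representation(imageHeight = "integer", imageWidth = "integer",
                 patch = "integer", stride = "integer",
                 origins = "matrix", rowRoles = "character",
                 colRoles = "character"),
  validity = function(object) {
    if (object@stride * 2L != object@patch)
      return("stride must be exactly half the patch size")
    if (nrow(object@origins) != length(object@rowRoles) ||
        nrow(object@origins) != length(object@colRoles))
      return("one role pair per origin required")
    nr <- (object@imageHeight - object@patch) %/% object@stride + 1L
    nc <- (object@imageWidth - object@patch) %/% object@stride + 1L
    if (nrow(object@origins) != nr * nc)
      return("origin count does not match the tiling geometry")
    TRUE
  })

#' ProbabilityMap: per-pixel class scores
#'
#' An `H x W x C` array of per-pixel class scores (typically softmax
#' probabilities from a pixel classifier), with class names attached. The
#' default three-class semantics are `background`, `object`, `object_edge`.
#'
#' @slot values numeric array `H x W x C`, finite.
#' @slot classNames character vector of length `C`.
#' @export
setClass("ProbabilityMap",
  representation(values = "array", classNames = "character"),
  validity = function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("values must be an H x W x C array")
    if (any(!is.finite(v))) return("values must be finite")
    if (length(object@classNames) != dim(v)[3])
      return("one class name per channel required")
    TRUE
  })

#' Construct a ProbabilityMap
#'
#' @param values numeric `H x W` matrix (treated as one channel) or
#'   `H x W x C` array.
#' @param classNames optional channel names; defaults to `class1..classC`,
#'   or to `background`/`object`/`object_edge` when `C == 3`.
#' @return A [ProbabilityMap-class] object.
#' @examples
#' pm <- ProbabilityMap(array(1/3, c(8, 8, 3)))
#' classNames(pm)
#' @export
ProbabilityMap <- function(values, classNames = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  C <- dim(values)[3]
  if (is.null(classNames)) {
    classNames <- if (C == 3L) c("background", "object", "object_edge")
                  else paste0("class", seq_len(C))
  }
  new("ProbabilityMap", values = values, classNames = classNames)
}

#' ArtefactProfile: border-localized predictor error model
#'
#' Describes how the simulated predictor's error grows toward patch borders:
#' the additive noise applied to a patch prediction has standard deviation
#' `baseNoise + edgeNoise * profile(d)` where `d` is the pixel's distance to
#' the patch border, normalized to `[0, 1]` (0 = border ring, 1 = patch
#' centre), and `profile` is a non-increasing function with
#' `profile(0) = 1`, `profile(1) = 0`. This operationalizes the observation
#' that patch-based CNN segmentation errors are largest near patch edges and
#' corners.
#'
#' @slot baseNoise noise sd at the patch centre.
#' @slot edgeNoise additional noise sd at the patch border.
#' @slot profile monotone non-increasing function of normalized
#'   centre-distance.
#' @slot softness amount of uniform mixing applied to the one-hot truth
#'   before corruption (0 = exact one-hot).
#' @slot seed integer seed; each patch origin gets its own substream.
#' @export
setClass("ArtefactProfile",
  representation(baseNoise = "numeric", edgeNoise = "numeric",
                 profile = "function", softness = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@baseNoise < 0 || object@edgeNoise < 0)
      return("noise levels must be non-negative")
    if (object@softness < 0 || object@softness > 1)
      return("softness must be in [0, 1]")
    d <- seq(0, 1, length.out = 33)
    p <- vapply(d, object@profile, numeric(1))
    if (any(diff(p) > 1e-12))
      return("profile must be non-increasing in distance from the border")
    TRUE
  })

#' Construct an ArtefactProfile
#'
#' @param baseNoise noise sd at patch centre (default 0.05).
#' @param edgeNoise extra noise sd at the patch border (default 0.35).
#' @param profile non-increasing function of normalized distance-to-centre;
#'   default `(1 - d)^2`, i.e. quadratic decay of the border penalty.
#' @param softness uniform mixing of the one-hot truth (default 0 = exact).
#' @param seed integer seed for the noise streams.
#' @return An [ArtefactProfile-class] object.
#' @export
ArtefactProfile <- function(baseNoise = 0.05, edgeNoise = 0.35,
                            profile = function(d) (1 - d)^2,
                            softness = 0, seed = 1L) {
  new("ArtefactProfile", baseNoise = baseNoise, edgeNoise = edgeNoise,
      profile = profile, softness = softness, seed = as.integer(seed))
}

#' SceneSpec: synthetic three-class scene parameters
#'
#' Parameters of the synthetic ground truth: elliptical nuclei-like blobs on
#' a background, each blob wrapped in an `object_edge` ring of width
#' `edgeBand` pixels, mirroring the three-class (background / object /
#' object-edge) structure used for nucleus segmentation.
#'
#' @slot height,width scene extent in pixels.
#' @slot nBlobs number of blobs to place.
#' @slot radiusRange length-2 numeric, min/max semi-axis in pixels.
#' @slot edgeBand width of the object-edge ring in pixels.
#' @slot seed integer seed.
#' @export
setClass("SceneSpec",
  representation(height = "integer", width = "integer", nBlobs = "integer",
                 radiusRange = "numeric", edgeBand = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@radiusRange) != 2L ||
        any(object@radiusRange <= 0) || diff(object@radiusRange) < 0)
      return("radiusRange must be an increasing positive pair")
    if (object@edgeBand < 0) return("edgeBand must be non-negative")
    if (object@nBlobs < 0) return("nBlobs must be non-negative")
    if (2 * object@radiusRange[2] >= min(object@height, object@width))
      return("radiusRange does not fit the scene")
    TRUE
  })

#' Construct a SceneSpec
#'
#' Defaults emulate a 512x512 crop of a nuclei segmentation scene: 30
#' elliptical blobs with semi-axes between 8 and 20 pixels and a 3-pixel
#' edge ring.
#'
#' @param height,width scene extent in pixels.
#' @param nBlobs number of elliptical blobs.
#' @param radiusRange min/max semi-axis in pixels.
#' @param edgeBand object-edge ring width in pixels.
#' @param seed integer seed.
#' @return A [SceneSpec-class] object.
#' @export
SceneSpec <- function(height = 512L, width = 512L, nBlobs = 30L,
                      radiusRange = c(8, 20), edgeBand = 3, seed = 1L) {
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      nBlobs = as.integer(nBlobs), radiusRange = as.numeric(radiusRange),
      edgeBand = as.numeric(edgeBand), seed = as.integer(seed))
}
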