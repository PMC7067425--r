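#' Accessors for WindowStitch classes
#'
#' `windowWeights()` returns the weight matrix of a [Window2D-class];
#' `windowKind()` and `windowRole()` its kind and role tag. `probValues()`
#' returns the `H x W x C` array of a [ProbabilityMap-class] and
#' `classNames()` its channel names. `patchOrigins()` returns the 0-based
#' origin matrix of a [PatchGrid-class], `patchRoles()` the per-origin role
#' labels, and `nPatches()` the patch count.
#'
#' @param x a WindowStitch object.
#' @return The slot contents, as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("windowWeights", function(x) standardGeneric("windowWeights"))
#' @rdname accessors
#' @export
setGeneric("windowKind", function(x) standardGeneric("windowKind"))
#' @rdname accessors
#' @export
setGeneric("windowRole", function(x) standardGeneric("windowRole"))
#' @rdname accessors
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("patchOrigins", function(x) standardGeneric("patchOrigins"))
#' @rdname accessors
#' @export
setGeneric("patchRoles", function(x) standardGeneric("patchRoles"))
#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname accessors
#' @export
setMethod("windowWeights", "Window2D", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("windowKind", "Window2D", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("windowRole", "Window2D", function(x) x@role)
#' @rdname accessors
#' @export
setMethod("probValues", "ProbabilityMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("classNames", "ProbabilityMap", function(x) x@classNames)
#' @rdname accessors
#' @export
setMethod("patchOrigins", "PatchGrid", function(x) x@origins)
#' @rdname accessors
#' @export
setMethod("nPatches", "PatchGrid", function(x) nrow(x@origins))

#' @rdname accessors
#' @export
setMethod("patchRoles", "PatchGrid", function(x) {
  mapply(.roleLabel, x@rowRoles, x@colRoles, USE.NAMES = FALSE)
})

#' @describeIn accessors spatial dimensions (and channels) of a map.
#' @export
setMethod("dim", "ProbabilityMap", function(x) dim(x@values))

setMethod("show", "Window2D", function(object) {
  w <- object@weights
  cat(sprintf("Window2D: %s (%s), %d x %d, weights in [%.4g, %.4g]\n",
              object@kind, object@role, nrow(w), ncol(w), min(w), max(w)))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf(
    "PatchGrid: %d x %d image, %d x %d patches at stride %d -> %d patches\n",
    object@imageHeight, object@imageWidth, object@patch, object@patch,
    object@stride, nrow(object@origins)))
  tab <- table(patchRoles(object))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbabilityMap: %d x %d pixels, %d classes (%s)\n",
              d[1], d[2], d[3], paste(object@classNames, collapse = ", ")))
  cat(sprintf("  values in [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d, %d blobs (semi-axes %.4g-%.4g px), edge band %.4g px, seed %d\n",
    object@height, object@width, object@nBlobs, object@radiusRange[1],
    object@radiusRange[2], object@edgeBand, object@seed))
})

setMethod("show", "ArtefactProfile", function(object) {
  cat(sprintf(
    "ArtefactProfile: sd %.4g at centre, +%.4g at border, softness %.4g, seed %d\n",
    object@baseNoise, object@edgeNoise, object@softness, object@seed))
})

.roleLabel <- function(rowRole, colRole) {
  if (rowRole == "interior" && colRole == "interior") return("interior")
  rpart <- switch(rowRole, interior = NULL, begin = "up", end = "down",
                  both = c("up", "down"))
  cpart <- switch(colRole, interior = NULL, begin = "left", end = "right",
                  both = c("left", "right"))
  paste(c(rpart, cpart), collapse = "_")
}
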