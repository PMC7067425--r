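# Half-stride tiling geometry. Origins are 0-based (row, col) top-left
# corners enumerated row-major; patch intervals are half-open.

#' Plan a half-stride patch grid
#'
#' Enumerates square patch origins at a stride of exactly half the patch
#' side and tags each patch by its position: `begin`/`end` along each axis
#' when the patch touches the image border, `interior` otherwise, `both`
#' when a single patch spans the whole axis. For an image of `n` by `m`
#' whole patches this produces `(2n-1)(2m-1)` patches, versus `n*m` for
#' non-overlapping tiling — roughly a 4x cost for large images.
#'
#' @param imageHeight,imageWidth image extent in pixels; must be at least
#'   `patch` and a multiple of the stride `patch/2` (use [padToGrid()]
#'   first for arbitrary extents).
#' @param patch square patch side in pixels (even).
#' @return A [PatchGrid-class].
#' @examples
#' g <- planGrid(1024, 1024, 128)
#' nPatches(g)  # (2*8-1)^2 = 225
#' @export
planGrid <- function(imageHeight, imageWidth, patch) {
  patch <- .checkEven(patch)
  H <- as.integer(imageHeight); W <- as.integer(imageWidth)
  s <- patch %/% 2L
  if (H < patch || W < patch)
    stop("patch (", patch, ") larger than image (", H, " x ", W, ")",
         call. = FALSE)
  if (H %% s != 0L || W %% s != 0L)
    stop("image extent must be a multiple of the stride ", s,
         "; pad with padToGrid() first", call. = FALSE)
  rows <- seq.int(0L, H - patch, by = s)
  cols <- seq.int(0L, W - patch, by = s)
  axisRole <- function(pos, last) {
    if (last == 0L) return(rep("both", length(pos)))
    ifelse(pos == 0L, "begin", ifelse(pos == last, "end", "interior"))
  }
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  new("PatchGrid", imageHeight = H, imageWidth = W, patch = patch,
      stride = s, origins = origins,
      rowRoles = rep(axisRole(rows, H - patch), each = length(cols)),
      colRoles = rep(axisRole(cols, W - patch), times = length(rows)))
}

#' Reflect-pad an image to a whole number of patches
#'
#' Pads an image (matrix or `H x W x C` array) by edge reflection up to the
#' next multiple of `patch` in each dimension, and returns the crop record
#' needed to restore the original extent after reconstruction. Reflection is
#' used so that no artificial intensity edge is introduced at the padded
#' border.
#'
#' @param image numeric matrix or 3-D array, at least 2 x 2.
#' @param patch patch side in pixels.
#' @return List with `image` (padded) and `crop` (`NULL` when no padding was
#'   needed, else the original `c(height, width)`).
#' @seealso [cropToRecord()]
#' @export
padToGrid <- function(image, patch) {
  patch <- .checkEven(patch)
  d <- dim(image)
  if (length(d) < 2L || d[1] < 2L || d[2] < 2L)
    stop("image must be at least 2 x 2", call. = FALSE)
  H <- d[1]; W <- d[2]
  Ht <- as.integer(ceiling(H / patch) * patch)
  Wt <- as.integer(ceiling(W / patch) * patch)
  if (Ht == H && Wt == W) return(list(image = image, crop = NULL))
  idx <- function(n, target) {
    # reflected index sequence 1..n, n-1..1, 2..n, ... truncated to target
    base <- seq_len(n)
    reflect <- c(base, rev(base)[-1][-(n - 1L)])  # period 2n - 2
    reflect[((seq_len(target) - 1L) %% length(reflect)) + 1L]
  }
  ri <- idx(H, Ht); ci <- idx(W, Wt)
  padded <- if (length(d) == 2L) image[ri, ci, drop = FALSE]
            else image[ri, ci, , drop = FALSE]
  list(image = padded, crop = c(height = H, width = W))
}

#' @rdname padToGrid
#' @param padded the reconstructed full-size object (matrix, array, or
#'   [ProbabilityMap-class]).
#' @param crop the crop record returned by [padToGrid()].
#' @return `cropToRecord()`: the object restored to the original extent.
#' @export
cropToRecord <- function(padded, crop) {
  if (is.null(crop)) return(padded)
  if (is(padded, "ProbabilityMap"))
    return(new("ProbabilityMap",
               values = padded@values[seq_len(crop[1]), seq_len(crop[2]), ,
                                      drop = FALSE],
               classNames = padded@classNames))
  if (length(dim(padded)) == 2L)
    padded[seq_len(crop[1]), seq_len(crop[2]), drop = FALSE]
  else padded[seq_len(crop[1]), seq_len(crop[2]), , drop = FALSE]
}

#' Extract the patches of a grid
#'
#' Returns the patch contents in origin order (row-major). Mostly useful
#' for inspection and testing; the reconstruction functions slice patches
#' internally.
#'
#' @param image numeric matrix or `H x W x C` array matching the grid.
#' @param grid a [PatchGrid-class].
#' @return List of patches (matrix or array, `patch x patch (x C)`), with
#'   the 0-based origin attached as attribute `origin`.
#' @export
extractPatches <- function(image, grid) {
  d <- dim(image)
  if (d[1] != grid@imageHeight || d[2] != grid@imageWidth)
    stop("image extent (", d[1], " x ", d[2],
         ") does not match the grid", call. = FALSE)
  I <- grid@patch
  lapply(seq_len(nPatches(grid)), function(k) {
    r <- grid@origins[k, 1L]; cc <- grid@origins[k, 2L]
    p <- if (length(d) == 2L) image[(r + 1L):(r + I), (cc + 1L):(cc + I),
                                    drop = FALSE]
         else image[(r + 1L):(r + I), (cc + 1L):(cc + I), , drop = FALSE]
    attr(p, "origin") <- c(row = unname(r), col = unname(cc))
    p
  })
}

#' Serialize a grid for provenance logs
#'
#' @param grid a [PatchGrid-class].
#' @return A plain list (geometry, origins, roles) suitable for JSON
#'   serialization.
#' @export
gridAsList <- function(grid) {
  list(imageHeight = grid@imageHeight, imageWidth = grid@imageWidth,
       patch = grid@patch, stride = grid@stride,
       origins = unname(apply(grid@origins, 1L, as.list)),
       roles = patchRoles(grid))
}
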