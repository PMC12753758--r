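#' Deterministic tile origins covering an image
#'
#' Per axis, tile starts are 0, stride, 2*stride, ...; a final start clamped
#' to \code{dim - patchSize} is appended when the regular grid does not
#' already reach it, so every pixel is covered and no tile leaves the
#' image. With \code{stride = patchSize} the tiling is an exact, disjoint
#' mosaic (the regime used for unlabeled slides); annotated slides use
#' \code{stride = patchSize - overlap} (default overlap 128 at patch 512).
#'
#' @param width,height image dimensions in pixels.
#' @param patchSize tile edge in pixels; must not exceed either dimension.
#' @param stride step between tile starts (>= 1).
#' @return integer matrix with columns \code{x0}, \code{y0}; 0-based
#'   origins of half-open tiles, sorted row-major (by y, then x).
#' @examples
#' tileOrigins(1024, 512, 512, 512)   # two tiles side by side
#' nrow(tileOrigins(1024, 1024, 512, 384))  # 9: per-axis starts 0, 384, 512
#' @export
tileOrigins <- function(width, height, patchSize, stride) {
  width <- as.integer(width); height <- as.integer(height)
  patchSize <- as.integer(patchSize); stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (patchSize > width || patchSize > height)
    stop(sprintf(
      "slide too small for configuration: patch %d exceeds image %d x %d",
      patchSize, width, height))
  axisStarts <- function(dimSize) {
    last <- dimSize - patchSize
    s <- seq.int(0L, last, by = stride)
    if (s[length(s)] != last) s <- c(s, last)
    s
  }
  xs <- axisStarts(width)
  ys <- axisStarts(height)
  origins <- cbind(x0 = rep(xs, times = length(ys)),
                   y0 = rep(ys, each = length(xs)))
  storage.mode(origins) <- "integer"
  origins
}

#' @rdname tileOrigins
#' @return \code{TileGrid} returns a [TileGrid-class] wrapping the origins.
#' @export
TileGrid <- function(width, height, patchSize, stride) {
  new("TileGrid", patchSize = as.integer(patchSize),
      stride = as.integer(stride),
      origins = tileOrigins(width, height, patchSize, stride))
}

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d tiles of %d px, stride %d\n",
              nrow(object@origins), object@patchSize, object@stride))
})

#' Extract one patch from a slide
#'
#' @param slide a [SlideRecord-class].
#' @param origin integer (x0, y0), 0-based top-left corner; the tile
#'   \code{[x0, x0+patchSize) x [y0, y0+patchSize)} must lie fully inside
#'   the slide.
#' @param patchSize patch edge in pixels.
#' @param withMask if TRUE and the slide carries a label mask, attach the
#'   aligned mask crop.
#' @return a [Patch-class].
#' @export
extractPatch <- function(slide, origin, patchSize, withMask = FALSE) {
  origin <- as.integer(origin)
  patchSize <- as.integer(patchSize)
  d <- dim(slide@image)
  x0 <- origin[1L]; y0 <- origin[2L]
  if (x0 < 0L || y0 < 0L || x0 + patchSize > d[2L] || y0 + patchSize > d[1L])
    stop(sprintf("patch origin (%d, %d) with size %d out of bounds for %d x %d",
                 x0, y0, patchSize, d[2L], d[1L]))
  rows <- (y0 + 1L):(y0 + patchSize)
  cols <- (x0 + 1L):(x0 + patchSize)
  px <- slide@image[rows, cols, , drop = FALSE]
  mk <- NULL
  if (withMask) {
    if (is.null(slide@labelMask))
      stop("slide '", slide@slideId, "' carries no label mask")
    mk <- LabelMask(slide@labelMask@codes[rows, cols, drop = FALSE],
                    slide@labelMask@scheme)
  }
  new("Patch", slideId = slide@slideId, origin = origin, pixels = px,
      mask = mk)
}

#' Tile a whole slide into patches
#'
#' @inheritParams extractPatch
#' @param stride step between tile starts; defaults to \code{patchSize}
#'   (no overlap).
#' @param mask optional [LabelMask-class] to crop instead of the slide's
#'   own (used to attach predicted masks to unlabeled slides).
#' @return list of [Patch-class] in row-major tile order.
#' @export
tileSlide <- function(slide, patchSize, stride = patchSize,
                      withMask = FALSE, mask = NULL) {
  d <- dim(slide@image)
  origins <- tileOrigins(d[2L], d[1L], patchSize, stride)
  if (!is.null(mask)) {
    if (!identical(dim(mask@codes), d[1:2]))
      stop("provided mask does not match slide dimensions")
    tmp <- SlideRecord(slide@slideId, slide@image, slide@mpp,
                       labelMask = mask, artifactMask = slide@artifactMask)
    return(lapply(seq_len(nrow(origins)), function(i)
      extractPatch(tmp, origins[i, ], patchSize, withMask = TRUE)))
  }
  lapply(seq_len(nrow(origins)), function(i)
    extractPatch(slide, origins[i, ], patchSize, withMask = withMask))
}

setMethod("show", "Patch", function(object) {
  cat(sprintf("Patch %s @(%d, %d), %d px%s\n", object@slideId,
              object@origin[1], object@origin[2], dim(object@pixels)[1],
              if (is.null(object@mask)) "" else ", with mask"))
})
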