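#' Construct a SlideRecord
#'
#' @param slideId character identifier.
#' @param image numeric H x W x 3 array with values in 0-255.
#' @param mpp micrometers per pixel (> 0). By the 10x = 1.0 um/px
#'   convention, a 40x scan is about 0.25.
#' @param labelMask optional [LabelMask-class] matching the image; a slide
#'   is annotated exactly when one is present.
#' @param artifactMask optional binary 0/1 matrix marking pixels to exclude
#'   from pseudo-label training (e.g. external artifact detection output).
#' @return a [SlideRecord-class].
#' @export
SlideRecord <- function(slideId, image, mpp, labelMask = NULL,
                        artifactMask = NULL) {
  if (!is.null(artifactMask)) {
    storage.mode(artifactMask) <- "integer"
    if (!all(artifactMask %in% c(0L, 1L)))
      stop("artifactMask must be binary (0/1)")
  }
  new("SlideRecord",
      slideId = as.character(slideId),
      image = image, mpp = as.numeric(mpp),
      labelMask = labelMask, artifactMask = artifactMask,
      annotated = !is.null(labelMask))
}

#' @rdname SlideRecord
#' @param slide a [SlideRecord-class].
#' @export
slideId <- function(slide) slide@slideId

#' @rdname SlideRecord
#' @export
slideImage <- function(slide) slide@image

#' @rdname SlideRecord
#' @export
slideMpp <- function(slide) slide@mpp

#' @rdname SlideRecord
#' @export
labelMask <- function(slide) slide@labelMask

#' @rdname SlideRecord
#' @export
artifactMask <- function(slide) slide@artifactMask

#' @rdname SlideRecord
#' @export
isAnnotated <- function(slide) slide@annotated

setMethod("dim", "SlideRecord", function(x) dim(x@image))

setMethod("show", "SlideRecord", function(object) {
  d <- dim(object@image)
  cat(sprintf("SlideRecord '%s': %d x %d px, %.3g um/px, %s\n",
              object@slideId, d[1], d[2], object@mpp,
              if (object@annotated) "annotated" else "unlabeled"))
  if (!is.null(object@artifactMask))
    cat(sprintf("  artifact pixels: %d\n", sum(object@artifactMask)))
})

#' Rescale a slide to a target resolution
#'
#' Resamples the image by the factor \code{slideMpp(slide) / targetMpp}
#' using bilinear interpolation; label and artifact masks are resampled
#' with nearest-neighbour so no new codes are introduced. The returned
#' record carries \code{mpp = targetMpp}.
#'
#' @param slide a [SlideRecord-class].
#' @param targetMpp target micrometers per pixel (> 0). 1.0 corresponds to
#'   the 10x working magnification at which patches are extracted.
#' @return a rescaled [SlideRecord-class].
#' @examples
#' sc <- ClassScheme(c("background", "tumor"), 0:1, tumorCodes = 1L)
#' img <- array(127, c(8, 8, 3))
#' s <- SlideRecord("s1", img, mpp = 0.25)
#' dim(rescaleToTarget(s, 1.0))  # 2 x 2 x 3
#' @export
rescaleToTarget <- function(slide, targetMpp) {
  if (!is.numeric(targetMpp) || length(targetMpp) != 1L || targetMpp <= 0)
    stop("targetMpp must be a single positive number")
  if (slide@mpp == targetMpp) return(slide)
  d <- dim(slide@image)
  scale <- slide@mpp / targetMpp
  newH <- max(1L, as.integer(round(d[1L] * scale)))
  newW <- max(1L, as.integer(round(d[2L] * scale)))
  # EBImage resize maps its first argument's first dimension to `w`;
  # our rasters are row-major H x W, so pass w = newH, h = newW.
  img <- EBImage::resize(EBImage::Image(slide@image / 255, colormode = "Color"),
                         w = newH, h = newW, filter = "bilinear")
  img <- clamp255(round(as.array(img) * 255))
  dim(img) <- c(newH, newW, 3L)
  resampleNN <- function(m) {
    out <- EBImage::resize(EBImage::Image(m), w = newH, h = newW,
                           filter = "none")
    matrix(as.integer(round(as.array(out))), newH, newW)
  }
  lm <- slide@labelMask
  if (!is.null(lm)) lm <- LabelMask(resampleNN(lm@codes), lm@scheme)
  am <- slide@artifactMask
  if (!is.null(am)) am <- resampleNN(am)
  SlideRecord(slide@slideId, img, targetMpp, labelMask = lm,
              artifactMask = am)
}

#' Read / write a slide as PNG plus a JSON sidecar
#'
#' The raster goes to \code{<path>.png}; slide id, resolution and mask file
#' names go to \code{<path>.json}. Masks are written via
#' [writeLabelMask()] / read via [readLabelMask()].
#'
#' @param path base path without extension.
#' @param scheme [ClassScheme-class] used to validate any label mask.
#' @return \code{readSlide} returns a [SlideRecord-class];
#'   \code{writeSlide} returns \code{path} invisibly.
#' @export
readSlide <- function(path, scheme) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw <- png::readPNG(paste0(path, ".png"))
  img <- round(raw[, , 1:3] * 255)
  lm <- NULL
  if (isTRUE(meta$annotated))
    lm <- readLabelMask(file.path(dirname(path), meta$label_mask), scheme)
  am <- NULL
  if (!is.null(meta$artifact_mask) && !is.na(meta$artifact_mask)) {
    amRaw <- png::readPNG(file.path(dirname(path), meta$artifact_mask))
    if (length(dim(amRaw)) == 3L) amRaw <- amRaw[, , 1L]
    am <- matrix(as.integer(round(amRaw)), nrow(amRaw), ncol(amRaw))
  }
  SlideRecord(meta$slide_id, img, meta$mpp, labelMask = lm, artifactMask = am)
}

#' @rdname readSlide
#' @param slide a [SlideRecord-class].
#' @export
writeSlide <- function(slide, path) {
  png::writePNG(slide@image / 255, paste0(path, ".png"))
  base <- basename(path)
  maskFile <- NA_character_
  if (slide@annotated) {
    maskFile <- paste0(base, "_mask.png")
    writeLabelMask(slide@labelMask, file.path(dirname(path), maskFile))
  }
  artFile <- NA_character_
  if (!is.null(slide@artifactMask)) {
    artFile <- paste0(base, "_artifact.png")
    png::writePNG(slide@artifactMask + 0.0, file.path(dirname(path), artFile))
  }
  jsonlite::write_json(
    list(slide_id = slide@slideId, mpp = slide@mpp,
         annotated = slide@annotated, label_mask = maskFile,
         artifact_mask = artFile),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
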