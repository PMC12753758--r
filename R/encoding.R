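#' The built-in histogram/gradient patch encoder
#'
#' A deterministic, weight-free encoder used for tests and synthetic
#' cohorts: per-channel 8-bin intensity histograms (each normalized to sum
#' 1) concatenated with an 8-bin gradient-orientation histogram of the
#' luminance channel (magnitude-weighted, normalized; all-zero when the
#' patch has no gradient), giving d = 32. It is a pure function of the
#' pixel content. External foundation encoders plug in through
#' [externalEncoderAdapter()].
#'
#' @param inputSize expected patch edge in pixels (default 224, matching
#'   the tessellation used for similarity assessment at 10x).
#' @return an [EncoderSpec-class] with \code{encoderId = "hist32"}.
#' @examples
#' spec <- builtinEncoderSpec(8)
#' p <- array(255, c(8, 8, 3))
#' v <- spec@fun(p)  # uniform white patch: one-hot histograms, zero gradient
#' @export
builtinEncoderSpec <- function(inputSize = 224L) {
  new("EncoderSpec", encoderId = "hist32", inputSize = as.integer(inputSize),
      outputDim = 32L, fun = histGradEncode)
}

# d = 32 encoding of an H x W x 3 raster on the 0-255 scale.
histGradEncode <- function(px) {
  bins <- function(v) {
    b <- pmin(floor(v / 32), 7)
    h <- tabulate(b + 1L, nbins = 8L)
    h / sum(h)
  }
  colourPart <- c(bins(px[, , 1L]), bins(px[, , 2L]), bins(px[, , 3L]))
  lum <- luminance(px)
  h <- nrow(lum); w <- ncol(lum)
  gradPart <- numeric(8L)
  if (h >= 2L && w >= 2L) {
    # forward differences on the (h-1) x (w-1) interior grid
    gx <- lum[-h, -1L, drop = FALSE] - lum[-h, -w, drop = FALSE]
    gy <- lum[-1L, -w, drop = FALSE] - lum[-h, -w, drop = FALSE]
    mag <- sqrt(gx^2 + gy^2)
    tot <- sum(mag)
    if (tot > 0) {
      theta <- atan2(gy, gx) %% pi   # unsigned orientation in [0, pi)
      b <- pmin(floor(theta / (pi / 8)), 7)
      gradPart <- as.vector(tapply(mag, factor(b, levels = 0:7), sum))
      gradPart[is.na(gradPart)] <- 0
      gradPart <- gradPart / tot
    }
  }
  c(colourPart, gradPart)
}

#' Encode a single patch
#'
#' @param patch a [Patch-class].
#' @param spec an [EncoderSpec-class].
#' @param resize if TRUE, patches whose edge differs from
#'   \code{spec@inputSize} are bilinearly resized first; if FALSE (default)
#'   a size mismatch is an error.
#' @return numeric feature vector of length \code{spec@outputDim}.
#' @export
encodePatch <- function(patch, spec, resize = FALSE) {
  px <- patch@pixels
  if (dim(px)[1L] != spec@inputSize) {
    if (!resize)
      stop(sprintf("patch size %d does not match encoder input size %d",
                   dim(px)[1L], spec@inputSize))
    img <- EBImage::resize(EBImage::Image(px / 255, colormode = "Color"),
                           w = spec@inputSize, h = spec@inputSize,
                           filter = "bilinear")
    px <- clamp255(round(as.array(img) * 255))
    dim(px) <- c(spec@inputSize, spec@inputSize, 3L)
  }
  v <- spec@fun(px)
  if (length(v) != spec@outputDim || any(!is.finite(v)))
    stop(sprintf("encoder '%s' returned an invalid vector", spec@encoderId))
  as.numeric(v)
}

#' Encode a list of patches from one slide into a FeatureSet
#'
#' @param patches non-empty list of [Patch-class] from a single slide.
#' @inheritParams encodePatch
#' @return a [FeatureSet-class]; row i encodes patch i, order preserved.
#' @export
encodePatches <- function(patches, spec, resize = FALSE) {
  if (length(patches) == 0L)
    stop("no tumor patches available to encode")
  ids <- unique(vapply(patches, function(p) p@slideId, character(1)))
  if (length(ids) != 1L)
    stop("patches must come from a single slide; got: ",
         paste(ids, collapse = ", "))
  vectors <- t(vapply(patches, encodePatch, numeric(spec@outputDim),
                      spec = spec, resize = resize))
  refs <- t(vapply(patches, function(p) p@origin, integer(2)))
  colnames(refs) <- c("x0", "y0")
  new("FeatureSet", slideId = ids, vectors = vectors, patchRefs = refs,
      encoderId = spec@encoderId)
}

#' Register an external encoder behind the encoding contract
#'
#' Wraps a callable mapping an \code{inputSize x inputSize x 3} raster
#' (0-255) to a length-d numeric vector, e.g. a bridge to a foundation
#' encoder. At registration the callable is probed for output length and
#' determinism (same pixels encoded twice must give identical vectors);
#' a failing probe is an error.
#'
#' @param fun the encoding callable.
#' @param encoderId identifier for the adapter.
#' @param inputSize patch edge the callable expects.
#' @param outputDim feature dimension the callable must return.
#' @return an [EncoderSpec-class] usable anywhere the built-in encoder is.
#' @examples
#' # identity adapter over the built-in encoder
#' spec <- externalEncoderAdapter(builtinEncoderSpec(8)@fun, "mirror", 8, 32)
#' @export
externalEncoderAdapter <- function(fun, encoderId, inputSize, outputDim) {
  inputSize <- as.integer(inputSize)
  outputDim <- as.integer(outputDim)
  probeA <- array(rep(c(0, 128, 255), each = inputSize * inputSize),
                  c(inputSize, inputSize, 3L))
  probeB <- array(seq(0, 255, length.out = inputSize * inputSize * 3L),
                  c(inputSize, inputSize, 3L))
  for (probe in list(probeA, probeB)) {
    v1 <- fun(probe)
    if (!is.numeric(v1) || length(v1) != outputDim)
      stop(sprintf(
        "encoder '%s' returned length %d, expected %d", encoderId,
        length(v1), outputDim))
    if (any(!is.finite(v1)))
      stop(sprintf("encoder '%s' returned non-finite values", encoderId))
    v2 <- fun(probe)
    if (!identical(v1, v2))
      stop(sprintf("encoder '%s' failed the determinism probe", encoderId))
  }
  new("EncoderSpec", encoderId = encoderId, inputSize = inputSize,
      outputDim = outputDim, fun = function(px) as.numeric(fun(px)))
}

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet '%s': %d patches x d=%d (encoder %s)\n",
              object@slideId, nrow(object@vectors), ncol(object@vectors),
              object@encoderId))
})

#' Persist / load a FeatureSet cache
#'
#' Vectors and patch origins are written as TSV next to a JSON header
#' carrying the slide id, encoder id and dimension. On load the cache is
#' rejected (returns NULL) when the stored encoder id differs from
#' \code{expectEncoderId}.
#'
#' @param fs a [FeatureSet-class].
#' @param path base path without extension.
#' @param expectEncoderId encoder id the cache must match; mismatches
#'   invalidate the cache.
#' @return \code{readFeatureSet} returns a [FeatureSet-class] or NULL.
#' @export
writeFeatureSet <- function(fs, path) {
  utils::write.table(fs@vectors, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fs@patchRefs, paste0(path, ".refs.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(slide_id = fs@slideId, encoder_id = fs@encoderId,
         d = ncol(fs@vectors), n = nrow(fs@vectors)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureSet
#' @export
readFeatureSet <- function(path, expectEncoderId = NULL) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(expectEncoderId) && !identical(hdr$encoder_id, expectEncoderId))
    return(NULL)
  vectors <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  dimnames(vectors) <- NULL
  refs <- as.matrix(utils::read.table(paste0(path, ".refs.tsv"), sep = "\t"))
  dimnames(refs) <- NULL
  storage.mode(refs) <- "integer"
  colnames(refs) <- c("x0", "y0")
  new("FeatureSet", slideId = hdr$slide_id, vectors = vectors,
      patchRefs = refs, encoderId = hdr$encoder_id)
}
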