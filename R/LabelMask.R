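#' Construct a LabelMask
#'
#' @param codes integer matrix of per-pixel class codes.
#' @param scheme the [ClassScheme-class] the codes belong to. Every value
#'   must be one of the scheme's codes or its ignore code.
#' @return a [LabelMask-class].
#' @examples
#' sc <- ClassScheme(c("background", "tumor"), 0:1, tumorCodes = 1L)
#' m <- LabelMask(matrix(0:1, 2, 2), sc)
#' @export
LabelMask <- function(codes, scheme) {
  storage.mode(codes) <- "integer"
  new("LabelMask", codes = codes, scheme = scheme)
}

#' @rdname LabelMask
#' @param mask a [LabelMask-class].
#' @export
maskCodes <- function(mask) mask@codes

#' @rdname LabelMask
#' @export
maskScheme <- function(mask) mask@scheme

setMethod("dim", "LabelMask", function(x) dim(x@codes))

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@codes)
  tab <- table(factor(object@codes,
                      levels = c(object@scheme@codes, object@scheme@ignoreCode)))
  present <- tab[tab > 0]
  cat(sprintf("LabelMask %d x %d\n", d[1], d[2]))
  cat("  codes present:",
      paste(sprintf("%s(%d)", names(present), as.integer(present)),
            collapse = " "), "\n")
})

#' Read / write a label mask as a single-channel 8-bit PNG
#'
#' Round trips are byte exact: the integer codes are stored directly in the
#' 8-bit channel. On read, any value outside the scheme's codes and ignore
#' code is an error naming the offending code(s).
#'
#' @param path PNG file path.
#' @param scheme [ClassScheme-class] used to validate the codes.
#' @return \code{readLabelMask} returns a [LabelMask-class];
#'   \code{writeLabelMask} returns \code{path} invisibly.
#' @export
readLabelMask <- function(path, scheme) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] > 1L && !all(raw[, , 1L] == raw[, , -1L]))
      stop("label mask must be a single-channel raster: ", path)
    raw <- raw[, , 1L]
  }
  codes <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  bad <- setdiff(unique(as.vector(codes)),
                 c(scheme@codes, scheme@ignoreCode))
  if (length(bad))
    stop("mask contains codes outside the scheme: ",
         paste(sort(bad), collapse = ", "), " (", path, ")")
  LabelMask(codes, scheme)
}

#' @rdname readLabelMask
#' @param mask a [LabelMask-class].
#' @export
writeLabelMask <- function(mask, path) {
  codes <- mask@codes
  if (min(codes) < 0L || max(codes) > 255L)
    stop("mask codes must fit an 8-bit raster (0-255)")
  png::writePNG(codes / 255, path)
  invisible(path)
}
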