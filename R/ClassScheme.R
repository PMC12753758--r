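#' Construct a ClassScheme
#'
#' @param labels ordered character vector of class names.
#' @param codes integer codes, one per label.
#' @param tumorCodes integer subset of \code{codes} treated as tumor and
#'   tumor stroma (routed through the matched expert during pseudo-label
#'   fusion).
#' @param ignoreCode integer code excluded from training and scoring
#'   (default 255, the convention for 8-bit mask rasters).
#' @return a [ClassScheme-class] object.
#' @examples
#' sc <- ClassScheme(c("background", "tumor", "stroma"), 0:2, tumorCodes = 1:2)
#' schemeCodes(sc)
#' @export
ClassScheme <- function(labels, codes, tumorCodes = integer(), ignoreCode = 255L) {
  new("ClassScheme",
      labels = as.character(labels),
      codes = as.integer(codes),
      tumorCodes = as.integer(tumorCodes),
      ignoreCode = as.integer(ignoreCode))
}

#' The default 12-code colorectal tissue scheme
#'
#' Eleven annotated histological classes (tumor, tumor stroma, benign
#' mucosa, submucosa, smooth muscle, adventitia, vessels, lymphoid,
#' ulceration/necrosis, mucin, bleeding) plus slide background. Tumor and
#' tumor stroma form the tumor-code set.
#'
#' @return a [ClassScheme-class].
#' @examples
#' defaultClassScheme()
#' @export
defaultClassScheme <- function() {
  labels <- c("background", "tumor", "tumor_stroma", "benign_mucosa",
              "submucosa", "smooth_muscle", "adventitia", "vessels",
              "lymphoid", "ulceration_necrosis", "mucin", "bleeding")
  ClassScheme(labels, seq_along(labels) - 1L, tumorCodes = c(1L, 2L),
              ignoreCode = 255L)
}

#' @rdname ClassScheme
#' @param scheme a [ClassScheme-class].
#' @export
schemeLabels <- function(scheme) scheme@labels

#' @rdname ClassScheme
#' @export
schemeCodes <- function(scheme) {
  stats::setNames(scheme@codes, scheme@labels)
}

#' @rdname ClassScheme
#' @export
tumorCodes <- function(scheme) scheme@tumorCodes

#' @rdname ClassScheme
#' @export
ignoreCode <- function(scheme) scheme@ignoreCode

#' Look up the code of a class label
#'
#' @param scheme a [ClassScheme-class].
#' @param label class name.
#' @return integer code.
#' @export
codeOf <- function(scheme, label) {
  i <- match(label, scheme@labels)
  if (anyNA(i))
    stop("unknown class label(s): ", paste(label[is.na(i)], collapse = ", "))
  scheme@codes[i]
}

# Background code: the code of the "background" label when present,
# otherwise NA (callers fall back to treating every class as foreground).
backgroundCode <- function(scheme) {
  i <- match("background", scheme@labels)
  if (is.na(i)) NA_integer_ else scheme@codes[i]
}

#' Read / write a ClassScheme as JSON
#'
#' @param path file path.
#' @return \code{readClassScheme} returns a [ClassScheme-class];
#'   \code{writeClassScheme} returns \code{path} invisibly.
#' @export
readClassScheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ClassScheme(x$labels, x$codes, x$tumor_codes, x$ignore_code)
}

#' @rdname readClassScheme
#' @param scheme a [ClassScheme-class].
#' @export
writeClassScheme <- function(scheme, path) {
  jsonlite::write_json(
    list(labels = scheme@labels, codes = scheme@codes,
         tumor_codes = scheme@tumorCodes, ignore_code = scheme@ignoreCode),
    path, auto_unbox = FALSE)
  invisible(path)
}

setMethod("show", "ClassScheme", function(object) {
  cat("ClassScheme with", length(object@labels), "classes\n")
  cat("  codes:", paste(sprintf("%s=%d", object@labels, object@codes),
                        collapse = ", "), "\n")
  cat("  tumorCodes:", paste(object@tumorCodes, collapse = ", "),
      " ignoreCode:", object@ignoreCode, "\n")
})
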