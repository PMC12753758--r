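#' Fuse expert and supervised predictions with tumor precedence
#'
#' Per pixel: where the expert predicts a tumor or tumor-stroma code, the
#' expert's code wins; everywhere else the supervised model's code is
#' taken. No confidence values are consulted anywhere — fusion depends
#' only on the predicted codes.
#'
#' @param expertMask,supervisedMask [LabelMask-class] objects of the same
#'   shape over the same scheme.
#' @param tumorCodes integer codes with expert precedence; defaults to the
#'   scheme's tumor codes.
#' @return the fused [LabelMask-class].
#' @examples
#' sc <- ClassScheme(c("bg", "tumor", "stroma", "mucosa", "vessel"),
#'                   0:4, tumorCodes = 1:2)
#' ex <- LabelMask(matrix(c(1L, 0L, 2L, 0L), 2), sc)
#' su <- LabelMask(matrix(c(3L, 3L, 3L, 4L), 2), sc)
#' maskCodes(fuseMasks(ex, su))  # [1, 2; 3, 4]
#' @export
fuseMasks <- function(expertMask, supervisedMask,
                      tumorCodes = expertMask@scheme@tumorCodes) {
  if (!identical(dim(expertMask@codes), dim(supervisedMask@codes)))
    stop("expert and supervised masks differ in shape")
  e <- expertMask@codes
  s <- supervisedMask@codes
  useExpert <- matrix(e %in% tumorCodes, nrow(e))
  out <- s
  out[useExpert] <- e[useExpert]
  LabelMask(out, expertMask@scheme)
}

#' Blank out artifact pixels
#'
#' Sets pixels flagged in the binary artifact mask to the scheme's ignore
#' code; all other pixels are unchanged. Idempotent.
#'
#' @param mask a [LabelMask-class].
#' @param artifact binary 0/1 matrix of the same shape (e.g. produced by
#'   an external slide quality-control tool).
#' @return the cleaned [LabelMask-class].
#' @export
applyArtifactMask <- function(mask, artifact) {
  if (is.null(artifact)) return(mask)
  if (!identical(dim(mask@codes), dim(artifact)))
    stop("artifact mask shape does not match the label mask")
  out <- mask@codes
  out[artifact == 1L] <- mask@scheme@ignoreCode
  LabelMask(out, mask@scheme)
}

# Shared pseudo-labeling core: predicts both channels on no-overlap tiles,
# fuses with expert precedence, removes artifacts, records provenance.
# The traditional-SSL baseline is this same path with expert := supervised.
pseudolabelWithExpert <- function(slide, expertModel, supervisedModel,
                                  patchSize, matchedExpert, similarity) {
  expertMask <- predictSlideMask(expertModel, slide, patchSize, patchSize)
  supervisedMask <-
    if (identical(expertModel@modelId, supervisedModel@modelId)) expertMask
    else predictSlideMask(supervisedModel, slide, patchSize, patchSize)
  fused <- fuseMasks(expertMask, supervisedMask)
  cleaned <- applyArtifactMask(fused, slide@artifactMask)
  prov <- matrix(2L, nrow(cleaned@codes), ncol(cleaned@codes))
  prov[matrix(expertMask@codes %in% expertMask@scheme@tumorCodes,
              nrow(prov))] <- 1L
  prov[cleaned@codes == cleaned@scheme@ignoreCode] <- 0L
  new("PseudoLabelResult", slideId = slide@slideId, mask = cleaned,
      matchedExpert = matchedExpert, similarity = similarity,
      provenance = prov)
}

#' Generate the fused pseudo-label mask for an unlabeled slide
#'
#' Selects the morphology expert via [matchExpert()], predicts the slide
#' with both the expert and the supervised model on no-overlap tiles,
#' fuses with tumor/stroma precedence, and blanks artifact pixels to the
#' ignore code. Pixel provenance (expert / supervised / ignore) is
#' recorded on the result.
#'
#' @param slide an unlabeled [SlideRecord-class] present among the
#'   similarity matrix queries.
#' @param pool an [ExpertPool-class] with experts and a supervised model.
#' @param matrix the [SimilarityMatrix-class] from
#'   [buildSimilarityMatrix()].
#' @param patchSize prediction tile size (unlabeled slides tile without
#'   overlap).
#' @return a [PseudoLabelResult-class].
#' @export
generatePseudolabels <- function(slide, pool, matrix, patchSize = 512L) {
  if (slide@annotated)
    stop("slide '", slide@slideId, "' is annotated; pseudo-labels are for ",
         "unlabeled slides")
  if (!slide@slideId %in% matrix@queryIds)
    stop("slide '", slide@slideId, "' is not in the similarity matrix; ",
         "run the similarity stage first")
  if (is.null(pool@supervised))
    stop("expert pool carries no supervised model")
  matched <- matchExpert(matrix, slide@slideId)
  sim <- matrix@values[match(slide@slideId, matrix@queryIds),
                       match(matched, matrix@annotatedIds)]
  pseudolabelWithExpert(slide, pool@experts[[matched]], pool@supervised,
                        patchSize, matched, sim)
}

setMethod("show", "PseudoLabelResult", function(object) {
  cat(sprintf("PseudoLabelResult '%s': expert %s (similarity %.4f)\n",
              object@slideId, object@matchedExpert, object@similarity))
  cat(sprintf("  pixels from expert: %d, supervised: %d, ignored: %d\n",
              sum(object@provenance == 1L), sum(object@provenance == 2L),
              sum(object@provenance == 0L)))
})

#' Assemble the combined labeled + pseudo-labeled training set
#'
#' Annotated slides are tiled with the overlap regime, pseudo-labeled
#' slides without overlap; patches whose mask is entirely the ignore code
#' (e.g. fully-artifact regions) are dropped.
#'
#' @param annotated list of annotated [SlideRecord-class].
#' @param pseudo list of [PseudoLabelResult-class] with matching
#'   [SlideRecord-class] in \code{unlabeled}.
#' @param unlabeled list of the unlabeled [SlideRecord-class] the results
#'   refer to.
#' @param patchSize training patch size.
#' @param annotatedStride stride for annotated slides (default overlap of
#'   a quarter patch, i.e. 384 at patch 512).
#' @return non-empty list of [Patch-class] with masks.
#' @export
assembleSslDataset <- function(annotated, pseudo, unlabeled,
                               patchSize = 512L,
                               annotatedStride = patchSize -
                                 as.integer(round(patchSize / 4))) {
  out <- list()
  for (s in annotated)
    out <- c(out, tileSlide(s, patchSize, annotatedStride, withMask = TRUE))
  ids <- vapply(unlabeled, function(s) s@slideId, character(1))
  for (p in pseudo) {
    i <- match(p@slideId, ids)
    if (is.na(i)) stop("no SlideRecord for pseudo-labeled slide '",
                       p@slideId, "'")
    out <- c(out, tileSlide(unlabeled[[i]], patchSize, patchSize,
                            mask = p@mask))
  }
  ignore <- if (length(out)) out[[1L]]@mask@scheme@ignoreCode else 255L
  out <- Filter(function(p) any(p@mask@codes != ignore), out)
  if (!length(out))
    stop("assembled dataset is empty (all patches fully ignored)")
  out
}

#' Write a pseudo-label result to disk
#'
#' Mask and provenance go out as single-channel PNGs, plus a JSON report
#' (matched expert, similarity, per-class pixel counts).
#'
#' @param result a [PseudoLabelResult-class].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writePseudoLabelResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, result@slideId)
  writeLabelMask(result@mask, paste0(base, "_pseudo.png"))
  png::writePNG(result@provenance / 255, paste0(base, "_provenance.png"))
  counts <- table(result@mask@codes)
  jsonlite::write_json(
    list(slide_id = result@slideId, matched_expert = result@matchedExpert,
         similarity = result@similarity,
         pixel_counts = as.list(stats::setNames(as.numeric(counts),
                                                names(counts)))),
    paste0(base, "_pseudo.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
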