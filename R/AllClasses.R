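#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ClassScheme: the tissue class dictionary
#'
#' Maps ordered class labels to integer pixel codes, designates which codes
#' count as tumor / tumor stroma (the classes routed through the matched
#' morphology expert), and fixes the ignore code excluded from training and
#' scoring.
#'
#' @slot labels ordered character vector of class names.
#' @slot codes integer vector, one code per label.
#' @slot tumorCodes integer subset of \code{codes} treated as tumor and
#'   tumor stroma.
#' @slot ignoreCode integer code excluded from loss and scoring; must not
#'   collide with \code{codes}.
#' @seealso [defaultClassScheme()]
#' @exportClass ClassScheme
setClass("ClassScheme",
  slots = c(
    labels = "character",
    codes = "integer",
    tumorCodes = "integer",
    ignoreCode = "integer"
  )
)

setValidity("ClassScheme", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@codes))
    msg <- c(msg, "labels and codes must have equal length")
  if (anyDuplicated(object@codes))
    msg <- c(msg, "codes must be unique")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "labels must be unique")
  if (!all(object@tumorCodes %in% object@codes))
    msg <- c(msg, "tumorCodes must be a subset of codes")
  if (object@ignoreCode %in% object@codes)
    msg <- c(msg, "ignoreCode must not be one of the class codes")
  if (length(msg)) msg else TRUE
})

#' LabelMask: per-pixel integer class codes
#'
#' An H x W integer grid whose values are drawn from a [ClassScheme]'s codes
#' plus its ignore code. The unit of annotation, pseudo-labels and
#' evaluation.
#'
#' @slot codes integer matrix of pixel codes.
#' @slot scheme the [ClassScheme] the codes refer to.
#' @exportClass LabelMask
setClass("LabelMask",
  slots = c(codes = "matrix", scheme = "ClassScheme")
)

setValidity("LabelMask", function(object) {
  v <- object@codes
  if (!is.numeric(v)) return("codes must be a numeric/integer matrix")
  allowed <- c(object@scheme@codes, object@scheme@ignoreCode)
  bad <- setdiff(unique(as.vector(v)), allowed)
  if (length(bad))
    return(sprintf("mask contains codes outside the scheme: %s",
                   paste(sort(bad), collapse = ", ")))
  TRUE
})

setClassUnion("LabelMaskOrNULL", c("LabelMask", "NULL"))

#' SlideRecord: one slide's raster and metadata
#'
#' Holds a whole-slide-scale RGB raster (H x W x 3, values 0-255), its
#' physical resolution in micrometers per pixel, and optional label /
#' artifact masks. A slide is annotated exactly when it carries a label
#' mask.
#'
#' @slot slideId character identifier.
#' @slot image numeric array H x W x 3 with values in 0-255.
#' @slot mpp micrometers per pixel, > 0.
#' @slot labelMask optional [LabelMask] matching the image dimensions.
#' @slot artifactMask optional binary (0/1) matrix matching the image.
#' @slot annotated logical; TRUE iff \code{labelMask} is present.
#' @exportClass SlideRecord
setClass("SlideRecord",
  slots = c(
    slideId = "character",
    image = "array",
    mpp = "numeric",
    labelMask = "LabelMaskOrNULL",
    artifactMask = "matrixOrNULL",
    annotated = "logical"
  )
)

setValidity("SlideRecord", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3L] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (!is.numeric(object@mpp) || length(object@mpp) != 1L || object@mpp <= 0)
    msg <- c(msg, "mpp must be a single positive number")
  if (!is.null(object@labelMask) &&
      !identical(dim(object@labelMask@codes), d[1:2]))
    msg <- c(msg, "labelMask dimensions must match the image")
  if (!is.null(object@artifactMask) &&
      !identical(dim(object@artifactMask), d[1:2]))
    msg <- c(msg, "artifactMask dimensions must match the image")
  if (object@annotated != !is.null(object@labelMask))
    msg <- c(msg, "annotated must be TRUE exactly when a labelMask is present")
  if (length(msg)) msg else TRUE
})

#' TileGrid: deterministic tiling of a slide
#'
#' Stores the patch size, stride and the list of 0-based (x0, y0) top-left
#' tile origins covering an image; tiles are half-open
#' \code{[x0, x0+patch) x [y0, y0+patch)}.
#'
#' @slot patchSize tile edge in pixels.
#' @slot stride step between tile starts in pixels.
#' @slot origins integer matrix with columns \code{x0}, \code{y0}, sorted
#'   row-major.
#' @exportClass TileGrid
setClass("TileGrid",
  slots = c(patchSize = "integer", stride = "integer", origins = "matrix")
)

#' Patch: one tile cut from a slide
#'
#' @slot slideId source slide identifier.
#' @slot origin integer (x0, y0), 0-based top-left corner on the slide.
#' @slot pixels patch raster, patchSize x patchSize x 3.
#' @slot mask optional [LabelMask] crop aligned with \code{pixels}.
#' @exportClass Patch
setClass("Patch",
  slots = c(
    slideId = "character",
    origin = "integer",
    pixels = "array",
    mask = "LabelMaskOrNULL"
  )
)

setValidity("Patch", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3L] != 3L || d[1L] != d[2L])
    return("pixels must be a square H x H x 3 array")
  if (!is.null(object@mask) && !identical(dim(object@mask@codes), d[1:2]))
    return("mask must align with pixels")
  TRUE
})

#' EncoderSpec: the patch-to-feature-vector contract
#'
#' @slot encoderId identifier, also used to key feature caches.
#' @slot inputSize expected patch edge in pixels.
#' @slot outputDim feature dimension d.
#' @slot fun function mapping an inputSize x inputSize x 3 raster (0-255)
#'   to a length-d numeric vector; must be a pure function of the pixels.
#' @exportClass EncoderSpec
setClass("EncoderSpec",
  slots = c(
    encoderId = "character",
    inputSize = "integer",
    outputDim = "integer",
    fun = "function"
  )
)

setValidity("EncoderSpec", function(object) {
  if (object@inputSize <= 0L) return("inputSize must be > 0")
  if (object@outputDim <= 0L) return("outputDim must be > 0")
  TRUE
})

#' FeatureSet: per-slide patch embeddings
#'
#' @slot slideId source slide.
#' @slot vectors n x d numeric matrix; row i embeds patch i.
#' @slot patchRefs n x 2 integer matrix of patch origins (x0, y0).
#' @slot encoderId encoder that produced the vectors.
#' @exportClass FeatureSet
setClass("FeatureSet",
  slots = c(
    slideId = "character",
    vectors = "matrix",
    patchRefs = "matrix",
    encoderId = "character"
  )
)

setValidity("FeatureSet", function(object) {
  if (nrow(object@vectors) != nrow(object@patchRefs))
    return("vectors and patchRefs must have the same number of rows")
  if (nrow(object@vectors) > 0L && any(!is.finite(object@vectors)))
    return("feature vectors must be finite")
  TRUE
})

#' RepresentativeSet: centroid-nearest exemplar embeddings of one slide
#'
#' The k feature vectors closest to the K-means centroids of a slide's
#' tumor-patch embeddings; every row is an exact member of the source
#' [FeatureSet].
#'
#' @slot slideId source slide.
#' @slot vectors kEff x d matrix of exemplar embeddings.
#' @slot sourceRefs kEff x 2 matrix of the exemplar patch origins.
#' @exportClass RepresentativeSet
setClass("RepresentativeSet",
  slots = c(slideId = "character", vectors = "matrix", sourceRefs = "matrix")
)

#' SimilarityMatrix: slide-level similarity grid
#'
#' Rows are query (unlabeled) slides, columns annotated slides; entry (q, a)
#' is the mean pairwise similarity between the two slides' representative
#' sets under \code{metric}.
#'
#' @slot annotatedIds ordered annotated slide ids (columns).
#' @slot queryIds ordered query slide ids (rows).
#' @slot values numeric |queries| x |annotated| grid, complete.
#' @slot metric one of \code{"cosine"}, \code{"neg_L1"}, \code{"neg_L2"}.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  slots = c(
    annotatedIds = "character",
    queryIds = "character",
    values = "matrix",
    metric = "character"
  )
)

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@values),
                 c(length(object@queryIds), length(object@annotatedIds))))
    msg <- c(msg, "values must be |queries| x |annotated|")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "similarity grid must be complete and finite")
  if (object@metric == "cosine" &&
      nrow(object@values) > 0 &&
      (min(object@values) < -1 - 1e-9 || max(object@values) > 1 + 1e-9))
    msg <- c(msg, "cosine similarities must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' SimilarityConfig: parameters of the similarity engine
#'
#' @slot tumorContentThreshold fraction in (0, 1); a patch is a tumor patch
#'   when its tumor content is strictly greater than this (default 0.60).
#' @slot kRepresentatives number of K-means representatives per slide
#'   (default 5).
#' @slot metric similarity metric; distances are negated so that most
#'   similar is always arg-max.
#' @slot kmeansSeed seed for the K-means restarts.
#' @slot kmeansRestarts number of k-means++ restarts (default 10).
#' @exportClass SimilarityConfig
setClass("SimilarityConfig",
  slots = c(
    tumorContentThreshold = "numeric",
    kRepresentatives = "integer",
    metric = "character",
    kmeansSeed = "integer",
    kmeansRestarts = "integer"
  )
)

setValidity("SimilarityConfig", function(object) {
  msg <- character()
  if (object@tumorContentThreshold <= 0 || object@tumorContentThreshold >= 1)
    msg <- c(msg, "tumorContentThreshold must lie strictly in (0, 1)")
  if (object@kRepresentatives < 1L)
    msg <- c(msg, "kRepresentatives must be >= 1")
  if (!object@metric %in% c("cosine", "neg_L1", "neg_L2"))
    msg <- c(msg, "metric must be one of cosine, neg_L1, neg_L2")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: training hyper-parameters for a segmentation role
#'
#' Defaults follow the convention of 36 epochs without early stopping, a
#' step-decay learning-rate schedule with step size 10, an adaptive-moment
#' optimizer, and a 90/10 train/validation split; the checkpoint with the
#' best validation score is kept.
#'
#' @slot epochs number of epochs (default 36).
#' @slot lr initial learning rate (used by iterative backends).
#' @slot lrStepSize epochs between learning-rate decays (default 10).
#' @slot lrGamma multiplicative decay factor (default 0.1).
#' @slot valFraction fraction of patches held out for validation
#'   (default 0.10).
#' @slot splitSeed seed of the deterministic split shuffle.
#' @slot classWeights optional named numeric vector of per-code weights;
#'   computed from the training label histogram when empty.
#' @slot backendId segmentation backend identifier (see [getBackend()]).
#' @slot backendParams backend-specific parameter list.
#' @slot initCheckpointId token naming the shared initialization checkpoint;
#'   all experts in a pool share it.
#' @slot optimizer optimizer name (informational for toy backends).
#' @exportClass TrainConfig
setClass("TrainConfig",
  slots = c(
    epochs = "integer",
    lr = "numeric",
    lrStepSize = "integer",
    lrGamma = "numeric",
    valFraction = "numeric",
    splitSeed = "integer",
    classWeights = "numeric",
    backendId = "character",
    backendParams = "list",
    initCheckpointId = "character",
    optimizer = "character"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must lie strictly in (0, 1)")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (length(object@classWeights) && any(object@classWeights <= 0))
    msg <- c(msg, "classWeights must be positive")
  if (length(msg)) msg else TRUE
})

#' ModelHandle: a trained segmentation model plus its provenance
#'
#' @slot modelId identifier.
#' @slot role one of \code{"expert"}, \code{"supervised"},
#'   \code{"tumor_locator"}, \code{"ssl_final"}.
#' @slot sourceSlides slide ids the model was trained on; an expert has
#'   exactly one.
#' @slot bestValScore best validation score over epochs (mean foreground
#'   Dice).
#' @slot epochScores per-epoch validation scores.
#' @slot state backend state of the best checkpoint.
#' @slot backendId backend that produced the state.
#' @slot initCheckpointId shared initialization token.
#' @slot scheme the [ClassScheme] the model predicts over.
#' @exportClass ModelHandle
setClass("ModelHandle",
  slots = c(
    modelId = "character",
    role = "character",
    sourceSlides = "character",
    bestValScore = "numeric",
    epochScores = "numeric",
    state = "list",
    backendId = "character",
    initCheckpointId = "character",
    scheme = "ClassScheme"
  )
)

setValidity("ModelHandle", function(object) {
  msg <- character()
  if (!object@role %in% c("expert", "supervised", "tumor_locator", "ssl_final"))
    msg <- c(msg, "unknown role")
  if (object@role == "expert" && length(object@sourceSlides) != 1L)
    msg <- c(msg, "an expert must have exactly one source slide")
  if (length(msg)) msg else TRUE
})

setClassUnion("ModelHandleOrNULL", c("ModelHandle", "NULL"))

#' ExpertPool: the swarm of per-case experts plus shared models
#'
#' @slot experts named list of expert [ModelHandle]s, keyed by annotated
#'   slide id.
#' @slot supervised the pooled supervised model (or NULL until trained).
#' @slot tumorLocator the 3-class tumor/non-tumor/background locator used to
#'   harvest tumor patches on unlabeled slides (or NULL).
#' @exportClass ExpertPool
setClass("ExpertPool",
  slots = c(
    experts = "list",
    supervised = "ModelHandleOrNULL",
    tumorLocator = "ModelHandleOrNULL"
  )
)

setValidity("ExpertPool", function(object) {
  msg <- character()
  if (length(object@experts)) {
    ok <- vapply(object@experts, function(e)
      is(e, "ModelHandle") && e@role == "expert" &&
        length(e@sourceSlides) == 1L, logical(1))
    if (!all(ok)) msg <- c(msg, "experts must be expert ModelHandles")
    keys <- names(object@experts)
    src <- vapply(object@experts, function(e) e@sourceSlides, character(1))
    if (!identical(unname(keys), unname(src)))
      msg <- c(msg, "expert keys must equal their source slide ids")
    init <- unique(vapply(object@experts, function(e) e@initCheckpointId,
                          character(1)))
    if (length(init) > 1L)
      msg <- c(msg, "all experts must share the same initCheckpointId")
  }
  if (length(msg)) msg else TRUE
})

#' PseudoLabelResult: fused pseudo-label mask for one unlabeled slide
#'
#' @slot slideId the pseudo-labeled slide.
#' @slot mask fused [LabelMask] (expert tumor/stroma with precedence,
#'   supervised elsewhere, artifacts set to the ignore code).
#' @slot matchedExpert annotated slide id whose expert supplied the
#'   tumor/stroma channel.
#' @slot similarity similarity of the slide to the matched expert's case.
#' @slot provenance integer matrix: 1 where the mask value came from the
#'   expert, 2 where from the supervised model, 0 where ignored.
#' @exportClass PseudoLabelResult
setClass("PseudoLabelResult",
  slots = c(
    slideId = "character",
    mask = "LabelMask",
    matchedExpert = "character",
    similarity = "numeric",
    provenance = "matrix"
  )
)
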