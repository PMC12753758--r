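#' Tiling configuration for the pipeline stages
#'
#' Defaults reproduce the two extraction regimes at 10x working
#' magnification: 512-pixel training patches with 128-pixel overlap on
#' annotated slides and no overlap on unlabeled slides, plus 224-pixel
#' tessellation for similarity assessment and the tumor locator. Tests
#' and synthetic cohorts scale everything down proportionally.
#'
#' @param patchSize training patch edge (default 512).
#' @param annotatedOverlap overlap between annotated-slide tiles
#'   (default 128; stride = patchSize - overlap). Unlabeled slides always
#'   tile without overlap.
#' @param similarityPatchSize patch edge for similarity assessment
#'   (default 224).
#' @param locatorPatchSize patch edge for the tumor locator (default 224).
#' @return a named list of tiling parameters including the derived
#'   \code{annotatedStride}.
#' @export
tilingConfig <- function(patchSize = 512L, annotatedOverlap = 128L,
                         similarityPatchSize = 224L,
                         locatorPatchSize = similarityPatchSize) {
  patchSize <- as.integer(patchSize)
  annotatedOverlap <- as.integer(annotatedOverlap)
  if (annotatedOverlap < 0L || annotatedOverlap >= patchSize)
    stop("annotatedOverlap must lie in [0, patchSize)")
  list(patchSize = patchSize,
       annotatedStride = patchSize - annotatedOverlap,
       similarityPatchSize = as.integer(similarityPatchSize),
       locatorPatchSize = as.integer(locatorPatchSize))
}

# Harvest tumor-patch representative sets for the similarity stage.
# Annotated slides filter by their ground-truth masks; unlabeled slides by
# the tumor locator's predicted 3-class mask. Both sides use the same
# strict tumor definition (the locator's tumor class).
harvestRepresentatives <- function(slides, cfg, simCfg, tiling, encoderSpec,
                                   locator = NULL, includeStroma = FALSE) {
  out <- vector("list", length(slides))
  for (i in seq_along(slides)) {
    slide <- slides[[i]]
    if (is.null(locator)) {
      scheme <- slide@labelMask@scheme
      harvestCodes <- if (includeStroma) scheme@tumorCodes
                      else scheme@tumorCodes[1L]
      patches <- tileSlide(slide, tiling$similarityPatchSize,
                           tiling$similarityPatchSize, withMask = TRUE)
    } else {
      harvestCodes <- tumorCodes(locator@scheme)
      locMask <- predictSlideMask(locator, slide, tiling$locatorPatchSize)
      patches <- tileSlide(slide, tiling$similarityPatchSize,
                           tiling$similarityPatchSize, mask = locMask)
    }
    kept <- filterTumorPatches(patches, simCfg, harvestCodes)
    if (!length(kept))
      stop("slide '", slide@slideId, "' has no patches above the ",
           sprintf("%.0f%%", 100 * simCfg@tumorContentThreshold),
           " tumor-content threshold")
    fs <- encodePatches(kept, encoderSpec)
    slideSim <- simCfg
    slideSim@kmeansSeed <- deriveSeed(simCfg@kmeansSeed, slide@slideId)
    out[[i]] <- selectRepresentatives(fs, slideSim)
  }
  out
}

#' Run one training paradigm end to end
#'
#' The three paradigms: \code{"supervised"} trains only the pooled
#' supervised model; \code{"traditional_ssl"} additionally pseudo-labels
#' every unlabeled slide with that supervised model and trains a final
#' model on the combined set; \code{"som_ssl"} trains the per-case expert
#' pool and the tumor locator, builds the slide similarity matrix, routes
#' each unlabeled slide through its matched morphology expert for
#' tumor/stroma pseudo-labels (fused with the supervised model's other
#' classes), and trains the final model on the combined set. With a
#' deterministic backend the whole run is reproducible from the seed.
#'
#' @param annotated list of annotated [SlideRecord-class].
#' @param unlabeled list of unlabeled [SlideRecord-class] (may be empty
#'   for the supervised paradigm).
#' @param paradigm one of \code{"supervised"}, \code{"traditional_ssl"},
#'   \code{"som_ssl"}.
#' @param tiling a [tilingConfig()].
#' @param simCfg a [similarityConfig()].
#' @param trainCfg [trainConfig()] for the supervised model, experts and
#'   locator.
#' @param finalTrainCfg [trainConfig()] for the final SSL model; defaults
#'   to \code{trainCfg}.
#' @param encoderSpec an [EncoderSpec-class]; defaults to the built-in
#'   encoder at the similarity patch size.
#' @param includeStroma whether tumor stroma counts as tumor when
#'   harvesting similarity patches (default FALSE: strict tumor only).
#' @param seed master seed; split and k-means seeds are derived from it.
#' @param outputDir optional directory for the run manifest, similarity
#'   matrix, matching table and pseudo-label masks.
#' @return a \code{PipelineRun} list: \code{paradigm}, \code{seed},
#'   \code{configHash}, \code{stages}, \code{models} (supervised, experts,
#'   locator, final), \code{similarity} ([SimilarityMatrix-class] or NULL),
#'   \code{matches} (data.frame or NULL), \code{pseudo} (list of
#'   [PseudoLabelResult-class]).
#' @export
runPipeline <- function(annotated, unlabeled = list(),
                        paradigm = c("som_ssl", "traditional_ssl",
                                     "supervised"),
                        tiling = tilingConfig(),
                        simCfg = similarityConfig(),
                        trainCfg = trainConfig(),
                        finalTrainCfg = trainCfg,
                        encoderSpec = builtinEncoderSpec(tiling$similarityPatchSize),
                        includeStroma = FALSE, seed = 1L,
                        outputDir = NULL) {
  paradigm <- match.arg(paradigm)
  if (!length(annotated)) stop("no annotated slides provided")
  if (paradigm != "supervised" && !length(unlabeled))
    stop("paradigm '", paradigm, "' needs unlabeled slides")
  cfg <- trainCfg; cfg@splitSeed <- deriveSeed(seed, "split")
  finalCfg <- finalTrainCfg
  finalCfg@splitSeed <- deriveSeed(seed, "final-split")
  sim <- simCfg; sim@kmeansSeed <- deriveSeed(seed, "kmeans")
  cfgHash <- fnvHash(paste(
    paradigm, seed, tiling$patchSize, tiling$annotatedStride,
    tiling$similarityPatchSize, sim@metric, sim@kRepresentatives,
    sim@tumorContentThreshold, cfg@epochs, cfg@backendId,
    jsonlite::toJSON(cfg@backendParams, auto_unbox = TRUE),
    finalCfg@backendId,
    jsonlite::toJSON(finalCfg@backendParams, auto_unbox = TRUE),
    collapse = "|"))
  stages <- "train_supervised"
  supervised <- trainSupervised(annotated, cfg, tiling$patchSize,
                                tiling$annotatedStride)
  experts <- NULL; locator <- NULL; simMatrix <- NULL; matches <- NULL
  pseudo <- list(); final <- supervised
  if (paradigm == "traditional_ssl") {
    stages <- c(stages, "pseudolabel_supervised", "train_ssl")
    pseudo <- lapply(unlabeled, function(s)
      pseudolabelWithExpert(s, supervised, supervised, tiling$patchSize,
                            matchedExpert = supervised@modelId,
                            similarity = NA_real_))
    dataset <- assembleSslDataset(annotated, pseudo, unlabeled,
                                  tiling$patchSize, tiling$annotatedStride)
    sp <- splitCasePatches(dataset, finalCfg)
    final <- trainSegmentation(sp$train, sp$val,
                               annotated[[1L]]@labelMask@scheme, finalCfg,
                               role = "ssl_final", modelId = "ssl_final")
  } else if (paradigm == "som_ssl") {
    stages <- c(stages, "train_experts", "train_tumor_locator",
                "similarity", "pseudolabel_experts", "train_ssl")
    pool <- trainExpertPool(annotated, cfg, tiling$patchSize,
                            tiling$annotatedStride)
    locator <- trainTumorLocator(annotated, cfg, tiling$locatorPatchSize,
                                 includeStroma)
    pool <- new("ExpertPool", experts = pool@experts,
                supervised = supervised, tumorLocator = locator)
    experts <- pool
    annRep <- harvestRepresentatives(annotated, cfg, sim, tiling,
                                     encoderSpec,
                                     includeStroma = includeStroma)
    qryRep <- harvestRepresentatives(unlabeled, cfg, sim, tiling,
                                     encoderSpec, locator = locator)
    simMatrix <- buildSimilarityMatrix(annRep, qryRep, sim@metric)
    matches <- matchAllExperts(simMatrix)
    pseudo <- lapply(unlabeled, function(s)
      generatePseudolabels(s, pool, simMatrix, tiling$patchSize))
    dataset <- assembleSslDataset(annotated, pseudo, unlabeled,
                                  tiling$patchSize, tiling$annotatedStride)
    sp <- splitCasePatches(dataset, finalCfg)
    final <- trainSegmentation(sp$train, sp$val,
                               annotated[[1L]]@labelMask@scheme, finalCfg,
                               role = "ssl_final", modelId = "ssl_final")
  }
  run <- structure(
    list(paradigm = paradigm, seed = as.integer(seed),
         configHash = cfgHash, stages = stages,
         models = list(supervised = supervised, experts = experts,
                       locator = locator, final = final),
         similarity = simMatrix, matches = matches, pseudo = pseudo),
    class = "PipelineRun")
  if (!is.null(outputDir)) writePipelineRun(run, outputDir)
  run
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat(sprintf("PipelineRun '%s' (seed %d, config %d)\n", x$paradigm,
              x$seed, x$configHash))
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat(sprintf("  final model: %s (val score %.4f)\n",
              x$models$final@modelId, x$models$final@bestValScore))
  if (!is.null(x$matches))
    cat(sprintf("  expert matches: %d queries, %d distinct experts\n",
                nrow(x$matches), length(unique(x$matches$matched_id))))
  invisible(x)
}

# Persist the audit trail of a run: manifest (config hash, seeds, stages,
# per-query expert matches with similarities), similarity matrix, and
# pseudo-label masks.
writePipelineRun <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(paradigm = run$paradigm, seed = run$seed,
         config_hash = run$configHash, stages = run$stages,
         final_val_score = run$models$final@bestValScore,
         matches = run$matches),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  if (!is.null(run$similarity))
    exportSimilarityMatrix(run$similarity,
                           csvPath = file.path(dir, "similarity.csv"),
                           jsonPath = file.path(dir, "similarity.json"))
  if (!is.null(run$matches))
    utils::write.csv(run$matches, file.path(dir, "matches.csv"),
                     row.names = FALSE)
  if (length(run$pseudo))
    for (p in run$pseudo) writePseudoLabelResult(p, file.path(dir, "pseudo"))
  invisible(dir)
}

#' Score a model on held-out slides
#'
#' Predicts each slide with no-overlap tiles and scores every class
#' against the reference masks.
#'
#' @param model a trained [ModelHandle-class].
#' @param slides list of [SlideRecord-class].
#' @param refMasks named list of reference [LabelMask-class] keyed by
#'   slide id; defaults to the slides' own label masks.
#' @param patchSize prediction tile size.
#' @return data.frame of per-slide per-class scores (see [scoreMask()]).
#' @export
evaluateModel <- function(model, slides, refMasks = NULL, patchSize = 512L) {
  rows <- lapply(slides, function(s) {
    ref <- if (is.null(refMasks)) s@labelMask else refMasks[[s@slideId]]
    if (is.null(ref)) stop("no reference mask for slide '", s@slideId, "'")
    pred <- predictSlideMask(model, s, patchSize)
    scoreMask(pred, ref, model@scheme, unit = s@slideId)
  })
  do.call(rbind, rows)
}

#' Run an ablation grid over cohort sizes and paradigms
#'
#' Executes every (nAnnotated, nUnlabeled, paradigm) cell with
#' \code{replicates} independent seeds; each replicate draws its own
#' random annotated/unlabeled subsets from the pools. Failures in a cell
#' are recorded and remaining cells continue.
#'
#' @param annotatedPool,unlabeledPool slide pools to subsample.
#' @param heldout held-out slides for scoring.
#' @param heldoutMasks named list of reference masks for \code{heldout}
#'   (NULL to use their own masks).
#' @param nAnnotated,nUnlabeled,paradigms grid axes.
#' @param replicates replicate runs per cell (default 3).
#' @param seed master seed.
#' @param ... passed on to [runPipeline()] (tiling, configs, backend).
#' @return long-format data.frame: n_annotated, n_unlabeled, paradigm,
#'   replicate, unit, class, dice (NA rows for failed cells, with the
#'   error in attribute \code{"failures"}).
#' @export
runAblation <- function(annotatedPool, unlabeledPool, heldout,
                        heldoutMasks = NULL,
                        nAnnotated = length(annotatedPool),
                        nUnlabeled = length(unlabeledPool),
                        paradigms = c("supervised", "traditional_ssl",
                                      "som_ssl"),
                        replicates = 3L, seed = 1L, ...) {
  patchSize <- list(...)$tiling$patchSize %||% 512L
  rows <- list(); failures <- list()
  for (na in nAnnotated) for (nu in nUnlabeled) for (pd in paradigms) {
    for (r in seq_len(replicates)) {
      cellId <- sprintf("a%d_u%d_%s_r%d", na, nu, pd, r)
      cellSeed <- deriveSeed(seed, cellId)
      res <- tryCatch({
        idxA <- withSeed(cellSeed, sample.int(length(annotatedPool), na))
        idxU <- withSeed(deriveSeed(cellSeed, "u"),
                         sample.int(length(unlabeledPool), nu))
        run <- runPipeline(annotatedPool[idxA], unlabeledPool[idxU],
                           paradigm = pd, seed = cellSeed, ...)
        sc <- evaluateModel(run$models$final, heldout, heldoutMasks,
                            patchSize)
        cbind(n_annotated = na, n_unlabeled = nu, paradigm = pd,
              replicate = r, sc[, c("unit", "class", "dice")])
      }, error = function(e) {
        failures[[cellId]] <<- conditionMessage(e)
        data.frame(n_annotated = na, n_unlabeled = nu, paradigm = pd,
                   replicate = r, unit = NA_character_,
                   class = NA_character_, dice = NA_real_)
      })
      rows[[cellId]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
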