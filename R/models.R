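#' Construct a TrainConfig
#'
#' Defaults mirror the training convention used throughout: 36 epochs
#' without early stopping, step-decay learning rate (step size 10, factor
#' 0.1), an adaptive-moment optimizer, a 90/10 train/validation split, and
#' checkpoint selection by best validation score (mean foreground Dice).
#'
#' @param epochs,lr,lrStepSize,lrGamma,valFraction,splitSeed see
#'   [TrainConfig-class].
#' @param classWeights optional named per-code weights; when empty they are
#'   computed from the training label histogram via [classWeights()].
#' @param backendId segmentation backend: \code{"proto"} (nearest-prototype
#'   colour classifier; default) or \code{"mlp"} (tiny pixel MLP).
#' @param backendParams backend parameter list. For \code{"proto"}:
#'   \code{nPrototypes} (prototypes per class, default 1; the model
#'   capacity knob), \code{maxPixelsPerPatch} (training subsample, default
#'   200). For \code{"mlp"}: \code{hidden} (default 8),
#'   \code{maxPixelsPerPatch}, \code{iterPerEpoch} (default 25).
#' @param initCheckpointId token naming the shared initialization
#'   checkpoint; every expert in a pool must carry the same token (for the
#'   toy backends it seeds the shared RNG initialization).
#' @param optimizer optimizer name (informational for the toy backends).
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 36L, lr = 1e-3, lrStepSize = 10L,
                        lrGamma = 0.1, valFraction = 0.10, splitSeed = 1L,
                        classWeights = numeric(), backendId = "proto",
                        backendParams = list(), initCheckpointId = "shared-init",
                        optimizer = "adam") {
  new("TrainConfig", epochs = as.integer(epochs), lr = lr,
      lrStepSize = as.integer(lrStepSize), lrGamma = lrGamma,
      valFraction = valFraction, splitSeed = as.integer(splitSeed),
      classWeights = classWeights, backendId = backendId,
      backendParams = backendParams,
      initCheckpointId = initCheckpointId, optimizer = optimizer)
}

## ---- backend registry -----------------------------------------------------

.backends <- new.env(parent = emptyenv())

#' Segmentation backend registry
#'
#' A backend is a list of functions implementing the training contract:
#' \code{init(scheme, params, seed)} returning an initial state;
#' \code{fitEpoch(state, patches, weights, lr, epoch)} returning an
#' updated state; \code{predictPixels(state, px)} mapping an N x 3 matrix
#' of RGB values (0-255) to N integer class codes; and
#' \code{oneShot} (logical) declaring that the state converges after the
#' first epoch so training can stop early. Two toy backends ship with the
#' package: \code{"proto"}, a nearest-prototype colour classifier whose
#' per-class prototypes are k-means centroids of training pixels, and
#' \code{"mlp"}, a tiny single-hidden-layer pixel classifier trained
#' iteratively (exercising the epoch/checkpoint contract). Heavier
#' encoder-decoder networks can be registered through
#' \code{registerBackend} without changing any pipeline code.
#'
#' @param backendId backend identifier.
#' @param backend the backend list.
#' @return \code{getBackend} returns the backend list.
#' @export
getBackend <- function(backendId) {
  if (!exists(backendId, envir = .backends))
    stop("unknown backend '", backendId, "'; registered: ",
         paste(ls(.backends), collapse = ", "))
  get(backendId, envir = .backends)
}

#' @rdname getBackend
#' @export
registerBackend <- function(backendId, backend) {
  stopifnot(is.list(backend),
            all(c("init", "fitEpoch", "predictPixels") %in% names(backend)))
  assign(backendId, backend, envir = .backends)
  invisible(backendId)
}

# Subsample up to maxPx (pixel, code) pairs per patch, ignore pixels
# excluded. Deterministic given the state seed and patch order.
collectPixelSamples <- function(patches, ignore, maxPx, seed) {
  withSeed(seed, {
    xs <- vector("list", length(patches))
    ys <- vector("list", length(patches))
    for (i in seq_along(patches)) {
      p <- patches[[i]]
      if (is.null(p@mask)) stop("training patch without mask")
      codes <- as.vector(p@mask@codes)
      keep <- which(codes != ignore)
      if (!length(keep)) next
      if (length(keep) > maxPx) keep <- sort(sample(keep, maxPx))
      px <- matrix(p@pixels, ncol = 3L)
      xs[[i]] <- px[keep, , drop = FALSE]
      ys[[i]] <- codes[keep]
    }
    list(x = do.call(rbind, xs), y = unlist(ys))
  })
}

# ---- "proto" backend: nearest-prototype colour classifier ----
# Per class, prototypes are the k-means centroids (k = nPrototypes) of that
# class's training pixels in RGB space; prediction assigns each pixel the
# class of its nearest prototype (ties resolve to the lowest class code via
# prototype ordering). Fitting is closed-form given the sample, so the
# backend declares oneShot and ignores the learning rate; class weights do
# not enter (no gradient objective), which the training contract permits.
protoBackend <- list(
  oneShot = TRUE,
  init = function(scheme, params, seed) {
    list(backend = "proto",
         nPrototypes = as.integer(params$nPrototypes %||% 1L),
         maxPixelsPerPatch = as.integer(params$maxPixelsPerPatch %||% 200L),
         seed = as.integer(seed), codes = integer(), prototypes = NULL,
         protoClass = integer())
  },
  fitEpoch = function(state, patches, weights, lr, epoch) {
    if (epoch > 1L) return(state)
    ignore <- patches[[1L]]@mask@scheme@ignoreCode
    smp <- collectPixelSamples(patches, ignore, state$maxPixelsPerPatch,
                               state$seed)
    if (is.null(smp$x) || !nrow(smp$x))
      stop("no labelled pixels available for training")
    codes <- sort(unique(smp$y))
    protos <- list(); protoClass <- integer()
    for (cd in codes) {
      px <- smp$x[smp$y == cd, , drop = FALSE]
      kEff <- min(state$nPrototypes, nrow(unique(px)))
      if (kEff <= 1L) centers <- matrix(colMeans(px), 1L)
      else centers <- kmeansBest(px, kEff, deriveSeed(state$seed,
                                                      paste0("class", cd)),
                                 5L)$centers
      protos[[length(protos) + 1L]] <- centers
      protoClass <- c(protoClass, rep(cd, nrow(centers)))
    }
    state$codes <- codes
    state$prototypes <- do.call(rbind, protos)
    state$protoClass <- protoClass
    state
  },
  predictPixels = function(state, px) {
    if (is.null(state$prototypes)) stop("untrained prototype model")
    P <- state$prototypes
    # squared distances pixel x prototype, chunked to bound memory
    n <- nrow(px)
    out <- integer(n)
    p2 <- rowSums(P^2)
    chunk <- 100000L
    for (s in seq(1L, n, by = chunk)) {
      e <- min(n, s + chunk - 1L)
      block <- px[s:e, , drop = FALSE]
      d2 <- outer(rowSums(block^2), p2, "+") - 2 * block %*% t(P)
      out[s:e] <- state$protoClass[max.col(-d2, ties.method = "first")]
    }
    out
  },
  serializeState = function(state) state,
  deserializeState = function(x) {
    x$prototypes <- matrix(unlist(x$prototypes), ncol = 3L)
    x$codes <- as.integer(unlist(x$codes))
    x$protoClass <- as.integer(unlist(x$protoClass))
    x
  }
)

# ---- "mlp" backend: tiny single-hidden-layer pixel classifier ----
# Logistic-sigmoid hidden layer + softmax output over the observed codes,
# trained via nnet with class-weighted examples; each epoch continues
# optimization from the previous weights for iterPerEpoch iterations, so
# per-epoch validation checkpointing is exercised for real. Prediction is
# a hand-rolled forward pass from the stored weight vector, keeping the
# state numeric and serializable.
mlpForward <- function(state, px) {
  x <- cbind(1, px / 255)
  nIn <- 3L; nH <- state$hidden; nOut <- length(state$codes)
  w <- state$wts
  W1 <- matrix(w[seq_len((nIn + 1L) * nH)], nIn + 1L, nH)
  W2 <- matrix(w[-seq_len((nIn + 1L) * nH)], nH + 1L, nOut)
  h <- 1 / (1 + exp(-(x %*% W1)))
  scores <- cbind(1, h) %*% W2
  state$codes[max.col(scores, ties.method = "first")]
}

mlpBackend <- list(
  oneShot = FALSE,
  init = function(scheme, params, seed) {
    list(backend = "mlp",
         hidden = as.integer(params$hidden %||% 8L),
         maxPixelsPerPatch = as.integer(params$maxPixelsPerPatch %||% 100L),
         iterPerEpoch = as.integer(params$iterPerEpoch %||% 25L),
         seed = as.integer(seed), codes = integer(), wts = NULL,
         sample = NULL)
  },
  fitEpoch = function(state, patches, weights, lr, epoch) {
    if (is.null(state$sample)) {
      ignore <- patches[[1L]]@mask@scheme@ignoreCode
      state$sample <- collectPixelSamples(patches, ignore,
                                          state$maxPixelsPerPatch, state$seed)
      if (is.null(state$sample$x) || !nrow(state$sample$x))
        stop("no labelled pixels available for training")
      state$codes <- sort(unique(state$sample$y))
    }
    x <- state$sample$x / 255
    yFac <- factor(state$sample$y, levels = state$codes)
    y <- nnet::class.ind(yFac)
    w <- if (length(weights)) unname(weights[as.character(state$sample$y)])
         else rep(1, length(yFac))
    w[is.na(w)] <- 1
    fit <- withSeed(deriveSeed(state$seed, paste0("epoch", epoch)), {
      if (is.null(state$wts))
        nnet::nnet(x, y, size = state$hidden, softmax = TRUE,
                   maxit = state$iterPerEpoch, weights = w, trace = FALSE)
      else
        nnet::nnet(x, y, size = state$hidden, softmax = TRUE,
                   maxit = state$iterPerEpoch, weights = w,
                   Wts = state$wts, trace = FALSE)
    })
    state$wts <- fit$wts
    state
  },
  predictPixels = function(state, px) {
    if (is.null(state$wts)) stop("untrained mlp model")
    mlpForward(state, px)
  },
  serializeState = function(state) state[setdiff(names(state), "sample")],
  deserializeState = function(x) {
    x$codes <- as.integer(unlist(x$codes))
    x$wts <- as.numeric(unlist(x$wts))
    x
  }
)

`%||%` <- function(a, b) if (is.null(a)) b else a

registerBackend("proto", protoBackend)
registerBackend("mlp", mlpBackend)

## ---- training operations --------------------------------------------------

#' Deterministic 90/10 split of one case's patches
#'
#' Shuffles by \code{splitSeed} and holds out
#' \code{max(1, round(valFraction * n))} patches for validation; train and
#' validation are disjoint and jointly exhaust the input.
#'
#' @param patches list of at least two [Patch-class].
#' @param cfg a [TrainConfig-class].
#' @return list with elements \code{train} and \code{val}.
#' @export
splitCasePatches <- function(patches, cfg) {
  n <- length(patches)
  if (n < 2L) stop("need at least 2 patches to split")
  perm <- withSeed(cfg@splitSeed, sample.int(n))
  nVal <- max(1L, as.integer(round(cfg@valFraction * n)))
  list(train = patches[perm[-seq_len(nVal)]],
       val = patches[perm[seq_len(nVal)]])
}

#' Inverse-frequency class weights
#'
#' \code{w_i = N / (K * n_i)} over the K observed classes with N total
#' pixels, the inverse-frequency weighting normalized so a uniform
#' histogram gives weight 1 everywhere; classes present in the histogram
#' with zero count receive the maximum observed weight. The ignore code
#' must not appear in the histogram.
#'
#' @param labelHistogram named numeric vector, code -> pixel count.
#' @return named numeric vector of weights.
#' @examples
#' classWeights(c("1" = 900, "2" = 100))  # 0.5556, 5.0
#' @export
classWeights <- function(labelHistogram) {
  if (!length(labelHistogram) || all(labelHistogram == 0))
    stop("label histogram is empty")
  obs <- labelHistogram[labelHistogram > 0]
  N <- sum(obs); K <- length(obs)
  w <- N / (K * obs)
  out <- stats::setNames(rep(max(w), length(labelHistogram)),
                         names(labelHistogram))
  out[names(w)] <- w
  out
}

# Pixel-count histogram over patch masks, ignore excluded.
labelHistogram <- function(patches) {
  ignore <- patches[[1L]]@mask@scheme@ignoreCode
  counts <- table(unlist(lapply(patches, function(p) {
    v <- p@mask@codes
    v[v != ignore]
  })))
  stats::setNames(as.numeric(counts), names(counts))
}

# Mean foreground Dice of a state over validation patches: pooled
# intersection/size counts per class (background and ignore excluded),
# averaged over the classes for which Dice is defined.
meanForegroundDice <- function(backend, state, valPatches, scheme) {
  bg <- backgroundCode(scheme)
  ignore <- scheme@ignoreCode
  inter <- sizeP <- sizeR <- numeric(0)
  classKey <- character(0)
  acc <- new.env(parent = emptyenv())
  for (p in valPatches) {
    ref <- as.vector(p@mask@codes)
    px <- matrix(p@pixels, ncol = 3L)
    keep <- ref != ignore
    pred <- backend$predictPixels(state, px[keep, , drop = FALSE])
    ref <- ref[keep]
    for (cd in union(unique(ref), unique(pred))) {
      if (!is.na(bg) && cd == bg) next
      key <- as.character(cd)
      prev <- if (!is.null(acc[[key]])) acc[[key]] else c(0, 0, 0)
      acc[[key]] <- prev + c(sum(pred == cd & ref == cd),
                             sum(pred == cd), sum(ref == cd))
    }
  }
  dices <- vapply(ls(acc), function(key) {
    v <- acc[[key]]
    if (v[2] + v[3] == 0) NA_real_ else 2 * v[1] / (v[2] + v[3])
  }, numeric(1))
  dices <- dices[!is.na(dices)]
  if (!length(dices)) return(0)
  mean(dices)
}

#' Train a segmentation model under the backend contract
#'
#' Fits the configured backend on (patch, mask) pairs with inverse-
#' frequency class weights, evaluates mean foreground Dice on the
#' validation patches after each epoch under the step-decay learning-rate
#' schedule, and returns the checkpoint with the best validation score.
#' Deterministic given the config seeds and a deterministic backend.
#' One-shot backends (closed-form fits) stop after their first epoch.
#'
#' @param train,val non-empty lists of [Patch-class] with valid masks.
#' @param scheme the [ClassScheme-class] of the masks.
#' @param cfg a [TrainConfig-class].
#' @param role,modelId,sourceSlides metadata recorded on the handle.
#' @return a [ModelHandle-class].
#' @export
trainSegmentation <- function(train, val, scheme, cfg, role = "supervised",
                              modelId = role,
                              sourceSlides = unique(vapply(train,
                                function(p) p@slideId, character(1)))) {
  if (!length(train) || !length(val))
    stop("train and validation sets must be non-empty")
  backend <- getBackend(cfg@backendId)
  weights <- if (length(cfg@classWeights)) cfg@classWeights
             else classWeights(labelHistogram(train))
  state <- backend$init(scheme, cfg@backendParams,
                        deriveSeed(fnvHash(cfg@initCheckpointId), modelId))
  bestState <- NULL
  bestScore <- -Inf
  scores <- numeric(0)
  for (epoch in seq_len(cfg@epochs)) {
    lr <- cfg@lr * cfg@lrGamma^((epoch - 1L) %/% cfg@lrStepSize)
    state <- backend$fitEpoch(state, train, weights, lr, epoch)
    score <- meanForegroundDice(backend, state, val, scheme)
    scores <- c(scores, score)
    if (score > bestScore) {
      bestScore <- score
      bestState <- state
    }
    if (isTRUE(backend$oneShot)) break
  }
  new("ModelHandle", modelId = modelId, role = role,
      sourceSlides = sourceSlides, bestValScore = bestScore,
      epochScores = scores, state = bestState, backendId = cfg@backendId,
      initCheckpointId = cfg@initCheckpointId, scheme = scheme)
}

setMethod("show", "ModelHandle", function(object) {
  cat(sprintf("ModelHandle '%s' (%s, backend %s): val score %.4f, %d epoch(s)\n",
              object@modelId, object@role, object@backendId,
              object@bestValScore, length(object@epochScores)))
  cat("  source slides:", paste(object@sourceSlides, collapse = ", "), "\n")
})

#' Train one morphology expert per annotated slide
#'
#' Each expert trains on its own slide's patches only, split 90/10 per
#' case; all experts share the configured initialization checkpoint token.
#'
#' @param annotated non-empty list of annotated [SlideRecord-class].
#' @param cfg a [TrainConfig-class].
#' @param patchSize,stride tiling for training patches (annotated regime:
#'   default overlap of 128 at patch 512 scales down with patch size).
#' @return an [ExpertPool-class] carrying the experts (supervised model and
#'   tumor locator slots empty).
#' @export
trainExpertPool <- function(annotated, cfg, patchSize = 512L,
                            stride = patchSize - as.integer(round(patchSize / 4))) {
  if (!length(annotated)) stop("need at least one annotated slide")
  experts <- list()
  for (slide in annotated) {
    if (!slide@annotated) stop("slide '", slide@slideId, "' is not annotated")
    patches <- tileSlide(slide, patchSize, stride, withMask = TRUE)
    if (!length(patches))
      stop("slide '", slide@slideId, "' produced no patches")
    caseCfg <- cfg
    caseCfg@splitSeed <- deriveSeed(cfg@splitSeed, slide@slideId)
    sp <- splitCasePatches(patches, caseCfg)
    experts[[slide@slideId]] <- trainSegmentation(
      sp$train, sp$val, slide@labelMask@scheme, cfg, role = "expert",
      modelId = paste0("expert_", slide@slideId),
      sourceSlides = slide@slideId)
  }
  new("ExpertPool", experts = experts, supervised = NULL, tumorLocator = NULL)
}

#' Train the pooled supervised model
#'
#' Pools patches from all annotated slides and splits 90/10 at the pooled
#' level.
#'
#' @inheritParams trainExpertPool
#' @return a [ModelHandle-class] with role \code{"supervised"}.
#' @export
trainSupervised <- function(annotated, cfg, patchSize = 512L,
                            stride = patchSize - as.integer(round(patchSize / 4))) {
  if (!length(annotated)) stop("need at least one annotated slide")
  patches <- unlist(lapply(annotated, function(s) {
    if (!s@annotated) stop("slide '", s@slideId, "' is not annotated")
    tileSlide(s, patchSize, stride, withMask = TRUE)
  }), recursive = FALSE)
  sp <- splitCasePatches(patches, cfg)
  trainSegmentation(sp$train, sp$val, annotated[[1L]]@labelMask@scheme, cfg,
                    role = "supervised", modelId = "supervised")
}

# The fixed 3-class scheme the tumor locator predicts over.
locatorScheme <- function() {
  ClassScheme(c("background", "non_tumor", "tumor"), 0:2, tumorCodes = 2L,
              ignoreCode = 255L)
}

# Remap a full-scheme mask to the locator's 3 classes.
remapToLocator <- function(mask, harvestCodes) {
  sc <- mask@scheme
  bg <- backgroundCode(sc)
  v <- mask@codes
  out <- matrix(1L, nrow(v), ncol(v))          # non_tumor
  if (!is.na(bg)) out[v == bg] <- 0L            # background
  out[matrix(v %in% harvestCodes, nrow(v))] <- 2L  # tumor
  out[v == sc@ignoreCode] <- 255L
  LabelMask(out, locatorScheme())
}

#' Train the 3-class tumor locator
#'
#' A tumor / non-tumor / background model trained on remapped annotated
#' patches (default patch size 224, the tessellation used for similarity
#' assessment). Its predictions select tumor patches on unlabeled slides;
#' they are never used as pseudo-labels. By default only the tumor class
#' itself maps to "tumor"; set \code{includeStroma} to also count tumor
#' stroma.
#'
#' @inheritParams trainExpertPool
#' @param patchSize locator patch size (default 224).
#' @param includeStroma logical; if TRUE all of the scheme's tumor codes
#'   (tumor and tumor stroma) map to the locator's tumor class.
#' @return a [ModelHandle-class] with role \code{"tumor_locator"}; its
#'   scheme is the 3-class locator scheme.
#' @export
trainTumorLocator <- function(annotated, cfg, patchSize = 224L,
                              includeStroma = FALSE) {
  if (!length(annotated)) stop("need at least one annotated slide")
  scheme <- annotated[[1L]]@labelMask@scheme
  harvestCodes <- if (includeStroma) scheme@tumorCodes
                  else scheme@tumorCodes[1L]
  patches <- unlist(lapply(annotated, function(s) {
    ps <- tileSlide(s, patchSize, patchSize, withMask = TRUE)
    lapply(ps, function(p) {
      p@mask <- remapToLocator(p@mask, harvestCodes)
      p
    })
  }), recursive = FALSE)
  sp <- splitCasePatches(patches, cfg)
  trainSegmentation(sp$train, sp$val, locatorScheme(), cfg,
                    role = "tumor_locator", modelId = "tumor_locator")
}

#' Predict a slide-sized label mask
#'
#' Tiles the slide, predicts every tile with the model's backend, and
#' assembles the predictions into one mask. Where tiles overlap, later
#' tiles overwrite earlier ones except at pixels already carrying a tumor
#' or tumor-stroma code, which persist (the precedence rule applied at
#' patch boundaries). With \code{stride = patchSize} the assembly is a
#' pure mosaic.
#'
#' @param model a trained [ModelHandle-class].
#' @param slide a [SlideRecord-class].
#' @param patchSize,stride tiling parameters.
#' @return a [LabelMask-class] over the model's scheme.
#' @export
predictSlideMask <- function(model, slide, patchSize, stride = patchSize) {
  if (is.null(model@state$prototypes) && is.null(model@state$wts))
    stop("model '", model@modelId, "' is untrained")
  backend <- getBackend(model@backendId)
  d <- dim(slide@image)
  origins <- tileOrigins(d[2L], d[1L], patchSize, stride)
  out <- matrix(NA_integer_, d[1L], d[2L])
  tc <- model@scheme@tumorCodes
  for (i in seq_len(nrow(origins))) {
    x0 <- origins[i, 1L]; y0 <- origins[i, 2L]
    rows <- (y0 + 1L):(y0 + patchSize)
    cols <- (x0 + 1L):(x0 + patchSize)
    px <- matrix(slide@image[rows, cols, , drop = FALSE], ncol = 3L)
    pred <- matrix(backend$predictPixels(model@state, px), patchSize,
                   patchSize)
    cur <- out[rows, cols]
    keep <- !is.na(cur) & (cur %in% tc)
    pred[keep] <- cur[keep]
    out[rows, cols] <- pred
  }
  LabelMask(out, model@scheme)
}

## ---- persistence ----------------------------------------------------------

#' Save / load a ModelHandle as a directory
#'
#' The directory holds a JSON manifest (id, role, sources, scores, backend,
#' init token), the backend state (JSON; toy backend states are fully
#' numeric) and the class scheme.
#'
#' @param model a [ModelHandle-class].
#' @param dir directory path (created if missing).
#' @return \code{readModelHandle} returns the restored
#'   [ModelHandle-class].
#' @export
saveModelHandle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  backend <- getBackend(model@backendId)
  ser <- if (!is.null(backend$serializeState)) backend$serializeState
         else identity
  jsonlite::write_json(
    list(model_id = model@modelId, role = model@role,
         source_slides = model@sourceSlides,
         best_val_score = model@bestValScore,
         epoch_scores = model@epochScores,
         backend_id = model@backendId,
         init_checkpoint_id = model@initCheckpointId),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(ser(model@state), file.path(dir, "state.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeClassScheme(model@scheme, file.path(dir, "scheme.json"))
  invisible(dir)
}

#' @rdname saveModelHandle
#' @export
readModelHandle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  backend <- getBackend(man$backend_id)
  state <- jsonlite::read_json(file.path(dir, "state.json"),
                               simplifyVector = TRUE)
  if (!is.null(backend$deserializeState))
    state <- backend$deserializeState(state)
  new("ModelHandle", modelId = man$model_id, role = man$role,
      sourceSlides = man$source_slides,
      bestValScore = man$best_val_score,
      epochScores = as.numeric(man$epoch_scores), state = state,
      backendId = man$backend_id,
      initCheckpointId = man$init_checkpoint_id,
      scheme = readClassScheme(file.path(dir, "scheme.json")))
}

setMethod("show", "ExpertPool", function(object) {
  cat(sprintf("ExpertPool: %d expert(s)%s%s\n", length(object@experts),
              if (is.null(object@supervised)) "" else " + supervised",
              if (is.null(object@tumorLocator)) "" else " + tumor locator"))
  if (length(object@experts))
    cat("  experts:", paste(names(object@experts), collapse = ", "), "\n")
})
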