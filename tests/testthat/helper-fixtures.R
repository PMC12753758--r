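# Shared in-code fixtures: tiny schemes, slides and feature sets, plus the
# independent exhaustive K-means oracle used against selectRepresentatives.

tinyScheme <- function() {
  ClassScheme(c("background", "tumor", "tumor_stroma", "benign_mucosa",
                "smooth_muscle"),
              0:4, tumorCodes = 1:2, ignoreCode = 255L)
}

# A small slide with a deterministic blocky layout over tinyScheme codes.
tinySlide <- function(id = "s1", size = 64L, tumorColour = c(200, 60, 60),
                      annotated = TRUE, mpp = 1.0) {
  sc <- tinyScheme()
  img <- array(245, c(size, size, 3L))
  mask <- matrix(0L, size, size)
  mid <- size %/% 2L
  # benign strip, stroma frame, tumor core
  img[1:mid, , 1] <- 250; img[1:mid, , 2] <- 235; img[1:mid, , 3] <- 205
  mask[1:mid, ] <- 3L
  img[(mid + 1):size, , 1] <- 240; img[(mid + 1):size, , 2] <- 170
  img[(mid + 1):size, , 3] <- 200
  mask[(mid + 1):size, ] <- 2L
  core <- (mid + 5L):(size - 4L)
  for (ch in 1:3) img[core, core, ch] <- tumorColour[ch]
  mask[core, core] <- 1L
  lm <- if (annotated) LabelMask(mask, sc) else NULL
  list(slide = SlideRecord(id, img, mpp, labelMask = lm),
       mask = LabelMask(mask, sc))
}

featureSetOf <- function(x, id = "s") {
  new("FeatureSet", slideId = id, vectors = x,
      patchRefs = cbind(x0 = seq_len(nrow(x)) - 1L,
                        y0 = rep(0L, nrow(x))),
      encoderId = "test")
}

repSetOf <- function(x, id = "r") {
  new("RepresentativeSet", slideId = id, vectors = x,
      sourceRefs = matrix(0L, nrow(x), 2L,
                          dimnames = list(NULL, c("x0", "y0"))))
}

uniformPatch <- function(colour, size = 8L, id = "p") {
  px <- array(0, c(size, size, 3L))
  for (ch in 1:3) px[, , ch] <- colour[ch]
  new("Patch", slideId = id, origin = c(0L, 0L), pixels = px, mask = NULL)
}

maskedPatch <- function(codes, colour = c(128, 128, 128), id = "p") {
  sc <- tinyScheme()
  size <- nrow(codes)
  px <- array(0, c(size, size, 3L))
  for (ch in 1:3) px[, , ch] <- colour[ch]
  new("Patch", slideId = id, origin = c(0L, 0L), pixels = px,
      mask = LabelMask(codes, sc))
}

# Independent oracle for representative selection: enumerate every
# partition of the rows of x into at most k non-empty blocks, keep all
# partitions whose within-cluster SSE is globally minimal (ties included),
# and return the centroid-nearest member set of each (lowest row index on
# distance ties), rows sorted for comparison.
exhaustiveRepresentativeSets <- function(x, k, tieTol = 1e-9) {
  n <- nrow(x)
  partitions <- list()
  sses <- numeric()
  assign <- integer(n)
  rec <- function(i, maxB) {
    if (i > n) {
      sse <- 0
      for (b in seq_len(max(assign))) {
        m <- x[assign == b, , drop = FALSE]
        sse <- sse + sum(sweep(m, 2, colMeans(m))^2)
      }
      partitions[[length(partitions) + 1L]] <<- assign
      sses[length(sses) + 1L] <<- sse
      return(invisible())
    }
    for (b in seq_len(min(maxB + 1L, k))) {
      assign[i] <<- b
      rec(i + 1L, max(maxB, b))
    }
    assign[i] <<- 0L
  }
  rec(1L, 0L)
  best <- min(sses)
  lapply(partitions[sses <= best + tieTol], function(cl) {
    reps <- matrix(NA_real_, max(cl), ncol(x))
    for (b in seq_len(max(cl))) {
      m <- x[cl == b, , drop = FALSE]
      ctr <- colMeans(m)
      reps[b, ] <- m[which.min(colSums((t(m) - ctr)^2)), ]
    }
    reps[do.call(order, as.data.frame(reps)), , drop = FALSE]
  })
}

sortRows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]

# Toy-scale pipeline settings shared by the integration and acceptance
# tests: 192-px slides, 32-px training patches with 8-px overlap, 32-px
# similarity patches.
toyTiling <- function() {
  tilingConfig(patchSize = 32L, annotatedOverlap = 8L,
               similarityPatchSize = 32L)
}

toyTrainConfig <- function(...) trainConfig(epochs = 1L, ...)

toyFinalConfig <- function() {
  trainConfig(epochs = 1L, backendParams = list(nPrototypes = 4L))
}

# Matching accuracy of a som_ssl run against the cohort truth table.
matchingAccuracy <- function(matches, truth) {
  annStyle <- stats::setNames(truth$style_id[truth$annotated],
                              truth$slide_id[truth$annotated])
  qStyle <- truth$style_id[match(matches$query_id, truth$slide_id)]
  mean(annStyle[matches$matched_id] == qStyle)
}
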