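#' Construct a StyleSpec: one case's tumor morphology style
#'
#' A style stands in for inter-case tumor heterogeneity: each case renders
#' its tumor regions with a characteristic base colour plus an oriented
#' periodic texture and colour jitter, so that same-style slides are more
#' similar than cross-style slides under the built-in encoder.
#'
#' @param styleId identifier.
#' @param baseColour RGB triplet in 0-255.
#' @param stripeOrientation texture stripe orientation in radians.
#' @param stripeFreq number of stripe periods across a rendered region.
#' @param amplitude stripe amplitude in intensity units (applied to all
#'   channels).
#' @param jitterSd per-pixel Gaussian colour jitter sd (>= 0).
#' @return a \code{StyleSpec} object.
#' @export
styleSpec <- function(styleId, baseColour, stripeOrientation = 0,
                      stripeFreq = 6, amplitude = 15, jitterSd = 8) {
  stopifnot(length(baseColour) == 3L, all(baseColour >= 0),
            all(baseColour <= 255), jitterSd >= 0, amplitude >= 0)
  new("StyleSpec", styleId = as.character(styleId),
      baseColour = as.numeric(baseColour),
      stripeOrientation = as.numeric(stripeOrientation),
      stripeFreq = as.numeric(stripeFreq),
      amplitude = as.numeric(amplitude), jitterSd = as.numeric(jitterSd))
}

#' @rdname styleSpec
#' @param n number of styles (up to 4 predefined).
#' @return \code{defaultStyles} returns a list of n well-separated styles
#'   (base colours at least 64 apart in every pair, distinct stripe
#'   orientations).
#' @export
defaultStyles <- function(n = 4L) {
  base <- list(c(190, 60, 60), c(60, 190, 60), c(60, 60, 190),
               c(200, 200, 60))
  if (n > length(base)) stop("at most ", length(base), " default styles")
  lapply(seq_len(n), function(i)
    styleSpec(paste0("style", i), base[[i]],
              stripeOrientation = (i - 1) * pi / 4))
}

setClass("StyleSpec",
  slots = c(styleId = "character", baseColour = "numeric",
            stripeOrientation = "numeric", stripeFreq = "numeric",
            amplitude = "numeric", jitterSd = "numeric"))

setMethod("show", "StyleSpec", function(object) {
  cat(sprintf("StyleSpec '%s': base (%d, %d, %d), orientation %.2f rad\n",
              object@styleId, object@baseColour[1], object@baseColour[2],
              object@baseColour[3], object@stripeOrientation))
})

#' SyntheticCohortConfig: the study conditions of a synthetic cohort
#'
#' @slot nAnnotated,nUnlabeled cohort sizes.
#' @slot styles list of [styleSpec()] styles; annotated slides cover them
#'   round-robin.
#' @slot slideSize slide edge in pixels.
#' @slot noiseSd per-pixel Gaussian noise sd for non-tumor tissue.
#' @slot seed master seed; the cohort is fully deterministic given it.
#' @slot confusable if TRUE, the smooth-muscle colour is placed close to
#'   the third style's tumor colour (orthogonally to the gray axis), so a
#'   pooled single-prototype model confuses that style's tumor with
#'   smooth muscle while the per-case expert does not.
#' @slot mixedStyleSlides number of unlabeled slides whose tumor mixes two
#'   styles half-and-half (exercising mid-range similarity).
#' @slot scheme the [ClassScheme-class] for the masks.
#' @exportClass SyntheticCohortConfig
setClass("SyntheticCohortConfig",
  slots = c(nAnnotated = "integer", nUnlabeled = "integer", styles = "list",
            slideSize = "integer", noiseSd = "numeric", seed = "integer",
            confusable = "logical", mixedStyleSlides = "integer",
            scheme = "ClassScheme"))

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character()
  if (object@nAnnotated < 1L) msg <- c(msg, "need at least 1 annotated slide")
  if (!length(object@styles)) msg <- c(msg, "need at least 1 style")
  if (object@slideSize < 96L)
    msg <- c(msg, "slideSize must be >= 96 for a feasible layout")
  if (object@mixedStyleSlides > object@nUnlabeled)
    msg <- c(msg, "mixedStyleSlides cannot exceed nUnlabeled")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticCohortConfig-class
#' @param nAnnotated,nUnlabeled,styles,slideSize,noiseSd,seed,confusable,mixedStyleSlides,scheme
#'   see the class slots.
#' @return a [SyntheticCohortConfig-class].
#' @export
syntheticCohortConfig <- function(nAnnotated = 4L, nUnlabeled = 20L,
                                  styles = defaultStyles(4L),
                                  slideSize = 192L, noiseSd = 8,
                                  seed = 1L, confusable = FALSE,
                                  mixedStyleSlides = 0L,
                                  scheme = defaultClassScheme()) {
  new("SyntheticCohortConfig", nAnnotated = as.integer(nAnnotated),
      nUnlabeled = as.integer(nUnlabeled), styles = styles,
      slideSize = as.integer(slideSize), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed), confusable = confusable,
      mixedStyleSlides = as.integer(mixedStyleSlides), scheme = scheme)
}

# Class colours of the non-tumor tissue classes. In confusable mode the
# smooth-muscle colour sits 50 intensity units from the third style's
# tumor colour, displaced orthogonally to the gray axis so the stripe
# texture (which modulates along gray) cannot widen the gap.
stylePalette <- function(cfg) {
  sc <- cfg@scheme
  pal <- list()
  pal[[as.character(codeOf(sc, "background"))]] <- c(245, 245, 245)
  pal[[as.character(codeOf(sc, "tumor_stroma"))]] <- c(240, 170, 200)
  pal[[as.character(codeOf(sc, "benign_mucosa"))]] <- c(250, 235, 205)
  sm <- c(120, 200, 235)
  if (cfg@confusable) {
    target <- cfg@styles[[min(3L, length(cfg@styles))]]@baseColour
    sm <- clamp255(target + 50 * c(1, -1, 0) / sqrt(2))
  }
  pal[[as.character(codeOf(sc, "smooth_muscle"))]] <- sm
  pal
}

#' Render a styled tumor texture
#'
#' Deterministic given the seed: base colour plus an oriented sinusoidal
#' stripe pattern (same shift on all channels) plus per-pixel Gaussian
#' jitter, clamped to 0-255. With zero amplitude and zero jitter the
#' raster is constant at the base colour.
#'
#' @param style a [styleSpec()] style.
#' @param size raster edge in pixels.
#' @param seed RNG seed for the jitter.
#' @return numeric size x size x 3 array in 0-255.
#' @export
renderTexture <- function(style, size, seed) {
  stopifnot(size > 0)
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), times = size), size)
  phase <- 2 * pi * style@stripeFreq *
    (xs * cos(style@stripeOrientation) + ys * sin(style@stripeOrientation)) /
    size
  stripes <- style@amplitude * sin(phase)
  withSeed(seed, {
    out <- array(0, c(size, size, 3L))
    for (ch in 1:3)
      out[, , ch] <- style@baseColour[ch] + stripes +
        stats::rnorm(size * size, 0, style@jitterSd)
    clamp255(round(out))
  })
}

# Flat-colour tissue texture: base colour + Gaussian noise.
renderFlat <- function(colour, h, w, noiseSd, seed) {
  withSeed(seed, {
    out <- array(0, c(h, w, 3L))
    for (ch in 1:3)
      out[, , ch] <- colour[ch] + stats::rnorm(h * w, 0, noiseSd)
    clamp255(round(out))
  })
}

#' Generate one synthetic slide
#'
#' Layout: a background border; a benign-mucosa strip; a smooth-muscle
#' strip; and a tumor block (styled texture) wrapped in a tumor-stroma
#' frame. The tumor region covers well over a quarter of the tissue so
#' the 60 percent tumor-content filter always retains enough patches.
#' The mask is exact by construction. Region edges jitter a few pixels
#' with the seed.
#'
#' @param style a [styleSpec()] style (or a list of two styles for a
#'   mixed-style slide: the tumor block is split half-and-half).
#' @param cfg a [SyntheticCohortConfig-class].
#' @param seed slide seed.
#' @param slideId identifier.
#' @return an annotated [SlideRecord-class] with exact label mask
#'   (callers strip the mask for unlabeled use).
#' @export
generateSlide <- function(style, cfg, seed, slideId = "slide") {
  S <- cfg@slideSize
  sc <- cfg@scheme
  pal <- stylePalette(cfg)
  border <- max(8L, S %/% 10L)
  jit <- withSeed(seed, sample(-4:4, 4L, replace = TRUE))
  i0 <- border + 1L; i1 <- S - border         # interior rows/cols
  mucosaH <- max(24L, S %/% 5L) + jit[1L]
  muscleW <- max(16L, S %/% 8L) + jit[2L]
  stromaT <- max(8L, S %/% 16L)
  img <- renderFlat(pal[[as.character(codeOf(sc, "background"))]], S, S,
                    cfg@noiseSd, deriveSeed(seed, "bg"))
  mask <- matrix(codeOf(sc, "background"), S, S)
  paint <- function(rows, cols, colour, code, tex = NULL) {
    block <- if (is.null(tex))
      renderFlat(colour, length(rows), length(cols), cfg@noiseSd,
                 deriveSeed(seed, paste0("c", code, rows[1], cols[1])))
    else tex
    img[rows, cols, ] <<- block
    mask[rows, cols] <<- code
  }
  # benign mucosa strip across the top of the interior
  paint(i0:(i0 + mucosaH - 1L), i0:i1,
        pal[[as.character(codeOf(sc, "benign_mucosa"))]],
        codeOf(sc, "benign_mucosa"))
  # smooth muscle strip down the left below the mucosa
  lower0 <- i0 + mucosaH
  paint(lower0:i1, i0:(i0 + muscleW - 1L),
        pal[[as.character(codeOf(sc, "smooth_muscle"))]],
        codeOf(sc, "smooth_muscle"))
  # tumor-stroma block filling the rest, tumor core inside it
  tr <- lower0:i1
  tc <- (i0 + muscleW):i1
  paint(tr, tc, pal[[as.character(codeOf(sc, "tumor_stroma"))]],
        codeOf(sc, "tumor_stroma"))
  coreR <- (tr[1L] + stromaT):(tr[length(tr)] - stromaT + jit[3L])
  coreC <- (tc[1L] + stromaT):(tc[length(tc)] - stromaT + jit[4L])
  if (length(coreR) < 48L || length(coreC) < 48L)
    stop("layout infeasible at slide size ", S)
  styles <- if (is(style, "StyleSpec")) list(style) else style
  if (length(styles) == 1L) {
    paint(coreR, coreC, NULL, codeOf(sc, "tumor"),
          tex = renderTexture(styles[[1L]], max(length(coreR), length(coreC)),
                              deriveSeed(seed, "tumor"))[
            seq_along(coreR), seq_along(coreC), , drop = FALSE])
  } else {
    half <- length(coreC) %/% 2L
    for (s in 1:2) {
      cols <- if (s == 1L) coreC[seq_len(half)] else coreC[(half + 1L):length(coreC)]
      paint(coreR, cols, NULL, codeOf(sc, "tumor"),
            tex = renderTexture(styles[[s]], max(length(coreR), length(cols)),
                                deriveSeed(seed, paste0("tumor", s)))[
              seq_along(coreR), seq_along(cols), , drop = FALSE])
    }
  }
  SlideRecord(slideId, img, mpp = 1.0, labelMask = LabelMask(mask, sc))
}

#' Generate a synthetic cohort with ground truth
#'
#' Annotated slides cover the style list round-robin; unlabeled slides are
#' drawn from the same styles (also round-robin, with fresh per-slide
#' seeds, so every style appears among the queries). The truth table maps
#' every slide to its style for matching-accuracy evaluation; unlabeled
#' records are returned without masks, with the exact masks kept in
#' \code{truthMasks}. Fully deterministic given \code{cfg@seed}.
#'
#' @param cfg a [SyntheticCohortConfig-class].
#' @return list with elements \code{annotated} (list of annotated
#'   [SlideRecord-class]), \code{unlabeled} (mask-free records),
#'   \code{truth} (data.frame slide_id, style_id, annotated) and
#'   \code{truthMasks} (named list of [LabelMask-class] for the unlabeled
#'   slides).
#' @export
generateCohort <- function(cfg) {
  nStyles <- length(cfg@styles)
  annotated <- list(); unlabeled <- list(); truthMasks <- list()
  rows <- list()
  for (i in seq_len(cfg@nAnnotated)) {
    st <- cfg@styles[[(i - 1L) %% nStyles + 1L]]
    id <- sprintf("A%02d", i)
    annotated[[id]] <- generateSlide(st, cfg, deriveSeed(cfg@seed, id), id)
    rows[[length(rows) + 1L]] <-
      data.frame(slide_id = id, style_id = st@styleId, annotated = TRUE)
  }
  for (i in seq_len(cfg@nUnlabeled)) {
    id <- sprintf("U%02d", i)
    mixed <- i <= cfg@mixedStyleSlides && nStyles >= 2L
    if (mixed) {
      pair <- cfg@styles[c((i - 1L) %% nStyles + 1L, i %% nStyles + 1L)]
      full <- generateSlide(pair, cfg, deriveSeed(cfg@seed, id), id)
      styleId <- paste0("mixed:", pair[[1L]]@styleId, "+", pair[[2L]]@styleId)
    } else {
      st <- cfg@styles[[(i - 1L) %% nStyles + 1L]]
      full <- generateSlide(st, cfg, deriveSeed(cfg@seed, id), id)
      styleId <- st@styleId
    }
    truthMasks[[id]] <- full@labelMask
    unlabeled[[id]] <- SlideRecord(id, full@image, full@mpp)
    rows[[length(rows) + 1L]] <-
      data.frame(slide_id = id, style_id = styleId, annotated = FALSE)
  }
  list(annotated = unname(annotated), unlabeled = unname(unlabeled),
       truth = do.call(rbind, rows), truthMasks = truthMasks)
}

#' Write a synthetic cohort to disk
#'
#' Slides and masks go out through [writeSlide()], plus a truth-table CSV
#' (slide_id, style_id, annotated).
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$annotated) writeSlide(s, file.path(dir, s@slideId))
  for (s in cohort$unlabeled) writeSlide(s, file.path(dir, s@slideId))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
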