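randomMask <- function(codes, nr = 8L, nc = 8L) {
  LabelMask(matrix(sample(codes, nr * nc, replace = TRUE), nr, nc),
            tinyScheme())
}

test_that("fusion applies the per-pixel expert-precedence rule", {
  sc <- tinyScheme()
  # worked 2x2 example: expert [T, S; B, B], supervised [M, M; M, V]
  ex <- LabelMask(matrix(c(1L, 0L, 2L, 0L), 2), sc)
  su <- LabelMask(matrix(c(3L, 3L, 3L, 4L), 2), sc)
  expect_equal(maskCodes(fuseMasks(ex, su)),
               matrix(c(1L, 3L, 2L, 4L), 2))
  # expert with no tumor codes: output equals the supervised mask
  exNone <- LabelMask(matrix(c(0L, 3L, 4L, 0L), 2), sc)
  expect_equal(maskCodes(fuseMasks(exNone, su)), maskCodes(su))
  # expert all tumor: output all tumor
  exAll <- LabelMask(matrix(1L, 2, 2), sc)
  expect_true(all(maskCodes(fuseMasks(exAll, su)) == 1L))
  expect_error(fuseMasks(ex, LabelMask(matrix(0L, 3, 3), sc)), "shape")
})

test_that("fusion is deterministic, idempotent and verbatim per pixel", {
  set.seed(77)
  sc <- tinyScheme()
  for (i in 1:50) {
    ex <- randomMask(0:4)
    su <- randomMask(0:4)
    fused <- fuseMasks(ex, su)
    useExpert <- ex@codes %in% 1:2
    expect_identical(fused@codes[useExpert], ex@codes[useExpert])
    expect_identical(fused@codes[!useExpert], su@codes[!useExpert])
    # idempotent: fusing the fused mask with the same supervised mask
    # changes nothing at expert-tumor pixels and reproduces itself
    expect_identical(maskCodes(fuseMasks(fused, su)), maskCodes(fused))
  }
})

test_that("artifact application ignores flagged pixels and is idempotent", {
  sc <- tinyScheme()
  m <- LabelMask(matrix(1:0, 4, 4), sc)
  none <- matrix(0L, 4, 4)
  expect_identical(maskCodes(applyArtifactMask(m, none)), maskCodes(m))
  all1 <- matrix(1L, 4, 4)
  expect_true(all(maskCodes(applyArtifactMask(m, all1)) == 255L))
  part <- matrix(0L, 4, 4); part[1, ] <- 1L
  once <- applyArtifactMask(m, part)
  expect_true(all(once@codes[1, ] == 255L))
  expect_identical(maskCodes(applyArtifactMask(once, part)), maskCodes(once))
  expect_error(applyArtifactMask(m, matrix(0L, 2, 2)), "shape")
})

test_that("pseudo-label generation routes through the matched expert", {
  cfg <- syntheticCohortConfig(nAnnotated = 2L, nUnlabeled = 4L,
                               styles = defaultStyles(2L), seed = 42L)
  co <- generateCohort(cfg)
  tc <- toyTiling()
  run <- runPipeline(co$annotated, co$unlabeled, paradigm = "som_ssl",
                     tiling = tc, trainCfg = toyTrainConfig(), seed = 5L)
  truthStyles <- co$truth$style_id[match(run$matches$query_id,
                                         co$truth$slide_id)]
  annStyles <- stats::setNames(co$truth$style_id[co$truth$annotated],
                               co$truth$slide_id[co$truth$annotated])
  expect_equal(unname(annStyles[run$matches$matched_id]), truthStyles)
  # provenance: expert-sourced pixels always carry tumor/stroma codes,
  # and nearly all fused tumor/stroma pixels came from the expert
  for (p in run$pseudo) {
    tumorish <- p@mask@codes %in% 1:2
    fromExpert <- p@provenance == 1L
    expect_true(all(tumorish[fromExpert]))
    expect_gt(mean(fromExpert[tumorish]), 0.95)
    expect_s4_class(p@mask, "LabelMask")
  }
  # slide missing from the matrix errors with guidance
  expect_error(generatePseudolabels(
    SlideRecord("ghost", co$unlabeled[[1]]@image, 1.0),
    run$models$experts, run$similarity, tc$patchSize),
    "similarity")
})

test_that("identical expert and supervised models collapse the fusion", {
  fx <- tinySlide("only", size = 64L)
  cfgT <- trainConfig(epochs = 1L)
  sup <- trainSupervised(list(fx$slide), cfgT, patchSize = 16L, stride = 16L)
  un <- SlideRecord("u1", fx$slide@image, 1.0)
  res <- SwarmSeg:::pseudolabelWithExpert(un, sup, sup, 16L, "only", 1.0)
  direct <- predictSlideMask(sup, un, 16L, 16L)
  expect_identical(maskCodes(res@mask), maskCodes(direct))
})

test_that("the SSL dataset combines regimes and drops all-ignore patches", {
  fx <- tinySlide("ann", size = 64L)
  sc <- tinyScheme()
  un <- SlideRecord("uns", fx$slide@image, 1.0)
  pseudoMask <- LabelMask(fx$mask@codes, sc)
  pseudo <- new("PseudoLabelResult", slideId = "uns", mask = pseudoMask,
                matchedExpert = "ann", similarity = 0.9,
                provenance = matrix(2L, 64, 64))
  ds <- assembleSslDataset(list(fx$slide), list(pseudo), list(un),
                           patchSize = 16L, annotatedStride = 8L)
  nAnn <- nrow(tileOrigins(64, 64, 16, 8))
  nUn <- nrow(tileOrigins(64, 64, 16, 16))
  expect_length(ds, nAnn + nUn)   # counts additive across slides
  # zero pseudo slides reduces to the supervised dataset
  dsSup <- assembleSslDataset(list(fx$slide), list(), list(),
                              patchSize = 16L, annotatedStride = 8L)
  expect_length(dsSup, nAnn)
  # a fully-ignored pseudo slide contributes nothing
  allIgnore <- new("PseudoLabelResult", slideId = "uns",
                   mask = LabelMask(matrix(255L, 64, 64), sc),
                   matchedExpert = "ann", similarity = 0.1,
                   provenance = matrix(0L, 64, 64))
  dsIgn <- assembleSslDataset(list(fx$slide), list(allIgnore), list(un),
                              patchSize = 16L, annotatedStride = 8L)
  expect_length(dsIgn, nAnn)
})
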