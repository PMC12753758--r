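test_that("tumor fraction counts ignore pixels in the denominator", {
  sc <- tinyScheme()
  expect_equal(tumorFraction(LabelMask(matrix(1L, 4, 4), sc), 1:2), 1.0)
  m <- matrix(c(1L, 1L, 1L, 0L), 2)
  expect_equal(tumorFraction(LabelMask(m, sc), 1:2), 0.75)
  expect_equal(tumorFraction(LabelMask(matrix(0L, 3, 3), sc), 1:2), 0.0)
  mixed <- matrix(c(1L, 255L, 255L, 255L), 2)
  expect_equal(tumorFraction(LabelMask(mixed, sc), 1:2), 0.25)
  expect_error(tumorFraction(matrix(integer(), 0, 0), 1L), "empty")
})

test_that("the 60% filter is strict and monotone in the threshold", {
  sc <- tinyScheme()
  mkPatch <- function(nTumor) {
    codes <- matrix(0L, 10, 10)
    if (nTumor > 0) codes[seq_len(nTumor)] <- 1L
    maskedPatch(codes)
  }
  patches <- lapply(c(50, 60, 61, 100), mkPatch)
  cfg <- similarityConfig()
  kept <- filterTumorPatches(patches, cfg, 1:2)
  # exactly 60% is excluded (strictly more than 60% required)
  expect_length(kept, 2L)
  expect_equal(sapply(kept, function(p) sum(p@mask@codes == 1L)), c(61, 100))
  # raising the threshold never increases the retained count
  thresholds <- c(0.2, 0.4, 0.6, 0.75, 0.9)
  counts <- sapply(thresholds, function(th)
    length(filterTumorPatches(patches, similarityConfig(
      tumorContentThreshold = th), 1:2)))
  expect_true(all(diff(counts) <= 0))
  expect_length(filterTumorPatches(list(), cfg, 1L), 0L)
})

test_that("representative selection matches the exhaustive min-SSE oracle", {
  # two tight 1-D triplets: clusters {0, .1, .2} and {10, 10.1, 10.2},
  # centroid-nearest members 0.1 and 10.1
  x <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  got <- selectRepresentatives(featureSetOf(x),
                               similarityConfig(kRepresentatives = 2L))
  expect_equal(sort(as.vector(got@vectors)), c(0.1, 10.1))
  # degenerate collapse: identical vectors give a single representative
  same <- matrix(1.5, 3, 2)
  got <- selectRepresentatives(featureSetOf(same), similarityConfig())
  expect_equal(dim(got@vectors), c(1L, 2L))
  expect_equal(got@vectors[1, ], c(1.5, 1.5))
  # n >= 5 distinct vectors: exactly 5 representatives, all members
  set.seed(3)
  x <- matrix(rnorm(16), 8, 2)
  got <- selectRepresentatives(featureSetOf(x), similarityConfig())
  expect_equal(nrow(got@vectors), 5L)
  expect_true(all(apply(got@vectors, 1, function(r)
    any(apply(x, 1, function(v) all(v == r))))))
  expect_error(selectRepresentatives(featureSetOf(matrix(0, 0, 2)),
                                     similarityConfig()),
               "insufficient tumor patches")
  # determinism under the configured seed
  a <- selectRepresentatives(featureSetOf(x), similarityConfig(kmeansSeed = 5L))
  b <- selectRepresentatives(featureSetOf(x), similarityConfig(kmeansSeed = 5L))
  expect_identical(a@vectors, b@vectors)
})

test_that("mean pairwise similarity averages the full comparison grid", {
  # hand-computed 2x2 unit-vector grid: (1 + 0.70711 + 0 + 0.70711) / 4
  a <- repSetOf(rbind(c(1, 0), c(0, 1)), "a")
  b <- repSetOf(rbind(c(1, 0), c(0.70711, 0.70711)), "b")
  expect_equal(pairwiseMeanSimilarity(a, b), 0.603553, tolerance = 1e-5)
  expect_equal(pairwiseMeanSimilarity(a, b), pairwiseMeanSimilarity(b, a))
  one <- repSetOf(rbind(c(3, 4)), "one")
  expect_equal(pairwiseMeanSimilarity(one, one), 1.0)
  # 5 + 5 representatives average exactly 25 comparisons
  set.seed(11)
  r5a <- repSetOf(matrix(rnorm(15), 5, 3), "ra")
  r5b <- repSetOf(matrix(rnorm(15), 5, 3), "rb")
  grid <- SwarmSeg:::metricGrid(r5a@vectors, r5b@vectors, "cosine")
  expect_equal(length(grid), 25L)
  expect_equal(pairwiseMeanSimilarity(r5a, r5b), mean(grid))
  # negated distances: identical sets score 0, symmetric
  expect_equal(pairwiseMeanSimilarity(one, one, "neg_L1"), 0)
  expect_equal(pairwiseMeanSimilarity(one, one, "neg_L2"), 0)
  expect_equal(pairwiseMeanSimilarity(r5a, r5b, "neg_L1"),
               pairwiseMeanSimilarity(r5b, r5a, "neg_L1"))
  zero <- repSetOf(rbind(c(0, 0)), "z")
  expect_error(pairwiseMeanSimilarity(zero, one), "zero-norm")
})

test_that("self-similarity is 1 only for identical representatives", {
  mixed <- repSetOf(rbind(c(1, 0), c(0.9, 0.1)), "m")
  expect_lt(pairwiseMeanSimilarity(mixed, mixed), 1.0)
  same <- repSetOf(rbind(c(2, 1), c(2, 1)), "s")
  expect_equal(pairwiseMeanSimilarity(same, same), 1.0)
})

test_that("similarity matrices are complete, symmetric and exportable", {
  set.seed(21)
  anns <- lapply(1:3, function(i)
    repSetOf(matrix(rnorm(10) + i, 5, 2), paste0("A", i)))
  qrys <- lapply(1:2, function(i)
    repSetOf(matrix(rnorm(10), 5, 2), paste0("U", i)))
  sm <- buildSimilarityMatrix(anns, qrys)
  expect_equal(dim(sm@values), c(2L, 3L))
  expect_true(all(is.finite(sm@values)))
  # query identical to an annotated slide with one representative: entry 1
  single <- repSetOf(rbind(c(1, 2)), "A1")
  qsame <- repSetOf(rbind(c(2, 4)), "Uq")  # parallel vector: cosine 1
  sm1 <- buildSimilarityMatrix(list(single), list(qsame))
  expect_equal(sm1@values[1, 1], 1.0)
  # annotated-vs-annotated grid is symmetric
  smAA <- buildSimilarityMatrix(anns, anns)
  expect_equal(smAA@values, t(smAA@values), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(buildSimilarityMatrix(list(anns[[1]], anns[[1]]), qrys),
               "duplicate")
  dir <- withr::local_tempdir()
  exportSimilarityMatrix(sm, file.path(dir, "m.csv"), file.path(dir, "m.json"))
  csv <- utils::read.csv(file.path(dir, "m.csv"))
  expect_equal(csv$query_id, c("U1", "U2"))
  expect_equal(unname(as.matrix(csv[, -1])), unname(sm@values),
               tolerance = 1e-12)
})

test_that("expert matching takes arg-max with lexicographic tie-break", {
  sm <- new("SimilarityMatrix", annotatedIds = c("A", "B", "C"),
            queryIds = c("q1", "q2", "q3"),
            values = rbind(c(0.4, 0.9, 0.1),
                           c(0.7, 0.7, 0.1),
                           c(0.2, 0.2, 0.2)),
            metric = "cosine")
  expect_equal(matchExpert(sm, "q1"), "B")
  expect_equal(matchExpert(sm, "q2"), "A")  # tie breaks to smallest id
  expect_equal(matchExpert(sm, "q3"), "A")
  expect_error(matchExpert(sm, "nope"), "unknown query")
  tbl <- matchAllExperts(sm)
  expect_equal(tbl$matched_id, c("B", "A", "A"))
  expect_equal(tbl$similarity, c(0.9, 0.7, 0.2))
  # single annotated slide: always that slide
  sm1 <- new("SimilarityMatrix", annotatedIds = "only",
             queryIds = "q", values = matrix(0.123), metric = "cosine")
  expect_equal(matchExpert(sm1, "q"), "only")
})

test_that("cosine and neg_L2 arg-max agree on L2-normalized vectors", {
  # per pair, cosine is monotone in -|u - v| on the unit sphere, so with
  # one representative per slide the two metrics must pick the same expert
  set.seed(31)
  for (rep in 1:30) {
    anns <- lapply(1:4, function(i) {
      m <- matrix(rnorm(6), 1, 6)
      repSetOf(m / sqrt(sum(m^2)), paste0("A", i))
    })
    m <- matrix(rnorm(6), 1, 6)
    q <- list(repSetOf(m / sqrt(sum(m^2)), "q"))
    mCos <- buildSimilarityMatrix(anns, q, "cosine")
    mL2 <- buildSimilarityMatrix(anns, q, "neg_L2")
    expect_equal(matchExpert(mCos, "q"), matchExpert(mL2, "q"))
  }
})
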