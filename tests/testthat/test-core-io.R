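test_that("tile origins follow the clamped-grid rule and cover every pixel", {
  expect_equal(tileOrigins(512, 512, 512, 512),
               cbind(x0 = 0L, y0 = 0L))
  expect_equal(tileOrigins(1024, 512, 512, 512),
               cbind(x0 = c(0L, 512L), y0 = c(0L, 0L)))
  # overlapping regime: per-axis starts {0, 384, 512}, 9 tiles
  o <- tileOrigins(1024, 1024, 512, 384)
  expect_equal(nrow(o), 9L)
  expect_equal(sort(unique(o[, "x0"])), c(0L, 384L, 512L))
  expect_equal(sort(unique(o[, "y0"])), c(0L, 384L, 512L))
  # brute-force coverage and no out-of-bounds tiles, several geometries
  cases <- list(c(100, 70, 32, 32), c(97, 65, 32, 24), c(64, 64, 64, 1),
                c(130, 41, 40, 33))
  for (cs in cases) {
    o <- tileOrigins(cs[1], cs[2], cs[3], cs[4])
    expect_true(all(o[, "x0"] + cs[3] <= cs[1]))
    expect_true(all(o[, "y0"] + cs[3] <= cs[2]))
    expect_false(any(duplicated(o)))
    covered <- matrix(FALSE, cs[2], cs[1])
    for (i in seq_len(nrow(o)))
      covered[o[i, "y0"] + seq_len(cs[3]), o[i, "x0"] + seq_len(cs[3])] <- TRUE
    expect_true(all(covered))
  }
  # stride = patch: pairwise disjoint mosaic (pixel counted exactly once)
  o <- tileOrigins(96, 96, 32, 32)
  counts <- matrix(0L, 96, 96)
  for (i in seq_len(nrow(o)))
    counts[o[i, "y0"] + 1:32, o[i, "x0"] + 1:32] <-
      counts[o[i, "y0"] + 1:32, o[i, "x0"] + 1:32] + 1L
  expect_true(all(counts == 1L))
  expect_error(tileOrigins(100, 100, 128, 32), "too small")
})

test_that("patch extraction is exact, deterministic and bounds-checked", {
  fx <- tinySlide(size = 48L)
  s <- fx$slide
  p <- extractPatch(s, c(0L, 0L), 48L, withMask = TRUE)
  expect_identical(p@pixels, s@image)
  expect_identical(p@mask@codes, fx$mask@codes)
  p1 <- extractPatch(s, c(8L, 4L), 16L)
  p2 <- extractPatch(s, c(8L, 4L), 16L)
  expect_identical(p1@pixels, p2@pixels)
  # (x, y) = (column, row): x offsets move along columns
  expect_identical(p1@pixels[1, 1, ], s@image[5, 9, ])
  expect_error(extractPatch(s, c(40L, 0L), 16L), "out of bounds")
  # all-tumor mask region stays all tumor in the crop
  core <- extractPatch(s, c(30L, 30L), 8L, withMask = TRUE)
  expect_true(all(core@mask@codes == 1L))
})

test_that("rescaling halves dimensions by mpp ratio and preserves mask codes", {
  fx <- tinySlide(size = 64L, mpp = 0.25)
  s <- fx$slide
  expect_identical(rescaleToTarget(s, 0.25), s)
  r <- rescaleToTarget(s, 1.0)   # 4x downscale: 40x scan to 10x working
  expect_equal(dim(r@image), c(16L, 16L, 3L))
  expect_equal(r@mpp, 1.0)
  expect_true(all(unique(as.vector(r@labelMask@codes)) %in%
                  unique(as.vector(s@labelMask@codes))))
  # non-square geometry maps each axis independently
  img <- array(100, c(20, 40, 3))
  s2 <- SlideRecord("ns", img, 0.5)
  r2 <- rescaleToTarget(s2, 1.0)
  expect_equal(dim(r2@image)[1:2], c(10L, 20L))
  expect_error(rescaleToTarget(s, -1), "positive")
})

test_that("label mask PNG round trips are byte exact and validated", {
  sc <- tinyScheme()
  set.seed(42)
  codes <- matrix(sample(c(0:4, 255L), 30 * 20, replace = TRUE), 30, 20)
  m <- LabelMask(codes, sc)
  path <- withr::local_tempfile(fileext = ".png")
  writeLabelMask(m, path)
  back <- readLabelMask(path, sc)
  expect_identical(back@codes, m@codes)
  # all-ignore masks are legal
  allIgnore <- LabelMask(matrix(255L, 4, 4), sc)
  writeLabelMask(allIgnore, path)
  expect_identical(readLabelMask(path, sc)@codes, allIgnore@codes)
  # out-of-scheme code errors and names the offender
  png::writePNG(matrix(200 / 255, 4, 4), path)
  expect_error(readLabelMask(path, sc), "200")
  expect_error(LabelMask(matrix(7L, 2, 2), sc), "outside the scheme")
})

test_that("class schemes validate and round trip through JSON", {
  sc <- defaultClassScheme()
  expect_length(schemeLabels(sc), 12L)
  expect_equal(tumorCodes(sc), c(1L, 2L))
  expect_equal(codeOf(sc, "tumor_stroma"), 2L)
  expect_error(ClassScheme(c("a", "b"), c(1L, 1L)), "unique")
  expect_error(ClassScheme(c("a", "b"), 0:1, tumorCodes = 5L), "subset")
  expect_error(ClassScheme(c("a", "b"), 0:1, ignoreCode = 1L), "ignoreCode")
  path <- withr::local_tempfile(fileext = ".json")
  writeClassScheme(sc, path)
  back <- readClassScheme(path)
  expect_equal(schemeLabels(back), schemeLabels(sc))
  expect_equal(schemeCodes(back), schemeCodes(sc))
  expect_equal(ignoreCode(back), ignoreCode(sc))
})

test_that("slide records enforce their invariants and round trip to disk", {
  fx <- tinySlide(size = 32L)
  expect_true(isAnnotated(fx$slide))
  expect_error(SlideRecord("x", fx$slide@image, -0.5), "positive")
  expect_error(SlideRecord("x", fx$slide@image, 1,
                           labelMask = LabelMask(matrix(0L, 4, 4),
                                                 tinyScheme())),
               "match the image")
  dir <- withr::local_tempdir()
  am <- matrix(0L, 32, 32); am[1:4, 1:4] <- 1L
  s <- SlideRecord("disk1", fx$slide@image, 0.5,
                   labelMask = fx$slide@labelMask, artifactMask = am)
  writeSlide(s, file.path(dir, "disk1"))
  back <- readSlide(file.path(dir, "disk1"), tinyScheme())
  expect_identical(back@image, s@image)
  expect_identical(back@labelMask@codes, s@labelMask@codes)
  expect_identical(back@artifactMask, s@artifactMask)
  expect_equal(back@mpp, 0.5)
})
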