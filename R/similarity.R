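#' Construct a SimilarityConfig
#'
#' @param tumorContentThreshold strict lower bound on the tumor area
#'   fraction for a patch to enter similarity assessment (default 0.60:
#'   patches with more than 60 percent tumor are retained).
#' @param kRepresentatives number of K-means clusters / representative
#'   vectors per slide (default 5, giving 25 pair comparisons per slide
#'   pair).
#' @param metric \code{"cosine"} (default), \code{"neg_L1"} or
#'   \code{"neg_L2"}; distances are negated so arg-max always selects the
#'   most similar slide.
#' @param kmeansSeed,kmeansRestarts seed and number of k-means++ restarts
#'   (default 10) behind [selectRepresentatives()].
#' @return a [SimilarityConfig-class].
#' @export
similarityConfig <- function(tumorContentThreshold = 0.60,
                             kRepresentatives = 5L,
                             metric = c("cosine", "neg_L1", "neg_L2"),
                             kmeansSeed = 1L, kmeansRestarts = 10L) {
  new("SimilarityConfig",
      tumorContentThreshold = tumorContentThreshold,
      kRepresentatives = as.integer(kRepresentatives),
      metric = match.arg(metric),
      kmeansSeed = as.integer(kmeansSeed),
      kmeansRestarts = as.integer(kmeansRestarts))
}

#' Tumor area fraction of a mask crop
#'
#' Fraction of pixels whose code lies in \code{tumorCodes}; ignore pixels
#' count in the denominator (an unannotated or artifact pixel dilutes the
#' tumor content rather than being excluded).
#'
#' @param mask a [LabelMask-class] or integer matrix of codes.
#' @param tumorCodes integer codes counted as tumor.
#' @return fraction in [0, 1].
#' @examples
#' sc <- ClassScheme(c("background", "tumor"), 0:1, tumorCodes = 1L)
#' tumorFraction(LabelMask(matrix(c(1L, 1L, 1L, 0L), 2), sc), 1L)  # 0.75
#' @export
tumorFraction <- function(mask, tumorCodes) {
  codes <- if (is(mask, "LabelMask")) mask@codes else mask
  if (length(codes) == 0L) stop("empty mask crop")
  mean(codes %in% tumorCodes)
}

#' Retain patches with more than the threshold tumor content
#'
#' Strict inequality at the threshold: a patch at exactly 60 percent tumor
#' content is excluded under the default configuration. Order is
#' preserved; the result may be empty.
#'
#' @param patches list of [Patch-class], each carrying a mask (ground
#'   truth for annotated slides, a tumor-locator prediction for unlabeled
#'   slides).
#' @param cfg a [SimilarityConfig-class].
#' @param tumorCodes integer codes counted as tumor for the filter.
#' @return the retained sublist of \code{patches}.
#' @export
filterTumorPatches <- function(patches, cfg, tumorCodes) {
  if (length(patches) == 0L) return(patches)
  keep <- vapply(patches, function(p) {
    if (is.null(p@mask))
      stop("patch at (", p@origin[1], ", ", p@origin[2],
           ") carries no mask; tumor filtering needs one")
    tumorFraction(p@mask, tumorCodes) > cfg@tumorContentThreshold
  }, logical(1))
  patches[keep]
}

# k-means++ seeding: distance-proportional sampling of k initial centers
# from the rows of x (assumes the caller set the RNG state).
kmeansPPInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) i <- sample.int(n, 1L)
      else i <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

# Best-of-restarts k-means via stats::kmeans (Hartigan-Wong) with
# k-means++ seeding. Returns the fit with the lowest total within-cluster
# SSE over the restarts.
kmeansBest <- function(x, k, seed, restarts) {
  distinct <- unique(x)
  if (k >= nrow(distinct)) {
    # one cluster per distinct vector: assignment is exact, no search needed
    centers <- distinct
    cl <- apply(x, 1L, function(r)
      which.min(colSums((t(centers) - r)^2)))
    return(list(centers = centers, cluster = as.integer(cl)))
  }
  withSeed(seed, {
    best <- NULL
    bestSSE <- Inf
    for (r in seq_len(restarts)) {
      init <- kmeansPPInit(distinct, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$tot.withinss < bestSSE - 1e-12) {
        best <- fit
        bestSSE <- fit$tot.withinss
      }
    }
    if (is.null(best))
      stop("k-means failed on all restarts")
    list(centers = best$centers, cluster = as.integer(best$cluster))
  })
}

#' Select centroid-nearest representative vectors of a slide
#'
#' Runs K-means (k-means++ seeding, Lloyd iterations, best of
#' \code{kmeansRestarts} restarts under \code{kmeansSeed}) with
#' \code{kEff = min(kRepresentatives, number of distinct vectors)} on the
#' slide's tumor-patch embeddings, then returns, for each cluster, the
#' input vector closest (Euclidean) to its centroid; distance ties break
#' to the lowest row index. Every representative is an exact member of the
#' input.
#'
#' @param features a non-empty [FeatureSet-class].
#' @param cfg a [SimilarityConfig-class].
#' @return a [RepresentativeSet-class], rows ordered by cluster index.
#' @export
selectRepresentatives <- function(features, cfg) {
  x <- features@vectors
  if (nrow(x) == 0L)
    stop("insufficient tumor patches: slide '", features@slideId,
         "' has an empty feature set")
  kEff <- min(cfg@kRepresentatives, nrow(unique(x)))
  fit <- kmeansBest(x, kEff, cfg@kmeansSeed, cfg@kmeansRestarts)
  reps <- matrix(NA_real_, kEff, ncol(x))
  refs <- matrix(NA_integer_, kEff, 2L)
  for (j in seq_len(kEff)) {
    members <- which(fit$cluster == j)
    d2 <- colSums((t(x[members, , drop = FALSE]) - fit$centers[j, ])^2)
    pick <- members[which.min(d2)]   # which.min: first = lowest row index
    reps[j, ] <- x[pick, ]
    refs[j, ] <- features@patchRefs[pick, ]
  }
  colnames(refs) <- c("x0", "y0")
  new("RepresentativeSet", slideId = features@slideId, vectors = reps,
      sourceRefs = refs)
}

setMethod("show", "RepresentativeSet", function(object) {
  cat(sprintf("RepresentativeSet '%s': %d exemplars x d=%d\n",
              object@slideId, nrow(object@vectors), ncol(object@vectors)))
})

# Pairwise metric grid between the rows of two matrices.
metricGrid <- function(a, b, metric, idA = "a", idB = "b") {
  switch(metric,
    cosine = {
      na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
      if (any(na == 0))
        stop("zero-norm representative vector in slide '", idA,
             "' (row ", which(na == 0)[1], "); cosine undefined")
      if (any(nb == 0))
        stop("zero-norm representative vector in slide '", idB,
             "' (row ", which(nb == 0)[1], "); cosine undefined")
      (a / na) %*% t(b / nb)
    },
    neg_L1 = {
      g <- matrix(0, nrow(a), nrow(b))
      for (i in seq_len(nrow(a)))
        g[i, ] <- -colSums(abs(t(b) - a[i, ]))
      g
    },
    neg_L2 = {
      g <- matrix(0, nrow(a), nrow(b))
      for (i in seq_len(nrow(a)))
        g[i, ] <- -sqrt(colSums((t(b) - a[i, ])^2))
      g
    },
    stop("unknown metric: ", metric))
}

#' Mean pairwise similarity between two representative sets
#'
#' The slide-to-slide similarity: the mean of the metric over all
#' \code{|a| * |b|} ordered pairs of representatives (25 comparisons for
#' the default 5 + 5), collapsed into one value. Symmetric in its
#' arguments.
#'
#' @param a,b [RepresentativeSet-class] objects (non-empty).
#' @param metric \code{"cosine"} (u.v / (|u||v|)), \code{"neg_L1"}
#'   (-sum |u_i - v_i|) or \code{"neg_L2"} (-|u - v|).
#' @return a single numeric similarity.
#' @examples
#' a <- new("RepresentativeSet", slideId = "a",
#'          vectors = rbind(c(1, 0), c(0, 1)),
#'          sourceRefs = matrix(0L, 2, 2))
#' b <- new("RepresentativeSet", slideId = "b",
#'          vectors = rbind(c(1, 0), c(0.70711, 0.70711)),
#'          sourceRefs = matrix(0L, 2, 2))
#' pairwiseMeanSimilarity(a, b)  # ~ 0.60355
#' @export
pairwiseMeanSimilarity <- function(a, b,
                                   metric = c("cosine", "neg_L1", "neg_L2")) {
  metric <- match.arg(metric)
  if (nrow(a@vectors) == 0L || nrow(b@vectors) == 0L)
    stop("representative sets must be non-empty")
  mean(metricGrid(a@vectors, b@vectors, metric, a@slideId, b@slideId))
}

#' Build the annotated x query similarity matrix
#'
#' @param annotated list of [RepresentativeSet-class] for annotated slides.
#' @param queries list of [RepresentativeSet-class] for query (unlabeled)
#'   slides.
#' @inheritParams pairwiseMeanSimilarity
#' @return a [SimilarityMatrix-class]: complete grid, rows = queries,
#'   columns = annotated slides.
#' @export
buildSimilarityMatrix <- function(annotated, queries,
                                  metric = c("cosine", "neg_L1", "neg_L2")) {
  metric <- match.arg(metric)
  if (length(annotated) == 0L || length(queries) == 0L)
    stop("annotated and query lists must be non-empty")
  aIds <- vapply(annotated, function(r) r@slideId, character(1))
  qIds <- vapply(queries, function(r) r@slideId, character(1))
  if (anyDuplicated(aIds))
    stop("duplicate annotated slide ids: ",
         paste(unique(aIds[duplicated(aIds)]), collapse = ", "))
  if (anyDuplicated(qIds))
    stop("duplicate query slide ids: ",
         paste(unique(qIds[duplicated(qIds)]), collapse = ", "))
  values <- matrix(NA_real_, length(queries), length(annotated),
                   dimnames = list(qIds, aIds))
  for (q in seq_along(queries))
    for (a in seq_along(annotated))
      values[q, a] <- pairwiseMeanSimilarity(queries[[q]], annotated[[a]],
                                             metric)
  new("SimilarityMatrix", annotatedIds = aIds, queryIds = qIds,
      values = values, metric = metric)
}

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d queries x %d annotated\n",
              object@metric, length(object@queryIds),
              length(object@annotatedIds)))
  if (length(object@values))
    cat(sprintf("  range: [%.4f, %.4f]\n", min(object@values),
                max(object@values)))
})

#' Match a query slide to its morphology expert
#'
#' Arg-max of the query's row of the similarity matrix; exact ties break
#' to the lexicographically smallest annotated slide id. For negated
#' distance metrics the arg-max equals the arg-min of the distance.
#'
#' @param matrix a [SimilarityMatrix-class].
#' @param queryId a query slide id present in the matrix.
#' @return the matched annotated slide id.
#' @export
matchExpert <- function(matrix, queryId) {
  q <- match(queryId, matrix@queryIds)
  if (is.na(q)) stop("unknown query slide: ", queryId)
  row <- matrix@values[q, ]
  best <- which(row == max(row))
  cand <- matrix@annotatedIds[best]
  sort(cand)[1L]
}

#' Matching table for every query slide
#'
#' @param matrix a [SimilarityMatrix-class].
#' @return data.frame with columns \code{query_id}, \code{matched_id},
#'   \code{similarity}.
#' @export
matchAllExperts <- function(matrix) {
  matched <- vapply(matrix@queryIds, function(q) matchExpert(matrix, q),
                    character(1))
  sim <- vapply(seq_along(matrix@queryIds), function(i)
    matrix@values[i, match(matched[i], matrix@annotatedIds)], numeric(1))
  data.frame(query_id = matrix@queryIds, matched_id = unname(matched),
             similarity = sim, row.names = NULL)
}

#' Export a similarity matrix as CSV and JSON
#'
#' CSV rows are queries, columns annotated slide ids; JSON carries the
#' grid plus metric metadata.
#'
#' @param matrix a [SimilarityMatrix-class].
#' @param csvPath,jsonPath output paths (either may be NULL to skip).
#' @return invisibly, the matrix.
#' @export
exportSimilarityMatrix <- function(matrix, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) {
    df <- as.data.frame(matrix@values)
    utils::write.csv(cbind(query_id = matrix@queryIds, df), csvPath,
                     row.names = FALSE)
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(metric = matrix@metric, annotated_ids = matrix@annotatedIds,
           query_ids = matrix@queryIds,
           values = apply(matrix@values, 1L, as.numeric, simplify = FALSE)),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(matrix)
}
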