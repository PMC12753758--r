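# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals
#' (k-means restarts, train/val splits, texture synthesis) never perturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a hash of a character string, reduced to a positive integer
# below 2^31. Used to derive stable per-slide seeds and config hashes.
fnvHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

# Derive a child seed from a base seed and a string tag, kept < 2^31.
deriveSeed <- function(seed, tag) {
  as.integer((as.double(seed) + as.double(fnvHash(tag))) %% .Machine$integer.max)
}

clamp255 <- function(x) {
  d <- dim(x)
  out <- pmin(255, pmax(0, x))
  dim(out) <- d
  out
}

# Rec. 601 luminance of an HxWx3 raster (0-255 scale).
luminance <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

isWholeNumber <- function(x, tol = 1e-8) all(abs(x - round(x)) < tol)
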