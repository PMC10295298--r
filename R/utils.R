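# Internal helpers shared across modules.

# Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Peak-normalize a nonnegative spectrum to max 1.
peakNormalize <- function(x) {
  m <- max(x)
  if (m <= 0) stop("degenerate spectrum: all-zero, cannot peak-normalize")
  x / m
}

# Flatten a (band, row, col) cube into a B x N pixel matrix whose columns
# are in the same order as the elements of a (row, col) matrix.
pixelMatrix <- function(data) {
  d <- dim(data)
  dim(data) <- c(d[1L], d[2L] * d[3L])
  data
}

# Inverse of pixelMatrix for one scalar image.
asImage <- function(v, shape) matrix(v, nrow = shape[1L], ncol = shape[2L])

# Ellipse membership on a pixel grid (centers at integer coordinates).
ellipseMask <- function(shape, center, axes) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c_ <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  ((r - center[1L]) / axes[1L])^2 + ((c_ - center[2L]) / axes[2L])^2 <= 1
}

stopIfNot <- function(ok, ...) if (!ok) stop(..., call. = FALSE)
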