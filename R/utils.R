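# Internal helpers: classed errors, seeded evaluation, small image filters.

stopClassed <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "peelstackError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopInput <- function(fmt, ...) stopClassed("peelstackInputError", fmt, ...)
stopIO <- function(fmt, ...) stopClassed("peelstackIOError", fmt, ...)
stopDetection <- function(fmt, ...) stopClassed("peelstackDetectionError", fmt, ...)
stopConfig <- function(fmt, ...) stopClassed("peelstackConfigError", fmt, ...)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed from a master seed (Lehmer step + offset),
# kept below 2^31 so it is a valid R integer seed.
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
             k) %% 2147483647L
}

# 1-D Gaussian convolution along one dimension of an array, truncated at
# 3 sigma with edge renormalization (the kernel is re-normalized over the
# in-bounds support, so constants are preserved and output range never
# exceeds input range).
gaussAlong <- function(a, sigma, along) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  nd <- length(d)
  perm <- c(along, setdiff(seq_len(nd), along))
  M <- aperm(a, perm)
  dm <- dim(M)
  n <- d[along]
  M <- matrix(M, nrow = n)
  K <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(seq(-K, K), sd = sigma)
  acc <- matrix(0, n, ncol(M))
  norm <- numeric(n)
  for (j in seq_along(w)) {
    k <- j - K - 1L
    lo <- max(1L, 1L - k)
    hi <- min(n, n - k)
    if (lo > hi) next
    io <- seq.int(lo, hi)
    acc[io, ] <- acc[io, ] + w[j] * M[io + k, , drop = FALSE]
    norm[io] <- norm[io] + w[j]
  }
  acc <- acc / norm
  aperm(array(acc, dm), order(perm))
}

# Isotropic separable Gaussian over all dimensions of a 2-D or 3-D array.
gaussSmooth <- function(a, sigma) {
  for (d in seq_along(dim(a))) a <- gaussAlong(a, sigma, d)
  a
}

# Exact 2-D median filter, square window of the given radius, replicated
# borders.  Exactness matters: height values are in slice units and must
# not be quantized (rules out constant-time approximate filters).
medianFilter2D <- function(m, radius) {
  if (radius <= 0) return(m)
  ny <- nrow(m)
  nx <- ncol(m)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  win <- matrix(0, ny * nx, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    yy <- pmin(pmax(seq_len(ny) + offs$dy[j], 1L), ny)
    xx <- pmin(pmax(seq_len(nx) + offs$dx[j], 1L), nx)
    win[, j] <- m[yy, xx]
  }
  matrix(apply(win, 1L, stats::median), ny, nx)
}

# Smallest power of two >= x (>= 1); used as a lossless float scale.
pow2Ceiling <- function(x) {
  x <- max(1, x)
  2^ceiling(log2(x))
}

isWholeNumber <- function(x, tol = 0) all(x == floor(x))
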