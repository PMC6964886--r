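# Fixtures built in code; no binary files on disk.

# Step-surface stack: marker 0 above z = step, `signal` from z = step on,
# in every column.  Returns a single-channel ImageStack.
stepStack <- function(nz = 10L, ny = 8L, nx = 8L, step = 5L, signal = 100) {
  v <- array(0, c(nz, ny, nx))
  v[(step + 1L):nz, , ] <- signal
  ImageStack(v)
}

# Seeded random integer stack (single channel unless nc > 1).
randomIntStack <- function(nz, ny, nx, nc = 1L, maxI = 200L, seed = 1L) {
  set.seed(seed)
  v <- array(sample.int(maxI + 1L, nc * nz * ny * nx, replace = TRUE) - 1L,
             c(nc, nz, ny, nx))
  ImageStack(array(as.numeric(v), dim(v)))
}

# Random single-run-per-column mask (each column selects one contiguous,
# possibly empty, z interval).
randomRunMask <- function(nz, ny, nx, seed = 1L) {
  set.seed(seed)
  m <- array(FALSE, c(nz, ny, nx))
  for (yy in seq_len(ny)) {
    for (xx in seq_len(nx)) {
      lo <- sample.int(nz + 1L, 1L)
      if (lo > nz) next
      hi <- sample(lo:nz, 1L)
      m[lo:hi, yy, xx] <- TRUE
    }
  }
  LayerMask(m)
}

# Brute-force oracle for the layer rule: a voxel at zero-based z belongs
# to the layer iff the real number z lies in [h + o, h + o + d) — the
# half-open interval applied directly, with no ceiling arithmetic.
bruteForceMask <- function(h, offset, depth, nz) {
  ny <- nrow(h); nx <- ncol(h)
  m <- array(FALSE, c(nz, ny, nx))
  for (yy in seq_len(ny)) for (xx in seq_len(nx)) for (z0 in 0:(nz - 1L)) {
    lo <- h[yy, xx] + offset
    m[z0 + 1L, yy, xx] <- (z0 >= lo) && (z0 < lo + depth)
  }
  m
}

# Brute-force oracle for nearest-valid-neighbour gap filling with the
# smallest-(y, x) lexicographic tie-break.
bruteForceFill <- function(h, valid) {
  ny <- nrow(h); nx <- ncol(h)
  vy <- row(valid)[valid]; vx <- col(valid)[valid]
  out <- h
  for (yy in seq_len(ny)) for (xx in seq_len(nx)) {
    if (valid[yy, xx]) next
    d2 <- (vy - yy)^2 + (vx - xx)^2
    best <- which(d2 == min(d2))
    best <- best[order(vy[best], vx[best])][1L]
    out[yy, xx] <- h[vy[best], vx[best]]
  }
  out
}

# Brute-force square-window median with replicated borders.
bruteForceMedian <- function(m, radius) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (yy in seq_len(ny)) for (xx in seq_len(nx)) {
    ys <- pmin(pmax((yy - radius):(yy + radius), 1L), ny)
    xs <- pmin(pmax((xx - radius):(xx + radius), 1L), nx)
    out[yy, xx] <- median(m[ys, xs])
  }
  out
}
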