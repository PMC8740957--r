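# Independent oracles and small fixture builders shared across tests.

# direct (loop-free but naive) 3D same-padding correlation, double precision
naiveConv3 <- function(X, W, b) {
  Cin <- dim(X)[1]; dd <- dim(X)[-1]
  Cout <- dim(W)[1]; k <- dim(W)[3]; h <- k %/% 2
  Y <- array(0, c(Cout, dd))
  for (co in seq_len(Cout)) for (x in seq_len(dd[1])) for (y in seq_len(dd[2]))
    for (z in seq_len(dd[3])) {
      acc <- b[co]
      for (ci in seq_len(Cin)) for (kx in seq_len(k)) for (ky in seq_len(k))
        for (kz in seq_len(k)) {
          sx <- x + kx - 1 - h; sy <- y + ky - 1 - h; sz <- z + kz - 1 - h
          if (sx >= 1 && sx <= dd[1] && sy >= 1 && sy <= dd[2] &&
              sz >= 1 && sz <= dd[3])
            acc <- acc + W[co, ci, kx, ky, kz] * X[ci, sx, sy, sz]
        }
      Y[co, x, y, z] <- acc
    }
  Y
}

# separable 1D zero-extension convolution along one axis, plain R
naiveSepConv1 <- function(a, taps, axis) {
  d <- dim(a); h <- (length(taps) - 1) / 2
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (t in seq_along(taps)) {
      p <- c(i, j, k)
      p[axis] <- p[axis] + t - 1 - h
      if (p[axis] >= 1 && p[axis] <= d[axis])
        acc <- acc + taps[t] * a[p[1], p[2], p[3]]
    }
    out[i, j, k] <- acc
  }
  out
}

naiveSmooth3 <- function(a, taps) {
  for (ax in 1:3) a <- naiveSepConv1(a, taps, ax)
  a
}

# random soft label array (uses the caller's RNG stream)
randLabel <- function(ext, density = 0.1, soft = TRUE) {
  a <- array(0, ext)
  n <- max(1L, round(prod(ext) * density))
  idx <- sample(prod(ext), n)
  a[idx] <- if (soft) runif(n) else 1
  a
}

# small phantom pair for pipeline tests (24^3 keeps network tests fast)
smallPair <- function(seed = 1L, amplitude = 2, extents = c(24L, 24L, 24L),
                      cropTo = NULL) {
  ph <- makePhantom(phantomConfig(extents = extents, spacing = 0.6,
                                  radiusRange = c(2, 3), seed = seed),
                    groupId = paste0("g", seed))
  makeDeformedPair(ph, deformConfig(controlSpacing = 8L,
                                    amplitude = amplitude, sigma = 1L,
                                    seed = seed + 1000L), cropTo = cropTo)
}
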