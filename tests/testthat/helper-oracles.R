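# Brute-force oracles, deliberately independent of the package internals.

# Niblack with a circular window: explicit loop over window pixels,
# population standard deviation, border clipping; same tie rule (v > T).
niblack_brute <- function(img, radius, k) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di * di + dj * dj > radius * radius) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      vals <- c(vals, img[ii, jj])
    }
    n <- length(vals)
    m <- sum(vals) / n
    v <- sum(vals^2) / n - m * m
    if (v < 0) v <- 0
    T <- m + k * sqrt(v)
    out[i, j] <- if (img[i, j] > T) 1L else 0L
  }
  out
}

# median filter with replicate padding: per-pixel sort-and-middle
median_brute <- function(img, window) {
  img <- img + 0  # double storage, matching the filter under test
  nr <- nrow(img); nc <- ncol(img); h <- window %/% 2
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (-h:h), 1), nr)
    jj <- pmin(pmax(j + (-h:h), 1), nc)
    out[i, j] <- sort(as.vector(img[ii, jj]))[(window * window + 1) %/% 2]
  }
  out
}

# a small phantom shared across test files (generation ~1 s); cached per
# R session
.test_cache <- new.env(parent = emptyenv())
default_phantom <- function() {
  if (is.null(.test_cache$ph))
    .test_cache$ph <- generate_phantom(phantom_params(seed = 101))
  .test_cache$ph
}

# tiny volume builder for io tests
tiny_volume <- function(nb = 4, na = 16, nz = 8, fill = NULL) {
  g <- scan_geometry(nb, na, nz)
  v <- if (is.null(fill)) array(sample(0:255, nb * na * nz, TRUE), c(nb, na, nz))
       else array(fill, c(nb, na, nz))
  volume_scan(v, g, 24.0, "OD")
}
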