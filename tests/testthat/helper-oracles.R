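# Independent brute-force oracles used across the suite. These deliberately
# use plain per-cell loops and textbook formulas, not the package's
# vectorised implementations.

# Horn 3x3 gradient magnitude in degrees, interior cells only.
oracle_slope_interior <- function(dem) {
  v <- dem$values; cs <- dem$cell_size
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in 2:(nrow(v) - 1)) for (j in 2:(ncol(v) - 1)) {
    a <- v[i - 1, j - 1]; b <- v[i - 1, j]; cc <- v[i - 1, j + 1]
    d <- v[i, j - 1]; f <- v[i, j + 1]
    g <- v[i + 1, j - 1]; h <- v[i + 1, j]; ii <- v[i + 1, j + 1]
    dzdx <- ((cc + 2 * f + ii) - (a + 2 * d + g)) / (8 * cs)
    dzdy <- ((a + 2 * b + cc) - (g + 2 * h + ii)) / (8 * cs)
    out[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  }
  out
}

# exhaustive neighbourhood max - min scan
oracle_relief <- function(dem, window) {
  v <- dem$values
  r <- (window - 1) %/% 2
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    if (!is.finite(v[i, j])) next
    rows <- max(1, i - r):min(nrow(v), i + r)
    cols <- max(1, j - r):min(ncol(v), j + r)
    vals <- v[rows, cols]
    vals <- vals[is.finite(vals)]
    out[i, j] <- max(vals) - min(vals)
  }
  out
}

# D8 receivers by per-cell loop over the fixed neighbour order
# (E, SE, S, SW, W, NW, N, NE), strict greatest distance-weighted drop.
oracle_d8_receivers <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  drs <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dcs <- c(1, 1, 0, -1, -1, -1, 0, 1)
  rec <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!is.finite(z[i, j])) next
    best <- 0
    for (k in 1:8) {
      ii <- i + drs[k]; jj <- j + dcs[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (!is.finite(z[ii, jj])) next
      drop <- (z[i, j] - z[ii, jj]) / (cs * sqrt(drs[k]^2 + dcs[k]^2))
      if (drop > best) { best <- drop; rec[i, j] <- (jj - 1L) * nr + ii }
    }
  }
  rec
}

# accumulation by walking every cell's pointer chain downstream
oracle_d8_accumulation <- function(z, cs) {
  rec <- oracle_d8_receivers(z, cs)
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(ifelse(is.finite(z), 0, NA_real_), nr, nc)
  for (c in which(is.finite(z))) {
    j <- c
    repeat {
      acc[j] <- acc[j] + 1
      j <- rec[j]
      if (j == 0L) break
    }
  }
  acc * cs * cs
}

# two-pass group-variance q oracle
oracle_q <- function(y, labels) {
  groups <- unique(labels)
  N <- length(y)
  mu <- sum(y) / N
  sst <- sum((y - mu)^2)
  ssw <- 0
  for (g in groups) {
    yg <- y[labels == g]
    ssw <- ssw + sum((yg - mean(yg))^2)
  }
  1 - ssw / sst
}

# exhaustive optimal 1-D partition into k contiguous classes (total
# within-class SS), by enumerating all cut positions; tiny n only.
oracle_best_partition_ss <- function(v, k) {
  v <- sort(v)
  n <- length(v)
  ss <- function(x) sum((x - mean(x))^2)
  best <- Inf
  for (cuts in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    b <- c(0, cuts, n)
    tot <- 0
    for (c in seq_len(k)) tot <- tot + ss(v[(b[c] + 1):b[c + 1]])
    best <- min(best, tot)
  }
  best
}

within_ss_of_labels <- function(v, labels) {
  tot <- 0
  for (g in unique(labels)) {
    x <- v[labels == g]
    tot <- tot + sum((x - mean(x))^2)
  }
  tot
}

# binary dilation by Chebyshev radius r within a validity mask
oracle_dilate <- function(pres, valid, r = 1L) {
  nr <- nrow(pres); nc <- ncol(pres)
  out <- pres
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!valid[i, j] || pres[i, j] == 1) next
    rows <- max(1, i - r):min(nr, i + r)
    cols <- max(1, j - r):min(nc, j + r)
    if (any(pres[rows, cols] == 1)) out[i, j] <- 1
  }
  out
}

# small helper: raster from a matrix with unit geometry
rg <- function(m, cs = 1) raster_grid(as.matrix(m), cs,
                                      origin = c(0, nrow(as.matrix(m)) * cs))
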