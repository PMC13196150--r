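# Independent brute-force oracles, written directly from the objective
# definitions with plain loops; deliberately separate from the package's
# vectorized/C++ code paths.

# --- automatic thresholds -------------------------------------------------
# All oracles return the 0-based split index s: background bins < s.

oracleOtsu <- function(counts) {
  B <- length(counts)
  g <- 0:(B - 1)
  best <- NA_integer_; bestVal <- -Inf
  for (s in 1:(B - 1)) {
    h0 <- counts[1:s]; h1 <- counts[(s + 1):B]
    w0 <- sum(h0); w1 <- sum(h1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(g[1:s] * h0) / w0
    mu1 <- sum(g[(s + 1):B] * h1) / w1
    val <- w0 * w1 * (mu0 - mu1)^2
    if (val > bestVal) { bestVal <- val; best <- s }
  }
  best
}

oracleHuang <- function(counts) {
  B <- length(counts)
  g <- 0:(B - 1)
  nz <- which(counts > 0)
  C <- max(nz) - min(nz)
  shannon <- function(u) {
    v <- 1 - u
    s <- 0
    if (u > 0) s <- s - u * log(u)
    if (v > 0) s <- s - v * log(v)
    s
  }
  best <- NA_integer_; bestVal <- Inf
  for (s in 1:(B - 1)) {
    h0 <- counts[1:s]; h1 <- counts[(s + 1):B]
    w0 <- sum(h0); w1 <- sum(h1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(g[1:s] * h0) / w0
    mu1 <- sum(g[(s + 1):B] * h1) / w1
    E <- 0
    for (i in seq_len(B)) {
      if (counts[i] == 0) next
      mu <- if (i <= s) mu0 else mu1
      u <- 1 / (1 + abs(g[i] - mu) / C)
      E <- E + counts[i] * shannon(u)
    }
    if (E < bestVal) { bestVal <- E; best <- s }
  }
  best
}

oracleTriangle <- function(counts) {
  B <- length(counts)
  peak <- which(counts == max(counts))[1] - 1L
  nz <- which(counts > 0)
  lo <- min(nz) - 1L; hi <- max(nz) - 1L
  e <- if ((hi - peak) >= (peak - lo)) hi else lo
  a <- min(peak, e); b <- max(peak, e)
  if (b - a < 2) return(max(a, 1L))
  yp <- counts[peak + 1L]; ye <- counts[e + 1L]
  best <- NA_integer_; bestVal <- -Inf
  for (x in (a + 1L):(b - 1L)) {
    y <- counts[x + 1L]
    d <- abs((ye - yp) * (x - peak) - (e - peak) * (y - yp))
    if (d > bestVal) { bestVal <- d; best <- x }
  }
  best
}

# --- morphology -----------------------------------------------------------

oracleErode <- function(mask, cycles, diamond = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (diamond) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else {
            o <- list()
            for (a in -1:1) for (b in -1:1)
              if (!(a == 0 && b == 0)) o[[length(o) + 1]] <- c(a, b)
            o
          }
  cur <- mask
  for (it in seq_len(cycles)) {
    nxt <- matrix(FALSE, nr, nc)
    for (r in 1:nr) for (c in 1:nc) {
      if (!cur[r, c]) next
      keep <- TRUE
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || !cur[rr, cc]) {
          keep <- FALSE; break
        }
      }
      nxt[r, c] <- keep
    }
    cur <- nxt
  }
  cur
}

neighbors8 <- function(r, c, nr, nc) {
  out <- list()
  for (a in -1:1) for (b in -1:1) {
    if (a == 0 && b == 0) next
    rr <- r + a; cc <- c + b
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
      out[[length(out) + 1]] <- c(rr, cc)
  }
  out
}

neighbors4 <- function(r, c, nr, nc) {
  out <- list()
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    rr <- r + o[1]; cc <- c + o[2]
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
      out[[length(out) + 1]] <- c(rr, cc)
  }
  out
}

# flood fill background from the border (4-connected, the dual of the
# 8-connected foreground); unreached background becomes TRUE
oracleFillHoles <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reached <- matrix(FALSE, nr, nc)
  queue <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if ((r == 1 || r == nr || c == 1 || c == nc) && !mask[r, c] &&
        !reached[r, c]) {
      reached[r, c] <- TRUE
      queue[[length(queue) + 1]] <- c(r, c)
    }
  }
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    for (q in neighbors4(p[1], p[2], nr, nc)) {
      if (!mask[q[1], q[2]] && !reached[q[1], q[2]]) {
        reached[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  mask | !reached
}

# label 8-connected components by BFS; returns integer matrix
oracleLabel <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c] || lab[r, c] != 0) next
    nxt <- nxt + 1L
    lab[r, c] <- nxt
    queue <- list(c(r, c))
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (q in neighbors8(p[1], p[2], nr, nc)) {
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

oracleSizeFilter <- function(mask, minArea, maxArea) {
  lab <- oracleLabel(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (max(lab) == 0) return(out)
  for (k in seq_len(max(lab))) {
    area <- sum(lab == k)
    if (area >= minArea && area <= maxArea) out[lab == k] <- TRUE
  }
  out
}

# --- filters --------------------------------------------------------------

reflect1 <- function(p, n) {
  while (p < 1 || p > n) {
    if (p < 1) p <- 1 - p
    if (p > n) p <- 2 * n + 1 - p
  }
  p
}

oracleDiskMedian <- function(plane, radius) {
  nr <- nrow(plane); nc <- ncol(plane)
  offs <- list()
  for (a in -radius:radius) for (b in -radius:radius)
    if (a * a + b * b <= radius * radius)
      offs[[length(offs) + 1]] <- c(a, b)
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    vals <- vapply(offs, function(o)
      plane[reflect1(r + o[1], nr), reflect1(c + o[2], nc)], numeric(1))
    out[r, c] <- median(vals)
  }
  out
}

oracleGaussianBlur <- function(plane, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  nr <- nrow(plane); nc <- ncol(plane)
  out <- matrix(0, nr, nc)
  for (rr in 1:nr) for (cc in 1:nc) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      acc <- acc + k1[a + r + 1] * k1[b + r + 1] *
        plane[reflect1(rr + a, nr), reflect1(cc + b, nc)]
    }
    out[rr, cc] <- acc
  }
  out
}

# --- fixtures -------------------------------------------------------------

randomBlobMask <- function(seed, n = 64, p = 0.6) {
  set.seed(seed)
  noise <- matrix(runif(n * n), n, n)
  gaussianBlur(noise, 2) > quantile(gaussianBlur(noise, 2), p)
}

randomHistogram <- function(seed, nBins = 256) {
  set.seed(seed)
  kind <- seed %% 3
  if (kind == 0) {                       # bimodal gaussian mixture
    x <- 0:(nBins - 1)
    m1 <- runif(1, 20, 100); m2 <- runif(1, 140, 240)
    h <- round(3000 * dnorm(x, m1, runif(1, 5, 25)) +
               1500 * dnorm(x, m2, runif(1, 5, 25)))
  } else if (kind == 1) {                # skewed spot-like histogram
    h <- round(5000 * dexp(0:(nBins - 1) / runif(1, 10, 60)))
  } else {                               # rough noise
    h <- rpois(nBins, lambda = runif(nBins, 0, 20))
  }
  if (sum(h > 0) < 2) h[c(10, 200)] <- h[c(10, 200)] + 5
  h
}
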