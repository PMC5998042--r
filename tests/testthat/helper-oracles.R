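# Independent brute-force oracles. Each is written as plain scalar
# loops / direct formulas so it shares no code path with the package.

# Exhaustive Otsu: minimize weighted within-class variance over every
# integer threshold in the observed range; ties -> floor of the mean of
# the optimal thresholds (including the flat runs between observed
# values, which are equally optimal).
oracleOtsu <- function(x) {
  v <- as.integer(round(as.numeric(x)))
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(NA_real_)
  best <- Inf
  bestTs <- integer(0)
  for (t in lo:(hi - 1)) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    wcv <- length(g0) * popVar(g0) + length(g1) * popVar(g1)
    if (wcv < best - 1e-9) {
      best <- wcv
      bestTs <- t
    } else if (abs(wcv - best) <= 1e-9) {
      bestTs <- c(bestTs, t)
    }
  }
  floor(mean(bestTs))
}

popVar <- function(x) if (length(x) == 0) 0 else mean((x - mean(x))^2)

# 8-connected components by breadth-first flood fill, labels in
# column-major first-encounter order.
oracleLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nextLab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nextLab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nextLab
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Flat grayscale erosion/dilation/white top-hat by per-pixel loops over
# the structuring element's offsets (out-of-image ignored).
oracleMorph <- function(img, brush, what = c("erode", "dilate")) {
  what <- match.arg(what)
  ctr <- (dim(brush) + 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  offs <- which(brush > 0, arr.ind = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (k in seq_len(nrow(offs))) {
      r <- i + (offs[k, 1] - ctr[1]) * (if (what == "erode") 1 else -1)
      c <- j + (offs[k, 2] - ctr[2]) * (if (what == "erode") 1 else -1)
      if (r >= 1 && r <= nr && c >= 1 && c <= nc) vals <- c(vals, img[r, c])
    }
    out[i, j] <- if (what == "erode") min(vals) else max(vals)
  }
  out
}

oracleTophat <- function(img, radius) {
  brush <- EBImage::makeBrush(2L * radius + 1L, "disc")
  opened <- oracleMorph(oracleMorph(img, brush, "erode"), brush, "dilate")
  pmax(img - opened, 0)
}

# Moment-equivalent ellipse from an explicit list of (row, col) pixel
# coordinates, unit-square pixel convention (+ 1/12 on the diagonal).
oracleEllipse <- function(coords) {
  n <- nrow(coords)
  mr <- 0; mc <- 0
  for (i in seq_len(n)) { mr <- mr + coords[i, 1]; mc <- mc + coords[i, 2] }
  mr <- mr / n; mc <- mc / n
  srr <- 0; scc <- 0; src <- 0
  for (i in seq_len(n)) {
    srr <- srr + (coords[i, 1] - mr)^2
    scc <- scc + (coords[i, 2] - mc)^2
    src <- src + (coords[i, 1] - mr) * (coords[i, 2] - mc)
  }
  vrr <- srr / n + 1 / 12; vcc <- scc / n + 1 / 12; vrc <- src / n
  ev <- eigen(matrix(c(vrr, vrc, vrc, vcc), 2, 2))$values
  list(major = 4 * sqrt(max(ev)), minor = 4 * sqrt(min(ev)),
       aspect = sqrt(min(ev) / max(ev)))
}

# Seeded minimum-cost propagation by scalar fixed-point iteration over
# individual pixels (cost = step length + lambda*|dI|, ties -> lower
# seed label).
oraclePropagate <- function(intensity, seeds, mask, lambda) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  lab <- matrix(as.integer(seeds), nr, nc)
  mask <- mask | lab > 0
  dist <- matrix(Inf, nr, nc)
  dist[lab > 0] <- 0
  eps <- 1e-9
  repeat {
    changed <- FALSE
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      if (!mask[i, j] || seeds[i, j] > 0) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- i + dr; c <- j + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (!mask[r, c] || lab[r, c] == 0L || !is.finite(dist[r, c])) next
        cd <- dist[r, c] + sqrt(dr^2 + dc^2) +
          lambda * abs(intensity[i, j] - intensity[r, c])
        if (cd < dist[i, j] - eps ||
            (abs(cd - dist[i, j]) <= eps && lab[i, j] > 0L &&
               lab[r, c] < lab[i, j])) {
          dist[i, j] <- cd
          lab[i, j] <- lab[r, c]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab[!mask] <- 0L
  list(labels = lab, dist = dist)
}

# Two-sample KS D by explicit ECDF enumeration at every observed point.
oracleKsD <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (p in pts) {
    fa <- sum(a <= p) / length(a)
    fb <- sum(b <= p) / length(b)
    d <- max(d, abs(fa - fb))
  }
  d
}

# Kruskal-Wallis H with tie correction, direct formula on joint ranks.
oracleKwH <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 0
  for (g in levels(groups)) {
    rg <- r[groups == g]
    h <- h + sum(rg)^2 / length(rg)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Per-label mean intensity by explicit pixel loop.
oracleLabelMeans <- function(img, lab) {
  ids <- sort(unique(as.integer(lab[lab > 0])))
  out <- setNames(numeric(length(ids)), ids)
  for (ix in seq_along(ids)) {
    s <- 0; n <- 0
    for (j in seq_len(ncol(lab))) for (i in seq_len(nrow(lab))) {
      if (lab[i, j] == ids[ix]) { s <- s + img[i, j]; n <- n + 1 }
    }
    out[ix] <- s / n
  }
  out
}

# Histogram counting by scalar loop (half-open bins, last closed).
oracleHist <- function(values, edges) {
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (v in values) {
    for (b in seq_len(nb)) {
      hi <- edges[b + 1]
      inBin <- v >= edges[b] && (v < hi || (b == nb && v <= hi))
      if (inBin) { counts[b] <- counts[b] + 1L; break }
    }
  }
  counts
}
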