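# Internal helpers shared across modules.

# 384-well convention: rows A..P, columns 1..24 (no zero padding required;
# "B7" and "B07" both accepted and normalized to unpadded form).
isValidWell <- function(well) {
  grepl("^[A-P](0?[1-9]|1[0-9]|2[0-4])$", well)
}

normalizeWell <- function(well) {
  stopifnot(isValidWell(well))
  sub("^([A-P])0", "\\1", well)
}

# Deterministic per-field seed derived from (master seed, well, field).
# Simple multiplicative string hash folded into [0, 2^31 - 2]; double
# arithmetic keeps every intermediate exactly representable (< 2^53).
deriveSeed <- function(masterSeed, well, fieldIndex) {
  key <- sprintf("%d|%s|%d", as.integer(masterSeed), well,
                 as.integer(fieldIndex))
  h <- 5381
  for (code in utf8ToInt(key)) h <- (h * 33 + code) %% 2147483647
  as.integer(h)
}

# Otsu threshold on a 65,536-bin histogram of raw integer counts.
# Returns the threshold t (counts) such that foreground = x > t.
# Maximizes between-class variance; among tied maxima the midpoint of
# the optimal threshold range is taken (rounded down).
otsuThreshold <- function(x) {
  v <- as.integer(round(as.numeric(x)))
  v[v < 0L] <- 0L
  v[v > MAX_COUNT] <- MAX_COUNT
  counts <- as.numeric(tabulate(v + 1L, nbins = MAX_COUNT + 1L))
  n <- sum(counts)
  if (n == 0L) return(NA_real_)
  lev <- 0:MAX_COUNT
  w0 <- cumsum(counts)                    # pixels with value <= t
  s0 <- cumsum(counts * lev)
  tot <- s0[MAX_COUNT + 1L]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(NA_real_)       # constant image
  mu0 <- s0 / w0
  mu1 <- (tot - s0) / w1
  sigmaB <- w0 * w1 * (mu0 - mu1)^2
  sigmaB[!valid] <- -Inf
  best <- which(sigmaB == max(sigmaB))    # thresholds t = best - 1
  floor(mean(best - 1L))
}

# 8-connected component labeling of a binary mask. EBImage::bwlabel is
# 4-connected; diagonal-adjacent labels are merged with union-find and
# the result relabeled 1..K in first-pixel order.
labelComponents <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  k <- max(lab)
  if (k < 2) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]     # down-left
  pick <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    cbind(a[sel], b[sel])
  }
  pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  out <- matrix(0L, nr, nc)
  fg <- lab > 0
  out[fg] <- root[lab[fg]]
  relabelSequential(out)
}

# Relabel positive labels to 1..K preserving first-occurrence order in
# column-major scan; 0 stays background.
relabelSequential <- function(lab) {
  ids <- unique(as.integer(lab[lab > 0]))
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- matrix(0L, nrow(lab), ncol(lab))
  fg <- lab > 0
  out[fg] <- lut[lab[fg]]
  out
}

# Areas of labels 1..K as an integer vector.
labelAreas <- function(lab, k = max(lab)) {
  if (k < 1) return(integer(0))
  tabulate(lab[lab > 0], nbins = k)
}

# Centroids (row, col; 0-based pixel-center coordinates) of labels 1..K.
labelCentroids <- function(lab, k = max(lab)) {
  if (k < 1) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab)
  cols <- (idx - 1L) %/% nrow(lab)
  n <- tabulate(l, nbins = k)
  sr <- rowsum(as.numeric(rows), l)
  sc <- rowsum(as.numeric(cols), l)
  out <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("row", "col")))
  present <- as.integer(rownames(sr))
  out[present, 1] <- sr[, 1] / n[present]
  out[present, 2] <- sc[, 1] / n[present]
  out
}

# Shift a matrix by (dr, dc), padding with `fill`.
shiftMatrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

clip16 <- function(m) {
  m[m < 0] <- 0
  m[m > MAX_COUNT] <- MAX_COUNT
  m
}
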