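# Synthetic field generation with full ground truth.
#
# A field is rendered as noise-free signal per channel (discs for nuclei
# and soma, rotated filled ellipses for mitochondria), optically blurred,
# then degraded with Poisson shot noise on signal + background plus
# additive Gaussian read noise, and clipped to the 16-bit range.

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Add `amplitude` to `img` over a disc centered at 0-based (r0, c0).
addDisc <- function(img, r0, c0, radius, amplitude) {
  nr <- nrow(img); nc <- ncol(img)
  rs <- max(0, floor(r0 - radius)):min(nr - 1, ceiling(r0 + radius))
  cs <- max(0, floor(c0 - radius)):min(nc - 1, ceiling(c0 + radius))
  if (!length(rs) || !length(cs)) return(img)
  dr <- rs - r0
  dc <- cs - c0
  inside <- outer(dr^2, dc^2, "+") <= radius^2
  sub <- img[rs + 1, cs + 1, drop = FALSE]
  img[rs + 1, cs + 1] <- sub + amplitude * inside
  img
}

# Add `amplitude` over a filled rotated ellipse (semi-axes a >= b,
# orientation theta radians from the row axis).
addEllipse <- function(img, r0, c0, a, b, theta, amplitude) {
  nr <- nrow(img); nc <- ncol(img)
  ext <- a
  rs <- max(0, floor(r0 - ext)):min(nr - 1, ceiling(r0 + ext))
  cs <- max(0, floor(c0 - ext)):min(nc - 1, ceiling(c0 + ext))
  if (!length(rs) || !length(cs)) return(img)
  dr <- matrix(rs - r0, length(rs), length(cs))
  dc <- matrix(cs - c0, length(rs), length(cs), byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[rs + 1, cs + 1, drop = FALSE]
  img[rs + 1, cs + 1] <- sub + amplitude * inside
  img
}

# Rejection-sample n cell centers with pairwise distance >= minSep and
# margin `margin` from every border. Returns a matrix (row, col), possibly
# fewer rows than requested (with a warning) if the field saturates.
placeCenters <- function(n, shape, minSep, margin, maxTries = 200L) {
  centers <- matrix(numeric(0), 0, 2)
  lo <- margin
  hiR <- shape[1] - 1 - margin
  hiC <- shape[2] - 1 - margin
  if (hiR <= lo || hiC <= lo) stop("image too small for the requested margin")
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      cand <- c(runif(1, lo, hiR), runif(1, lo, hiC))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
                minSep^2)) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      warning(sprintf("placed only %d of %d cells (field saturated)",
                      nrow(centers), n))
      break
    }
  }
  dimnames(centers) <- list(NULL, c("row", "col"))
  centers
}

emptyTruthCells <- function() {
  data.frame(cell = integer(0), row = numeric(0), col = numeric(0),
             live = logical(0), tmrmScale = numeric(0),
             nucleusRadius = numeric(0), somaRadius = numeric(0),
             markerPositive = logical(0))
}

emptyTruthMito <- function() {
  data.frame(cell = integer(0), row = numeric(0), col = numeric(0),
             semiMajor = numeric(0), semiMinor = numeric(0),
             theta = numeric(0))
}

#' Generate one synthetic three-channel field with ground truth
#'
#' Renders nuclei on the nuclear channel for all cells, soma discs on
#' the cytoplasmic channel for live cells only, and mitochondrial
#' ellipses (amplitude proportional to the membrane-potential factor
#' \code{tmrmScale}) inside live-cell soma on the mitochondrial channel.
#' Dead cells receive no cytoplasmic or mitochondrial signal.  With a
#' fixed seed the output is bit-reproducible; the caller's RNG state is
#' left untouched.
#'
#' @param spec a \linkS4class{SyntheticFieldSpec}.
#' @param plateId,well,fieldIndex provenance stamped on the result.
#' @return list with elements \code{field} (\linkS4class{FieldImage})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' out <- generateField(syntheticFieldSpec(imageShape = c(128, 128),
#'                                         nCells = 5, seed = 7))
#' out$field
#' out$truth
#' @export
generateField <- function(spec, plateId = "plate", well = "A1",
                          fieldIndex = 0L) {
  validObject(spec)
  withSeed(spec@seed, {
    shape <- spec@imageShape
    n <- if (spec@nCellsPoisson) rpois(1, spec@nCells) else spec@nCells

    centers <- if (n > 0) {
      placeCenters(n, shape, spec@minSeparationPx, spec@somaRadiusPx)
    } else matrix(numeric(0), 0, 2)
    n <- nrow(centers)

    nuclear <- matrix(0, shape[1], shape[2])
    cyto <- matrix(0, shape[1], shape[2])
    mito <- matrix(0, shape[1], shape[2])
    hasMarker <- !is.na(spec@markerFraction)
    marker <- if (hasMarker) matrix(0, shape[1], shape[2]) else NULL

    cells <- emptyTruthCells()
    mitoTruth <- emptyTruthMito()
    mitoRows <- list()

    if (n > 0) {
      live <- runif(n) >= spec@deadFraction
      markerPos <- if (hasMarker) runif(n) < spec@markerFraction else
        rep(NA, n)
      nucR <- pmax(2, rnorm(n, spec@nucleusRadiusPx, spec@nucleusRadiusSd))
      somR <- pmax(nucR + 2,
                   rnorm(n, spec@somaRadiusPx, spec@somaRadiusSd))
      bright <- rlnorm(n, 0, spec@brightnessSdLog)

      for (i in seq_len(n)) {
        r0 <- unname(centers[i, 1]); c0 <- unname(centers[i, 2])
        nuclear <- addDisc(nuclear, r0, c0, nucR[i],
                           spec@nuclearAmplitude * bright[i])
        if (live[i]) {
          cyto <- addDisc(cyto, r0, c0, somR[i],
                          spec@cytoAmplitude * bright[i])
          if (spec@mitoCytoFraction > 0)
            mito <- addDisc(mito, r0, c0, somR[i],
                            spec@mitoCytoFraction * spec@mitoAmplitude *
                              spec@tmrmScale * bright[i])
        }
        if (hasMarker && markerPos[i])
          marker <- addDisc(marker, r0, c0, somR[i],
                            spec@cytoAmplitude * bright[i])
        if (live[i] && spec@mitoPerCell > 0) {
          k <- rpois(1, spec@mitoPerCell)
          for (j in seq_len(k)) {
            len <- max(spec@mitoWidthPx,
                       rnorm(1, spec@mitoLengthPx, spec@mitoLengthSd))
            a <- len / 2
            b <- spec@mitoWidthPx / 2
            # uniform placement in the soma annulus outside the nucleus;
            # a long ellipse may overhang the soma edge slightly
            dmin <- nucR[i] + b
            dmax <- max(dmin + 0.5, somR[i] - b - 1)
            d <- sqrt(runif(1, dmin^2, dmax^2))
            phi <- runif(1, 0, 2 * pi)
            theta <- runif(1, 0, pi)
            mr <- r0 + d * cos(phi)
            mc <- c0 + d * sin(phi)
            amp <- spec@mitoAmplitude * spec@tmrmScale * bright[i]
            mito <- addEllipse(mito, mr, mc, a, b, theta, amp)
            mitoRows[[length(mitoRows) + 1L]] <-
              c(cell = i, row = mr, col = mc, semiMajor = a, semiMinor = b,
                theta = theta)
          }
        }
      }
      if (length(mitoRows)) {
        m <- do.call(rbind, mitoRows)
        mitoTruth <- data.frame(cell = as.integer(m[, "cell"]),
                                row = m[, "row"], col = m[, "col"],
                                semiMajor = m[, "semiMajor"],
                                semiMinor = m[, "semiMinor"],
                                theta = m[, "theta"])
      }
      cells <- data.frame(cell = seq_len(n), row = centers[, 1],
                          col = centers[, 2], live = live,
                          tmrmScale = spec@tmrmScale,
                          nucleusRadius = nucR, somaRadius = somR,
                          markerPositive = markerPos)
    }

    degrade <- function(sig) {
      if (spec@blurSigma > 0)
        sig <- as.matrix(EBImage::gblur(sig, sigma = spec@blurSigma))
      lambda <- sig + spec@backgroundLevel
      px <- rpois(length(lambda), lambda) +
        rnorm(length(lambda), 0, spec@noiseSd)
      matrix(clip16(round(px)), nrow(sig), ncol(sig))
    }

    channels <- list(nuclear = degrade(nuclear),
                     cytoplasm = degrade(cyto),
                     mito = degrade(mito))
    if (hasMarker) channels$marker <- degrade(marker)

    list(field = FieldImage(channels, plateId = plateId, well = well,
                            fieldIndex = fieldIndex),
         truth = new("GroundTruth", cells = cells, mitochondria = mitoTruth))
  })
}
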