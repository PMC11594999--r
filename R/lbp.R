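#' Local Binary Pattern parameters
#'
#' \code{P} circular neighbors on a circle of radius \code{R} pixels around
#' each center pixel. The study configuration is \code{P = 24, R = 3}, which
#' yields 26 possible rotation-invariant uniform (riu2) codes.
#'
#' @param P Number of circular neighbors (>= 4; default 24).
#' @param R Circle radius in pixels (> 0; default 3).
#' @return An object of class \code{"lbp_params"}.
#' @export
lbp_params <- function(P = 24L, R = 3) {
  if (!is.numeric(P) || length(P) != 1L || P < 4L || P != round(P))
    stop("P must be an integer >= 4")
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("R must be > 0")
  structure(list(P = as.integer(P), R = as.numeric(R)), class = "lbp_params")
}

#' @export
print.lbp_params <- function(x, ...) {
  cat(sprintf("<lbp_params P=%d R=%g (%d riu2 codes)>\n", x$P, x$R, x$P + 2L))
  invisible(x)
}

#' Number of attainable riu2 codes
#'
#' Uniform patterns (at most two circular 0-1 transitions) are coded by
#' their number of set bits, 0..P; all non-uniform patterns share the single
#' sentinel code P+1. The descriptor alphabet therefore has P+2 codes
#' (26 for P = 24).
#'
#' @param P Number of circular neighbors.
#' @return Integer, P + 2.
#' @export
n_riu2_codes <- function(P) as.integer(P) + 2L

# Sampling offsets (dx, dy) for neighbor i = 0..P-1 at angle 2*pi*i/P, with
# x to the right and y downward: dx = R cos(theta), dy = -R sin(theta).
# When P is divisible by 4 the table is built from the first quadrant and
# closed under exact 90-degree rotation (dx, dy) -> (dy, -dx), so that
# rotating an image by 90 degrees maps sample points onto sample points to
# the last bit. Offsets within 1e-9 of an integer are snapped so that
# samples falling on pixel centers take exactly that pixel's value.
lbp_offsets <- function(p) {
  P <- p$P; R <- p$R
  if (P %% 4L == 0L) {
    q <- P %/% 4L
    i <- seq_len(q) - 1L
    theta <- 2 * pi * i / P
    c0 <- R * cos(theta); s0 <- R * sin(theta)
    dx0 <- c0;  dy0 <- -s0            # quadrant 1
    dx1 <- -s0; dy1 <- -c0            # rotated 90 deg CCW in image coords
    dx2 <- -c0; dy2 <- s0
    dx3 <- s0;  dy3 <- c0
    dx <- c(dx0, dx1, dx2, dx3); dy <- c(dy0, dy1, dy2, dy3)
  } else {
    theta <- 2 * pi * (seq_len(P) - 1L) / P
    dx <- R * cos(theta); dy <- -R * sin(theta)
  }
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  cbind(dx = snap(dx), dy = snap(dy))
}

#' Sample the circular neighborhood of one pixel
#'
#' Returns the \code{P} neighbor intensities of the pixel at 0-based
#' coordinates (\code{cx}, \code{cy}), sampled at angles \code{2*pi*i/P} on
#' the circle of radius \code{R} by bilinear interpolation over the four
#' surrounding pixels; samples that fall exactly on a pixel center take that
#' pixel's value.
#'
#' @param m Numeric matrix (rows = y, cols = x).
#' @param cx,cy 0-based center coordinates (x = column, y = row).
#' @param p An [lbp_params()].
#' @return Numeric vector of length \code{P}.
#' @export
sample_neighbors <- function(m, cx, cy, p = lbp_params()) {
  off <- lbp_offsets(p)
  sx <- cx + off[, "dx"]; sy <- cy + off[, "dy"]
  if (any(sx < 0) || any(sy < 0) || any(sx > ncol(m) - 1L) || any(sy > nrow(m) - 1L))
    stop("sampling circle exits the matrix")
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  x0 <- pmin(x0, ncol(m) - 1L); y0 <- pmin(y0, nrow(m) - 1L)
  x1 <- pmin(x0 + 1L, ncol(m) - 1L); y1 <- pmin(y0 + 1L, nrow(m) - 1L)
  a <- m[cbind(y0 + 1L, x0 + 1L)]; b <- m[cbind(y0 + 1L, x1 + 1L)]
  d <- m[cbind(y1 + 1L, x0 + 1L)]; e <- m[cbind(y1 + 1L, x1 + 1L)]
  (1 - fx) * (1 - fy) * a + fx * (1 - fy) * b +
    (1 - fx) * fy * d + fx * fy * e
}

#' Circular uniformity of a binary pattern
#'
#' Number of 0-1 or 1-0 transitions around the circular pattern, including
#' the wrap-around comparison between the last and first bit.
#'
#' @param bits 0/1 vector of length P.
#' @return Integer transition count (even, in 0..P).
#' @export
uniformity <- function(bits) {
  if (!all(bits %in% c(0, 1))) stop("bits must be 0/1")
  sum(abs(diff(c(bits, bits[1L]))))
}

#' Rotation-invariant uniform (riu2) code of a binary pattern
#'
#' Uniform patterns (uniformity <= 2) are coded by their count of ones;
#' every non-uniform pattern maps to the sentinel P + 1.
#'
#' @param bits 0/1 vector of length P.
#' @return Integer code in 0..P+1.
#' @export
riu2_code <- function(bits) {
  if (!all(bits %in% c(0, 1))) stop("bits must be 0/1")
  if (uniformity(bits) <= 2L) as.integer(sum(bits)) else length(bits) + 1L
}

#' riu2 Local Binary Pattern transform of a cell ROI
#'
#' For every interior pixel, the P circular neighbor intensities (bilinear
#' interpolation, see [sample_neighbors()]) are thresholded against the
#' center value with the indicator s(x) = 1 if x >= 0, and the resulting
#' binary pattern is mapped to its riu2 code. A border of width
#' \code{ceiling(R)} is excluded (no padding), so the code matrix has shape
#' \code{(h - 2*ceiling(R)) x (w - 2*ceiling(R))}.
#'
#' The code depends only on the sign of intensity differences, making the
#' descriptor invariant to monotone intensity changes (exactly so wherever
#' sampling needs no interpolation, and under affine intensity maps in
#' general), and the riu2 coding makes the code histogram rotation
#' invariant.
#'
#' @param roi Numeric ROI matrix without NaN.
#' @param p An [lbp_params()].
#' @return An object of class \code{"lbp_code_matrix"}: list with the
#'   integer \code{codes} matrix, \code{params}, and the excluded border
#'   width \code{border}.
#' @examples
#' roi <- matrix(runif(400), 20, 20)
#' cm <- lbp_transform(roi, lbp_params(P = 8, R = 1))
#' lbp_histogram(cm)
#' @export
lbp_transform <- function(roi, p = lbp_params()) {
  if (anyNA(roi)) stop("ROI contains NaN pixels")
  b <- as.integer(ceiling(p$R))
  h <- nrow(roi); w <- ncol(roi)
  if (h <= 2L * b || w <= 2L * b)
    stop(sprintf("ROI %d x %d too small for radius R=%g (needs > %d in both dims)",
                 h, w, p$R, 2L * b))
  off <- lbp_offsets(p)
  vh <- h - 2L * b; vw <- w - 2L * b
  # center block (1-based row/col ranges of valid centers)
  rows <- (b + 1L):(h - b); cols <- (b + 1L):(w - b)
  ctr <- roi[rows, cols, drop = FALSE]
  ones <- matrix(0L, vh, vw)     # popcount accumulator
  trans <- matrix(0L, vh, vw)    # transition accumulator
  first_bit <- NULL; prev_bit <- NULL
  for (i in seq_len(p$P)) {
    dx <- off[i, "dx"]; dy <- off[i, "dy"]
    x0 <- floor(dx); y0 <- floor(dy)
    fx <- dx - x0;   fy <- dy - y0
    sub <- function(ddy, ddx) roi[rows + ddy, cols + ddx, drop = FALSE]
    if (fx == 0 && fy == 0) {
      s <- sub(y0, x0)
    } else if (fy == 0) {
      s <- (1 - fx) * sub(y0, x0) + fx * sub(y0, x0 + 1)
    } else if (fx == 0) {
      s <- (1 - fy) * sub(y0, x0) + fy * sub(y0 + 1, x0)
    } else {
      s <- (1 - fx) * (1 - fy) * sub(y0, x0) + fx * (1 - fy) * sub(y0, x0 + 1) +
        (1 - fx) * fy * sub(y0 + 1, x0) + fx * fy * sub(y0 + 1, x0 + 1)
    }
    bit <- (s >= ctr) + 0L
    ones <- ones + bit
    if (is.null(first_bit)) first_bit <- bit else trans <- trans + abs(bit - prev_bit)
    prev_bit <- bit
  }
  trans <- trans + abs(prev_bit - first_bit)  # circular wrap
  codes <- ifelse(trans <= 2L, ones, p$P + 1L)
  storage.mode(codes) <- "integer"
  structure(list(codes = codes, params = p, border = b),
            class = "lbp_code_matrix")
}

#' @export
print.lbp_code_matrix <- function(x, ...) {
  cat(sprintf("<lbp_code_matrix %d x %d, P=%d R=%g, border %d px excluded>\n",
              nrow(x$codes), ncol(x$codes), x$params$P, x$params$R, x$border))
  invisible(x)
}

#' Histogram of riu2 codes
#'
#' Counts of each of the P+2 codes over the valid region; these 26 numbers
#' (for P = 24) are the texture descriptor vector of the cell.
#'
#' @param c An [lbp_transform()] result.
#' @return List of class \code{"lbp_histogram"} with integer \code{counts}
#'   (length P+2, names \code{"0".."P+1"}) and \code{normalized}
#'   frequencies summing to 1.
#' @export
lbp_histogram <- function(c) {
  stopifnot(inherits(c, "lbp_code_matrix"))
  if (length(c$codes) == 0L) stop("empty code matrix")
  P <- c$params$P
  counts <- tabulate(as.vector(c$codes) + 1L, nbins = P + 2L)
  names(counts) <- as.character(0:(P + 1L))
  structure(list(counts = counts, normalized = counts / sum(counts)),
            class = "lbp_histogram")
}

#' Summary statistics of the riu2 code matrix
#'
#' Mean, standard deviation and (population moment) skewness of the integer
#' codes over the valid region, and the Shannon entropy of the normalized
#' (P+2)-bin code histogram. These four numbers are the "LBP mean / SD /
#' skewness / entropy" features used for the discriminant analysis.
#'
#' @param c An [lbp_transform()] result.
#' @param entropy_base \code{"e"} (default), \code{"2"} or \code{"10"}.
#' @return Named list with \code{lbp_mean, lbp_sd, lbp_skewness,
#'   lbp_entropy}.
#' @export
lbp_stats <- function(c, entropy_base = "e") {
  stopifnot(inherits(c, "lbp_code_matrix"))
  v <- as.vector(c$codes)
  if (length(v) == 0L) stop("empty code matrix")
  p <- lbp_histogram(c)$normalized
  p <- p[p > 0]
  list(
    lbp_mean     = mean(v),
    lbp_sd       = stats::sd(v),
    lbp_skewness = moment_skewness(v),
    lbp_entropy  = -sum(p * log(p)) / entropy_log_base(entropy_base)
  )
}
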