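#' Empirical percentile with linear interpolation
#'
#' Linear interpolation between order statistics (the default convention of
#' most statistics software, quantile type 7). Monotone in \code{q};
#' \code{q = 0} and \code{q = 1} return the minimum and maximum.
#'
#' @param values Non-empty numeric vector.
#' @param q Fraction in [0, 1].
#' @return The interpolated empirical quantile.
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L) stop("percentile of an empty vector")
  if (!is.numeric(q) || any(q < 0) || any(q > 1)) stop("q must lie in [0, 1]")
  if (anyNA(values)) stop("values contain NA/NaN")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

# population (biased) Fisher-Pearson moment skewness m3 / m2^1.5
moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

entropy_log_base <- function(entropy_base) {
  switch(as.character(entropy_base),
         "e" = 1, "2" = log(2), "10" = log(10),
         stop("entropy_base must be one of 'e', '2', '10'"))
}

# Shannon entropy of the equal-width-bin histogram of x over [min, max]
shannon_entropy <- function(x, bins, base = "e") {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(x, br, all.inside = TRUE)
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / entropy_log_base(base)
}

#' First-order lifetime-histogram features of a cell ROI
#'
#' Computes the per-cell summary statistics of the pixel lifetime
#' distribution inside a rectangular ROI: mean, standard deviation,
#' skewness, Shannon entropy, and the 5th/95th percentiles.
#'
#' Skewness is the population moment coefficient m3 / m2^(3/2) (no
#' small-sample correction). Entropy is computed on the normalized histogram
#' over \code{entropy_bins} equal-width bins spanning the ROI's own
#' [min, max] range, so it is invariant to shifting or rescaling the
#' lifetimes; its absolute value depends on the (configurable) binning.
#' A constant ROI is degenerate: skewness and entropy are reported as 0 by
#' convention, with a warning.
#'
#' @param roi Numeric ROI matrix (picoseconds), at least 2 pixels, no NaN.
#' @param entropy_bins Number of equal-width histogram bins (default 32).
#' @param entropy_base Logarithm base for the entropy: \code{"e"} (natural,
#'   default), \code{"2"} or \code{"10"}.
#' @return A named list of class \code{"flim_features"} with elements
#'   \code{mean_ps, sd_ps, skewness, entropy, p5_ps, p95_ps}.
#' @examples
#' set.seed(1)
#' roi <- matrix(rnorm(400, 175.5, 30.2), 20, 20)
#' histogram_stats(roi)
#' @export
histogram_stats <- function(roi, entropy_bins = 32L, entropy_base = "e") {
  x <- as.vector(roi)
  if (length(x) < 2L) stop("ROI must contain at least 2 pixels")
  if (anyNA(x)) stop("ROI contains NaN pixels; ROIs must lie strictly inside the cell")
  if (entropy_bins < 1L) stop("entropy_bins must be >= 1")
  constant <- (min(x) == max(x))
  if (constant)
    warning("constant ROI: skewness and entropy reported as 0 by convention")
  out <- list(
    mean_ps  = mean(x),
    sd_ps    = stats::sd(x),
    skewness = if (constant) 0 else moment_skewness(x),
    entropy  = shannon_entropy(x, entropy_bins, entropy_base),
    p5_ps    = percentile(x, 0.05),
    p95_ps   = percentile(x, 0.95)
  )
  class(out) <- "flim_features"
  out
}

#' @export
print.flim_features <- function(x, ...) {
  cat("FLIM histogram features:\n")
  cat(sprintf("  mean %.2f ps, sd %.2f ps, skewness %.3f, entropy %.3f\n",
              x$mean_ps, x$sd_ps, x$skewness, x$entropy))
  cat(sprintf("  p5 %.2f ps, p95 %.2f ps\n", x$p5_ps, x$p95_ps))
  invisible(x)
}
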