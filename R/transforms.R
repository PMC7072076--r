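# Fluorescence transform and density-based threshold placement shared by the
# gating and metric layers.

#' Inverse-hyperbolic-sine fluorescence transform
#'
#' Standard cytometry display/analysis transform `asinh(x / cofactor)`:
#' near-linear around zero, logarithmic for bright signals. Applied to the
#' four fluorescence channels only; scatter is analysed untransformed.
#'
#' @param x Numeric vector of raw intensities.
#' @param cofactor Positive scale (default 150, typical for conventional
#'   cytometers).
#' @return Transformed values.
#' @export
asinh_transform <- function(x, cofactor = 150) {
  stopifnot(is.numeric(cofactor), length(cofactor) == 1, cofactor > 0)
  asinh(x / cofactor)
}

#' Place a scalar cut at the density valley above the lowest mode
#'
#' Kernel-density based threshold used for the CD16-positive gate, the
#' CD16/CD62L dim-bright cuts and the PF520-positivity cut when no negative
#' reference is available. The density (Gaussian kernel, bandwidth by the
#' standard `nrd0` rule) is scanned for local maxima; the cut is the
#' deepest local minimum between the lowest-intensity mode (the
#' negative/dim population) and the next mode above it. For a bimodal
#' distribution this is exactly the valley between the two modes; when the
#' positive population itself is multimodal (discrete particle counts
#' produce brightness sub-modes) the cut stays at the negative/positive
#' boundary instead of wandering between sub-modes. Distributions without
#' two detectable modes fall back to a quantile cut.
#'
#' Candidate maxima are cleaned up first: peaks shorter than
#' `min_peak_frac` of the tallest are noise, and adjacent peaks whose
#' intervening minimum does not drop below `valley_depth_frac` of the
#' smaller of the two are ripples on one mode and are merged (keeping the
#' taller).
#'
#' @param x Numeric sample (transformed intensities).
#' @param fallback_quantile Quantile used when the density is unimodal.
#' @param min_peak_frac Local maxima shorter than this fraction of the
#'   tallest peak are ignored as noise.
#' @param valley_depth_frac Separation required between distinct modes
#'   (see above).
#' @return List with `cut` (numeric), `method` (`"valley"` or
#'   `"quantile"`).
#' @export
find_density_cut <- function(x, fallback_quantile = 0.05,
                             min_peak_frac = 0.01,
                             valley_depth_frac = 0.5) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || stats::sd(x) == 0) {
    return(list(cut = unname(stats::quantile(x, fallback_quantile)),
                method = "quantile"))
  }
  d <- stats::density(x, bw = "nrd0", n = 512)
  y <- d$y
  dd <- diff(sign(diff(y)))
  maxima <- which(dd == -2) + 1L
  maxima <- maxima[y[maxima] >= min_peak_frac * max(y)]
  modes <- sort(maxima)
  if (length(modes) > 1) {
    merged <- modes[1]
    for (m in modes[-1]) {
      prev <- merged[length(merged)]
      vmin <- min(y[prev:m])
      if (vmin > valley_depth_frac * min(y[prev], y[m])) {
        if (y[m] > y[prev]) merged[length(merged)] <- m
      } else {
        merged <- c(merged, m)
      }
    }
    modes <- merged
  }
  if (length(modes) < 2) {
    return(list(cut = unname(stats::quantile(x, fallback_quantile)),
                method = "quantile"))
  }
  lo <- modes[1]
  hi <- modes[2]
  seg <- lo:hi
  cut_idx <- seg[which.min(y[seg])]
  list(cut = d$x[cut_idx], method = "valley")
}

# Ray-casting point-in-polygon test; points on an edge count as inside.
points_in_polygon <- function(px, py, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # boundary points: treat as inside via a small tolerance re-test
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (xi + t * dx - px)^2 + (yi + t * dy - py)^2
      on_edge <- on_edge | d2 < 1e-18 * max(1, len2)
    }
    j <- i
  }
  inside | on_edge
}
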