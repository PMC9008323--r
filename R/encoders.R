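#' Triangle population-rate code
#'
#' A scalar value \eqn{v} is distributed over a population of coding
#' neurons with preferred values \eqn{a_i}; neuron \eqn{i} fires at rate
#' \deqn{f_i = \max\!\left(0,\; h - h\,\frac{|a_i - v|}{w}\right)}
#' — a triangular tuning curve of half-base \eqn{w} and peak rate \eqn{h}.
#' The population response is continuous and piecewise linear in \eqn{v},
#' peaks when \eqn{v} sits on a preferred value, and is exactly zero for
#' neurons further than \eqn{w} from \eqn{v}.
#'
#' @param centers preferred values \eqn{a_i}, strictly increasing, in
#'   feature units (measured from the low end of the feature range).
#' @param half_width triangle half-base \eqn{w}, feature units, positive.
#'   (This is the encoder width, unrelated to synaptic weights.)
#' @param peak_rate peak firing rate \eqn{h}, Hz, positive.
#' @return an object of class \code{triangle_code}.
#' @export
#' @examples
#' tc <- triangle_code(make_centers(12, c(0, 11)), half_width = 2, peak_rate = 20)
#' triangle_rates(5.5, tc)
triangle_code <- function(centers, half_width, peak_rate) {
  stopifnot(half_width > 0, peak_rate > 0, length(centers) >= 1)
  if (is.unsorted(centers, strictly = TRUE))
    stop("centers must be strictly increasing")
  structure(list(centers = centers, half_width = half_width,
                 peak_rate = peak_rate), class = "triangle_code")
}

#' Evenly spaced tuning-curve centers
#'
#' @param n_per_feature number of coding neurons, at least 2.
#' @param feature_range length-2 vector \code{c(lo, hi)}, \code{lo < hi}.
#' @return numeric vector of \code{n_per_feature} centers spanning the
#'   range, measured from \code{lo}.
#' @export
make_centers <- function(n_per_feature, feature_range) {
  stopifnot(n_per_feature >= 2, length(feature_range) == 2L)
  if (feature_range[1] >= feature_range[2]) stop("degenerate feature range")
  seq(feature_range[1], feature_range[2], length.out = n_per_feature)
}

#' Per-neuron firing rates for one input value
#'
#' @param value the scalar input, finite, in feature units.
#' @param code a \code{\link{triangle_code}}.
#' @return vector of rates in Hz, one per coding neuron.
#' @export
triangle_rates <- function(value, code) {
  if (!is.finite(value)) stop("value must be finite")
  h <- code$peak_rate
  pmax(0, h - h * abs(code$centers - value) / code$half_width)
}

#' Decode a value from a population rate vector
#'
#' Rate-weighted mean of the centers; inverse companion to
#' \code{\link{triangle_rates}} used for round-trip checks.
#'
#' @param rates per-neuron rates, Hz.
#' @param code a \code{\link{triangle_code}}.
#' @return the decoded value (NA when all rates are zero).
#' @export
triangle_decode <- function(rates, code) {
  s <- sum(rates)
  if (s <= 0) return(NA_real_)
  sum(rates * code$centers) / s
}

#' Latency (time-to-first-spike) code for grayscale images
#'
#' Pixels above \code{threshold} emit a spike whose latency decreases
#' linearly with intensity: brighter pixels fire earlier, pixels at or
#' below the threshold stay silent. The normalised intensity
#' \eqn{(p - \theta)/(1 - \theta)} maps linearly onto the lead window, so
#' the brightest pixel (\eqn{p = 1}) fires at time 0 and a pixel just
#' above threshold fires at \code{lead} ms. With a finite
#' \code{repeat_period} the pattern re-emits periodically through the
#' presentation window.
#'
#' @param threshold encoding threshold \eqn{\theta} in \eqn{[0, 1)};
#'   pixels with \eqn{p \le \theta} never spike (strict inequality).
#' @param window presentation duration, ms.
#' @param lead latency spread, ms (first-spike times fall in
#'   \code{[0, lead]}).
#' @param repeat_period re-emission period in ms, or \code{NULL} for a
#'   single spike per pixel per presentation.
#' @return an object of class \code{latency_code}.
#' @export
latency_code <- function(threshold = 0.3, window = 200, lead = 100,
                         repeat_period = NULL) {
  stopifnot(threshold >= 0, threshold < 1, window > 0, lead > 0,
            lead <= window)
  if (!is.null(repeat_period)) stopifnot(repeat_period > 0)
  structure(list(threshold = threshold, window = window, lead = lead,
                 repeat_period = repeat_period), class = "latency_code")
}

#' Convert an image to a spike script
#'
#' @param pixels numeric vector or matrix with values in \eqn{[0, 1]}
#'   (divide 8-bit images by 255 at load time); flattened in column-major
#'   order so pixel \eqn{k} drives input neuron \eqn{k}.
#' @param code a \code{\link{latency_code}}.
#' @return a data frame with columns \code{neuron} and \code{time} (ms),
#'   sorted by time, suitable as a \code{kind = "spikes"} stimulus.
#' @export
latency_spikes <- function(pixels, code) {
  p <- as.numeric(pixels)
  if (any(p < 0 | p > 1)) stop("pixels must lie in [0, 1]")
  on <- which(p > code$threshold)
  t1 <- code$lead *
    (1 - (p[on] - code$threshold) / (1 - code$threshold))
  if (is.null(code$repeat_period)) {
    out <- data.frame(neuron = on, time = t1)
  } else {
    reps <- lapply(seq(0, code$window, by = code$repeat_period), function(off) {
      keep <- t1 + off < code$window
      data.frame(neuron = on[keep], time = t1[keep] + off)
    })
    out <- do.call(rbind, reps)
  }
  out[order(out$time, out$neuron), , drop = FALSE]
}

#' Encode a feature table with per-feature triangle codes
#'
#' Each column of \code{x} is min-max scaled onto \code{[0, n_per_feature
#' - 1]} using the reference ranges in \code{ranges} (typically computed
#' on the training split only), then passed through a triangle code with
#' integer-spaced centers. The per-feature rate vectors are concatenated,
#' giving \code{ncol(x) * n_per_feature} coding neurons.
#'
#' @param x numeric matrix or data frame of features (rows = samples).
#' @param n_per_feature coding neurons per feature.
#' @param half_width triangle half-base in units of the center spacing.
#' @param peak_rate peak rate, Hz.
#' @param ranges a 2-row matrix (min; max) per feature, or \code{NULL} to
#'   use the ranges of \code{x} itself.
#' @return a list with \code{rates} (samples x coding neurons matrix),
#'   \code{ranges}, and the shared \code{\link{triangle_code}}.
#' @export
encode_features <- function(x, n_per_feature = 12, half_width = 2,
                            peak_rate = 20, ranges = NULL) {
  x <- as.matrix(x)
  if (is.null(ranges)) ranges <- apply(x, 2, range)
  code <- triangle_code(make_centers(n_per_feature, c(0, n_per_feature - 1)),
                        half_width, peak_rate)
  rates <- matrix(0, nrow(x), ncol(x) * n_per_feature)
  for (j in seq_len(ncol(x))) {
    lo <- ranges[1, j]; hi <- ranges[2, j]
    v <- (x[, j] - lo) / (hi - lo) * (n_per_feature - 1)
    cols <- (j - 1) * n_per_feature + seq_len(n_per_feature)
    for (i in seq_len(nrow(x))) rates[i, cols] <- triangle_rates(v[i], code)
  }
  list(rates = rates, ranges = ranges, code = code)
}
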