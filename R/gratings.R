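#' Parameters of one cortical grating filter
#'
#' A cortical filter is a rectified sinusoidal grating described by six
#' parameters: orientation (degrees, 0 = horizontal bars, counterclockwise,
#' period 180), spatial frequency (cycles per degree), phase (degrees, 0 =
#' zero-crossing at the aperture center), the dark/light duty-cycle constant
#' `K` (additive offset applied before rectification; negative values
#' thicken dark bars, positive values thicken bright bars; identically 0 for
#' fellow-eye simulations), the saturation threshold `T` (the rectification
#' bound), and the amblyopia constant `A` (scales the filter's drive).
#'
#' @param orientation degrees in \[0, 180).
#' @param spatial_frequency cycles per degree, > 0.
#' @param phase degrees in \[0, 360).
#' @param K duty-cycle constant in \[-1, 1\].
#' @param T_sat saturation threshold in \[0, 2\].
#' @param A amblyopia constant in \[0, 1\].
#' @return An object of class `grating_params`.
#' @export
grating_params <- function(orientation, spatial_frequency, phase = 0,
                           K = 0, T_sat = 1, A = 1) {
  if (spatial_frequency <= 0) stop("spatial_frequency must be > 0")
  if (K < -1 || K > 1) stop("duty constant K must lie in [-1, 1]")
  if (T_sat < 0 || T_sat > 2) stop("saturation threshold T must lie in [0, 2]")
  if (A < 0 || A > 1) stop("amblyopia constant A must lie in [0, 1]")
  structure(
    list(orientation = orientation %% 180,
         spatial_frequency = spatial_frequency,
         phase = phase %% 360, K = K, T_sat = T_sat, A = A),
    class = "grating_params")
}

#' @export
print.grating_params <- function(x, ...) {
  cat(sprintf(
    "<grating_params> theta=%.2f deg, f=%.3g cpd, phi=%.1f deg, K=%.3f, T=%.3f, A=%.3f\n",
    x$orientation, x$spatial_frequency, x$phase, x$K, x$T_sat, x$A))
  invisible(x)
}

#' Render a sinusoidal grating inside a circular aperture
#'
#' The grating value at pixel (x, y) (degrees, field-centered coordinates)
#' is `sin(2 pi f (x sin(theta) + y cos(theta)) + phi)`; at `theta = 0` the
#' bars are horizontal (the pattern varies along y only). Pixels outside the
#' inscribed circular aperture are set to 0 (mean background).
#'
#' @param params a `grating_params`.
#' @param extent_deg field diameter in degrees (default 3.2).
#' @param pixels_per_degree pixel density (default 80, i.e. 256 px for the
#'   default field; Nyquist 40 cpd).
#' @param n_pixels optional explicit side length; overrides
#'   `pixels_per_degree` via `n_pixels / extent_deg`.
#' @return an `image_field` with values in \[-1, 1\].
#' @export
make_grating <- function(params, extent_deg = 3.2, pixels_per_degree = 80,
                         n_pixels = NULL) {
  if (!is.null(n_pixels)) pixels_per_degree <- n_pixels / extent_deg
  if (extent_deg <= 0 || pixels_per_degree <= 0)
    stop("geometry must be positive")
  nyquist <- pixels_per_degree / 2
  if (params$spatial_frequency >= nyquist)
    stop(sprintf("spatial frequency %.3g cpd at or above Nyquist %.3g cpd",
                 params$spatial_frequency, nyquist))
  n <- round(extent_deg * pixels_per_degree)
  co <- field_coords(n, pixels_per_degree)
  th <- params$orientation * pi / 180
  ph <- params$phase * pi / 180
  f <- params$spatial_frequency
  # phase surface: rows index y, columns index x
  surf <- outer(2 * pi * f * cos(th) * co$y, 2 * pi * f * sin(th) * co$x, "+")
  image_field(sin(surf + ph), extent_deg = extent_deg,
              pixels_per_degree = pixels_per_degree)
}

#' Rectify a grating into a cortical filter
#'
#' Adds the duty-cycle constant `K` to the grating and saturates the result
#' at `+/- T`: values at or above `T` become `T`, values at or below `-T`
#' become `-T`, all others are kept. Equivalent to an elementwise clip of
#' `G + K` to \[-T, T\]. The circular aperture is re-applied afterwards.
#'
#' @inheritParams make_grating
#' @return an `image_field` with values in \[-T, T\].
#' @export
make_filter <- function(params, extent_deg = 3.2, pixels_per_degree = 80,
                        n_pixels = NULL) {
  g <- make_grating(params, extent_deg, pixels_per_degree, n_pixels)
  v <- pmin(pmax(g$values + params$K, -params$T_sat), params$T_sat)
  v[!g$aperture] <- 0
  g$values <- v
  g
}

#' Stimulus-drive weight of a grating
#'
#' The weight of filter i is the amblyopia constant `A` times the average of
#' the stimulus-grating product over the aperture (the zero-lag normalized
#' cross-correlation reading of the average convolution between stimulus and
#' grating): maximal when the grating matches the stimulus parameters and
#' near zero for orthogonal orientations.
#'
#' @param stimulus an `image_field` (the grating stimulus S).
#' @param params `grating_params` of the probe grating.
#' @return scalar weight.
#' @export
filter_weight <- function(stimulus, params) {
  g <- make_grating(params, extent_deg = stimulus$extent_deg,
                    pixels_per_degree = stimulus$pixels_per_degree)
  stop_if_geometry_mismatch(stimulus, g)
  ap <- stimulus$aperture
  params$A * mean(stimulus$values[ap] * g$values[ap])
}

#' Ordered collection of cortical filters with weights
#'
#' @param filters list of `grating_params`.
#' @param weights numeric vector, one finite weight per filter.
#' @return an object of class `filter_set`.
#' @export
filter_set <- function(filters, weights) {
  if (inherits(filters, "grating_params")) filters <- list(filters)
  if (length(filters) < 1) stop("filter_set needs at least one filter")
  if (length(weights) != length(filters))
    stop("one weight per filter required")
  if (!all(vapply(filters, inherits, TRUE, "grating_params")))
    stop("filters must be grating_params objects")
  if (!all(is.finite(weights))) stop("weights must be finite")
  structure(list(filters = filters, weights = as.numeric(weights)),
            class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf("<filter_set> %d filter(s)\n", length(x$filters)))
  for (i in seq_along(x$filters))
    cat(sprintf(
      "  [%d] W=%+.3f theta=%.1f f=%.3g phi=%.1f K=%+.3f T=%.3f A=%.3f\n",
      i, x$weights[i], x$filters[[i]]$orientation,
      x$filters[[i]]$spatial_frequency, x$filters[[i]]$phase,
      x$filters[[i]]$K, x$filters[[i]]$T_sat, x$filters[[i]]$A))
  invisible(x)
}

#' Synthesize a simulated percept from a filter set
#'
#' The percept is the saturated weighted sum of the rectified filters:
#' `clip(sum_i W_i F_i, -1, 1)` (the outer saturation bound is the display
#' contrast range and can be changed via `sat_limit`).
#'
#' @param fs a `filter_set`.
#' @inheritParams make_grating
#' @param sat_limit outer saturation bound (default 1).
#' @return an `image_field` with values in \[-sat_limit, sat_limit\].
#' @export
synthesize_percept <- function(fs, extent_deg = 3.2, pixels_per_degree = 80,
                               n_pixels = NULL, sat_limit = 1) {
  if (!inherits(fs, "filter_set")) stop("fs must be a filter_set")
  acc <- NULL
  for (i in seq_along(fs$filters)) {
    f <- make_filter(fs$filters[[i]], extent_deg, pixels_per_degree, n_pixels)
    if (is.null(acc)) {
      acc <- f
      acc$values <- fs$weights[i] * f$values
    } else {
      acc$values <- acc$values + fs$weights[i] * f$values
    }
  }
  acc$values <- pmin(pmax(acc$values, -sat_limit), sat_limit)
  acc$values[!acc$aperture] <- 0
  acc
}
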