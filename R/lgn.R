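#' Spatial frequency tuning curve
#'
#' Mean firing rates across a strictly increasing set of spatial
#' frequencies at one stimulus contrast.
#'
#' @param spatial_frequencies cpd, strictly increasing.
#' @param mean_rates spikes/s, non-negative, same length.
#' @param contrast stimulus contrast in percent.
#' @param n_trials trials per frequency.
#' @return An object of class `tuning_curve`.
#' @export
tuning_curve <- function(spatial_frequencies, mean_rates, contrast = 98,
                         n_trials = 10) {
  if (length(spatial_frequencies) != length(mean_rates))
    stop("frequency and rate vectors differ in length")
  if (any(diff(spatial_frequencies) <= 0))
    stop("spatial frequencies must be strictly increasing")
  if (any(mean_rates < 0)) stop("rates must be non-negative")
  structure(list(spatial_frequencies = spatial_frequencies,
                 mean_rates = mean_rates, contrast = contrast,
                 n_trials = n_trials),
            class = "tuning_curve")
}

#' Gaussian fit of a spatial frequency tuning curve
#'
#' Least-squares Gaussian over spatial frequency:
#' `rate(sf) = baseline + gain * exp(-(sf - preferred_sf)^2 / (2 width^2))`.
#' The `included` flag applies the population filter `R^2 > r2_min`
#' (default 0.9).
#'
#' @param curve a `tuning_curve` with at least 5 points.
#' @param r2_min inclusion threshold on goodness of fit.
#' @return list with `baseline`, `gain`, `preferred_sf`, `width`,
#'   `r_squared`, `converged`, `included`.
#' @export
fit_tuning <- function(curve, r2_min = 0.9) {
  if (length(curve$spatial_frequencies) < 5)
    stop("need at least 5 spatial frequency points")
  f <- gaussian_lsq(curve$spatial_frequencies, curve$mean_rates)
  list(baseline = f$g0, gain = f$g, preferred_sf = f$xp, width = f$sigma,
       r_squared = f$r_squared, converged = f$converged,
       included = isTRUE(f$converged) && isTRUE(f$r_squared > r2_min))
}

#' Low/high spatial-frequency response difference between contrasts
#'
#' Means of the high-contrast minus low-contrast rate difference over
#' spatial frequencies at or below the split (LSF) and above it (HSF).
#'
#' @param high,low `tuning_curve`s on the same spatial-frequency grid.
#' @param split LSF/HSF boundary in cpd (default 0.2).
#' @return list with `lsf_diff` and `hsf_diff` (spikes/s).
#' @export
lsf_hsf_difference <- function(high, low, split = 0.2) {
  if (!isTRUE(all.equal(high$spatial_frequencies, low$spatial_frequencies)))
    stop("tuning curves must share the spatial-frequency grid")
  d <- high$mean_rates - low$mean_rates
  lo <- high$spatial_frequencies <= split
  if (!any(lo) || all(lo))
    stop("split leaves one side of the spatial-frequency grid empty")
  list(lsf_diff = mean(d[lo]), hsf_diff = mean(d[!lo]))
}

# separable linear interpolation of a matrix onto a grid scaled by `factor`
interp_matrix <- function(m, factor) {
  n <- nrow(m); p <- ncol(m)
  xo <- seq(1, p, length.out = (p - 1) * factor + 1)
  yo <- seq(1, n, length.out = (n - 1) * factor + 1)
  t1 <- t(apply(m, 1, function(r) approx(seq_len(p), r, xout = xo)$y))
  apply(t1, 2, function(cl) approx(seq_len(n), cl, xout = yo)$y)
}

#' Spatiotemporal receptive field by reverse correlation
#'
#' Computes the spike-triggered average of a binary checkerboard movie at
#' `n_lags` time lags (one stimulus frame per lag), normalizes the
#' resulting (x, y, lag) volume by subtracting its mean and dividing by the
#' maximum absolute value, and smooths each lag plane by two-dimensional
#' linear interpolation with the given scaling factor. Polarity is the sign
#' of the largest-magnitude value of the normalized volume: ON for a
#' positive (light-driven) peak, OFF for a negative one.
#'
#' @param spike_times spike times in ms, within the movie duration.
#' @param stimulus_movie 3-D array (x, y, frame) of contrast values
#'   (light = +1, dark = -1).
#' @param frame_ms frame duration in ms (default 15.5).
#' @param n_lags number of time lags (default 19, i.e. ~285 ms at 15 ms
#'   resolution).
#' @param spike_weights optional per-spike weights (default 1).
#' @param interp_factor spatial interpolation factor (default 3).
#' @return An object of class `spatiotemporal_rf`: `volume` (interpolated,
#'   max |value| = 1), `raw_volume`, `polarity` (`"ON"`/`"OFF"`),
#'   `peak_lag`, `peak_xy` (on the raw check grid), `n_spikes_used`.
#' @export
reverse_correlate <- function(spike_times, stimulus_movie, frame_ms = 15.5,
                              n_lags = 19, spike_weights = NULL,
                              interp_factor = 3) {
  dm <- dim(stimulus_movie)
  if (length(dm) != 3) stop("stimulus_movie must be a 3-D array")
  n_frames <- dm[3]
  duration <- n_frames * frame_ms
  spike_times <- spike_times[spike_times >= 0 & spike_times < duration]
  if (is.null(spike_weights)) spike_weights <- rep(1, length(spike_times))
  if (length(spike_times) == 0) stop("no spikes within the movie duration")

  sta <- array(0, c(dm[1], dm[2], n_lags))
  frame_of <- floor(spike_times / frame_ms) + 1
  total_w <- numeric(n_lags)
  for (lag in seq_len(n_lags) - 1) {
    idx <- frame_of - lag
    ok <- idx >= 1
    if (!any(ok)) next
    acc <- matrix(0, dm[1], dm[2])
    tab <- tapply(spike_weights[ok], idx[ok], sum)
    frames <- as.integer(names(tab))
    for (j in seq_along(frames))
      acc <- acc + tab[j] * stimulus_movie[, , frames[j]]
    sta[, , lag + 1] <- acc
    total_w[lag + 1] <- sum(spike_weights[ok])
  }
  for (l in seq_len(n_lags))
    if (total_w[l] > 0) sta[, , l] <- sta[, , l] / total_w[l]

  sta <- sta - mean(sta)
  mx <- max(abs(sta))
  if (mx > 0) sta <- sta / mx

  pk <- which(abs(sta) == max(abs(sta)), arr.ind = TRUE)[1, ]
  polarity <- if (sta[pk[1], pk[2], pk[3]] >= 0) "ON" else "OFF"

  vol <- array(0, c((dm[1] - 1) * interp_factor + 1,
                    (dm[2] - 1) * interp_factor + 1, n_lags))
  for (l in seq_len(n_lags))
    vol[, , l] <- interp_matrix(sta[, , l], interp_factor)

  structure(
    list(volume = vol, raw_volume = sta, polarity = polarity,
         peak_lag = unname(pk[3]), peak_xy = unname(pk[1:2]),
         n_spikes_used = length(spike_times)),
    class = "spatiotemporal_rf")
}
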