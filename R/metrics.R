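#' Circular difference between two orientations in degrees
#'
#' Orientation has period 180 degrees; the returned difference lies in
#' \[0, 90\].
#'
#' @param a,b orientations in degrees.
#' @return absolute circular difference in degrees.
#' @export
orientation_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Distortion magnitude of a set of fitted percepts
#'
#' For all fits whose stimulus spatial frequency is at least `min_sf`
#' (default 3 cpd, where distortions are most common), every contributing
#' grating is classified as orientation-matched to its stimulus
#' (circular difference <= `match_tol`, default 5 degrees) or not-matched.
#' The raw distortion is `|Wn - Wm| * Kbar`: the absolute difference
#' between the mean not-matched and mean matched weights, times the mean
#' absolute duty-cycle constant over all contributing gratings. An empty
#' class contributes a mean weight of 0. The score is normalized by the
#' cohort maximum raw score when `cohort_raw` is supplied; for
#' single-subject use the normalized score is defined as 1 (or 0 when the
#' raw score is 0).
#'
#' @param fits a `fit_result`, or list of `fit_result`s (one per stimulus),
#'   each carrying its `stim_params`.
#' @param cohort_raw optional numeric vector of raw scores across the
#'   cohort (including this subject) used for normalization.
#' @param min_sf minimum stimulus spatial frequency (cpd) to include.
#' @param match_tol orientation-match tolerance in degrees.
#' @param use_abs take `|Wn - Wm|` (default) rather than the signed
#'   difference.
#' @return An object of class `distortion_score`: list with `raw`,
#'   `normalized`, `n_stimuli_used`, `matched_mean`, `notmatched_mean`,
#'   `duty_mean`.
#' @export
distortion_magnitude <- function(fits, cohort_raw = NULL, min_sf = 3,
                                 match_tol = 5, use_abs = TRUE) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  keep <- vapply(fits, function(f)
    f$stim_params$spatial_frequency >= min_sf, logical(1))
  if (!any(keep))
    stop("no stimuli with spatial frequency >= ", min_sf,
         " cpd; distortion score undefined")
  fits <- fits[keep]

  w_matched <- numeric(0)
  w_not <- numeric(0)
  k_all <- numeric(0)
  for (f in fits) {
    os <- f$stim_params$orientation
    for (i in seq_along(f$filter_set$filters)) {
      g <- f$filter_set$filters[[i]]
      w <- f$filter_set$weights[i]
      if (orientation_diff_deg(os, g$orientation) <= match_tol)
        w_matched <- c(w_matched, w)
      else
        w_not <- c(w_not, w)
      k_all <- c(k_all, abs(g$K))
    }
  }
  wm <- if (length(w_matched)) mean(w_matched) else 0
  wn <- if (length(w_not)) mean(w_not) else 0
  kbar <- mean(k_all)
  diff <- wn - wm
  raw <- (if (use_abs) abs(diff) else diff) * kbar
  normalized <- if (!is.null(cohort_raw) && max(cohort_raw) > 0)
    raw / max(cohort_raw)
  else if (raw > 0) 1 else 0
  structure(
    list(raw = raw, normalized = normalized, n_stimuli_used = length(fits),
         matched_mean = wm, notmatched_mean = wn, duty_mean = kbar),
    class = "distortion_score")
}

# Shared Gaussian least-squares fit: y ~ g0 + g * exp(-(x - xp)^2 / (2 s^2))
gaussian_lsq <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (sd(y) < .Machine$double.eps^0.5 * (abs(mean(y)) + 1))
    return(list(g0 = mean(y), g = 0, xp = mean(x), sigma = NA_real_,
                r_squared = NA_real_, converged = FALSE))
  start <- list(g0 = max(min(y), 0), g = max(y) - min(y),
                xp = x[which.max(y)], sigma = diff(range(x)) / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ g0 + g * exp(-(x - xp)^2 / (2 * sigma^2)),
      start = start, data = data.frame(x = x, y = y),
      lower = c(g0 = -Inf, g = 0, xp = min(x) / 4,
                sigma = diff(range(x)) / 50),
      upper = c(g0 = Inf, g = Inf, xp = max(x) * 4,
                sigma = diff(range(x)) * 4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(g0 = NA_real_, g = NA_real_, xp = NA_real_,
                sigma = NA_real_, r_squared = NA_real_, converged = FALSE))
  cf <- coef(fit)
  ss_res <- sum((y - fitted(fit))^2)
  ss_tot <- sum((y - mean(y))^2)
  list(g0 = unname(cf["g0"]), g = unname(cf["g"]), xp = unname(cf["xp"]),
       sigma = abs(unname(cf["sigma"])),
       r_squared = 1 - ss_res / ss_tot, converged = TRUE)
}

#' Fit a Gaussian contrast sensitivity function
#'
#' Fits `CS(sf) = g0 + g * exp(-(sf - sf_p)^2 / (2 sigma^2))` by least
#' squares: `g0` is the baseline gain, `g` the peak gain above baseline,
#' `sf_p` the preferred spatial frequency (cpd) and `sigma` the width
#' (cpd). The fitted peak sensitivity is `g0 + g` (the value at `sf_p`).
#'
#' @param table data frame with columns `sf_cpd` and `sensitivity` (or a
#'   two-column numeric data frame / matrix in that order).
#' @return An object of class `csf_model`: `g0`, `g`, `sf_p`, `sigma`,
#'   `peak`, `r_squared`, `converged`.
#' @export
fit_csf <- function(table) {
  tb <- as.data.frame(table)
  if (!all(c("sf_cpd", "sensitivity") %in% names(tb))) {
    names(tb)[1:2] <- c("sf_cpd", "sensitivity")
  }
  if (nrow(tb) < 4) stop("need at least 4 (sf, sensitivity) points")
  if (any(tb$sf_cpd <= 0)) stop("spatial frequencies must be > 0")
  f <- gaussian_lsq(tb$sf_cpd, tb$sensitivity)
  structure(
    list(g0 = f$g0, g = f$g, sf_p = f$xp, sigma = f$sigma,
         peak = f$g0 + f$g, r_squared = f$r_squared,
         converged = f$converged),
    class = "csf_model")
}

#' @export
print.csf_model <- function(x, ...) {
  cat(sprintf(
    "<csf_model> g0=%.3g g=%.3g sf_p=%.3g cpd sigma=%.3g (peak %.3g, R2=%.3f, %s)\n",
    x$g0, x$g, x$sf_p, x$sigma, x$peak,
    if (is.na(x$r_squared)) NA else x$r_squared,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Contrast sensitivity deficit of the amblyopic eye
#'
#' The fellow/amblyopic ratio of the fitted Gaussian peaks minus one,
#' floored at 0 so the deficit ranges from 0 (no deficit) upward. The peak
#' is the fitted maximum `g0 + g` (the value at the preferred spatial
#' frequency); set `peak_mode = "gain"` to use `g` alone.
#'
#' @param fellow,amblyopic converged `csf_model`s.
#' @param peak_mode `"fitted_max"` (default, `g0 + g`) or `"gain"` (`g`).
#' @return non-negative scalar deficit.
#' @export
cs_deficit <- function(fellow, amblyopic, peak_mode = c("fitted_max", "gain")) {
  peak_mode <- match.arg(peak_mode)
  if (!fellow$converged || !amblyopic$converged)
    stop("both CSF fits must have converged")
  pf <- if (peak_mode == "fitted_max") fellow$peak else fellow$g
  pa <- if (peak_mode == "fitted_max") amblyopic$peak else amblyopic$g
  if (pa <= 0) stop("non-positive amblyopic peak; deficit undefined")
  max(pf / pa - 1, 0)
}

#' Bootstrap-smoothed spatial frequency distribution
#'
#' Resamples the input spatial frequencies with replacement
#' (`n_per_sample` draws per bootstrap sample), adds uniform noise in
#' `+/- noise_half_range` cpd to smooth the distribution, bins each sample
#' into `n_bins` bins spanning the noisy support, normalizes each sample to
#' a probability vector, and averages over `n_boot` samples.
#'
#' @param frequencies spatial frequencies in cpd.
#' @param n_boot number of bootstrap samples (default 1000).
#' @param n_per_sample draws per sample (default 30).
#' @param noise_half_range half-range of the smoothing noise in cpd
#'   (default 2).
#' @param n_bins number of bins (default 9).
#' @param rng_seed seed.
#' @return list with `probability` (length `n_bins`, sums to 1),
#'   `bin_edges`, `bin_centers`.
#' @export
bootstrap_sf_distribution <- function(frequencies, n_boot = 1000,
                                      n_per_sample = 30,
                                      noise_half_range = 2, n_bins = 9,
                                      rng_seed = 1) {
  if (length(frequencies) < 1) stop("empty frequency list")
  edges <- seq(min(frequencies) - noise_half_range,
               max(frequencies) + noise_half_range,
               length.out = n_bins + 1)
  probs <- withr::with_seed(rng_seed, {
    acc <- numeric(n_bins)
    for (b in seq_len(n_boot)) {
      draw <- sample(frequencies, n_per_sample, replace = TRUE) +
        runif(n_per_sample, -noise_half_range, noise_half_range)
      counts <- tabulate(findInterval(draw, edges, rightmost.closed = TRUE,
                                      all.inside = TRUE), nbins = n_bins)
      acc <- acc + counts / n_per_sample
    }
    acc / n_boot
  })
  list(probability = probs, bin_edges = edges,
       bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r` and `p`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-sample Wilcoxon rank-sum test (thin wrapper)
#'
#' @param x,y numeric samples.
#' @return list with `statistic`, `p`, and the two sample `mean`s and `sd`s.
#' @export
ranksum_test <- function(x, y) {
  wt <- wilcox.test(x, y, exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)))
}

#' Exact binomial test (thin wrapper)
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p null success probability.
#' @return list with `p` (two-sided) and `estimate`.
#' @export
dominance_binom_test <- function(k, n, p = 0.5) {
  bt <- binom.test(k, n, p)
  list(p = bt$p.value, estimate = unname(bt$estimate))
}
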