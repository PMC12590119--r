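#' Specification of a synthetic perceptual drawing
#'
#' Synthetic drawings stand in for subject drawings of grating stimuli:
#' the percept of a known filter set, deformed by a smooth low-frequency
#' spatial jitter (emulating hand-drawing inaccuracy) and corrupted by
#' pixel noise. The generating filter set is returned alongside the
#' drawing so recovery can be scored.
#'
#' @param true_filters a `filter_set` generating the percept.
#' @param pixel_noise_sd Gaussian pixel noise SD (contrast units,
#'   default 0.02).
#' @param jitter_amplitude_deg amplitude of the sinusoidal displacement
#'   field in degrees (default 0.02, at most ~0.05 is realistic).
#' @param rng_seed seed recorded in the output.
#' @return An object of class `synthetic_drawing_spec`.
#' @export
synthetic_drawing_spec <- function(true_filters, pixel_noise_sd = 0.02,
                                   jitter_amplitude_deg = 0.02,
                                   rng_seed = 1) {
  if (!inherits(true_filters, "filter_set"))
    stop("true_filters must be a filter_set")
  if (pixel_noise_sd < 0 || jitter_amplitude_deg < 0)
    stop("noise and jitter must be >= 0")
  structure(list(true_filters = true_filters,
                 pixel_noise_sd = pixel_noise_sd,
                 jitter_amplitude_deg = jitter_amplitude_deg,
                 rng_seed = rng_seed),
            class = "synthetic_drawing_spec")
}

bilinear_sample <- function(m, yi, xi) {
  n <- nrow(m); p <- ncol(m)
  yi <- pmin(pmax(yi, 1), n)
  xi <- pmin(pmax(xi, 1), p)
  y0 <- pmin(floor(yi), n - 1); x0 <- pmin(floor(xi), p - 1)
  fy <- yi - y0; fx <- xi - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fy) * (1 - fx) + m[i10] * fy * (1 - fx) +
    m[i01] * (1 - fy) * fx + m[i11] * fy * fx
}

#' Generate a synthetic perceptual drawing
#'
#' @param spec a [synthetic_drawing_spec()].
#' @param extent_deg,pixels_per_degree,n_pixels field geometry (as in
#'   [make_grating()]).
#' @return list with `drawing` (`image_field`), `truth` (the generating
#'   `filter_set`), and `spec`.
#' @export
gen_drawing <- function(spec, extent_deg = 3.2, pixels_per_degree = 80,
                        n_pixels = NULL) {
  percept <- synthesize_percept(spec$true_filters, extent_deg,
                                pixels_per_degree, n_pixels)
  v <- percept$values
  n <- nrow(v)
  ppd <- percept$pixels_per_degree
  out <- withr::with_seed(spec$rng_seed, {
    if (spec$jitter_amplitude_deg > 0) {
      amp_px <- spec$jitter_amplitude_deg * ppd
      kx <- sample(1:2, 1); ky <- sample(1:2, 1)
      ph <- runif(2, 0, 2 * pi)
      idx <- seq_len(n)
      # smooth displacement field: two low-frequency sinusoidal components
      dx <- amp_px * outer(sin(2 * pi * ky * idx / n + ph[1]), rep(1, n))
      dy <- amp_px * outer(rep(1, n), sin(2 * pi * kx * idx / n + ph[2]))
      yi <- outer(idx, rep(1, n)) + dy
      xi <- outer(rep(1, n), idx) + dx
      v <- matrix(bilinear_sample(v, as.vector(yi), as.vector(xi)), n, n)
    }
    if (spec$pixel_noise_sd > 0)
      v <- v + matrix(rnorm(n * n, 0, spec$pixel_noise_sd), n, n)
    pmin(pmax(v, -1), 1)
  })
  drawing <- image_field(out, extent_deg = percept$extent_deg,
                         pixels_per_degree = ppd)
  list(drawing = drawing, truth = spec$true_filters, spec = spec)
}

#' Evaluate a Gaussian contrast sensitivity function
#'
#' @param params list with `g0`, `g`, `sf_p`, `sigma`.
#' @param sf spatial frequencies in cpd.
#' @return sensitivities.
#' @export
csf_eval <- function(params, sf) {
  params$g0 + params$g * exp(-(sf - params$sf_p)^2 / (2 * params$sigma^2))
}

#' Generate a fellow/amblyopic pair of contrast sensitivity tables
#'
#' Sensitivities are sampled from the Gaussian CSF at the standard stimulus
#' spatial frequencies and perturbed by multiplicative lognormal noise
#' (sensitivity spans orders of magnitude, from near 100 at low spatial
#' frequencies to below 10 at high ones).
#'
#' @param fellow_params,amblyopic_params CSF parameter lists
#'   (`g0`, `g`, `sf_p`, `sigma`).
#' @param noise_sd SD of the log-sensitivity noise (default 0.03).
#' @param rng_seed seed.
#' @param sfs sampling frequencies in cpd (default
#'   `c(1.25, 2.5, 5, 10, 16)`).
#' @return list of two data frames (`fellow`, `amblyopic`) with columns
#'   `eye`, `sf_cpd`, `sensitivity`.
#' @export
gen_csf_pair <- function(fellow_params, amblyopic_params, noise_sd = 0.03,
                         rng_seed = 1, sfs = c(1.25, 2.5, 5, 10, 16)) {
  stopifnot(fellow_params$sigma > 0, amblyopic_params$sigma > 0)
  withr::with_seed(rng_seed, {
    mk <- function(params, eye) {
      s <- csf_eval(params, sfs) * exp(rnorm(length(sfs), 0, noise_sd))
      data.frame(eye = eye, sf_cpd = sfs, sensitivity = s)
    }
    list(fellow = mk(fellow_params, "fellow"),
         amblyopic = mk(amblyopic_params, "amblyopic"))
  })
}

#' Generate a synthetic cortical orientation-preference map
#'
#' Band-pass filters complex white noise around the spatial frequency of
#' the target column wavelength and decodes the half-angle, yielding a
#' quasi-periodic map with pinwheel singularities and an approximately
#' uniform orientation histogram.
#'
#' @param shape integer side length (or length-2 vector) in pixels.
#' @param target_wavelength_mm dominant wavelength of the orientation
#'   signal in mm (column width is half of this; default 0.79, matching a
#'   ~0.395 mm macaque orientation column).
#' @param mm_per_pixel cortical magnification (default 3.3 / 57, the
#'   macaque patch sampling).
#' @param rng_seed seed.
#' @return an `orientation_map` with `provenance = "synthetic"`.
#' @export
gen_orientation_map <- function(shape = 57, target_wavelength_mm = 0.79,
                                mm_per_pixel = 3.3 / 57, rng_seed = 1) {
  if (length(shape) == 1) shape <- c(shape, shape)
  if (target_wavelength_mm <= 2 * mm_per_pixel)
    stop("target wavelength below map resolution (need > 2 px)")
  n <- shape[1]; m <- shape[2]
  f0 <- mm_per_pixel / target_wavelength_mm  # cycles per pixel
  z <- withr::with_seed(rng_seed, {
    noise <- matrix(complex(real = rnorm(n * m), imaginary = rnorm(n * m)),
                    n, m)
    fy <- ifelse(seq_len(n) - 1 > n / 2, seq_len(n) - 1 - n, seq_len(n) - 1) / n
    fx <- ifelse(seq_len(m) - 1 > m / 2, seq_len(m) - 1 - m, seq_len(m) - 1) / m
    fr <- sqrt(outer(fy^2, fx^2, "+"))
    mask <- exp(-(fr - f0)^2 / (2 * (f0 / 4)^2))
    fft(fft(noise) * mask, inverse = TRUE)
  })
  theta <- (Arg(z) / 2) %% pi * 180 / pi
  orientation_map(theta, mm_per_pixel, provenance = "synthetic")
}

#' Specification of a synthetic amblyopic cohort
#'
#' @param n_subjects number of subjects (default 7).
#' @param deficit_range range of contrast-sensitivity deficits spanned by
#'   the cohort (default `c(0.2, 2.5)`).
#' @param distortion_noise_sd SD of the noise on the generative link
#'   between deficit and the filter-set parameters (default 0.02).
#' @param rng_seed seed.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_subjects = 7,
                                  deficit_range = c(0.2, 2.5),
                                  distortion_noise_sd = 0.02,
                                  rng_seed = 1) {
  if (n_subjects < 3) stop("need at least 3 subjects for correlation")
  structure(list(n_subjects = n_subjects, deficit_range = deficit_range,
                 distortion_noise_sd = distortion_noise_sd,
                 rng_seed = rng_seed),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic cohort of amblyopic subjects
#'
#' Subjects span the deficit range. Each subject carries stable distortion
#' traits: an off-orientation filter weight and an absolute duty-cycle
#' constant that both grow with the contrast-sensitivity deficit, plus (for
#' severe deficits) a second mismatched orientation, so both the distortion
#' score and the predicted cortical spread grow with the deficit and the
#' generative deficit-distortion link is positive and recoverable end to
#' end. The traits are instantiated per stimulus: each stimulus gets a
#' filter set whose matched filter copies the stimulus geometry and whose
#' mismatched filters sit at subject-specific orientation offsets. CSF
#' tables are sampled so the fitted deficit matches the generative one up
#' to sampling noise. A shared synthetic orientation map is included for
#' cortical-spread simulations.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param stimuli list of `grating_params`, one per stimulus shown to every
#'   subject (default: horizontal and vertical 5 cpd gratings).
#' @return list with `subjects` (each: `id`, `deficit_true`, `csf_fellow`,
#'   `csf_amblyopic`, and `percepts` -- one
#'   `list(stim_params, true_filters, drawing_seed)` per stimulus),
#'   `map` (`orientation_map`), and `spec`.
#' @export
gen_cohort <- function(spec = synthetic_cohort_spec(),
                       stimuli = list(grating_params(0, 5),
                                      grating_params(90, 5))) {
  d <- seq(spec$deficit_range[1], spec$deficit_range[2],
           length.out = spec$n_subjects)
  fellow_csf <- list(g0 = 2, g = 98, sf_p = 3, sigma = 2)
  subjects <- withr::with_seed(spec$rng_seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      di <- d[i]
      # amblyopic peak = fellow peak / (1 + deficit)
      peak_a <- (fellow_csf$g0 + fellow_csf$g) / (1 + di)
      ambl_csf <- list(g0 = min(2, peak_a / 2), g = NA, sf_p = 3, sigma = 2)
      ambl_csf$g <- peak_a - ambl_csf$g0
      # off-orientation weight rises gently, |K| rises steeply: their
      # product (the distortion score) then grows near-linearly with the
      # deficit instead of plateauing
      wn <- 0.25 + 0.04 * di + rnorm(1, 0, spec$distortion_noise_sd)
      k <- 0.05 + 0.12 * di + rnorm(1, 0, spec$distortion_noise_sd)
      wn <- min(max(wn, 0.05), 1)
      k <- min(max(k, 0.02), 1)
      delta <- runif(2, 25, 45)
      percepts <- lapply(seq_along(stimuli), function(j) {
        sp <- stimuli[[j]]
        phase2 <- runif(2, 0, 360)
        filters <- list(
          grating_params(sp$orientation, sp$spatial_frequency,
                         sp$phase, K = -k, T_sat = 1, A = 0.8),
          grating_params(sp$orientation + delta[1], sp$spatial_frequency,
                         phase2[1], K = -k, T_sat = 1, A = wn))
        weights <- c(0.8, wn)
        # severe amblyopia recruits a further mismatched orientation, so
        # the predicted cortical spread also grows with the deficit
        if (di >= 1.5) {
          filters[[3]] <- grating_params(
            sp$orientation - delta[2], sp$spatial_frequency, phase2[2],
            K = -k, T_sat = 1, A = 0.7 * wn)
          weights <- c(weights, 0.7 * wn)
        }
        list(stim_params = sp, true_filters = filter_set(filters, weights),
             drawing_seed = spec$rng_seed * 1000 + i * 10 + j)
      })
      list(id = sprintf("S%02d", i), deficit_true = di,
           csf_params_fellow = fellow_csf, csf_params_amblyopic = ambl_csf,
           percepts = percepts,
           csf_seed = spec$rng_seed * 2000 + i)
    })
  })
  subjects <- lapply(subjects, function(s) {
    tabs <- gen_csf_pair(s$csf_params_fellow, s$csf_params_amblyopic,
                         rng_seed = s$csf_seed)
    s$csf_fellow <- tabs$fellow
    s$csf_amblyopic <- tabs$amblyopic
    s
  })
  map <- gen_orientation_map(rng_seed = spec$rng_seed + 7)
  list(subjects = subjects, map = map, spec = spec)
}
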