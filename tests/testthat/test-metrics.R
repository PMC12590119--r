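fake_fit <- function(stim_theta, stim_sf, filters, weights) {
  structure(list(filter_set = filter_set(filters, weights),
                 stim_params = grating_params(stim_theta, stim_sf)),
            class = "fit_result")
}

test_that("distortion magnitude matches the hand-computed example", {
  # {(0 deg, W=0.8, K=0.5), (45 deg, W=0.4, K=0.3)} on a 0 deg stimulus:
  # Wm=0.8, Wn=0.4, Kbar=0.4, raw = |0.4-0.8| * 0.4 = 0.16
  fit <- fake_fit(0, 5,
                  list(grating_params(0, 5, K = 0.5),
                       grating_params(45, 5, K = 0.3)),
                  weights = c(0.8, 0.4))
  d <- distortion_magnitude(fit)
  expect_equal(d$matched_mean, 0.8)
  expect_equal(d$notmatched_mean, 0.4)
  expect_equal(d$duty_mean, 0.4)
  expect_equal(d$raw, 0.16)
  # single subject with positive raw: normalized defined as 1
  expect_equal(d$normalized, 1)
})

test_that("fellow-eye filter sets (K = 0) score exactly zero", {
  fit <- fake_fit(0, 5,
                  list(grating_params(0, 5, K = 0),
                       grating_params(30, 5, K = 0)),
                  weights = c(0.9, 0.2))
  d <- distortion_magnitude(fit)
  expect_identical(d$raw, 0)
  expect_identical(d$normalized, 0)
})

test_that("distortion magnitude is invariant to filter order and zero-weight filters", {
  f1 <- grating_params(2, 5, K = 0.4)
  f2 <- grating_params(40, 5, K = 0.2)
  a <- distortion_magnitude(fake_fit(0, 5, list(f1, f2), c(0.7, 0.3)))
  b <- distortion_magnitude(fake_fit(0, 5, list(f2, f1), c(0.3, 0.7)))
  expect_equal(a$raw, b$raw)

  # a zero-weight filter with zero K changes neither class mean direction
  f3 <- grating_params(90, 5, K = 0)
  c_ <- distortion_magnitude(fake_fit(0, 5, list(f1, f2, f3),
                                      c(0.7, 0.3, 0)))
  # Wn becomes mean(0.3, 0) and Kbar mean(0.4, 0.2, 0); recompute by hand
  expect_equal(c_$raw, abs(mean(c(0.3, 0)) - 0.7) * mean(c(0.4, 0.2, 0)))
})

test_that("distortion magnitude selects stimuli at or above 3 cpd", {
  hi <- fake_fit(0, 5, list(grating_params(0, 5, K = 0.5),
                            grating_params(45, 5, K = 0.3)), c(0.8, 0.4))
  lo <- fake_fit(0, 1.25, list(grating_params(20, 1.25, K = 0.9)), 0.9)
  d <- distortion_magnitude(list(hi, lo))
  expect_equal(d$n_stimuli_used, 1)
  expect_equal(d$raw, 0.16)
  expect_error(distortion_magnitude(lo), ">= 3")
})

test_that("cohort normalization divides by the cohort maximum", {
  fit <- fake_fit(0, 5, list(grating_params(0, 5, K = 0.5),
                             grating_params(45, 5, K = 0.3)), c(0.8, 0.4))
  d <- distortion_magnitude(fit, cohort_raw = c(0.16, 0.32, 0.05))
  expect_equal(d$normalized, 0.5)
  expect_true(d$normalized >= 0 && d$normalized <= 1)
})

test_that("CSF fit recovers known parameters and flags degenerate input", {
  truth <- list(g0 = 2, g = 98, sf_p = 3, sigma = 2)
  tab <- csf_table_from(truth)
  fit <- fit_csf(tab)
  expect_true(fit$converged)
  expect_equal(fit$g0, truth$g0, tolerance = 0.01)
  expect_equal(fit$g, truth$g, tolerance = 0.01)
  expect_equal(fit$sf_p, truth$sf_p, tolerance = 0.01)
  expect_equal(fit$sigma, truth$sigma, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)

  # bandpass data ~100 at low SF, < 10 at high SF: peak inside sampled range
  tab2 <- data.frame(sf_cpd = c(1.25, 2.5, 5, 10, 16),
                     sensitivity = c(95, 100, 60, 12, 4))
  fit2 <- fit_csf(tab2)
  expect_true(fit2$converged)
  expect_gt(fit2$sf_p, 1.25)
  expect_lt(fit2$sf_p, 16)

  flat <- data.frame(sf_cpd = c(1, 2, 4, 8), sensitivity = rep(50, 4))
  expect_false(fit_csf(flat)$converged)
  expect_error(fit_csf(tab[1:3, ]), "at least 4")
})

test_that("contrast sensitivity deficit follows the peak-ratio-minus-one rule", {
  mk <- function(peak) structure(list(g0 = 2, g = peak - 2, sf_p = 3,
                                      sigma = 2, peak = peak,
                                      r_squared = 1, converged = TRUE),
                                 class = "csf_model")
  expect_equal(cs_deficit(mk(100), mk(100)), 0)
  expect_equal(cs_deficit(mk(100), mk(50)), 1)
  expect_equal(cs_deficit(mk(100), mk(80)), 0.25)
  # floored at zero when the amblyopic eye is better
  expect_equal(cs_deficit(mk(80), mk(100)), 0)
  # monotone decreasing in the amblyopic peak
  defs <- vapply(seq(20, 100, 10), function(p) cs_deficit(mk(100), mk(p)),
                 numeric(1))
  expect_true(all(diff(defs) <= 0))
  bad <- mk(50); bad$converged <- FALSE
  expect_error(cs_deficit(mk(100), bad), "converged")
})

test_that("bootstrap SF distribution is a stable probability vector", {
  freqs <- c(1.25, 2.5, 5, 10, 16)
  bs <- bootstrap_sf_distribution(freqs, rng_seed = 1)
  expect_equal(sum(bs$probability), 1, tolerance = 1e-9)
  expect_length(bs$probability, 9)

  # concentrated input: all mass within the noise support [3, 7]
  bs5 <- bootstrap_sf_distribution(rep(5, 10), rng_seed = 2)
  in_support <- bs5$bin_centers >= 3 - diff(bs5$bin_edges)[1] &
    bs5$bin_centers <= 7 + diff(bs5$bin_edges)[1]
  expect_equal(sum(bs5$probability[in_support]), 1, tolerance = 1e-9)

  # determinism and cross-seed convergence (total variation < 0.02)
  expect_identical(bootstrap_sf_distribution(freqs, rng_seed = 7),
                   bootstrap_sf_distribution(freqs, rng_seed = 7))
  p1 <- bootstrap_sf_distribution(freqs, rng_seed = 101)$probability
  p2 <- bootstrap_sf_distribution(freqs, rng_seed = 202)$probability
  expect_lt(sum(abs(p1 - p2)) / 2, 0.02)
})

test_that("correlation utility returns Pearson r with p and guards degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(x, rep(1, 5)), "variance")
  expect_error(correlate(x, x[1:3]), "length")

  withr::with_seed(5, {
    d <- seq(0.2, 2.5, length.out = 7)
    noisy <- d + rnorm(7, 0, 0.15)
    expect_gt(correlate(d, noisy)$r, 0.9)
  })
})
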