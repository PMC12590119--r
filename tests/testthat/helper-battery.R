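# Parameter-recovery battery: drawings generated from 1-4 known filters.
# Truth sets span orientation, frequency, phase, duty constant, saturation
# threshold and weight.
battery_truth <- function(n_filters) {
  specs <- list(
    list(th = 0,   f = 5,   ph = 0,   K = -0.30, T = 1.0, A = 0.80),
    list(th = 30,  f = 5,   ph = 120, K = -0.30, T = 1.0, A = 0.45),
    list(th = 75,  f = 2.5, ph = 200, K = 0.40,  T = 0.8, A = 0.35),
    list(th = 120, f = 5,   ph = 60,  K = -0.20, T = 1.2, A = 0.30)
  )[seq_len(n_filters)]
  filter_set(lapply(specs, function(s)
    grating_params(s$th, s$f, s$ph, K = s$K, T_sat = s$T, A = s$A)),
    weights = vapply(specs, `[[`, 0, "A"))
}

# fit one battery drawing and score the recovery
run_battery_case <- function(n_filters, seed, n_pixels = 128) {
  truth <- battery_truth(n_filters)
  sp <- grating_params(0, 5)
  stim <- make_grating(sp, n_pixels = n_pixels)
  dr <- gen_drawing(synthetic_drawing_spec(truth, pixel_noise_sd = 0.02,
                                           rng_seed = seed),
                    n_pixels = n_pixels)
  floor_nlpd <- nlpd(dr$drawing$values,
                     synthesize_percept(truth, n_pixels = n_pixels)$values)
  # fit threshold: 1.25x the drawing's own noise floor (the unmodelled
  # hand-jitter component keeps the floor itself out of reach)
  threshold <- 1.25 * floor_nlpd
  cfg <- fit_config(nlpd_threshold = 1e-6, max_filters = 6,
                    nlpd_tolerance = 0.005 * floor_nlpd,
                    max_iterations_per_filter = 250, n_restarts = 4,
                    rng_seed = seed)
  fit <- fit_percept(dr$drawing, stim, sp, cfg)
  rec_th <- vapply(fit$filter_set$filters, `[[`, 0, "orientation")
  rec_f <- vapply(fit$filter_set$filters, `[[`, 0, "spatial_frequency")
  matched <- all(vapply(truth$filters, function(g) {
    d <- orientation_diff_deg(g$orientation, rec_th)
    any(d <= 3 &
          abs(rec_f - g$spatial_frequency) / g$spatial_frequency <= 0.1)
  }, logical(1)))
  list(matched = matched, nlpd_ok = fit$final_nlpd <= threshold,
       fit = fit, truth = truth, threshold = threshold)
}
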