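#' Configuration of the iterative percept fit
#'
#' The fit adds one grating filter at a time, optimizing the six parameters
#' of the newest filter with Nelder-Mead while all previously accepted
#' filters stay fixed, and stops when the perceptual distance (NLPD) to the
#' drawing reaches `nlpd_threshold`, when a round fails to improve the NLPD
#' by more than `nlpd_tolerance`, or when `max_filters` is reached.
#'
#' @param nlpd_threshold stop when the NLPD falls to or below this value.
#'   There is no universal value: the appropriate threshold depends on the
#'   drawing's noise level and is typically set per drawing.
#' @param max_filters maximum number of filters (default 6).
#' @param max_iterations_per_filter Nelder-Mead iteration cap per restart
#'   (default 200; sensible values lie in 100-400).
#' @param parameter_tolerance simplex parameter tolerance.
#' @param nlpd_tolerance minimum NLPD improvement for a new filter to be
#'   accepted.
#' @param n_restarts Nelder-Mead restarts per filter round from jittered /
#'   grid-seeded starting points; the best result is kept (default 3).
#' @param rng_seed seed controlling restart jitter.
#' @param nlpd_params an [nlpd_params()] object for the objective.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(nlpd_threshold = 0.9, max_filters = 6,
                       max_iterations_per_filter = 200,
                       parameter_tolerance = 1e-4, nlpd_tolerance = 1e-6,
                       n_restarts = 3, rng_seed = 1,
                       nlpd_params = amblyosim::nlpd_params()) {
  if (nlpd_threshold <= 0 || nlpd_tolerance <= 0)
    stop("thresholds and tolerances must be > 0")
  if (max_filters < 1) stop("max_filters must be >= 1")
  structure(list(nlpd_threshold = nlpd_threshold, max_filters = max_filters,
                 max_iterations_per_filter = max_iterations_per_filter,
                 parameter_tolerance = parameter_tolerance,
                 nlpd_tolerance = nlpd_tolerance, n_restarts = n_restarts,
                 rng_seed = rng_seed, nlpd_params = nlpd_params),
            class = "fit_config")
}

#' Stimulus-matched initial filter set
#'
#' The fit starts from a single filter whose orientation, spatial frequency
#' and phase are copied from the stimulus, with `K = 0`, `T = 1`, `A = 1`
#' and unit weight, so that the initial simulated percept reproduces the
#' stimulus (the ideal percept).
#'
#' @param stimulus the stimulus `image_field` (geometry carrier).
#' @param stim_params `grating_params` describing the stimulus.
#' @return a `filter_set` with one filter and weight 1.
#' @export
initialize_from_stimulus <- function(stimulus, stim_params) {
  if (stimulus$pixels_per_degree <= 0) stop("invalid stimulus geometry")
  filter_set(
    grating_params(stim_params$orientation, stim_params$spatial_frequency,
                   stim_params$phase, K = 0, T_sat = 1, A = 1),
    weights = 1)
}

# Nelder-Mead is unconstrained, so the six filter parameters are optimized
# in an unbounded "raw" space and mapped to their domains by smooth bijective
# transforms (hard clamping would create flat plateaus that collapse the
# simplex). Orientation and phase are periodic; spatial frequency is kept
# between 1 cpd (below ~1 cycle/deg a "grating" degenerates into a luminance
# sheet) and 95% of Nyquist; K, T, A use tanh/logistic maps onto their
# published ranges.
raw_to_natural <- function(par, nyquist) {
  f_hi <- 0.95 * nyquist
  list(theta = par[1] %% 180,
       f = 1 + (f_hi - 1) * stats::plogis(par[2]),
       phase = par[3] %% 360,
       K = tanh(par[4]),
       T_sat = 1 + tanh(par[5]),
       A = stats::plogis(par[6]))
}

natural_to_raw <- function(theta, f, phase, K, T_sat, A, nyquist) {
  f_hi <- 0.95 * nyquist
  f <- min(max(f, 1 + 1e-6), f_hi - 1e-6)
  c(theta,
    stats::qlogis((f - 1) / (f_hi - 1)),
    phase,
    atanh(min(max(K, -0.999), 0.999)),
    atanh(min(max(T_sat - 1, -0.999), 0.999)),
    stats::qlogis(min(max(A, 1e-3), 1 - 1e-3)))
}

# Fast percept objective: NLPD(drawing, clip(fixed_sum + A * F(par), -1, 1))
make_round_objective <- function(fixed_sum, drawing_pyr, geom, p) {
  force(fixed_sum); force(drawing_pyr); force(geom); force(p)
  function(par) {
    q <- raw_to_natural(par, geom$nyquist)
    th <- q$theta * pi / 180
    ph <- q$phase * pi / 180
    surf <- outer(2 * pi * q$f * cos(th) * geom$y,
                  2 * pi * q$f * sin(th) * geom$x, "+")
    fv <- pmin(pmax(sin(surf + ph) + q$K, -q$T_sat), q$T_sat)
    v <- fixed_sum + q$A * fv
    v <- pmin(pmax(v, -1), 1)
    v[!geom$aperture] <- 0
    val <- nlpd_from_pyramids(drawing_pyr, build_normalized_pyramid(v, p))
    if (!is.finite(val))
      stop("non-finite NLPD objective at parameters: ",
           paste(signif(par, 4), collapse = ", "))
    val
  }
}

filter_values <- function(params, geom) {
  th <- params$orientation * pi / 180
  ph <- params$phase * pi / 180
  f <- params$spatial_frequency
  surf <- outer(2 * pi * f * cos(th) * geom$y, 2 * pi * f * sin(th) * geom$x, "+")
  fv <- pmin(pmax(sin(surf + ph) + params$K, -params$T_sat), params$T_sat)
  fv[!geom$aperture] <- 0
  fv
}

# Matching-pursuit seeding: locate the dominant sinusoidal components of
# the residual (drawing minus current percept) from its Fourier spectrum
# and turn each spectral peak into a candidate (orientation, frequency,
# amplitude); the phase is picked by a small 1-D sweep of the objective.
residual_seeds <- function(residual, obj, ppd, nyquist, n_starts,
                           exclude = list()) {
  n <- nrow(residual)
  am <- Mod(fft(residual))
  half <- function(idx) ifelse(idx - 1 > n / 2, idx - 1 - n, idx - 1)
  p_sgn <- half(seq_len(n))  # signed cycles per field, row axis
  fp <- outer(p_sgn, p_sgn, function(p, q) sqrt(p^2 + q^2)) * ppd / n
  am[fp < 1 | fp > 0.9 * nyquist] <- 0  # drop DC/near-DC and near-Nyquist bins
  ord <- order(am, decreasing = TRUE)

  picked <- list()
  for (idx in ord) {
    if (length(picked) >= n_starts || am[idx] <= 0) break
    ij <- arrayInd(idx, dim(am))
    p <- half(ij[1])
    q <- half(ij[2])
    th <- (atan2(q, p) * 180 / pi) %% 180
    f <- sqrt(p^2 + q^2) * ppd / n
    picked_nat <- lapply(picked, function(pp) {
      q <- raw_to_natural(pp, nyquist)
      c(q$theta, q$f)
    })
    dup <- any(vapply(c(picked_nat, exclude), function(s)
      orientation_diff_deg(s[1], th) < 8 && abs(s[2] - f) / f < 0.25,
      logical(1)))
    if (dup) next
    amp <- min(max(2 * am[idx] / n^2, 0.05), 0.95)
    # phase by coarse sweep at the seeded orientation/frequency
    phases <- seq(0, 315, by = 45)
    pv <- vapply(phases, function(ph)
      obj(natural_to_raw(th, f, ph, 0, 1, amp, nyquist)), numeric(1))
    picked[[length(picked) + 1]] <-
      natural_to_raw(th, f, phases[which.min(pv)], 0, 1, amp, nyquist)
  }
  picked
}

#' Fit the percept model to a drawing
#'
#' Iteratively adds rectified grating filters and minimizes the NLPD
#' between the simulated percept and the drawing with Nelder-Mead. The
#' first filter starts from the stimulus-matched initialization; each later
#' round seeds its restarts from a coarse orientation/frequency/phase grid
#' evaluated against the residual objective, then refines the best
#' candidates. Previously accepted filters are held fully fixed. A new
#' filter is accepted only if it lowers the best NLPD, so the per-round
#' trace is non-increasing.
#'
#' @param drawing the perceptual drawing (`image_field`).
#' @param stimulus the grating stimulus (`image_field`, same geometry).
#' @param stim_params `grating_params` of the stimulus.
#' @param cfg a [fit_config()].
#' @return An object of class `fit_result`: `filter_set`, `final_nlpd`,
#'   `nlpd_trace` (best NLPD after the initial percept and after each
#'   accepted round), `n_filters_used`, `converged`, `threshold`, and
#'   `stim_params`.
#' @export
fit_percept <- function(drawing, stimulus, stim_params, cfg = fit_config()) {
  stop_if_geometry_mismatch(drawing, stimulus)
  n <- nrow(drawing$values)
  co <- field_coords(n, drawing$pixels_per_degree)
  geom <- list(x = co$x, y = co$y, aperture = drawing$aperture,
               nyquist = drawing$pixels_per_degree / 2)
  p <- cfg$nlpd_params
  drawing_pyr <- build_normalized_pyramid(drawing$values, p)

  init <- initialize_from_stimulus(stimulus, stim_params)
  fixed_sum <- init$weights[1] * filter_values(init$filters[[1]], geom)
  best_nlpd <- nlpd_from_pyramids(
    drawing_pyr, build_normalized_pyramid(pmin(pmax(fixed_sum, -1), 1), p))

  filters <- list()
  weights <- numeric(0)
  trace <- best_nlpd
  converged <- FALSE

  for (round in seq_len(cfg$max_filters)) {
    obj <- make_round_objective(
      if (round == 1) matrix(0, n, n) else fixed_sum,
      drawing_pyr, geom, p)

    if (round == 1) {
      base <- natural_to_raw(stim_params$orientation,
                             stim_params$spatial_frequency,
                             stim_params$phase, 0, 1, 0.9, geom$nyquist)
      starts <- list(base)
      if (cfg$n_restarts > 1) {
        jit <- withr::with_seed(cfg$rng_seed + round, {
          lapply(seq_len(cfg$n_restarts - 1), function(i)
            base + c(rnorm(1, 0, 5), rnorm(1, 0, 0.2),
                     rnorm(1, 0, 20), rnorm(1, 0, 0.2),
                     rnorm(1, 0, 0.2), rnorm(1, 0, 0.5)))
        })
        starts <- c(starts, jit)
      }
    } else {
      percept_now <- pmin(pmax(fixed_sum, -1), 1)
      percept_now[!geom$aperture] <- 0
      accepted_tf <- lapply(filters, function(g)
        c(g$orientation, g$spatial_frequency))
      starts <- residual_seeds(drawing$values - percept_now, obj,
                               drawing$pixels_per_degree, geom$nyquist,
                               cfg$n_restarts, exclude = accepted_tf)
      if (length(starts) == 0) {
        converged <- TRUE  # residual has no further distinct component
        break
      }
    }

    # a candidate that converges onto an already-accepted filter's
    # orientation/frequency is a re-parametrization of that filter, not a
    # new percept component, and is not accepted
    is_dup <- function(par) {
      if (round == 1) return(FALSE)
      q <- raw_to_natural(par, geom$nyquist)
      any(vapply(filters, function(g)
        orientation_diff_deg(g$orientation, q$theta) < 6 &&
          abs(g$spatial_frequency - q$f) / q$f < 0.2, logical(1)))
    }

    round_best <- NULL
    round_val <- Inf
    # uniform simplex scaling: ~degrees for the angular coordinates, ~0.5
    # in the logit/atanh coordinates, independent of the start values
    pscale <- c(10, 0.5, 30, 0.5, 0.5, 0.5)
    for (s in starts) {
      res <- optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = cfg$max_iterations_per_filter,
                                  reltol = cfg$parameter_tolerance,
                                  parscale = pscale))
      if (res$value < round_val && !is_dup(res$par)) {
        round_val <- res$value
        round_best <- res$par
      }
    }
    if (is.null(round_best)) {
      converged <- TRUE
      break
    }

    improved <- round_val < best_nlpd - cfg$nlpd_tolerance
    if (round == 1 && round_val <= best_nlpd) improved <- TRUE
    if (!improved) {
      converged <- TRUE  # no further filter helps beyond tolerance
      break
    }

    q <- raw_to_natural(round_best, geom$nyquist)
    gp <- grating_params(q$theta, q$f, q$phase, K = q$K, T_sat = q$T_sat,
                         A = q$A)
    filters[[length(filters) + 1]] <- gp
    weights <- c(weights, q$A)
    fixed_sum <- (if (round == 1) 0 else fixed_sum) +
      q$A * filter_values(gp, geom)
    best_nlpd <- round_val
    trace <- c(trace, best_nlpd)

    if (best_nlpd <= cfg$nlpd_threshold) {
      converged <- TRUE
      break
    }
  }

  fs <- if (length(filters) > 0) filter_set(filters, weights) else init
  structure(
    list(filter_set = fs, final_nlpd = best_nlpd, nlpd_trace = trace,
         n_filters_used = length(fs$filters), converged = converged,
         threshold = cfg$nlpd_threshold, stim_params = stim_params),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %d filter(s), final NLPD %.4g (threshold %.4g), %s\n",
    x$n_filters_used, x$final_nlpd, x$threshold,
    if (x$converged) "converged" else "stopped at max_filters"))
  print(x$filter_set)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  rec <- list(
    filters = lapply(seq_along(fit$filter_set$filters), function(i) {
      g <- fit$filter_set$filters[[i]]
      list(orientation = g$orientation,
           spatial_frequency = g$spatial_frequency, phase = g$phase,
           K = g$K, T = g$T_sat, A = g$A,
           weight = fit$filter_set$weights[i])
    }),
    final_nlpd = fit$final_nlpd, nlpd_trace = fit$nlpd_trace,
    n_filters_used = fit$n_filters_used, converged = fit$converged,
    threshold = fit$threshold,
    stimulus = list(orientation = fit$stim_params$orientation,
                    spatial_frequency = fit$stim_params$spatial_frequency,
                    phase = fit$stim_params$phase))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit result written by [write_fit_result()]
#'
#' @param path JSON path.
#' @return a `fit_result`.
#' @export
read_fit_result <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = FALSE)
  filters <- lapply(rec$filters, function(fl)
    grating_params(fl$orientation, fl$spatial_frequency, fl$phase,
                   K = fl$K, T_sat = fl$T, A = fl$A))
  weights <- vapply(rec$filters, function(fl) fl$weight, numeric(1))
  structure(
    list(filter_set = filter_set(filters, weights),
         final_nlpd = rec$final_nlpd,
         nlpd_trace = unlist(rec$nlpd_trace),
         n_filters_used = rec$n_filters_used, converged = rec$converged,
         threshold = rec$threshold,
         stim_params = grating_params(rec$stimulus$orientation,
                                      rec$stimulus$spatial_frequency,
                                      rec$stimulus$phase)),
    class = "fit_result")
}
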