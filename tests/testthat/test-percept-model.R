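test_that("grating values follow the orientation/phase conventions", {
  # odd side so one pixel sits exactly at the field center
  g <- make_grating(grating_params(0, 1, 0), extent_deg = 3.25,
                    pixels_per_degree = 20)
  n <- nrow(g$values)
  expect_equal(n %% 2, 1)
  mid <- (n + 1) / 2
  expect_equal(g$values[mid, mid], 0, tolerance = 1e-12)

  # horizontal grating: rows constant along x inside the aperture
  gh <- make_tiny_grating(theta = 0, f = 5)
  for (i in c(10, 32, 50)) {
    row <- gh$values[i, gh$aperture[i, ]]
    expect_lt(diff(range(row)), 1e-12)
  }
  expect_true(all(gh$values >= -1 & gh$values <= 1))

  # many cycles across the aperture: mean ~ 0
  g5 <- make_tiny_grating(theta = 0, f = 5)
  expect_lt(abs(mean(g5$values[g5$aperture])), 1e-3)
})

test_that("grating construction rejects bad geometry and aliasing", {
  expect_error(make_grating(grating_params(0, 15), n_pixels = 64),
               "Nyquist")
  expect_error(make_grating(grating_params(0, 5), extent_deg = -1),
               "positive")
  expect_error(grating_params(0, 5, K = 1.5), "K")
  expect_error(grating_params(0, 5, T_sat = 2.5), "T")
  expect_error(grating_params(0, 5, A = -0.1), "A")
})

test_that("filter rectification equals elementwise clip (three-branch oracle)", {
  # brute-force per-pixel three-branch rule on random matrices
  clip_oracle <- function(m, K, T_sat) {
    out <- m
    for (i in seq_along(m)) {
      v <- m[i] + K
      out[i] <- if (v >= T_sat) T_sat else if (v <= -T_sat) -T_sat else v
    }
    out
  }
  withr::with_seed(42, {
    for (rep in 1:5) {
      m <- matrix(runif(256, -1, 1), 16, 16)
      K <- runif(1, -1, 1)
      T_sat <- runif(1, 0, 2)
      expect_identical(pmin(pmax(m + K, -T_sat), T_sat),
                       clip_oracle(m, K, T_sat))
    }
  })
})

test_that("filter examples: inactive clipping, duty-cycle asymmetry, exact pixel", {
  # K = 0, T = 1: clipping inactive, filter equals the grating
  g <- make_tiny_grating(theta = 30, f = 2.5)
  f0 <- make_filter(grating_params(30, 2.5, K = 0, T_sat = 1),
                    n_pixels = 64)
  expect_equal(f0$values, g$values, tolerance = 1e-12)

  # negative K thickens dark bars: more negative than positive pixels
  # (2 cpd at 20 px/deg samples 10 phases per cycle, enough to resolve the
  # duty-cycle asymmetry)
  fneg <- make_filter(grating_params(0, 2, K = -0.5, T_sat = 1),
                      n_pixels = 64)
  ap <- fneg$aperture
  expect_gt(mean(fneg$values[ap] < 0), mean(fneg$values[ap] > 0))

  # elementwise example: G = 0.6, K = 0.5, T = 0.8 -> clipped at 0.8
  expect_equal(min(max(0.6 + 0.5, -0.8), 0.8), 0.8)
  f2 <- make_filter(grating_params(0, 5, K = 0.5, T_sat = 0.8),
                    n_pixels = 64)
  idx <- which(abs(g_v <- make_tiny_grating(0, 5)$values - 0.6) < 0.02 &
                 f2$aperture, arr.ind = TRUE)
  expect_true(all(abs(f2$values[idx] - 0.8) < 0.03))
})

test_that("filter weight behaves as a zero-lag stimulus correlation", {
  s <- make_tiny_grating(theta = 0, f = 5)

  # A = 0 kills the weight
  expect_identical(filter_weight(s, grating_params(0, 5, A = 0)), 0)

  # matched grating: mean of sin^2 over whole periods ~ 1/2
  w_match <- filter_weight(s, grating_params(0, 5, A = 1))
  expect_equal(w_match, 0.5, tolerance = 0.02)

  # orthogonal orientations: near-zero weight
  w_orth <- filter_weight(s, grating_params(90, 5, A = 1))
  expect_lt(abs(w_orth), 0.01)

  # maximal over orientation at the stimulus orientation
  thetas <- seq(0, 175, by = 5)
  ws <- vapply(thetas, function(th)
    filter_weight(s, grating_params(th, 5, A = 1)), numeric(1))
  expect_equal(thetas[which.max(ws)], 0)
})

test_that("percept synthesis saturates, stays linear below saturation, and is symmetric", {
  g <- grating_params(0, 5)

  # single filter, weight 1, K = 0, T = 1: identity chain
  p1 <- synthesize_percept(filter_set(g, weights = 1), n_pixels = 64)
  expect_equal(p1$values, make_tiny_grating(0, 5)$values, tolerance = 1e-12)

  # outputs bounded for arbitrary sets
  withr::with_seed(7, {
    fs <- filter_set(lapply(1:3, function(i)
      grating_params(runif(1, 0, 180), runif(1, 1.5, 8),
                     runif(1, 0, 360), K = runif(1, -1, 1),
                     T_sat = runif(1, 0.5, 2), A = runif(1))),
      weights = runif(3, -1, 1))
    p <- synthesize_percept(fs, n_pixels = 64)
    expect_true(all(p$values >= -1 & p$values <= 1))
  })

  # linearity in the weights before saturation
  fs_small <- filter_set(list(grating_params(0, 5), grating_params(60, 2.5)),
                         weights = c(0.2, 0.15))
  fs_double <- filter_set(fs_small$filters, weights = c(0.4, 0.3))
  pa <- synthesize_percept(fs_small, n_pixels = 64)
  pb <- synthesize_percept(fs_double, n_pixels = 64)
  expect_equal(pb$values, 2 * pa$values, tolerance = 1e-12)

  # two orthogonal equal-weight cosine-phase gratings: 90 deg rotation symmetry
  fs_sym <- filter_set(list(grating_params(0, 5, phase = 90),
                            grating_params(90, 5, phase = 90)),
                       weights = c(0.4, 0.4))
  p <- synthesize_percept(fs_sym, n_pixels = 64)
  rot90 <- t(p$values)[nrow(p$values):1, ]
  expect_equal(p$values, rot90, tolerance = 1e-9)

  expect_error(synthesize_percept(list()), "filter_set")
})

test_that("image fields round-trip through CSV and PNG", {
  img <- make_tiny_grating(theta = 45, f = 2.5, phase = 30)
  csv <- tempfile(fileext = ".csv")
  png_f <- tempfile(fileext = ".png")
  write_image_field(img, csv)
  write_image_field(img, png_f)
  back_csv <- read_image_field(csv)
  back_png <- read_image_field(png_f)
  expect_equal(back_csv$values, img$values, tolerance = 1e-9)
  expect_equal(back_csv$pixels_per_degree, img$pixels_per_degree)
  # PNG is 8-bit: quantization within one gray level
  expect_lt(max(abs(back_png$values - img$values)), 2 / 255 + 1e-9)
  unlink(c(csv, png_f, paste0(c(csv, png_f), ".json")))
})
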