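#' Cortical orientation-preference map
#'
#' A rectangular grid of preferred orientations in degrees \[0, 180) with a
#' cortical magnification given as millimetres per pixel.
#'
#' @param preferred_orientation numeric matrix of orientations (degrees).
#' @param mm_per_pixel cortical millimetres per grid pixel (> 0).
#' @param provenance `"file"` or `"synthetic"`.
#' @return An object of class `orientation_map`.
#' @export
orientation_map <- function(preferred_orientation, mm_per_pixel,
                            provenance = c("synthetic", "file")) {
  provenance <- match.arg(provenance)
  m <- as.matrix(preferred_orientation) %% 180
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be > 0")
  structure(list(preferred_orientation = m, mm_per_pixel = mm_per_pixel,
                 provenance = provenance),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("<orientation_map> %d x %d px, %.4g mm/px (%s)\n",
              nrow(x$preferred_orientation), ncol(x$preferred_orientation),
              x$mm_per_pixel, x$provenance))
  invisible(x)
}

#' Read/write orientation maps as CSV plus JSON sidecar
#'
#' One orientation value (degrees) per cell, row-major CSV; the sidecar
#' `<file>.json` carries `{mm_per_pixel}`.
#'
#' @param map an `orientation_map`.
#' @param path CSV path.
#' @return path / `orientation_map`.
#' @export
write_orientation_map <- function(map, path) {
  write.table(map$preferred_orientation, path, sep = ",",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(mm_per_pixel = map$mm_per_pixel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_orientation_map
#' @export
read_orientation_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  orientation_map(m, meta$mm_per_pixel, provenance = "file")
}

#' Circular distance between orientations, scaled to \[0, 1\]
#'
#' `|o1 - o2| / 90` when the absolute difference (mod 180) is at most 90
#' degrees, `(180 - |o1 - o2|) / 90` otherwise: 0 for identical
#' orientations, 1 for orthogonal ones. Vectorized.
#'
#' @param o1,o2 orientations in degrees.
#' @return circular distance(s) in \[0, 1\].
#' @export
circ_dist <- function(o1, o2) {
  d <- abs(o1 - o2) %% 180
  pmin(d, 180 - d) / 90
}

#' Fellow-eye cortical response map
#'
#' Each cortical pixel responds with `1 - circ_dist(O_C, O_S)`: 1 when its
#' preferred orientation matches the stimulus, 0 when orthogonal.
#'
#' @param map an `orientation_map`.
#' @param stim_orientation stimulus orientation in degrees.
#' @param threshold_fraction spread threshold carried on the map
#'   (default 0.7).
#' @return An object of class `activation_map` (`response`, `eye`,
#'   `threshold_fraction`).
#' @export
fellow_response <- function(map, stim_orientation, threshold_fraction = 0.7) {
  r <- 1 - circ_dist(map$preferred_orientation, stim_orientation)
  structure(list(response = r, eye = "fellow",
                 threshold_fraction = threshold_fraction),
            class = "activation_map")
}

#' Orientation-similarity weight of a contributing grating
#'
#' Gaussian weight `exp(-circ_dist(o_g, o_s)^2 / (2 sigma^2))` centred at
#' zero circular distance from the stimulus orientation.
#'
#' @param o_g grating orientation (degrees).
#' @param o_s stimulus orientation (degrees).
#' @param sigma width of the Gaussian in circular-distance units
#'   (default 0.2).
#' @return weight in (0, 1\].
#' @export
grating_weight <- function(o_g, o_s, sigma = 0.2) {
  if (sigma <= 0) stop("sigma must be > 0")
  exp(-circ_dist(o_g, o_s)^2 / (2 * sigma^2))
}

#' Amblyopic-eye cortical response map
#'
#' Sums, over all gratings contributing to the simulated percept, the
#' pixel's orientation response to the grating
#' (`1 - circ_dist(O_C, O_G)`), weighted by the grating's similarity to the
#' stimulus orientation ([grating_weight()]).
#'
#' @param map an `orientation_map`.
#' @param filters a `filter_set` (only filter orientations are used).
#' @param stim_orientation stimulus orientation in degrees.
#' @param sigma Gaussian weight width (default 0.2).
#' @param threshold_fraction spread threshold (default 0.7).
#' @return an `activation_map` with `eye = "amblyopic"`.
#' @export
amblyopic_response <- function(map, filters, stim_orientation, sigma = 0.2,
                               threshold_fraction = 0.7) {
  if (!inherits(filters, "filter_set") || length(filters$filters) < 1)
    stop("filters must be a non-empty filter_set")
  r <- matrix(0, nrow(map$preferred_orientation),
              ncol(map$preferred_orientation))
  for (g in filters$filters) {
    wg <- grating_weight(g$orientation, stim_orientation, sigma)
    r <- r + (1 - circ_dist(map$preferred_orientation, g$orientation)) * wg
  }
  structure(list(response = r, eye = "amblyopic",
                 threshold_fraction = threshold_fraction),
            class = "activation_map")
}

#' Cortical spread: count of strongly activated pixels
#'
#' A pixel is strongly activated when its response is at least
#' `threshold_fraction` of the map's maximum response (per-eye maximum).
#'
#' @param act an `activation_map`.
#' @return integer count.
#' @export
spread <- function(act) {
  mx <- max(act$response)
  if (mx <= 0) stop("all-zero activation map; maximum undefined")
  sum(act$response >= act$threshold_fraction * mx)
}

#' Amblyopic/fellow cortical spread ratio
#'
#' @param fellow,amblyopic `activation_map`s of the same shape.
#' @return An object of class `spread_result`: `n_active_fellow`,
#'   `n_active_amblyopic`, `spread_ratio`.
#' @export
spread_ratio <- function(fellow, amblyopic) {
  if (!all(dim(fellow$response) == dim(amblyopic$response)))
    stop("activation maps differ in shape")
  nf <- spread(fellow)
  na <- spread(amblyopic)
  structure(list(n_active_fellow = nf, n_active_amblyopic = na,
                 spread_ratio = na / nf),
            class = "spread_result")
}

#' Column width and pinwheel density of an orientation map
#'
#' The orientation signal is embedded as the complex field
#' `z = exp(2 i theta)`. The orientation-column width is half the dominant
#' spatial wavelength of `z`, taken from the peak of the radially averaged
#' power spectrum (the reported spread is the power-weighted standard
#' deviation over the half-power band around the peak). Pinwheels are the
#' +/- half-integer phase singularities of `z`, counted by accumulating
#' wrapped phase differences around every 2 x 2 plaquette; density is per
#' square millimetre.
#'
#' @param map an `orientation_map` (at least ~20 x 20 pixels for a stable
#'   spectral estimate).
#' @return list with `column_width_mm`, `column_width_sd_mm`,
#'   `pinwheel_count`, `pinwheel_density_mm2`. A constant map yields 0
#'   pinwheels and `NA` width.
#' @export
map_metrics <- function(map) {
  th <- map$preferred_orientation * pi / 180
  z <- exp(2i * th)
  n <- nrow(z)
  m <- ncol(z)

  zc <- z - mean(z)
  if (sqrt(mean(Mod(zc)^2)) < 1e-10) {
    return(list(column_width_mm = NA_real_, column_width_sd_mm = NA_real_,
                pinwheel_count = 0L, pinwheel_density_mm2 = 0))
  }

  pw <- Mod(fft(zc))^2
  fy <- ifelse(seq_len(n) - 1 > n / 2, seq_len(n) - 1 - n, seq_len(n) - 1) / n
  fx <- ifelse(seq_len(m) - 1 > m / 2, seq_len(m) - 1 - m, seq_len(m) - 1) / m
  fr <- sqrt(outer(fy^2, fx^2, "+"))  # cycles per pixel
  nb <- floor(min(n, m) / 2)
  idx <- pmin(pmax(round(fr * min(n, m)), 1), nb)  # ring index, DC -> ring 1
  ring_pow <- tapply(as.vector(pw), as.vector(idx), sum)
  rings <- as.integer(names(ring_pow))
  ring_f <- rings / min(n, m)
  pk <- which.max(ring_pow)
  band <- ring_pow >= 0.5 * ring_pow[pk]
  halfwave_mm <- map$mm_per_pixel / (2 * ring_f)
  wmean <- sum(halfwave_mm[band] * ring_pow[band]) / sum(ring_pow[band])
  wsd <- sqrt(sum(ring_pow[band] * (halfwave_mm[band] - wmean)^2) /
                sum(ring_pow[band]))

  ph <- Arg(z)
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  d1 <- wrap(ph[-1, -m, drop = FALSE] - ph[-n, -m, drop = FALSE])
  d2 <- wrap(ph[-1, -1, drop = FALSE] - ph[-1, -m, drop = FALSE])
  d3 <- wrap(ph[-n, -1, drop = FALSE] - ph[-1, -1, drop = FALSE])
  d4 <- wrap(ph[-n, -m, drop = FALSE] - ph[-n, -1, drop = FALSE])
  winding <- round((d1 + d2 + d3 + d4) / (2 * pi))
  count <- sum(winding != 0)
  area_mm2 <- ((n - 1) * map$mm_per_pixel) * ((m - 1) * map$mm_per_pixel)

  list(column_width_mm = wmean, column_width_sd_mm = wsd,
       pinwheel_count = as.integer(count),
       pinwheel_density_mm2 = count / area_mm2)
}
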