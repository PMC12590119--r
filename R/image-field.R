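#' Square luminance-contrast image with visual-field geometry
#'
#' An `image_field` couples a square numeric matrix of luminance contrast
#' (dimensionless, nominally in \[-1, 1\] where 0 is the mean-luminance
#' background) with its visual geometry: the stimulus extent in degrees of
#' visual angle and the pixel density in pixels per degree. A circular
#' aperture inscribed in the square is applied; pixels outside it are held
#' at 0 (background).
#'
#' @param values square numeric matrix of finite values.
#' @param extent_deg stimulus diameter in degrees of visual angle.
#' @param pixels_per_degree pixel density (> 0). If `NULL`, derived from
#'   `ncol(values) / extent_deg`.
#' @param mask_aperture apply the circular aperture (default `TRUE`).
#'
#' @return An object of class `image_field`: a list with elements `values`,
#'   `extent_deg`, `pixels_per_degree` and `aperture` (logical matrix).
#' @export
image_field <- function(values, extent_deg = 3.2, pixels_per_degree = NULL,
                        mask_aperture = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("image_field: matrix must be square")
  if (!all(is.finite(values)))
    stop("image_field: values must be finite")
  if (is.null(pixels_per_degree))
    pixels_per_degree <- ncol(values) / extent_deg
  if (extent_deg <= 0 || pixels_per_degree <= 0)
    stop("image_field: geometry must be positive")
  ap <- aperture_mask(ncol(values), extent_deg, pixels_per_degree)
  if (mask_aperture) values[!ap] <- 0
  structure(
    list(values = values, extent_deg = extent_deg,
         pixels_per_degree = pixels_per_degree, aperture = ap),
    class = "image_field")
}

#' Pixel-center coordinates in degrees for a square field
#'
#' Coordinates are centered on the field: for odd side lengths the central
#' pixel sits exactly at the origin.
#'
#' @param n side length in pixels.
#' @param pixels_per_degree pixel density.
#' @return list with vectors `x` and `y` (degrees).
#' @export
field_coords <- function(n, pixels_per_degree) {
  v <- (seq_len(n) - (n + 1) / 2) / pixels_per_degree
  list(x = v, y = v)
}

aperture_mask <- function(n, extent_deg, pixels_per_degree) {
  co <- field_coords(n, pixels_per_degree)
  r2 <- (extent_deg / 2)^2
  outer(co$y^2, co$x^2, "+") <= r2
}

#' Test whether two image fields share geometry
#'
#' @param a,b `image_field` objects.
#' @return logical.
#' @export
same_geometry <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(a$extent_deg, b$extent_deg)) &&
    isTRUE(all.equal(a$pixels_per_degree, b$pixels_per_degree))
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b))
    stop("image fields do not share geometry (size, extent, pixel density)")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field> %d x %d px, %.3g deg extent, %.3g px/deg\n",
              nrow(x$values), ncol(x$values), x$extent_deg,
              x$pixels_per_degree))
  cat(sprintf("  values in [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read and write image fields
#'
#' Two interchange formats are supported: 8-bit grayscale PNG with the
#' linear mapping \[-1, 1\] -> \[0, 255\] (for inspection), and lossless CSV
#' numeric grids. Geometry travels in a JSON sidecar
#' (`{extent_deg, pixels_per_degree}`) named `<file>.json`.
#'
#' @param img an `image_field`.
#' @param path output/input file path (`.png` or `.csv`).
#' @return `write_image_field` returns `path` invisibly; `read_image_field`
#'   returns an `image_field`.
#' @export
write_image_field <- function(img, path) {
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(extent_deg = img$extent_deg,
         pixels_per_degree = img$pixels_per_degree),
    sidecar, auto_unbox = TRUE, digits = NA)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    v <- pmin(pmax((img$values + 1) / 2, 0), 1)
    png::writePNG(v, target = path)
  } else {
    write.table(img$values, path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_image_field
#' @export
read_image_field <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing geometry sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3) v <- v[, , 1]
    v <- v * 2 - 1
  } else {
    v <- as.matrix(read.csv(path, header = FALSE))
    dimnames(v) <- NULL
  }
  image_field(v, extent_deg = meta$extent_deg,
              pixels_per_degree = meta$pixels_per_degree)
}
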