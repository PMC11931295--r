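#' CIE 1931 2-degree color-matching functions
#'
#' Bundled abridged table at 10-nm steps over 400-700 nm.
#'
#' @param wavelengths wavelengths in nm; must lie on the bundled grid.
#' @return data.frame with columns `wavelength_nm`, `xbar`, `ybar`, `zbar`.
#' @export
cie_cmfs <- function(wavelengths = wavelength_grid()) {
  tab <- .cached("cmf", .extdata("cie1931_cmf_10nm.csv"))
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx)) stop("color-matching functions not tabulated at requested wavelengths")
  tab[idx, ]
}

#' Illuminant spectral power distribution
#'
#' @param name `"D65"` (CIE daylight, default) or `"E"` (equal energy).
#' @param wavelengths wavelengths in nm on the bundled grid.
#' @return Numeric vector of relative spectral power.
#' @export
illuminant_spd <- function(name = c("D65", "E"),
                           wavelengths = wavelength_grid()) {
  name <- match.arg(name)
  file <- if (name == "D65") "illuminant_d65_10nm.csv" else "illuminant_e_10nm.csv"
  tab <- .cached(paste0("ill_", name), .extdata(file))
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx)) stop("illuminant not tabulated at requested wavelengths")
  out <- tab$power[idx]
  attr(out, "illuminant") <- name
  out
}

#' Tristimulus values of a reflectance spectrum
#'
#' Discrete-summation CIEXYZ integration at the 10-nm grid:
#' `X = k * sum(E * xbar * theta)` (and likewise Y, Z) with
#' `k = 100 / sum(E * ybar)`, so the perfect diffuser has Y = 100 under any
#' illuminant.
#'
#' @param theta diffuse reflectance per wavelength (dimensionless), or a
#'   matrix with one spectrum per row.
#' @param illuminant illuminant name passed to [illuminant_spd()], or a
#'   numeric spectral power vector on the same grid.
#' @param wavelengths wavelength grid shared by all inputs.
#' @return Named numeric vector `c(x, y, z)`, or a matrix with columns
#'   `x`, `y`, `z` for matrix input.
#' @export
#' @examples
#' reflectance_to_xyz(rep(1, 31))  # perfect diffuser: y exactly 100
reflectance_to_xyz <- function(theta, illuminant = "D65",
                               wavelengths = wavelength_grid()) {
  E <- if (is.character(illuminant)) {
    illuminant_spd(illuminant, wavelengths)
  } else {
    if (length(illuminant) != length(wavelengths)) {
      stop("illuminant does not cover the wavelength grid")
    }
    illuminant
  }
  cmf <- cie_cmfs(wavelengths)
  one <- is.null(dim(theta))
  if (one) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != length(wavelengths)) {
    stop("spectrum does not cover the wavelength grid")
  }
  k <- 100 / sum(E * cmf$ybar)
  out <- k * theta %*% cbind(x = E * cmf$xbar, y = E * cmf$ybar,
                             z = E * cmf$zbar)
  if (one) setNames(as.numeric(out), c("x", "y", "z")) else out
}

#' Camera-to-XYZ calibration from a color chart
#'
#' Fits the 3x3 linear map `xyz = N1 %*% rgb` by least squares over the
#' chart chips (24 for a standard chart; at least 3 linearly independent
#' chips are required).
#'
#' @param chart_rgb matrix (chips x 3) of linear camera responses.
#' @param chart_xyz matrix (chips x 3) of reference tristimulus values.
#' @return Object of class `n1_cal`: the matrix, per-channel residual RMS,
#'   and the condition number of the fitted map.
#' @export
calibrate_n1 <- function(chart_rgb, chart_xyz) {
  chart_rgb <- as.matrix(chart_rgb)
  chart_xyz <- as.matrix(chart_xyz)
  if (nrow(chart_rgb) != nrow(chart_xyz)) stop("chip counts differ")
  if (nrow(chart_rgb) < 3) stop("need at least 3 chips")
  qr_rgb <- qr(chart_rgb)
  if (qr_rgb$rank < 3) stop("chart is rank-deficient: chips are not linearly independent")
  coefs <- qr.coef(qr_rgb, chart_xyz)     # 3x3, columns are XYZ targets
  n1 <- t(coefs)
  resid <- chart_xyz - chart_rgb %*% coefs
  structure(list(matrix = n1,
                 residual_rms = sqrt(colMeans(resid^2)),
                 condition_number = kappa(n1, exact = TRUE),
                 n_chips = nrow(chart_rgb)),
            class = "n1_cal")
}

#' @export
print.n1_cal <- function(x, ...) {
  cat(sprintf("n1_cal: 3x3 RGB->XYZ map fitted on %d chips\n", x$n_chips))
  print(round(x$matrix, 6))
  cat(sprintf("  residual RMS (X, Y, Z): %s; condition number %.3g\n",
              paste(signif(x$residual_rms, 3), collapse = ", "),
              x$condition_number))
  invisible(x)
}

#' Read / write a color-chart CSV
#'
#' Chart files have columns `chip_id, r, g, b, x_ref, y_ref, z_ref`.
#'
#' @param path CSV path.
#' @return List with matrices `rgb` and `xyz`.
#' @export
read_chart <- function(path) {
  tab <- read.csv(path)
  need <- c("r", "g", "b", "x_ref", "y_ref", "z_ref")
  if (!all(need %in% names(tab))) {
    stop("chart file must have columns r, g, b, x_ref, y_ref, z_ref")
  }
  list(rgb = as.matrix(tab[, c("r", "g", "b")]),
       xyz = as.matrix(tab[, c("x_ref", "y_ref", "z_ref")]))
}

#' White-reference correction of a raw image
#'
#' Divides each pixel/channel by the white-diffuser reference image and
#' scales by the diffuser reflectance, putting the image on a reflectance
#' scale and removing illumination non-uniformity.
#'
#' @param raw_image,white_image numeric arrays of identical shape.
#' @param white_reflectance reflectance of the reference diffuser (0.99).
#' @return Corrected array; pixels where the white image is not positive are
#'   set `NA` and flagged in the logical attribute `"invalid"`.
#' @export
white_correct <- function(raw_image, white_image, white_reflectance = 0.99) {
  if (!identical(dim(raw_image), dim(white_image))) {
    stop("raw and white images must have the same shape")
  }
  bad <- !(white_image > 0)
  out <- raw_image / white_image * white_reflectance
  out[bad] <- NA_real_
  attr(out, "invalid") <- bad
  out
}

#' Apply an RGB-to-XYZ calibration to an image
#'
#' Per-pixel matrix product `xyz = N1 %*% rgb` on a linear-scale image.
#'
#' @param image numeric array `(rows, cols, 3)`, channels ordered R, G, B,
#'   or a matrix `(pixels, 3)`.
#' @param n1 an `n1_cal` object or a bare 3x3 matrix.
#' @return Array (or matrix) of the same shape holding XYZ planes.
#' @export
rgb_image_to_xyz <- function(image, n1) {
  m <- if (inherits(n1, "n1_cal")) n1$matrix else as.matrix(n1)
  dims <- dim(image)
  if (is.null(dims) || dims[length(dims)] != 3) {
    stop("image must have 3 channels in the last dimension")
  }
  flat <- matrix(image, ncol = 3)
  out <- flat %*% t(m)
  dim(out) <- dims
  out
}
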