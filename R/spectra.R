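#' Default wavelength grid
#'
#' The visible-range grid on which all spectra in the package live:
#' 400 to 700 nm inclusive at 10-nm steps (31 points).
#'
#' @param from,to,by grid limits and step in nm.
#' @return Numeric vector of wavelengths in nm, ascending.
#' @export
#' @examples
#' wavelength_grid()
wavelength_grid <- function(from = 400, to = 700, by = 10) {
  wl <- seq(from, to, by = by)
  if (any(wl <= 0)) stop("wavelengths must be positive")
  wl
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "burnchrom")
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  read.csv(path)
}

# cache for bundled tables so repeated lookups do not re-read CSVs
.bc_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, envir = .bc_cache)) assign(key, expr, envir = .bc_cache)
  get(key, envir = .bc_cache)
}

#' Chromophore extinction/absorption table
#'
#' Returns the bundled spectrum for one chromophore on the default grid.
#' Hemoglobin derivatives are molar extinction coefficients in
#' L mol^-1 cm^-1 on the tetramer basis; the melanosome entry is an
#' absorption coefficient in cm^-1 corresponding to a pure (100 vol.%)
#' melanosome.
#'
#' @param chromophore one of `"HbO"`, `"HbR"`, `"metHb"`, `"melanosome"`.
#' @return A data.frame with columns `wavelength_nm`, `value`, `units` and a
#'   `source` attribute; class `extinction_table`.
#' @export
extinction_table <- function(chromophore = c("HbO", "HbR", "metHb",
                                             "melanosome")) {
  chromophore <- match.arg(chromophore)
  .cached(paste0("ext_", chromophore), {
    manifest <- .extdata("manifest.csv")
    row <- manifest[manifest$chromophore == chromophore, ]
    tab <- .extdata(row$file)
    if (any(tab$value < 0)) stop("extinction table has negative entries")
    attr(tab, "chromophore") <- chromophore
    attr(tab, "source") <- row$source
    class(tab) <- c("extinction_table", "data.frame")
    tab
  })
}

.extinction_at <- function(chromophore, wavelengths) {
  tab <- extinction_table(chromophore)
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx)) {
    stop("wavelengths outside the bundled 400-700 nm grid are not ",
         "extrapolated: ", paste(wavelengths[is.na(idx)], collapse = ", "))
  }
  tab$value[idx]
}

#' Reduced scattering coefficient of skin
#'
#' Power-law approximation combining a Mie-like and a Rayleigh-like term,
#' `2e5 * lambda^-1.5 + 2e12 * lambda^-4` with lambda in nm. The formula's
#' native output is taken as cm^-1 and converted to mm^-1 (the package-wide
#' unit for optical coefficients); set `unit = "cm^-1"` for the raw values.
#'
#' @param wavelengths wavelengths in nm, positive.
#' @param unit `"mm^-1"` (default) or `"cm^-1"`.
#' @return Numeric vector of reduced scattering coefficients, with a `unit`
#'   attribute recording the convention.
#' @export
#' @examples
#' reduced_scattering(c(400, 700), unit = "cm^-1")
reduced_scattering <- function(wavelengths = wavelength_grid(),
                               unit = c("mm^-1", "cm^-1")) {
  unit <- match.arg(unit)
  if (any(wavelengths <= 0)) stop("wavelengths must be positive")
  musp_cm <- 2e5 * wavelengths^-1.5 + 2e12 * wavelengths^-4
  out <- if (unit == "mm^-1") musp_cm / 10 else musp_cm
  attr(out, "unit") <- unit
  out
}

#' Absorption spectrum of a single chromophore
#'
#' Absorption scales linearly with concentration. For hemoglobin derivatives
#' `concentration` is molar (mol/L) and `mua = log(10) * epsilon * C` with
#' epsilon the decadic molar extinction coefficient; for the melanosome,
#' `concentration` is the melanin volume fraction in percent and the bundled
#' pure-melanosome spectrum is scaled by `concentration / 100`.
#'
#' @param chromophore one of `"HbO"`, `"HbR"`, `"metHb"`, `"melanosome"`.
#' @param concentration molar concentration (hemoglobins) or vol.% (melanin);
#'   non-negative.
#' @param wavelengths wavelengths in nm, must lie on the bundled grid.
#' @return Absorption coefficient spectrum in mm^-1.
#' @export
chromophore_absorption <- function(chromophore, concentration,
                                   wavelengths = wavelength_grid()) {
  if (concentration < 0) stop("concentration must be >= 0")
  val <- .extinction_at(chromophore, wavelengths)
  mua_cm <- if (chromophore == "melanosome") {
    (concentration / 100) * val
  } else {
    log(10) * val * concentration
  }
  mua_cm / 10
}

#' Hemoglobin concentration of whole blood
#'
#' Whole blood with hematocrit 45% is taken as 2.32 mM hemoglobin and
#' defines the 100 vol.% reference for the dermal blood volume fraction.
#' @keywords internal
.BLOOD_HB_MOLAR <- 2.32e-3

#' Dermal blood absorption spectrum
#'
#' Combines the three hemoglobin derivatives at a given total blood volume
#' fraction and saturations. The molar concentration of each derivative is
#' `(c_hbt/100) * 2.32 mM` times its saturation fraction; the deoxygenated
#' fraction is `1 - (sto2 + stmet)/100`.
#'
#' @param c_hbt total hemoglobin as blood volume fraction in the dermis,
#'   vol.% (0 to 100).
#' @param sto2 tissue oxygen saturation, % of total hemoglobin.
#' @param stmet methemoglobin saturation, % of total hemoglobin.
#' @param wavelengths wavelengths in nm on the bundled grid.
#' @return Dermis absorption coefficient spectrum in mm^-1.
#' @export
blood_absorption <- function(c_hbt, sto2, stmet,
                             wavelengths = wavelength_grid()) {
  if (c_hbt < 0) stop("c_hbt must be >= 0")
  if (sto2 < 0 || stmet < 0) stop("saturations must be >= 0")
  if (sto2 + stmet > 100 + 1e-9) {
    stop("sto2 + stmet must not exceed 100%")
  }
  c_total <- (c_hbt / 100) * .BLOOD_HB_MOLAR
  f_oxy <- sto2 / 100
  f_met <- stmet / 100
  f_deoxy <- 1 - f_oxy - f_met
  chromophore_absorption("HbO", c_total * f_oxy, wavelengths) +
    chromophore_absorption("HbR", c_total * f_deoxy, wavelengths) +
    chromophore_absorption("metHb", c_total * f_met, wavelengths)
}

#' Chromophore concentration set
#'
#' Bundles the four chromophore concentrations driving the skin model:
#' melanin volume fraction in the epidermis and the three hemoglobin
#' derivatives as blood volume fractions in the dermis, all in vol.%.
#'
#' @param c_hbo,c_hbr,c_methb oxygenated, deoxygenated, methemoglobin blood
#'   volume fractions, vol.%, non-negative.
#' @param c_m melanin volume fraction, vol.%, non-negative.
#' @return List of class `concentration_set` with the four fields plus the
#'   derived `c_hbt` (their sum) and, where `c_hbt > 0`, `sto2` and `stmet`.
#' @export
#' @examples
#' concentration_set(c_hbo = 0.3, c_hbr = 0.1, c_methb = 0.1, c_m = 2)
concentration_set <- function(c_hbo = 0, c_hbr = 0, c_methb = 0, c_m = 0) {
  vals <- c(c_hbo = c_hbo, c_hbr = c_hbr, c_methb = c_methb, c_m = c_m)
  if (any(vals < 0)) stop("concentrations must be >= 0")
  c_hbt <- c_hbo + c_hbr + c_methb
  out <- list(c_hbo = c_hbo, c_hbr = c_hbr, c_methb = c_methb, c_m = c_m,
              c_hbt = c_hbt,
              sto2 = if (c_hbt > 0) 100 * c_hbo / c_hbt else NA_real_,
              stmet = if (c_hbt > 0) 100 * c_methb / c_hbt else NA_real_)
  class(out) <- "concentration_set"
  out
}

#' @export
print.concentration_set <- function(x, ...) {
  cat(sprintf(
    "concentration_set: CHbO=%.3g CHbR=%.3g CmetHb=%.3g vol.%% (CHbT=%.3g), Cm=%.3g vol.%%\n",
    x$c_hbo, x$c_hbr, x$c_methb, x$c_hbt, x$c_m))
  invisible(x)
}

#' Build the two-layer skin optical model
#'
#' Epidermis (0.06 mm, melanin absorption) over dermis (4.94 mm, blood
#' absorption); both layers share the reduced scattering spectrum and a
#' refractive index of 1.4.
#'
#' @param conc a [concentration_set()].
#' @param wavelengths wavelengths in nm on the bundled grid.
#' @param d_epi,d_derm layer thicknesses in mm.
#' @param refractive_index tissue refractive index.
#' @return List with `epidermis` and `dermis`, each a list with fields
#'   `mua` (mm^-1 per wavelength), `musp` (mm^-1), `thickness` (mm),
#'   `refractive_index`, plus the shared `wavelengths`.
#' @export
build_skin_model <- function(conc, wavelengths = wavelength_grid(),
                             d_epi = 0.06, d_derm = 4.94,
                             refractive_index = 1.4) {
  if (!inherits(conc, "concentration_set")) {
    conc <- do.call(concentration_set, as.list(conc))
  }
  if (d_epi <= 0 || d_derm <= 0) stop("layer thicknesses must be > 0")
  musp <- as.numeric(reduced_scattering(wavelengths))
  # per-derivative molar concentration: (volume fraction / 100) * 2.32 mM
  mua_derm <-
    chromophore_absorption("HbO", (conc$c_hbo / 100) * .BLOOD_HB_MOLAR,
                           wavelengths) +
    chromophore_absorption("HbR", (conc$c_hbr / 100) * .BLOOD_HB_MOLAR,
                           wavelengths) +
    chromophore_absorption("metHb", (conc$c_methb / 100) * .BLOOD_HB_MOLAR,
                           wavelengths)
  layer <- function(mua, thickness) {
    list(mua = mua, musp = musp, thickness = thickness,
         refractive_index = refractive_index)
  }
  list(epidermis = layer(chromophore_absorption("melanosome", conc$c_m,
                                                wavelengths), d_epi),
       dermis = layer(mua_derm, d_derm),
       wavelengths = wavelengths)
}
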