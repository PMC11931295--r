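#' Simulate scattering path-length tables (white Monte Carlo)
#'
#' Runs one zero-absorption Monte Carlo transport simulation per wavelength
#' and records, for every photon exiting the top surface, its exit weight and
#' accumulated path length in each layer. Any absorption combination can then
#' be evaluated by Beer-Lambert reweighting ([reflectance_from_paths()]),
#' so a single scattering run per wavelength serves the whole training grid.
#'
#' Photons are launched as a collimated pencil beam at normal incidence;
#' scattering is isotropic with `mus = musp` (similarity relation, g = 0);
#' the specular entry reflection at the air/tissue boundary is excluded from
#' the diffuse channel (crossed-polarizer geometry); photons crossing the
#' bottom of the dermis are recorded as transmitted and discarded.
#'
#' @param wavelengths wavelengths in nm.
#' @param musp reduced scattering coefficients in mm^-1, one per wavelength
#'   (defaults to [reduced_scattering()] on `wavelengths`).
#' @param d_epi,d_derm layer thicknesses in mm.
#' @param n_tissue,n_air refractive indices.
#' @param n_photons photons launched per wavelength.
#' @param seed integer seed; wavelength `i` uses `seed + i - 1`.
#' @return Object of class `skin_lut`: a list with one path-length table per
#'   wavelength (fields `weight`, `le`, `ld`, `n_launched`, tallies), plus
#'   the geometry descriptor and seed.
#' @export
simulate_scattering <- function(wavelengths = wavelength_grid(),
                                musp = NULL,
                                d_epi = 0.06, d_derm = 4.94,
                                n_tissue = 1.4, n_air = 1.0,
                                n_photons = 1e5, seed = 1L) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (is.null(musp)) musp <- as.numeric(reduced_scattering(wavelengths))
  stopifnot(length(musp) == length(wavelengths))
  tables <- vector("list", length(wavelengths))
  for (i in seq_along(wavelengths)) {
    tab <- .mc_scatter(musp[i], musp[i], d_epi, d_derm, n_tissue, n_air,
                       as.integer(n_photons), seed + i - 1)
    tab$wavelength <- wavelengths[i]
    tab$musp <- musp[i]
    tab$seed <- seed + i - 1
    tables[[i]] <- tab
  }
  structure(list(tables = tables, wavelengths = wavelengths,
                 geometry = list(d_epi = d_epi, d_derm = d_derm,
                                 n_tissue = n_tissue, n_air = n_air),
                 n_photons = as.integer(n_photons), seed = seed),
            class = "skin_lut")
}

#' @export
print.skin_lut <- function(x, ...) {
  cat(sprintf(
    "skin_lut: %d wavelengths (%g-%g nm), %d photons/wavelength, seed %d\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$n_photons, x$seed))
  cat(sprintf("  geometry: epidermis %g mm / dermis %g mm, n = %g over air\n",
              x$geometry$d_epi, x$geometry$d_derm, x$geometry$n_tissue))
  det <- mean(vapply(x$tables, function(t) length(t$weight), 1)) / x$n_photons
  cat(sprintf("  mean detected fraction: %.3f\n", det))
  invisible(x)
}

#' Reflectance from a path-length table
#'
#' Beer-Lambert reweighting of a white-MC path-length table: the diffuse
#' reflectance at the table's wavelength for absorption coefficients
#' `mua_epi` and `mua_derm` is the mean over launched photons of
#' `weight * exp(-mua_epi*le - mua_derm*ld)`.
#'
#' @param table one per-wavelength element of a [simulate_scattering()] LUT
#'   (or the `skin_lut` itself with `wavelength` given).
#' @param mua_epi,mua_derm absorption coefficients in mm^-1, non-negative.
#' @param se if `TRUE`, return a list with the Monte Carlo standard error.
#' @return Diffuse reflectance (dimensionless, in \[0, 1\]) or a list
#'   `(theta, se)` when `se = TRUE`.
#' @export
reflectance_from_paths <- function(table, mua_epi, mua_derm, se = FALSE) {
  if (mua_epi < 0 || mua_derm < 0) stop("mua must be >= 0")
  out <- .mc_reweight(table$weight, table$le, table$ld,
                      table$n_launched, mua_epi, mua_derm)
  if (se) list(theta = unname(out[1, 1]), se = unname(out[1, 2]))
  else unname(out[1, 1])
}

#' Direct-absorption Monte Carlo reflectance
#'
#' Independent estimator used to validate the path-reweighting scheme:
#' transports photons with absorption applied continuously along each
#' substep (weight times `exp(-mua * s)`), with Russian-roulette termination
#' of low-weight photons.
#'
#' @param model two-layer model from [build_skin_model()].
#' @param wavelength a single wavelength present in the model grid.
#' @param n_photons photons to launch.
#' @param seed integer seed.
#' @return List with `theta` (reflectance) and `se` (MC standard error).
#' @export
simulate_reflectance_direct <- function(model, wavelength,
                                        n_photons = 1e5, seed = 1L) {
  i <- match(wavelength, model$wavelengths)
  if (is.na(i)) stop("wavelength not in the model grid")
  .mc_direct(model$epidermis$musp[i], model$dermis$musp[i],
             model$epidermis$mua[i], model$dermis$mua[i],
             model$epidermis$thickness, model$dermis$thickness,
             model$epidermis$refractive_index, 1.0,
             as.integer(n_photons), seed)
}

#' Reflectance spectrum for a concentration set
#'
#' Applies [build_skin_model()] and evaluates the stored path-length tables
#' at every wavelength of the LUT.
#'
#' @param lut a `skin_lut` from [simulate_scattering()].
#' @param conc a [concentration_set()].
#' @return Numeric vector: diffuse reflectance per wavelength.
#' @export
spectrum_for_concentrations <- function(lut, conc) {
  model <- build_skin_model(conc, lut$wavelengths,
                            d_epi = lut$geometry$d_epi,
                            d_derm = lut$geometry$d_derm,
                            refractive_index = lut$geometry$n_tissue)
  vapply(seq_along(lut$wavelengths), function(i) {
    reflectance_from_paths(lut$tables[[i]],
                           model$epidermis$mua[i], model$dermis$mua[i])
  }, numeric(1))
}

# Batched reweighting: reflectance matrix (combos x wavelengths) for
# matrices of per-combo absorption spectra. Used by the training-set builder.
.reflectance_batch <- function(lut, mua_epi, mua_derm) {
  n_wl <- length(lut$wavelengths)
  stopifnot(ncol(mua_epi) == n_wl, ncol(mua_derm) == n_wl,
            nrow(mua_epi) == nrow(mua_derm))
  theta <- matrix(NA_real_, nrow(mua_epi), n_wl)
  for (i in seq_len(n_wl)) {
    tab <- lut$tables[[i]]
    theta[, i] <- .mc_reweight(tab$weight, tab$le, tab$ld, tab$n_launched,
                               mua_epi[, i], mua_derm[, i])[, 1]
  }
  theta
}

#' Persist / load a scattering LUT
#'
#' Writes the per-wavelength path-length tables as an RDS file with a JSON
#' sidecar describing seed, photon count and geometry.
#'
#' @param lut a `skin_lut`.
#' @param path output path (`.rds`); the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_lut <- function(lut, path) {
  saveRDS(lut, path)
  meta <- list(n_photons = lut$n_photons, seed = lut$seed,
               wavelengths = lut$wavelengths, geometry = lut$geometry,
               package_version = as.character(utils::packageVersion("burnchrom")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  lut <- readRDS(path)
  if (!inherits(lut, "skin_lut")) stop("not a skin_lut file")
  lut
}
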