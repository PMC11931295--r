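#' Default in-silico test grid
#'
#' 63 concentration combinations held out from the training grid: total
#' hemoglobin CHbT in \{0.3, 0.5, 0.7\} vol.% (interleaving the 0.2-1.0
#' training steps), melanin Cm in \{1.5, 3.5, 5.5\} vol.% (interleaving the
#' 1-10 training values), and 7 saturation pairs drawn from StMet in
#' \{1, 20, 50, 80\}% with StO2 given by the fraction parameterization of
#' [saturation_pairs()] at oxygen fractions 50-90%, spanning StO2 from 10%
#' (f = 50, StMet = 80) to 89.1% (f = 90, StMet = 1).
#'
#' @param chbt,cm,pairs overrides for the axis values or the saturation-pair
#'   data.frame (columns `sto2`, `stmet`).
#' @return data.frame like [training_grid()]'s with 63 rows; the pairs are
#'   recorded in the `"pairs"` attribute.
#' @export
insilico_grid <- function(chbt = c(0.3, 0.5, 0.7), cm = c(1.5, 3.5, 5.5),
                          pairs = NULL) {
  if (is.null(pairs)) {
    g <- data.frame(f = c(90, 70, 50, 90, 50, 70, 50),
                    stmet = c(1, 1, 1, 20, 20, 50, 80))
    pairs <- data.frame(sto2 = g$f * (100 - g$stmet) / 100, stmet = g$stmet)
  }
  stopifnot(all(pairs$sto2 + pairs$stmet <= 100))
  training_grid(cm = cm, chbt = chbt, pairs = pairs)
}

#' Run the in-silico validation experiment
#'
#' Forward-simulates the test-grid reflectance spectra through the white-MC
#' path tables, integrates them to XYZ (no camera step, no noise), inverts
#' with the fitted quadratic regression, and compares estimates against
#' ground truth for each parameter (CHbO, CHbR, CmetHb, Cm, CHbT, StO2,
#' StMet): Pearson correlation, absolute RMSE (native units: vol.% for
#' concentrations, percentage points for saturations) and relative RMSE
#' (% of the ground-truth value).
#'
#' @param lut a `skin_lut` whose grid covers the spectra.
#' @param n2 an `n2_fit`; its training grid should exclude the test points.
#' @param grid test grid, default [insilico_grid()] (63 rows).
#' @param illuminant must match the illuminant used to train `n2` (enforced
#'   when both are named).
#' @param estimator optional replacement for the regression inverse, called
#'   as `estimator(xyz, grid)` and returning the four concentration columns;
#'   a harness hook for oracle checks, not used in normal operation.
#' @return Object of class `insilico_report`: per-parameter statistics, the
#'   estimate/truth table, `n_samples` and grid provenance.
#' @export
run_insilico <- function(lut, n2, grid = insilico_grid(),
                         illuminant = "D65", estimator = NULL) {
  if (!inherits(n2, "n2_fit")) stop("n2 must be an n2_fit")
  if (is.character(illuminant) && !is.null(n2$illuminant) &&
      n2$illuminant != "custom" && !identical(illuminant, n2$illuminant)) {
    stop("illuminant mismatch: n2 was trained under ", n2$illuminant)
  }
  xyz <- .grid_to_xyz(grid, lut, illuminant)
  est <- if (is.null(estimator)) predict(n2, xyz) else estimator(xyz, grid)
  truth <- cbind(c_hbo = grid$c_hbo, c_hbr = grid$c_hbr,
                 c_methb = grid$c_methb, c_m = grid$c_m)
  derived <- function(m) {
    c_hbt <- m[, "c_hbo"] + m[, "c_hbr"] + m[, "c_methb"]
    cbind(m, c_hbt = c_hbt,
          sto2 = 100 * m[, "c_hbo"] / c_hbt,
          stmet = 100 * m[, "c_methb"] / c_hbt)
  }
  est_all <- derived(est)
  truth_all <- derived(truth)
  stats <- lapply(colnames(truth_all), function(p) {
    e <- est_all[, p]; g <- truth_all[, p]
    ok <- is.finite(e) & is.finite(g)
    err <- e[ok] - g[ok]
    r <- if (sd(e[ok]) == 0 || sd(g[ok]) == 0) {
      if (all(err == 0)) 1 else NA_real_  # degenerate: constant parameter
    } else {
      cor(e[ok], g[ok])
    }
    list(pearson_r = r,
         rmse_absolute = sqrt(mean(err^2)),
         rmse_relative = sqrt(mean((err / g[ok])^2)) * 100)
  })
  names(stats) <- colnames(truth_all)
  structure(list(stats = stats, estimates = est_all, truth = truth_all,
                 n_samples = nrow(grid),
                 pairs = attr(grid, "pairs"),
                 illuminant = if (is.character(illuminant)) illuminant else "custom",
                 lut_seed = lut$seed, lut_photons = lut$n_photons),
            class = "insilico_report")
}

#' @export
print.insilico_report <- function(x, ...) {
  cat(sprintf("insilico_report: %d samples (LUT: %d photons, seed %d)\n",
              x$n_samples, x$lut_photons, x$lut_seed))
  cat(sprintf("  %-8s %10s %14s %14s\n", "param", "pearson_r",
              "rmse_abs", "rmse_rel_%"))
  for (p in names(x$stats)) {
    s <- x$stats[[p]]
    cat(sprintf("  %-8s %10.4f %14.4g %14.4g\n", p, s$pearson_r,
                s$rmse_absolute, s$rmse_relative))
  }
  invisible(x)
}

#' Serialize an in-silico report as JSON
#'
#' @param report an `insilico_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_insilico_report <- function(report, path) {
  obj <- list(n_samples = report$n_samples,
              stats = report$stats,
              pairs = report$pairs,
              illuminant = report$illuminant,
              lut_seed = report$lut_seed,
              lut_photons = report$lut_photons)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Synthetic phantom image with ground truth
#'
#' Builds an XYZ (optionally RGB) image from a scene of labelled regions,
#' each carrying one concentration set: per-region forward reflectance
#' through the LUT, tristimulus integration, optional inverse camera map and
#' optional additive Gaussian pixel noise. The ground-truth parameter maps
#' are returned alongside.
#'
#' @param scene list of regions, each a list with `mask` (logical matrix,
#'   all masks the same shape, tiling the image without overlap) and `conc`
#'   (a [concentration_set()]).
#' @param lut a `skin_lut`.
#' @param illuminant illuminant for the tristimulus integration.
#' @param n1 optional `n1_cal` (or 3x3 matrix); when given the returned
#'   image is RGB via the inverse map.
#' @param noise_sd additive Gaussian noise SD on the image planes (0 =
#'   noise-free).
#' @param seed integer seed for the noise draws.
#' @return List with `image` (rows x cols x 3), `space` (`"XYZ"` or
#'   `"RGB"`), `truth` (a `hemo_maps` of the construction values) and
#'   `region` (integer region-index matrix).
#' @export
make_phantom <- function(scene, lut, illuminant = "D65", n1 = NULL,
                         noise_sd = 0, seed = 1L) {
  if (!length(scene)) stop("scene has no regions")
  shape <- dim(scene[[1]]$mask)
  cover <- matrix(0L, shape[1], shape[2])
  for (rg in scene) {
    if (!identical(dim(rg$mask), shape)) stop("region masks differ in shape")
    cover <- cover + rg$mask
  }
  if (any(cover > 1)) stop("scene regions overlap")
  if (any(cover < 1)) stop("scene regions do not tile the image")
  img <- array(NA_real_, c(shape, 3))
  region <- matrix(NA_integer_, shape[1], shape[2])
  truth_planes <- lapply(c("c_hbo", "c_hbr", "c_methb", "c_m", "c_hbt",
                           "sto2", "stmet"),
                         function(p) matrix(NA_real_, shape[1], shape[2]))
  names(truth_planes) <- c("c_hbo", "c_hbr", "c_methb", "c_m", "c_hbt",
                           "sto2", "stmet")
  for (i in seq_along(scene)) {
    conc <- scene[[i]]$conc
    if (!inherits(conc, "concentration_set")) {
      conc <- do.call(concentration_set, as.list(conc))
    }
    theta <- spectrum_for_concentrations(lut, conc)
    xyz <- reflectance_to_xyz(theta, illuminant, lut$wavelengths)
    idx <- which(scene[[i]]$mask)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- xyz[ch]
      img[, , ch] <- plane
    }
    region[idx] <- i
    for (p in names(truth_planes)) {
      v <- conc[[p]]
      truth_planes[[p]][idx] <- if (is.null(v)) NA_real_ else v
    }
  }
  space <- "XYZ"
  if (!is.null(n1)) {
    m <- if (inherits(n1, "n1_cal")) n1$matrix else as.matrix(n1)
    img <- rgb_image_to_xyz(img, solve(m))   # inverse map: XYZ -> RGB
    space <- "RGB"
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + array(rnorm(length(img), sd = noise_sd), dim(img))
  }
  truth_planes$valid <- truth_planes$c_hbt > 0
  class(truth_planes) <- "hemo_maps"
  list(image = img, space = space, truth = truth_planes, region = region)
}

#' Default effect template for the synthetic rat study
#'
#' Per-group, per-timepoint means and SDs of (CHbT vol.%, StO2 %, StMet %),
#' following the qualitative post-burn trends of the scald model: controls
#' flat; superficial (70 degree) burns with a methemoglobin peak at 24 h and
#' recovering oxygenation; deep (78 degree) burns with depressed StO2 at all
#' timepoints, declining CHbT and strongly elevated StMet. The numbers are
#' synthetic fixtures, not measured values.
#'
#' @return data.frame with columns `group`, `t` (s), `chbt_mean`, `chbt_sd`,
#'   `sto2_mean`, `sto2_sd`, `stmet_mean`, `stmet_sd`.
#' @export
study_template <- function() {
  tp <- c(86400, 172800, 259200)   # 24, 48, 72 h in seconds
  rbind(
    data.frame(group = "control", t = tp,
               chbt_mean = c(0.60, 0.60, 0.60), chbt_sd = 0.05,
               sto2_mean = c(45, 45, 45), sto2_sd = 5,
               stmet_mean = c(5, 5, 5), stmet_sd = 2),
    data.frame(group = "burn70", t = tp,
               chbt_mean = c(0.55, 0.50, 0.48), chbt_sd = 0.05,
               sto2_mean = c(35, 55, 65), sto2_sd = 5,
               stmet_mean = c(30, 15, 8), stmet_sd = 5),
    data.frame(group = "burn78", t = tp,
               chbt_mean = c(0.50, 0.40, 0.32), chbt_sd = 0.05,
               sto2_mean = c(25, 22, 20), sto2_sd = 5,
               stmet_mean = c(60, 45, 35), stmet_sd = 8))
}

#' Generate a synthetic study feature table
#'
#' Draws per-subject ROI-mean features from Gaussian distributions with the
#' template's group-by-timepoint means and SDs, reproducing the structure of
#' a 3-group x 5-subject x 3-timepoint imaging study.
#'
#' @param template effect template as returned by [study_template()].
#' @param subjects_per_group subjects in each group (default 5).
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `group`, `t` (s), `chbt`,
#'   `sto2`, `stmet`; one row per subject-timepoint.
#' @export
make_study <- function(template = study_template(), subjects_per_group = 5,
                       seed = 1L) {
  if (subjects_per_group < 1) stop("subjects_per_group must be >= 1")
  if (any(c(template$chbt_sd, template$sto2_sd, template$stmet_sd) < 0)) {
    stop("template SDs must be >= 0")
  }
  set.seed(seed)
  groups <- unique(template$group)
  rows <- list()
  for (g in groups) {
    tg <- template[template$group == g, ]
    for (s in seq_len(subjects_per_group)) {
      subject <- paste0(g, "_", s)
      for (r in seq_len(nrow(tg))) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = subject, group = g, t = tg$t[r],
          chbt = max(rnorm(1, tg$chbt_mean[r], tg$chbt_sd[r]), 0),
          sto2 = min(max(rnorm(1, tg$sto2_mean[r], tg$sto2_sd[r]), 0), 100),
          stmet = min(max(rnorm(1, tg$stmet_mean[r], tg$stmet_sd[r]), 0), 100))
      }
    }
  }
  do.call(rbind, rows)
}

#' Study table to CDA design
#'
#' Expands a study feature table into the predictor matrix and label vector
#' for [fit_cda()] / [loocv()].
#'
#' @param study data.frame from [make_study()].
#' @param cross include pairwise cross-products in the expansion.
#' @return List with `features` (n x 14 or n x 8), `labels`, `unit`
#'   (subject ids, for leave-one-subject-out).
#' @export
study_design <- function(study, cross = TRUE) {
  feats <- expand_features(study$t, study$chbt, study$sto2, study$stmet,
                           cross = cross)
  list(features = feats, labels = study$group, unit = study$subject)
}
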