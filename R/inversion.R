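#' Saturation-pair grid
#'
#' Unique (StO2, StMet) pairs from the fraction parameterization
#' `sto2 = f * (100 - stmet) / 100`: every methemoglobin saturation is
#' crossed with every oxygen fraction `f` of the remaining (non-met)
#' hemoglobin, and duplicate pairs (the StMet = 100 column) are collapsed.
#' The default 6 x 6 grid yields the 31 unique pairs of the training set.
#'
#' @param stmet methemoglobin saturations, %.
#' @param f oxygen fractions of non-met hemoglobin, %.
#' @return data.frame with columns `sto2`, `stmet` (and the generating `f`).
#' @export
saturation_pairs <- function(stmet = seq(0, 100, 20), f = seq(0, 100, 20)) {
  g <- expand.grid(f = f, stmet = stmet)
  g$sto2 <- g$f * (100 - g$stmet) / 100
  g <- g[!duplicated(g[, c("sto2", "stmet")]), c("sto2", "stmet", "f")]
  rownames(g) <- NULL
  g
}

#' Quadratic feature vector of a tristimulus triple
#'
#' The ten monomials `(1, X, Y, Z, X^2, Y^2, Z^2, XY, XZ, YZ)` in that fixed
#' order; the column convention shared by the regression matrix.
#'
#' @param xyz numeric vector `c(x, y, z)` or matrix `(n, 3)`.
#' @return Numeric 10-vector, or matrix `(n, 10)`.
#' @export
#' @examples
#' quadratic_features(c(2, 0, 0))
quadratic_features <- function(xyz) {
  one <- is.null(dim(xyz))
  if (one) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  f <- cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z)
  colnames(f) <- c("1", "X", "Y", "Z", "X2", "Y2", "Z2", "XY", "XZ", "YZ")
  if (one) f[1, ] else f
}

#' Default training grid of concentration combinations
#'
#' 1550 combinations: melanin Cm = 1 to 10 vol.% at 1% steps (10 values),
#' total hemoglobin CHbT = 0.2 to 1.0 vol.% at 0.2% steps (5 values), and 31
#' saturation pairs. The pairs parameterize StO2 as an oxygen fraction of
#' the non-met hemoglobin: StMet in \{0, 20, ..., 100\}% crossed with
#' f in \{0, 20, ..., 100\}% gives `sto2 = f * (100 - stmet) / 100`; the
#' StMet = 100 column collapses to a single pair (StO2 forced to 0),
#' leaving 31 unique pairs. This parameterization keeps StO2 + StMet <= 100
#' by construction and spans both full 0-100% ranges.
#'
#' @param cm,chbt,pairs override the melanin values, total-hemoglobin values
#'   or the saturation-pair data.frame (columns `sto2`, `stmet`).
#' @return data.frame with columns `c_m`, `c_hbt`, `sto2`, `stmet` and the
#'   implied `c_hbo`, `c_hbr`, `c_methb`; attribute `"pairs"` records the
#'   saturation pairs used.
#' @export
training_grid <- function(cm = 1:10, chbt = seq(0.2, 1.0, 0.2),
                          pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- saturation_pairs()
  }
  g <- expand.grid(pair = seq_len(nrow(pairs)), c_hbt = chbt, c_m = cm)
  out <- data.frame(c_m = g$c_m, c_hbt = g$c_hbt,
                    sto2 = pairs$sto2[g$pair], stmet = pairs$stmet[g$pair])
  out$c_hbo <- out$c_hbt * out$sto2 / 100
  out$c_methb <- out$c_hbt * out$stmet / 100
  out$c_hbr <- out$c_hbt - out$c_hbo - out$c_methb
  attr(out, "pairs") <- pairs
  out
}

# Forward-simulate XYZ for a grid of concentration rows against a LUT.
.grid_to_xyz <- function(grid, lut, illuminant = "D65") {
  wl <- lut$wavelengths
  mel <- .extinction_at("melanosome", wl) / 10           # Cm = 100% in mm^-1
  e_hbo <- log(10) * .extinction_at("HbO", wl) / 10      # per mol/L, mm^-1
  e_hbr <- log(10) * .extinction_at("HbR", wl) / 10
  e_met <- log(10) * .extinction_at("metHb", wl) / 10
  mua_epi <- outer(grid$c_m / 100, mel)
  c_scale <- .BLOOD_HB_MOLAR / 100
  mua_derm <- outer(grid$c_hbo * c_scale, e_hbo) +
    outer(grid$c_hbr * c_scale, e_hbr) +
    outer(grid$c_methb * c_scale, e_met)
  theta <- .reflectance_batch(lut, mua_epi, mua_derm)
  reflectance_to_xyz(theta, illuminant, wl)
}

#' Build the regression training set
#'
#' Forward-simulates the diffuse reflectance spectrum of every concentration
#' combination in the grid through the white-MC path tables and integrates
#' each to CIEXYZ.
#'
#' @param lut a `skin_lut` from [simulate_scattering()] covering the grid.
#' @param grid concentration grid from [training_grid()] (default 1550 rows).
#' @param illuminant illuminant for the tristimulus integration.
#' @param expected_size if non-`NULL`, error unless the grid has exactly this
#'   many rows.
#' @return data.frame: the grid columns plus `x`, `y`, `z`; attributes record
#'   the illuminant and saturation pairs.
#' @export
build_training_set <- function(lut, grid = training_grid(),
                               illuminant = "D65", expected_size = NULL) {
  if (!is.null(expected_size) && nrow(grid) != expected_size) {
    stop("training grid has ", nrow(grid), " rows, expected ", expected_size)
  }
  xyz <- .grid_to_xyz(grid, lut, illuminant)
  out <- cbind(grid, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "illuminant") <- if (is.character(illuminant)) illuminant else "custom"
  attr(out, "pairs") <- attr(grid, "pairs")
  out
}

#' Fit the quadratic regression inverse
#'
#' Four independent ordinary-least-squares fits of the chromophore
#' concentrations (CHbO, CHbR, CmetHb, Cm) on the ten quadratic features of
#' the tristimulus values. The coefficients are packed as a 4 x 10 matrix
#' acting on the feature column vector
#' `(1, X, Y, Z, X^2, Y^2, Z^2, XY, XZ, YZ)`.
#'
#' @param training training set from [build_training_set()], or any
#'   data.frame with columns `x, y, z, c_hbo, c_hbr, c_methb, c_m`.
#' @return Object of class `n2_fit` with fields `coefficients` (4 x 10),
#'   `r_squared` (per target), `illuminant`, `pairs` and `n`.
#' @export
fit_n2 <- function(training) {
  need <- c("x", "y", "z", "c_hbo", "c_hbr", "c_methb", "c_m")
  if (!all(need %in% names(training))) {
    stop("training set must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(training) < 10) stop("need at least 10 training rows")
  feats <- quadratic_features(as.matrix(training[, c("x", "y", "z")]))
  qrf <- qr(feats)
  if (qrf$rank < 10) {
    bad <- colnames(feats)[-qrf$pivot[seq_len(qrf$rank)]]
    stop("rank-deficient quadratic features; offending columns: ",
         paste(bad, collapse = ", "))
  }
  targets <- as.matrix(training[, c("c_hbo", "c_hbr", "c_methb", "c_m")])
  coefs <- qr.coef(qrf, targets)                     # 10 x 4
  fitted <- feats %*% coefs
  ss_res <- colSums((targets - fitted)^2)
  ss_tot <- colSums(sweep(targets, 2, colMeans(targets))^2)
  n2 <- t(coefs)
  rownames(n2) <- c("c_hbo", "c_hbr", "c_methb", "c_m")
  colnames(n2) <- colnames(feats)
  structure(list(coefficients = n2,
                 r_squared = setNames(1 - ss_res / ss_tot, rownames(n2)),
                 illuminant = attr(training, "illuminant"),
                 pairs = attr(training, "pairs"),
                 n = nrow(training)),
            class = "n2_fit")
}

#' @export
print.n2_fit <- function(x, ...) {
  cat(sprintf("n2_fit: 4x10 quadratic XYZ->concentration map (%d training rows",
              x$n))
  if (!is.null(x$illuminant)) cat(", illuminant ", x$illuminant, sep = "")
  cat(")\n  training R^2: ",
      paste(sprintf("%s=%.4f", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.n2_fit <- function(object, ...) object$coefficients

#' Predict chromophore concentrations from tristimulus values
#'
#' @param object an `n2_fit`.
#' @param xyz matrix `(n, 3)` or vector `c(x, y, z)`.
#' @param ... unused.
#' @return Matrix `(n, 4)` with columns `c_hbo, c_hbr, c_methb, c_m`.
#' @export
predict.n2_fit <- function(object, xyz, ...) {
  feats <- quadratic_features(xyz)
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = 1)
  out <- feats %*% t(object$coefficients)
  colnames(out) <- rownames(object$coefficients)
  out
}

#' Serialize / load an `n2_fit` as JSON
#'
#' The JSON carries the coefficient matrix with its fixed column order, the
#' illuminant id, the saturation-pair grid provenance and the per-target
#' training R^2.
#'
#' @param fit an `n2_fit`.
#' @param path output path.
#' @return `path` invisibly; `read_n2()` returns the restored `n2_fit`.
#' @export
write_n2 <- function(fit, path) {
  obj <- list(feature_order = colnames(fit$coefficients),
              target_order = rownames(fit$coefficients),
              coefficients = unname(fit$coefficients),
              r_squared = as.list(fit$r_squared),
              illuminant = fit$illuminant,
              pairs = fit$pairs, n = fit$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_n2
#' @export
read_n2 <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- matrix(as.numeric(obj$coefficients), nrow = 4)
  rownames(coefs) <- obj$target_order
  colnames(coefs) <- obj$feature_order
  structure(list(coefficients = coefs,
                 r_squared = unlist(obj$r_squared),
                 illuminant = obj$illuminant,
                 pairs = obj$pairs, n = obj$n),
            class = "n2_fit")
}

#' Estimate chromophore maps from an XYZ image
#'
#' Applies the quadratic regression inverse pixel-wise and derives the
#' hemoglobin parameters: `c_hbt = c_hbo + c_hbr + c_methb`,
#' `sto2 = 100 * c_hbo / c_hbt` and `stmet = 100 * c_methb / c_hbt`.
#' Negative concentration estimates are reported as-is, but pixels with
#' `c_hbt <= 0` are masked invalid and their saturations set `NA`.
#'
#' @param xyz_image array `(rows, cols, 3)` of calibrated XYZ planes.
#' @param n2 an `n2_fit`.
#' @return Object of class `hemo_maps`: matrices `c_hbo, c_hbr, c_methb,
#'   c_m, c_hbt, sto2, stmet` and the logical `valid` mask.
#' @export
estimate_concentrations <- function(xyz_image, n2) {
  dims <- dim(xyz_image)
  if (is.null(dims) || length(dims) != 3 || dims[3] != 3) {
    stop("xyz_image must be an array (rows, cols, 3)")
  }
  if (!inherits(n2, "n2_fit")) stop("n2 must be an n2_fit")
  est <- predict(n2, matrix(xyz_image, ncol = 3))
  shape <- dims[1:2]
  m <- function(v) matrix(v, shape[1], shape[2])
  c_hbt <- est[, "c_hbo"] + est[, "c_hbr"] + est[, "c_methb"]
  valid <- is.finite(c_hbt) & c_hbt > 0
  sto2 <- ifelse(valid, 100 * est[, "c_hbo"] / c_hbt, NA_real_)
  stmet <- ifelse(valid, 100 * est[, "c_methb"] / c_hbt, NA_real_)
  structure(list(c_hbo = m(est[, "c_hbo"]), c_hbr = m(est[, "c_hbr"]),
                 c_methb = m(est[, "c_methb"]), c_m = m(est[, "c_m"]),
                 c_hbt = m(c_hbt), sto2 = m(sto2), stmet = m(stmet),
                 valid = m(valid)),
            class = "hemo_maps")
}

#' @export
print.hemo_maps <- function(x, ...) {
  cat(sprintf("hemo_maps: %d x %d pixels, %.1f%% valid\n",
              nrow(x$c_hbt), ncol(x$c_hbt), 100 * mean(x$valid)))
  for (p in c("c_hbt", "sto2", "stmet", "c_m")) {
    v <- x[[p]][x$valid]
    if (length(v)) {
      cat(sprintf("  %-7s mean %.3g, sd %.3g\n", p, mean(v), sd(v)))
    }
  }
  invisible(x)
}

#' Region-of-interest summary of a map
#'
#' Mean and standard deviation over the valid pixels of a rectangular ROI.
#'
#' @param map numeric matrix (one plane of a `hemo_maps`).
#' @param roi integer vector `c(row, col, nrow, ncol)`: top-left corner and
#'   extent. Defaults to a 300 x 300 region at the image center (clipped to
#'   the map if smaller).
#' @return Named vector `c(mean, sd)` over non-`NA` ROI pixels.
#' @export
roi_summary <- function(map, roi = NULL) {
  if (is.null(roi)) {
    h <- min(300, nrow(map)); w <- min(300, ncol(map))
    roi <- c(floor((nrow(map) - h) / 2) + 1, floor((ncol(map) - w) / 2) + 1,
             h, w)
  }
  rows <- roi[1]:(roi[1] + roi[3] - 1)
  cols <- roi[2]:(roi[2] + roi[4] - 1)
  if (min(rows) < 1 || max(rows) > nrow(map) ||
      min(cols) < 1 || max(cols) > ncol(map)) {
    stop("ROI extends outside the map")
  }
  vals <- map[rows, cols]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("ROI contains no valid pixels")
  c(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0)
}
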