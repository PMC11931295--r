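#' Second-order feature expansion
#'
#' Expands the base predictors (time after injury in seconds, total
#' hemoglobin, tissue oxygen saturation, methemoglobin saturation) with
#' their second-order terms. The full expansion is 14 values in fixed order:
#' the 4 linear terms, their 4 squares, then the 6 pairwise products
#' `(t*chbt, t*sto2, t*stmet, chbt*sto2, chbt*stmet, sto2*stmet)`. With
#' `cross = FALSE` only squares are added (8 values).
#'
#' @param t time after injury, s.
#' @param c_hbt total hemoglobin, vol.%.
#' @param sto2 tissue oxygen saturation, %.
#' @param stmet methemoglobin saturation, %.
#' @param cross include pairwise cross-products (default `TRUE`).
#' @return Named numeric vector (or matrix for vector inputs).
#' @export
#' @examples
#' expand_features(2, 0, 0, 0)
expand_features <- function(t, c_hbt, sto2, stmet, cross = TRUE) {
  base <- cbind(t = t, c_hbt = c_hbt, sto2 = sto2, stmet = stmet)
  sq <- base^2
  colnames(sq) <- paste0(colnames(base), "^2")
  out <- cbind(base, sq)
  if (cross) {
    nm <- colnames(base)
    cp <- NULL
    for (i in 1:3) for (j in (i + 1):4) {
      cp <- cbind(cp, base[, i] * base[, j])
      colnames(cp)[ncol(cp)] <- paste0(nm[i], "*", nm[j])
    }
    out <- cbind(out, cp)
  }
  if (nrow(out) == 1) out[1, ] else out
}

# Internal: canonical discriminant axes by whitening the pooled within-class
# scatter and eigendecomposing the between-class scatter in the whitened
# space. Returns coefficients scaled to unit pooled within-class variance.
.cda_core <- function(x, labels, tol = 1e-10) {
  classes <- sort(unique(labels))
  g <- length(classes)
  n <- nrow(x)
  grand <- colMeans(x)
  p <- ncol(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    xc <- sweep(xi, 2, mu)
    W <- W + crossprod(xc)
    B <- B + nrow(xi) * tcrossprod(mu - grand)
  }
  Wn <- W / (n - g)                      # pooled within-class covariance
  ew <- eigen(Wn, symmetric = TRUE)
  keep <- ew$values > tol * max(ew$values, tol)
  singular <- !all(keep)
  # pseudo-inverse square root of Wn restricted to its range
  Uh <- ew$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ew$values[keep]), sum(keep))
  M <- crossprod(Uh, B %*% Uh) / (n - g)
  eb <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(g - 1, sum(keep))
  eigvals <- pmax(eb$values[seq_len(n_axes)], 0)
  coefs <- Uh %*% eb$vectors[, seq_len(n_axes), drop = FALSE]
  # coefs already give unit pooled within-class variance: a' Wn a = 1
  list(coefficients = coefs, eigenvalues = eigvals, classes = classes,
       grand_mean = grand, singular = singular,
       wilks_lambda = prod(1 / (1 + eigvals)))
}

#' Fit a canonical discriminant model
#'
#' Canonical discriminant analysis of feature vectors against class labels:
#' features are standardized internally, the canonical axes are the leading
#' eigenvectors of the within-class-inverse times between-class scatter
#' (computed by whitening; a pseudo-inverse is used and flagged when the
#' within-class scatter is singular), and the canonical variates are scaled
#' to unit pooled within-class variance. Wilks' lambda is
#' `prod(1 / (1 + eigenvalue))` over the retained axes; 1 means no
#' separation.
#'
#' @param features numeric matrix (samples x features), e.g. rows of
#'   [expand_features()].
#' @param labels class labels (factor or character), at least 2 classes with
#'   at least 2 samples each.
#' @param n_axes number of canonical axes to retain (default
#'   `min(classes - 1, features)`).
#' @return Object of class `cda_fit`: standardization parameters, canonical
#'   coefficients (on standardized features), per-class centroids in
#'   canonical space, eigenvalues, `wilks_lambda` and the
#'   `singularity_warning` flag.
#' @export
fit_cda <- function(features, labels, n_axes = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes")
  if (any(counts < 2)) stop("every class needs at least 2 samples")
  center <- colMeans(features)
  scale_ <- apply(features, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(features, 2, center), 2, scale_, "/")
  core <- .cda_core(xs, labels)
  k <- min(if (is.null(n_axes)) Inf else n_axes, ncol(core$coefficients))
  coefs <- core$coefficients[, seq_len(k), drop = FALSE]
  colnames(coefs) <- paste0("z", seq_len(k))
  rownames(coefs) <- colnames(features)
  scores <- xs %*% coefs
  centroids <- do.call(rbind, lapply(core$classes, function(cl) {
    colMeans(scores[labels == cl, , drop = FALSE])
  }))
  rownames(centroids) <- core$classes
  structure(list(coefficients = coefs,
                 centroids = centroids,
                 classes = core$classes,
                 eigenvalues = core$eigenvalues,
                 wilks_lambda = core$wilks_lambda,
                 center = center, scale = scale_,
                 feature_names = colnames(features),
                 n = nrow(features), counts = c(counts),
                 singularity_warning = core$singular ||
                   ncol(features) > nrow(features)),
            class = "cda_fit")
}

#' @export
print.cda_fit <- function(x, ...) {
  cat(sprintf("cda_fit: %d classes (%s), %d samples, %d features, %d axes\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$n, length(x$feature_names), ncol(x$coefficients)))
  cat(sprintf("  Wilks' lambda = %.4g; eigenvalues: %s\n", x$wilks_lambda,
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  if (x$singularity_warning) {
    cat("  note: within-class scatter singular or p > n; pseudo-inverse used\n")
  }
  invisible(x)
}

#' Canonical scores of feature vectors
#'
#' @param model a `cda_fit`.
#' @param features matrix or single feature vector on the model's feature
#'   set.
#' @return Matrix of canonical coordinates (samples x axes).
#' @export
canonical_scores <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$center)) {
    stop("feature dimension does not match the fitted model")
  }
  xs <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  xs %*% model$coefficients
}

#' Classify feature vectors by nearest centroid in canonical space
#'
#' Assigns each sample to the class whose centroid is nearest (Euclidean
#' distance on the canonical plot). Exact ties break to the lowest class
#' index and are flagged.
#'
#' @param model a `cda_fit`.
#' @param features matrix (samples x features) or a single feature vector.
#' @return List with `label` (character), `scores` (canonical coordinates),
#'   `distances` (samples x classes) and logical `tie`.
#' @export
classify <- function(model, features) {
  z <- canonical_scores(model, features)
  d2 <- sapply(seq_along(model$classes), function(j) {
    rowSums(sweep(z, 2, model$centroids[j, ])^2)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  dists <- sqrt(d2)
  colnames(dists) <- model$classes
  best <- apply(dists, 1, which.min)    # ties: first (lowest class index)
  tie <- apply(dists, 1, function(r) sum(r == min(r)) > 1)
  list(label = model$classes[best], scores = z, distances = dists,
       tie = tie)
}

#' @export
predict.cda_fit <- function(object, features, ...) classify(object, features)

#' Leave-one-out cross-validation of the discriminant model
#'
#' Refits the model excluding each sample (or each unit) in turn and
#' classifies the held-out data; reports per-class and overall correct
#' classification rates as percentages.
#'
#' @param features matrix (samples x features).
#' @param labels class labels.
#' @param unit optional grouping vector: all samples of one unit (e.g. one
#'   subject) are held out together and the model refit on the rest.
#' @return List with `rates` (per class, %), `overall` (%), `predicted`,
#'   `scores` (negative distance to each class centroid, for ROC), and the
#'   audit counter `n_refits`.
#' @export
loocv <- function(features, labels, unit = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (is.null(unit)) unit <- seq_len(nrow(features))
  holds <- unique(unit)
  predicted <- character(nrow(features))
  scores <- matrix(NA_real_, nrow(features), length(unique(labels)),
                   dimnames = list(NULL, sort(unique(labels))))
  n_refits <- 0L
  for (h in holds) {
    test <- unit == h
    counts <- table(labels[!test])
    if (length(counts) < 2 || any(counts < 2)) {
      stop("holding out unit ", h, " empties a class")
    }
    fit <- fit_cda(features[!test, , drop = FALSE], labels[!test])
    n_refits <- n_refits + 1L
    res <- classify(fit, features[test, , drop = FALSE])
    predicted[test] <- res$label
    scores[test, colnames(res$distances)] <- -res$distances
  }
  rates <- sapply(sort(unique(labels)), function(cl) {
    100 * mean(predicted[labels == cl] == cl)
  })
  list(rates = rates, overall = 100 * mean(predicted == labels),
       predicted = predicted, scores = scores, n_refits = n_refits)
}

#' One-vs-rest ROC AUC
#'
#' Area under the ROC curve per class: each class in turn is the positive
#' set, scored by (negative) distance to that class centroid. The AUC is
#' computed by the exact midrank identity
#' `AUC = P(score_pos > score_neg) + P(tie)/2`, equivalent to trapezoidal
#' integration of the empirical ROC curve with tied scores midranked.
#'
#' @param scores matrix (samples x classes) of class scores, e.g. the
#'   cross-validated `scores` from [loocv()], or a `cda_fit` (scores are
#'   then negative training distances for `features`).
#' @param labels true class labels.
#' @param features required when `scores` is a `cda_fit`.
#' @return Named numeric vector of per-class AUCs; `NA` for absent classes.
#' @export
roc_auc <- function(scores, labels, features = NULL) {
  if (inherits(scores, "cda_fit")) {
    if (is.null(features)) stop("features required when scoring a cda_fit")
    scores <- -classify(scores, features)$distances
  }
  labels <- as.character(labels)
  sapply(colnames(scores), function(cl) {
    pos <- labels == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, cl])             # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
}

#' Pixel-wise burn-severity map
#'
#' Applies the canonical discriminant model to every valid pixel of the
#' hemoglobin maps at a given time after injury: expand the (t, CHbT, StO2,
#' StMet) features, project onto the canonical plane and assign the nearest
#' group centroid.
#'
#' @param model a `cda_fit` trained on [expand_features()] predictors.
#' @param maps a `hemo_maps` from [estimate_concentrations()].
#' @param t time after injury in seconds (single value per image).
#' @param cross passed to [expand_features()]; must match the training
#'   expansion.
#' @return Object of class `severity_image`: integer `label` matrix indexing
#'   `classes` (`NA` for invalid pixels), the canonical coordinate planes
#'   `z1`, `z2`, and the class labels.
#' @export
severity_map <- function(model, maps, t, cross = TRUE) {
  valid <- maps$valid & is.finite(maps$sto2) & is.finite(maps$stmet)
  if (!any(valid)) stop("no valid pixels to classify")
  idx <- which(valid)
  feats <- expand_features(rep(t, length(idx)), maps$c_hbt[idx],
                           maps$sto2[idx], maps$stmet[idx], cross = cross)
  res <- classify(model, feats)
  shape <- dim(maps$c_hbt)
  lab <- matrix(NA_integer_, shape[1], shape[2])
  lab[idx] <- match(res$label, model$classes)
  z1 <- matrix(NA_real_, shape[1], shape[2]); z2 <- z1
  z1[idx] <- res$scores[, 1]
  if (ncol(res$scores) > 1) z2[idx] <- res$scores[, 2]
  structure(list(label = lab, z1 = z1, z2 = z2, classes = model$classes,
                 t = t),
            class = "severity_image")
}

#' @export
print.severity_image <- function(x, ...) {
  occ <- occupancy_rates(x)
  cat(sprintf("severity_image: %d x %d pixels at t = %g s\n",
              nrow(x$label), ncol(x$label), x$t))
  cat("  occupancy:",
      paste(sprintf("%s %.1f%%", names(occ), 100 * occ), collapse = ", "),
      "\n")
  invisible(x)
}

#' Class occupancy rates of a severity image
#'
#' Fraction of valid pixels assigned to each severity class; fractions sum
#' to 1.
#'
#' @param image a `severity_image`.
#' @return Named numeric vector of per-class fractions.
#' @export
occupancy_rates <- function(image) {
  lab <- image$label[!is.na(image$label)]
  if (!length(lab)) stop("image has no valid pixels")
  counts <- tabulate(lab, nbins = length(image$classes))
  setNames(counts / length(lab), image$classes)
}

#' Canonical discriminant plot
#'
#' Scatter of samples on the canonical plane with group centroids.
#'
#' @param x a `cda_fit`.
#' @param features,labels the data to plot (defaults to nothing but
#'   centroids if omitted).
#' @param ... passed to [graphics::plot()].
#' @export
plot.cda_fit <- function(x, features = NULL, labels = NULL, ...) {
  cen <- x$centroids
  if (!is.null(features)) {
    z <- canonical_scores(x, as.matrix(features))
    cols <- match(as.character(labels), x$classes)
    graphics::plot(z[, 1], z[, 2], col = cols, pch = 16,
                   xlab = "z1", ylab = "z2", ...)
    graphics::points(cen[, 1], cen[, 2], pch = 3, cex = 2,
                     col = seq_len(nrow(cen)))
  } else {
    graphics::plot(cen[, 1], cen[, 2], pch = 3, cex = 2,
                   col = seq_len(nrow(cen)), xlab = "z1", ylab = "z2", ...)
  }
  graphics::legend("topright", legend = x$classes, col = seq_along(x$classes),
                   pch = 16, bty = "n")
  invisible(x)
}
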