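test_that("feature expansion produces the documented second-order terms", {
  expect_equal(as.numeric(expand_features(0, 0, 0, 0)), rep(0, 14))
  expect_equal(as.numeric(expand_features(1, 1, 1, 1)), rep(1, 14))
  f <- expand_features(2, 0, 0, 0)
  expect_equal(f[["t"]], 2)
  expect_equal(f[["t^2"]], 4)
  expect_equal(sum(f != 0), 2)    # only t and t^2
  f2 <- expand_features(2, 3, 0, 0)
  expect_equal(f2[["t*c_hbt"]], 6)
  # squares-only variant has 8 predictors
  expect_length(expand_features(1, 2, 3, 4, cross = FALSE), 8)
  # vector input gives one row per sample
  m <- expand_features(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  expect_equal(dim(m), c(2L, 14L))
})

test_that("Wilks' lambda is 1 when group means coincide", {
  set.seed(4)
  x <- matrix(rnorm(60), 30, 2)
  labels <- rep(c("a", "b", "c"), each = 10)
  # shift all groups to identical means
  for (g in unique(labels)) {
    x[labels == g, ] <- sweep(x[labels == g, ], 2,
                              colMeans(x[labels == g, , drop = FALSE]))
  }
  fit <- fit_cda(x, labels)
  expect_equal(fit$wilks_lambda, 1, tolerance = 1e-10)
})

test_that("well-separated clusters give near-zero lambda and perfect training accuracy", {
  cl <- gaussian_clusters(n_per = 5, sep = 10, sd = 1, seed = 3)
  fit <- fit_cda(cl$x, cl$labels)
  expect_lt(fit$wilks_lambda, 0.05)
  expect_gt(fit$wilks_lambda, 0)
  pred <- classify(fit, cl$x)
  expect_equal(pred$label, cl$labels)
  expect_equal(ncol(fit$coefficients), 2)    # min(3 - 1, p)
})

test_that("canonical variates have unit pooled within-class variance", {
  cl <- gaussian_clusters(n_per = 8, sep = 6, sd = 1.5, seed = 9)
  fit <- fit_cda(cl$x, cl$labels)
  z <- canonical_scores(fit, cl$x)
  n <- nrow(z); g <- length(fit$classes)
  pooled <- sapply(seq_len(ncol(z)), function(j) {
    sum(sapply(fit$classes, function(cli) {
      zi <- z[cl$labels == cli, j]
      sum((zi - mean(zi))^2)
    })) / (n - g)
  })
  expect_equal(pooled, rep(1, ncol(z)), tolerance = 1e-8)
})

test_that("relabeling permutes centroids without changing the separation", {
  cl <- gaussian_clusters(seed = 13)
  fit1 <- fit_cda(cl$x, cl$labels)
  relab <- c(a = "z", b = "y", c = "x")[cl$labels]
  fit2 <- fit_cda(cl$x, relab)
  expect_equal(fit2$wilks_lambda, fit1$wilks_lambda, tolerance = 1e-10)
  expect_equal(sort(rownames(fit2$centroids)), c("x", "y", "z"))
})

test_that("classification agrees with an exhaustive nearest-centroid check", {
  cl <- gaussian_clusters(n_per = 10, sep = 4, sd = 2, seed = 17)
  fit <- fit_cda(cl$x, cl$labels)
  set.seed(18)
  probe <- matrix(rnorm(100 * 4, sd = 4), 100, 4)
  res <- classify(fit, probe)
  z <- canonical_scores(fit, probe)
  for (i in seq_len(100)) {
    d <- apply(fit$centroids, 1, function(cen) sqrt(sum((z[i, ] - cen)^2)))
    expect_equal(res$label[i], names(which.min(d)))
    expect_equal(unname(res$distances[i, ]), unname(d))
  }
})

test_that("exact distance ties break to the lowest class index and are flagged", {
  # two symmetric clusters: the midpoint is equidistant
  x <- rbind(matrix(c(-5, -5, -5, 0, 0.5, -0.5), 3, 2),
             matrix(c(5, 5, 5, 0, 0.5, -0.5), 3, 2))
  labels <- rep(c("a", "b"), each = 3)
  fit <- fit_cda(x, labels)
  mid <- matrix(colMeans(x), 1)
  res <- classify(fit, mid)
  expect_true(res$tie[1])
  expect_equal(res$label[1], "a")
})

test_that("classification is invariant to affine rescaling of the features", {
  cl <- gaussian_clusters(n_per = 6, sep = 5, sd = 1.2, seed = 23)
  fit1 <- fit_cda(cl$x, cl$labels)
  scales <- c(100, 0.01, 7, 3)
  shifts <- c(-5, 40, 0, 2)
  xr <- sweep(sweep(cl$x, 2, scales, "*"), 2, shifts, "+")
  fit2 <- fit_cda(xr, cl$labels)
  set.seed(24)
  probe <- matrix(rnorm(50 * 4, sd = 4), 50, 4)
  pr <- sweep(sweep(probe, 2, scales, "*"), 2, shifts, "+")
  expect_equal(classify(fit2, pr)$label, classify(fit1, probe)$label)
  expect_equal(fit2$wilks_lambda, fit1$wilks_lambda, tolerance = 1e-8)
})

test_that("increasing between-class separation never increases lambda", {
  lambdas <- sapply(c(1, 2, 4, 8), function(sep) {
    cl <- gaussian_clusters(n_per = 8, sep = sep, sd = 1, seed = 29)
    fit_cda(cl$x, cl$labels)$wilks_lambda
  })
  expect_true(all(diff(lambdas) < 0))
})

test_that("canonical axes agree with the reference discriminant implementation", {
  skip_if_not_installed("MASS")
  cl <- gaussian_clusters(n_per = 10, sep = 3, sd = 1.5, seed = 31)
  fit <- fit_cda(cl$x, cl$labels)
  ref <- MASS::lda(cl$x, grouping = cl$labels)
  zs <- canonical_scores(fit, cl$x)
  zr <- predict(ref)$x
  # same axes up to sign: |correlation| of matched variates is 1
  expect_equal(abs(cor(zs[, 1], zr[, 1])), 1, tolerance = 1e-6)
  expect_equal(abs(cor(zs[, 2], zr[, 2])), 1, tolerance = 1e-6)
})

test_that("leave-one-out cross-validation refits once per sample", {
  cl <- gaussian_clusters(n_per = 5, sep = 10, sd = 1, seed = 37)
  cv <- loocv(cl$x, cl$labels)
  expect_equal(cv$n_refits, 15L)
  expect_equal(unname(cv$rates), c(100, 100, 100))
  expect_equal(cv$overall, 100)
})

test_that("random labels on identical features classify near chance", {
  set.seed(41)
  x <- matrix(rnorm(60 * 4), 60, 4)
  labels <- sample(rep(c("a", "b", "c"), each = 20))
  cv <- loocv(x, labels)
  # binomial bound: 60 trials at p = 1/3, stay within 5 sigma of chance
  p_hat <- cv$overall / 100
  expect_lt(abs(p_hat - 1 / 3), 5 * sqrt((1 / 3) * (2 / 3) / 60))
})

test_that("grouped cross-validation holds out whole units", {
  cl <- gaussian_clusters(n_per = 6, sep = 8, sd = 1, seed = 43)
  unit <- rep(seq_len(9), each = 2)
  cv <- loocv(cl$x, cl$labels, unit = unit)
  expect_equal(cv$n_refits, 9L)
  expect_equal(cv$overall, 100)
})

test_that("ROC AUC matches the brute-force pairwise comparison", {
  set.seed(47)
  n <- 50
  labels <- sample(c("a", "b", "c"), n, replace = TRUE)
  scores <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  scores[cbind(seq_len(n), match(labels, c("a", "b", "c")))] <-
    scores[cbind(seq_len(n), match(labels, c("a", "b", "c")))] + 1
  auc <- roc_auc(scores, labels)
  for (cl in c("a", "b", "c")) {
    s_pos <- scores[labels == cl, cl]
    s_neg <- scores[labels != cl, cl]
    brute <- (sum(outer(s_pos, s_neg, ">")) +
                0.5 * sum(outer(s_pos, s_neg, "=="))) /
      (length(s_pos) * length(s_neg))
    expect_equal(auc[[cl]], brute)
  }
})

test_that("ROC AUC handles the degenerate score patterns", {
  labels <- rep(c("a", "b"), each = 5)
  sep <- cbind(a = c(5:1, -(1:5)), b = c(-(1:5), 5:1))
  expect_equal(unname(roc_auc(sep, labels)), c(1, 1))
  flat <- matrix(1, 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(roc_auc(flat, labels)), c(0.5, 0.5))
  only_a <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_true(is.na(roc_auc(only_a, rep("a", 5))[["b"]]))
})

test_that("ROC AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  labels <- sample(c("a", "b"), 40, replace = TRUE)
  scores <- cbind(a = rnorm(40) + (labels == "a"),
                  b = rnorm(40) + (labels == "b"))
  ours <- roc_auc(scores, labels)
  for (cl in c("a", "b")) {
    ref <- pROC::auc(pROC::roc(response = labels == cl,
                               predictor = scores[, cl],
                               direction = "<", quiet = TRUE))
    expect_equal(ours[[cl]], as.numeric(ref))
  }
})

test_that("severity maps label pixels by the trained group geometry", {
  # train on synthetic study features, then feed maps at exact group means
  study <- make_study(seed = 5)
  des <- study_design(study)
  fit <- fit_cda(des$features, des$labels)
  template <- study_template()
  t24 <- 86400
  row <- template[template$group == "burn78" & template$t == t24, ]
  mk_plane <- function(v) matrix(v, 6, 8)
  maps <- structure(list(c_hbt = mk_plane(row$chbt_mean),
                         sto2 = mk_plane(row$sto2_mean),
                         stmet = mk_plane(row$stmet_mean),
                         valid = mk_plane(TRUE)),
                    class = "hemo_maps")
  img <- severity_map(fit, maps, t = t24)
  expect_equal(dim(img$label), c(6L, 8L))
  expect_equal(unique(img$classes[as.numeric(img$label)]), "burn78")
  occ <- occupancy_rates(img)
  expect_equal(occ[["burn78"]], 1)
  expect_equal(sum(occ), 1)
})

test_that("occupancy rates sum to one over valid pixels", {
  img <- structure(list(label = matrix(c(1L, 2L, 1L, NA), 2, 2),
                        classes = c("control", "burn70", "burn78")),
                   class = "severity_image")
  occ <- occupancy_rates(img)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ), c(2 / 3, 1 / 3, 0))
  empty <- structure(list(label = matrix(NA_integer_, 2, 2),
                          classes = c("a", "b")),
                     class = "severity_image")
  expect_error(occupancy_rates(empty), "no valid")
})

test_that("degenerate inputs raise informative errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_cda(x, rep("a", 10)), "2 classes")
  expect_error(fit_cda(x, c(rep("a", 9), "b")), "2 samples")
  cl <- gaussian_clusters()
  fit <- fit_cda(cl$x, cl$labels)
  expect_error(canonical_scores(fit, c(1, 2)), "dimension")
})
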