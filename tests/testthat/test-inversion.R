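test_that("quadratic features are the ten fixed-order monomials", {
  expect_equal(as.numeric(quadratic_features(c(0, 0, 0))),
               c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(quadratic_features(c(1, 1, 1))), rep(1, 10))
  expect_equal(as.numeric(quadratic_features(c(2, 0, 0))),
               c(1, 2, 0, 0, 4, 0, 0, 0, 0, 0))
  f <- quadratic_features(c(2, 3, 5))
  expect_equal(as.numeric(f[c("XY", "XZ", "YZ")]), c(6, 10, 15))
})

test_that("the default training grid enumerates the full design", {
  g <- training_grid()
  expect_equal(nrow(g), 1550)
  expect_equal(length(unique(g$c_m)), 10)
  expect_equal(length(unique(g$c_hbt)), 5)
  pairs <- attr(g, "pairs")
  expect_equal(nrow(pairs), 31)
  expect_false(any(duplicated(pairs[, c("sto2", "stmet")])))
  expect_true(all(pairs$sto2 + pairs$stmet <= 100))
  expect_true(all(abs(g$c_hbo + g$c_hbr + g$c_methb - g$c_hbt) < 1e-12))
  # no duplicated concentration combinations
  expect_false(any(duplicated(g[, c("c_m", "c_hbt", "sto2", "stmet")])))
})

test_that("saturation pairs follow the non-met fraction parameterization", {
  p <- saturation_pairs()
  expect_equal(nrow(p), 31)
  expect_equal(p$sto2, p$f * (100 - p$stmet) / 100)
  expect_equal(sum(p$stmet == 100), 1)    # collapsed column
  expect_equal(sort(unique(p$stmet)), seq(0, 100, 20))
})

test_that("training sets built on a restricted grid behave physically", {
  lut <- test_lut()
  small <- training_grid(cm = c(2, 6), chbt = c(0.2, 0.8),
                         pairs = data.frame(sto2 = c(30, 60),
                                            stmet = c(0, 10)))
  tr <- build_training_set(lut, small)
  expect_equal(nrow(tr), 8)
  expect_true(all(is.finite(as.matrix(tr[, c("x", "y", "z")]))))
  expect_true(all(tr$y > 0 & tr$y < 100))
  # more hemoglobin absorbs more light: lower Y at fixed melanin/saturation
  sub <- tr[tr$c_m == 2 & tr$sto2 == 30, ]
  expect_lt(sub$y[sub$c_hbt == 0.8], sub$y[sub$c_hbt == 0.2])
  expect_error(build_training_set(lut, small, expected_size = 1550),
               "expected")
})

test_that("the quadratic fit recovers an exactly quadratic truth", {
  set.seed(11)
  xyz <- matrix(runif(600, 10, 60), 200, 3)
  feats <- quadratic_features(xyz)
  true_coef <- matrix(rnorm(40, sd = 0.01), 4, 10)
  targets <- feats %*% t(true_coef)
  colnames(targets) <- c("c_hbo", "c_hbr", "c_methb", "c_m")
  training <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], targets)
  fit <- fit_n2(training)
  expect_equal(unname(fit$coefficients), unname(true_coef), tolerance = 1e-8)
  expect_true(all(fit$r_squared > 1 - 1e-12))
  # permutation invariance of ordinary least squares
  fit2 <- fit_n2(training[sample(nrow(training)), ])
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-9)
  # predictions reproduce the construction
  expect_equal(unname(predict(fit, xyz[3, ])),
               unname(targets[3, , drop = FALSE]), tolerance = 1e-8)
  expect_error(fit_n2(training[1:5, ]), "at least 10")
})

test_that("rank-deficient feature sets are rejected with the offending columns", {
  xyz <- cbind(seq(1, 50), 2 * seq(1, 50), 0)   # z identically zero
  training <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         c_hbo = runif(50), c_hbr = runif(50),
                         c_methb = runif(50), c_m = runif(50))
  expect_error(fit_n2(training), "rank-deficient")
})

test_that("n2 fits serialize to JSON and back", {
  lut <- test_lut()
  tr <- build_training_set(lut, training_grid(cm = c(2, 6),
                                              chbt = c(0.2, 0.6, 1.0)))
  fit <- fit_n2(tr)
  path <- file.path(tempdir(), "n2_test.json")
  write_n2(fit, path)
  back <- read_n2(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$r_squared, fit$r_squared)
  expect_equal(back$illuminant, "D65")
  unlink(path)
})

test_that("concentration maps derive hemoglobin parameters per the stated formulas", {
  # build a fit whose truth is exactly representable, then check derivations
  coefs <- matrix(0, 4, 10)
  coefs[1, 2] <- 0.01   # c_hbo = 0.01 X
  coefs[2, 3] <- 0.005  # c_hbr = 0.005 Y
  coefs[3, 4] <- 0.01   # c_methb = 0.01 Z
  coefs[4, 1] <- 2      # c_m = 2
  rownames(coefs) <- c("c_hbo", "c_hbr", "c_methb", "c_m")
  fit <- structure(list(coefficients = coefs), class = "n2_fit")
  img <- array(0, c(2, 2, 3))
  img[, , 1] <- 30; img[, , 2] <- 20; img[, , 3] <- 10
  maps <- estimate_concentrations(img, fit)
  expect_equal(maps$c_hbo[1, 1], 0.3)
  expect_equal(maps$c_hbr[1, 1], 0.1)
  expect_equal(maps$c_methb[1, 1], 0.1)
  expect_equal(maps$c_hbt[1, 1], 0.5)
  expect_equal(maps$sto2[1, 1], 60)
  expect_equal(maps$stmet[1, 1], 20)
  expect_true(all(maps$valid))
  # constant image gives constant maps
  expect_equal(length(unique(as.numeric(maps$sto2))), 1)
  # non-positive total hemoglobin is masked
  img2 <- img * -1
  maps2 <- estimate_concentrations(img2, fit)
  expect_false(any(maps2$valid))
  expect_true(all(is.na(maps2$sto2)))
  expect_error(estimate_concentrations(img[, , 1:2], fit), "rows, cols, 3")
})

test_that("estimates are exactly quadratic in the tristimulus values", {
  lut <- test_lut()
  tr <- build_training_set(lut, training_grid(cm = c(2, 6),
                                              chbt = c(0.2, 0.6, 1.0)))
  fit <- fit_n2(tr)
  xyz <- c(25, 30, 18)
  p1 <- predict(fit, xyz)
  # evaluate the polynomial identity at s * xyz from monomial coefficients
  s <- 2
  n2 <- fit$coefficients
  manual <- n2[, 1] + s * (n2[, 2] * xyz[1] + n2[, 3] * xyz[2] +
                           n2[, 4] * xyz[3]) +
    s^2 * (n2[, 5] * xyz[1]^2 + n2[, 6] * xyz[2]^2 + n2[, 7] * xyz[3]^2 +
           n2[, 8] * xyz[1] * xyz[2] + n2[, 9] * xyz[1] * xyz[3] +
           n2[, 10] * xyz[2] * xyz[3])
  expect_equal(as.numeric(predict(fit, s * xyz)), as.numeric(manual))
  expect_equal(dim(p1), c(1L, 4L))
})

test_that("ROI summaries match a brute-force computation", {
  m <- matrix(seq_len(25) / 25, 5, 5)
  s <- roi_summary(m, c(2, 2, 3, 3))
  block <- m[2:4, 2:4]
  expect_equal(s[["mean"]], mean(block))
  expect_equal(s[["sd"]], sd(block))
  # constant map
  expect_equal(roi_summary(matrix(2, 4, 4), c(1, 1, 4, 4)),
               c(mean = 2, sd = 0))
  # checkerboard
  cb <- matrix(c(0, 1), 4, 4)
  expect_equal(roi_summary(cb, c(1, 1, 4, 4))[["mean"]], 0.5)
  expect_error(roi_summary(m, c(4, 4, 5, 5)), "outside")
  allna <- matrix(NA_real_, 3, 3)
  expect_error(roi_summary(allna, c(1, 1, 3, 3)), "no valid")
})
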