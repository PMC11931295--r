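# Shared fixtures, built lazily and cached for the session so expensive
# Monte Carlo runs happen once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small LUT for fast pipeline tests: full grid, modest photon count.
test_lut <- function() {
  fixture("lut_small", simulate_scattering(n_photons = 2e4, seed = 101))
}

# Full-scale LUT for the acceptance-level checks.
acceptance_lut <- function() {
  fixture("lut_full", simulate_scattering(n_photons = 1e5, seed = 7))
}

acceptance_fit <- function() {
  fixture("n2_full", fit_n2(build_training_set(acceptance_lut(),
                                               expected_size = 1550)))
}

acceptance_report <- function() {
  fixture("report_full", run_insilico(acceptance_lut(), acceptance_fit()))
}

# Three well-separated Gaussian clusters in 2D, expanded to a fixed feature
# matrix; used by the discriminant-analysis tests.
gaussian_clusters <- function(n_per = 5, sep = 10, sd = 1, seed = 3,
                              p = 4) {
  set.seed(seed)
  centers <- matrix(0, 3, p)
  centers[2, 1] <- sep
  centers[3, 2] <- sep
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per * p, sd = sd), n_per, p) +
      matrix(centers[k, ], n_per, p, byrow = TRUE)
  }))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = rep(c("a", "b", "c"), each = n_per))
}
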