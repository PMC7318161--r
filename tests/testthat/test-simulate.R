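test_that("Watson density normalizes and concentrates as it should", {
  expect_equal(watson_density(c(0, 0, 1), c(0, 0, 1), 0), 1 / (4 * pi))
  mu <- c(1, 1, 1) / sqrt(3)
  for (kappa in c(0, 3, 11, 25)) {
    q <- powderlaw:::sphere_quadrature(48, 96)
    tot <- sum(watson_density(q$nodes, mu, kappa) * q$weights)
    expect_equal(tot, 1, tolerance = 1e-8)
  }
  perp <- c(1, -1, 0) / sqrt(2)
  expect_equal(watson_density(mu, mu, 11) / watson_density(perp, mu, 11),
               exp(11), tolerance = 1e-10)
  expect_error(watson_density(mu, mu, -1), "nonnegative")
})

test_that("Kummer normalizer matches its integral representation", {
  for (k in c(0, 0.5, 3, 11, 50, 200)) {
    oracle <- stats::integrate(function(t) exp(k * (t^2 - 1)), 0, 1,
                               rel.tol = 1e-12)$value * exp(k)
    expect_equal(kummer_m_half(k), oracle, tolerance = 1e-8)
  }
})

test_that("tissue model keeps fractions on the simplex", {
  t0 <- tissue_model()
  expect_equal(t0$f1 + t0$f2 + t0$f3, 1)
  expect_equal(t0$f1, 0.65)
  t1 <- tissue_model(f1 = 0.65, f3 = 0.2)
  expect_equal(t1$f1 + t1$f2 + t1$f3, 1)
  expect_equal(t1$f1 / t1$f2, 0.65 / 0.35, tolerance = 1e-12)
  expect_error(tissue_model(f1 = 1.2), "fractions")
})

test_that("a nearly coherent stick reproduces the single-axis exponential", {
  p <- build_protocol("explicit", b_delta = 1,
                      shells = data.frame(b_smm2 = c(0, 3000, 6000)),
                      n_dirs = 1, seed = 3)
  tis <- tissue_model(f1 = 1, kappa = 1e4, mu = c(0, 0, 1))
  s <- simulate_voxel(tis, p)
  expect_equal(s, exp(-c(0, 3, 6) * 2), tolerance = 1e-3)
})

test_that("a pure dot voxel holds its signal at every b", {
  p <- build_protocol("explicit", b_delta = -0.5,
                      shells = data.frame(b_smm2 = c(0, 4000, 10000)),
                      n_dirs = 6, seed = 2)
  tis <- tissue_model(f1 = 0, f3 = 1, R_s = 0)
  expect_equal(simulate_voxel(tis, p), rep(1, 13), tolerance = 1e-12)
})

test_that("simulated planar shell matches the semi-analytic composition", {
  p <- build_protocol("explicit", b_delta = -0.5,
                      shells = data.frame(b_smm2 = c(0, 10000)),
                      n_dirs = 60, seed = 1)
  s <- simulate_voxel(tissue_model(), p)     # defaults: f1 0.65, kappa 11, eta 0
  pa <- powder_average(s, p)
  semi <- 0.65 * pte_stick_signal(20) + 0.35 * powder_signal(10, -0.5, 2, 0.5)
  # absolute deviation on the signal-fraction scale (finite 60-direction
  # sampling of the orientation average)
  expect_lt(abs(unname(pa$curves) - semi), 2e-3)
})

test_that("dense-direction powder averages are invariant to the ODF", {
  p <- build_protocol("explicit", b_delta = -0.5,
                      shells = data.frame(b_smm2 = c(0, 8000)),
                      n_dirs = 240, seed = 5)
  base <- powder_average(simulate_voxel(tissue_model(), p), p)$curves
  rotated <- powder_average(simulate_voxel(
    tissue_model(mu = c(1, 2, -1) / sqrt(6)), p), p)$curves
  dispersed <- powder_average(simulate_voxel(
    tissue_model(kappa = 3), p), p)$curves
  expect_equal(unname(base), unname(rotated), tolerance = 1e-3)
  expect_equal(unname(base), unname(dispersed), tolerance = 1e-3)
})

test_that("Rician noise has the Rayleigh background and second moment", {
  expect_identical(add_rician_noise(c(0.5, 1), 0), c(0.5, 1))
  n <- 1e5
  bg <- add_rician_noise(rep(0, n), 0.3, seed = 31)
  expect_equal(mean(bg), 0.3 * sqrt(pi / 2), tolerance = 0.01)
  s <- add_rician_noise(rep(0.7, n), 0.2, seed = 32)
  expect_equal(mean(s^2), 0.7^2 + 2 * 0.2^2, tolerance = 0.01)
  expect_identical(add_rician_noise(rep(1, 5), 0.1, seed = 4),
                   add_rician_noise(rep(1, 5), 0.1, seed = 4))
  # background magnitudes pass a KS test against Rayleigh(sigma)
  bg2 <- add_rician_noise(rep(0, 1e4), 0.5, seed = 33)
  ks <- suppressWarnings(stats::ks.test(bg2, function(q) {
    stats::pweibull(q, shape = 2, scale = 0.5 * sqrt(2))
  }))
  expect_gt(ks$p.value, 0.01)
})

test_that("phantom background encodes the requested SNR", {
  layout <- array(0L, c(8, 8, 4))
  layout[3:6, 3:6, ] <- 1L
  p <- build_protocol("explicit", b_delta = -0.5,
                      shells = data.frame(b_smm2 = c(0, 8000)),
                      n_dirs = 12, seed = 6)
  ph <- make_phantom_volume(layout, list(tissue_model()), p,
                            snr_b0 = 150, seed = 21)
  b0 <- ph$signals[, , , 1]
  est <- estimate_sigma_snr(b0, layout > 0, layout == 0)
  expect_equal(est$snr, 150, tolerance = 0.05)
  expect_equal(est$sigma_hat, 1 / 150, tolerance = 0.1)
  expect_error(make_phantom_volume(array(0L, c(2, 2, 1)), list(), p),
               "no tissue")
})

test_that("datasets round-trip through NIfTI plus sidecars", {
  layout <- array(1L, c(3, 3, 2))
  p <- build_protocol("explicit", b_delta = c(0, -0.5),
                      shells = data.frame(b_smm2 = c(0, 6000)),
                      n_dirs = 4, seed = 8)
  ph <- make_phantom_volume(layout, list(tissue_model()), p,
                            snr_b0 = 1e9, seed = 3)   # effectively noise-free
  stem <- file.path(tempdir(), "ds")
  write_dwi_dataset(ph, stem)
  on.exit(unlink(paste0(stem, c(".nii.gz", ".bval", ".bvec", ".bdelta",
                                ".json", "_labels.nii.gz"))))
  rt <- read_dwi_dataset(stem)
  expect_equal(rt$signals, ph$signals, tolerance = 1e-6, ignore_attr = TRUE)
  v1 <- powderlaw:::protocol_volumes(p)
  v2 <- powderlaw:::protocol_volumes(rt$protocol)
  expect_equal(v2$b, v1$b, tolerance = 1e-9)
  expect_equal(v2$b_delta, v1$b_delta)
  expect_equal(rt$sigma, ph$sigma)
  expect_equal(rt$layout, ph$layout, ignore_attr = TRUE)
})
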