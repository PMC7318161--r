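test_that("noise-floor crossings follow the per-shape scaling laws", {
  # spherical encoding has a closed form to compare exactly
  for (snr in c(20, 50, 150)) {
    expect_equal(max_bD_noise_floor(0, snr),
                 3 * log(snr / (2 * sqrt(pi / 2))), tolerance = 1e-5)
  }
  # the power laws in SNR are asymptotic; measure them where bD is large
  snrs <- exp(seq(log(100), log(1000), length.out = 8))
  slope_of <- function(bd) {
    m <- vapply(snrs, function(s) max_bD_noise_floor(bd, s), numeric(1))
    stats::coef(stats::lm(log(m) ~ log(snrs)))[[2]]
  }
  expect_equal(slope_of(1), 2, tolerance = 0.05)      # quadratic in SNR
  expect_equal(slope_of(-0.5), 1, tolerance = 0.05)   # linear in SNR
  expect_error(max_bD_noise_floor(1, 2), "too low")
  expect_error(max_bD_noise_floor(0.3, 50), "b_delta")
})

test_that("MD/FA parametrization solves the axisymmetric tensor", {
  d <- powderlaw:::tensor_from_md_fa(1, 0.95)
  expect_equal((d$d_par + 2 * d$d_perp) / 3, 1, tolerance = 1e-10)
  fa <- abs(d$d_par - d$d_perp) / sqrt(d$d_par^2 + 2 * d$d_perp^2)
  expect_equal(fa, 0.95, tolerance = 1e-9)
  iso <- powderlaw:::tensor_from_md_fa(2, 0)
  expect_equal(iso$d_par, iso$d_perp)
})

test_that("an isotropic tensor is rotation-invariant with one direction", {
  md <- min_directions_for_invariance(1, b_list = 8, FA = 0, seed = 1)
  expect_equal(md$n_min, 1L)
})

test_that("rotational CV shrinks as the direction count grows", {
  # small-scale version of the invariance analysis: planar encoding, one
  # shell, CV at a sparse scheme dwarfs CV at a dense one
  dd <- powderlaw:::tensor_from_md_fa(1, 0.95)
  axes <- t(vapply(generate_rotations(128, seed = 7, restarts = 1),
                   function(R) R[, 3], numeric(3)))
  cv_at <- function(n) {
    X <- powderlaw:::repulsion_set(n, seed = 42, iters = 300, restarts = 2)
    C2 <- (X %*% t(axes))^2
    S <- exp(-(7 * 0.5 * (dd$d_par + 2 * dd$d_perp) - 7 * 0.5 *
                 (dd$d_perp + (dd$d_par - dd$d_perp) * C2)))
    m <- colMeans(S)
    sd(m) / mean(m)
  }
  cvs <- vapply(c(6, 12, 24, 48), cv_at, numeric(1))
  expect_lt(cvs[4], cvs[1] / 5)
  expect_true(all(diff(cvs) < 0))
})

test_that("alpha maps centre white matter near one", {
  layout <- array(0L, c(4, 4, 2))
  layout[1:3, , ] <- 1L               # stick-dominated, white-matter-like
  p <- build_protocol("explicit", b_delta = -0.5,
                      shells = data.frame(b_smm2 = c(0, seq(7000, 10000, 1000))),
                      n_dirs = 30, seed = 4)
  ph <- make_phantom_volume(layout, list(tissue_model()), p,
                            snr_b0 = 1e9, seed = 5)
  maps <- alpha_map(ph)
  wm_alpha <- maps$alpha[layout == 1]
  expect_equal(mean(wm_alpha), 1.15, tolerance = 0.2)
  expect_s3_class(maps$histogram, "histogram")
  expect_named(maps$histograms, "label1")
})

test_that("a free-water exponential has no power law: the fit saturates its bounds", {
  # noise-free Gaussian decay at high MD, fitted over the high-b window
  b <- seq(7, 10, by = 0.5)
  ft <- fit_powerlaw(b, exp(-3 * b))
  expect_gt(ft$alpha, 2)              # far above any stick exponent
  expect_false(ft$converged)          # flagged: bound hit, no power law
})

test_that("fraction sweeps run end-to-end and move alpha in the right direction", {
  sw <- sweep_fraction("dot", f3_grid = c(0, 0.02), b_delta_list = -0.5,
                       n_repeats = 3, seed = 17)
  expect_equal(nrow(sw), 2)
  # a dot fraction pulls the planar exponent away from (below) its
  # stick value
  expect_lt(sw$alpha_mean[2], sw$alpha_mean[1])
  expect_error(sweep_fraction("dot", f3_grid = c(0, 1)), "f3_grid")
})

test_that("experiment recipes are deterministic and discoverable", {
  out1 <- file.path(tempdir(), "exp1")
  out2 <- file.path(tempdir(), "exp2")
  r1 <- run_experiment("fig3", out1, seed = 5, quiet = TRUE,
                       config = list(snr_grid = c(25, 50, 100)))
  r2 <- run_experiment("fig3", out2, seed = 5, quiet = TRUE,
                       config = list(snr_grid = c(25, 50, 100)))
  f1 <- file.path(out1, "max_bD_vs_snr.tsv")
  f2 <- file.path(out2, "max_bD_vs_snr.tsv")
  expect_identical(readLines(f1), readLines(f2))
  tab <- read.delim(f1)
  expect_equal(tab$max_bD[tab$shape == "planar" & tab$snr == 50], 21.08,
               tolerance = 0.01)
  expect_error(run_experiment("figX"), "valid names")
  unlink(c(out1, out2), recursive = TRUE)
})
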