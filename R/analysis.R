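#' Powder average of a DWI dataset
#'
#' Direction-averages each shell (arithmetic mean over its gradient
#' directions) and normalizes by the mean b = 0 signal, per voxel. Voxels
#' whose b0 mean is zero or negative are flagged invalid and excluded from
#' downstream fitting.
#'
#' @param dataset a `dwi_dataset` (or a bare per-volume numeric vector with
#'   `protocol` supplied).
#' @param protocol used when `dataset` is a numeric vector.
#' @return list with `b` (shell b-values, ms/um^2, sorted), `b_delta`,
#'   `curves` (voxels x shells matrix, or a vector for a single voxel) and
#'   `valid` (logical per voxel).
#' @export
powder_average <- function(dataset, protocol = NULL) {
  if (is.numeric(dataset)) {
    stopifnot(!is.null(protocol))
    sig <- matrix(dataset, nrow = 1)
  } else {
    protocol <- dataset$protocol
    d <- dim(dataset$signals)
    sig <- matrix(dataset$signals, prod(d[1:3]), d[4])
  }
  v <- protocol_volumes(protocol)
  if (!any(v$b == 0)) stop("protocol has no b = 0 volume for normalization")
  b0_mean <- rowMeans(sig[, v$b == 0, drop = FALSE])
  shells <- sort(unique(v$b[v$b > 0]))
  curves <- vapply(shells, function(bb) {
    rowMeans(sig[, v$b == bb, drop = FALSE])
  }, numeric(nrow(sig)))
  curves <- matrix(curves, nrow = nrow(sig))
  valid <- is.finite(b0_mean) & b0_mean > 0
  curves[valid, ] <- curves[valid, , drop = FALSE] / b0_mean[valid]
  curves[!valid, ] <- NA_real_
  bd <- vapply(shells, function(bb) v$b_delta[match(bb, v$b)], numeric(1))
  list(b = shells, b_delta = bd,
       curves = if (nrow(curves) == 1) drop(curves) else curves,
       valid = valid)
}

#' Noise level and SNR from background and foreground masks
#'
#' Background magnitudes in a pure-noise region follow a Rayleigh
#' distribution with mean \eqn{\sigma\sqrt{\pi/2}}; inverting,
#' \eqn{\hat\sigma = \sqrt{2/\pi}\,\langle M_B\rangle}, and
#' \eqn{SNR = \langle M_S \rangle / \hat\sigma} with the foreground mean.
#'
#' @param volume 3-D numeric array (a single image volume).
#' @param foreground_mask,background_mask logical arrays of the same shape.
#' @return list with `sigma_hat` and `snr`.
#' @export
estimate_sigma_snr <- function(volume, foreground_mask, background_mask) {
  if (!any(background_mask)) stop("empty background mask")
  if (!any(foreground_mask)) stop("empty foreground mask")
  mb <- mean(volume[background_mask])
  sigma_hat <- sqrt(2 / pi) * mb
  if (sigma_hat <= 0) stop("background mean is nonpositive")
  list(sigma_hat = sigma_hat, snr = mean(volume[foreground_mask]) / sigma_hat)
}

#' Maximum b*D before the rectified noise floor
#'
#' Solves \eqn{S_{shape}(bD) = 2\sqrt{\pi/2}/SNR} for the powder-averaged
#' stick signal of the given encoding shape - the point where the decaying
#' signal meets twice the Rayleigh background mean (in b0-normalized units).
#' The shape signal is the closed-form erf expression for linear encoding,
#' the Dawson form for planar, and the exponential \eqn{e^{-bD/3}} for
#' spherical, so the three scale as \eqn{SNR^2}, \eqn{SNR} and
#' \eqn{\ln SNR} respectively.
#'
#' @param b_delta encoding shape: 1 (linear), -0.5 (planar) or 0 (spherical).
#' @param snr b0 signal-to-noise ratio; must exceed `2*sqrt(pi/2)` for a
#'   solution to exist.
#' @param tol root-finding tolerance on bD.
#' @return maximum dimensionless `b * D`.
#' @export
#' @examples
#' max_bD_noise_floor(1, 50)      # ~312 (linear)
#' max_bD_noise_floor(-0.5, 50)   # ~21  (planar)
#' max_bD_noise_floor(0, 50)      # ~9   (spherical)
max_bD_noise_floor <- function(b_delta, snr, tol = 1e-6) {
  floor_level <- 2 * sqrt(pi / 2) / snr
  if (floor_level >= 1) stop("snr too low: signal never exceeds the noise floor")
  shape_signal <- if (abs(b_delta - 1) < 1e-9) {
    function(bD) powder_signal(bD, 1, 1, 0)
  } else if (abs(b_delta + 0.5) < 1e-9) {
    function(bD) pte_stick_signal(bD)
  } else if (abs(b_delta) < 1e-9) {
    function(bD) exp(-bD / 3)
  } else {
    stop("b_delta must be one of 1, -0.5, 0")
  }
  hi <- 10
  while (shape_signal(hi) > floor_level) {
    hi <- hi * 2
    if (hi > 1e12) stop("signal never reaches the noise floor")
  }
  stats::uniroot(function(x) shape_signal(x) - floor_level,
                 c(1e-9, hi), tol = tol)$root
}

# (D_par, D_perp) of an axially symmetric tensor with given MD and FA
tensor_from_md_fa <- function(MD, FA) {
  if (MD <= 0) stop("MD must be positive")
  if (FA < 0 || FA >= 1) stop("FA must be in [0, 1)")
  if (FA == 0) return(list(d_par = MD, d_perp = MD))
  f <- function(dp) {
    dpar <- 3 * MD - 2 * dp
    abs(dpar - dp) / sqrt(dpar^2 + 2 * dp^2) - FA
  }
  dp <- stats::uniroot(f, c(0, MD * (1 - 1e-12)), tol = 1e-12)$root
  list(d_par = 3 * MD - 2 * dp, d_perp = dp)
}

#' Minimum direction count for a rotationally invariant powder average
#'
#' For an axially symmetric Gaussian tensor (given mean diffusivity and FA),
#' simulates \eqn{S = \exp(-\mathrm{tr}(BD))} for every gradient direction
#' and every rotation of the tensor axis, direction-averages per shell, and
#' computes the coefficient of variation CV = SD/mean across rotations.
#' Ascending direction counts are tried (electrostatic-repulsion schemes,
#' deterministic per seed) and the smallest count with CV below threshold at
#' *every* listed b-value is returned.
#'
#' @param b_delta encoding shape.
#' @param b_list shell b-values, ms/um^2 (default 7-10, step 1).
#' @param MD mean diffusivity, um^2/ms; @param FA fractional anisotropy.
#' @param cv_threshold invariance criterion (default 0.01).
#' @param n_rotations tensor orientations (default 512).
#' @param seed seed for direction and rotation schemes.
#' @param n_max search cap.
#' @param restarts repulsion restarts per candidate set (speed/quality
#'   trade-off; see vignette).
#' @return list with `n_min` (smallest qualifying count, or `NA` if the cap
#'   is hit), and `cv` matrix (candidates x shells) for diagnostics.
#' @export
min_directions_for_invariance <- function(b_delta, b_list = c(7, 8, 9, 10),
                                          MD = 1, FA = 0.95,
                                          cv_threshold = 0.01,
                                          n_rotations = 512, seed = 42,
                                          n_max = 200, restarts = 4) {
  dd <- tensor_from_md_fa(MD, FA)
  if (FA == 0) {
    # isotropic tensor: any single direction is rotation-invariant
    return(list(n_min = 1L, cv = matrix(0, 1, length(b_list),
                                        dimnames = list("1", format(b_list)))))
  }
  axes <- t(vapply(generate_rotations(n_rotations, seed = seed),
                   function(R) R[, 3], numeric(3)))
  iso <- (1 - b_delta) / 3 * (dd$d_par + 2 * dd$d_perp)
  cvs <- matrix(NA_real_, 0, length(b_list))
  tried <- integer(0)
  for (n in seq_len(n_max)) {
    X <- repulsion_set(n, seed, iters = 300, restarts = restarts)
    C2 <- (X %*% t(axes))^2                  # n x n_rotations
    cv_b <- vapply(b_list, function(b) {
      S <- exp(-(b * iso + b * b_delta *
                   (dd$d_perp + (dd$d_par - dd$d_perp) * C2)))
      m <- colMeans(S)                        # powder average per rotation
      stats::sd(m) / mean(m)
    }, numeric(1))
    cvs <- rbind(cvs, cv_b)
    tried <- c(tried, n)
    if (all(cv_b < cv_threshold)) {
      rownames(cvs) <- tried
      colnames(cvs) <- format(b_list)
      return(list(n_min = n, cv = cvs))
    }
  }
  rownames(cvs) <- tried
  colnames(cvs) <- format(b_list)
  list(n_min = NA_integer_, cv = cvs)
}

#' Fitted exponent versus dot / sphere signal fraction
#'
#' Sweeps the third-compartment fraction `f3` (dot: `R_s = 0`; sphere:
#' `R_s = 8` um by default), simulating the three-compartment voxel at each
#' grid point for each encoding shape, adding Rician noise, powder-averaging
#' and fitting the power law over the high-b window. Reports mean and SD of
#' the fitted `alpha` over noise repeats.
#'
#' @param component `"dot"` or `"sphere"`.
#' @param f3_grid fractions in `[0, 1)`.
#' @param b_delta_list encoding shapes to sweep (default planar and linear).
#' @param tissue_base baseline [tissue_model()]; defaults to the ground
#'   truth with `D_e_perp = 0.75` and shrinkage `eta = 1.5`.
#' @param protocol acquisition; defaults to shells covering the fit window
#'   (b = 0 and 7000-10000 s/mm^2 step 500, 60 directions).
#' @param snr b0 SNR for the Rician noise.
#' @param n_repeats noise realizations per grid point.
#' @param b_range fit window, ms/um^2.
#' @param seed base seed; repeat `r` of grid point `i` uses
#'   `seed + 1000*i + r`.
#' @param R_s sphere radius (um) for `component = "sphere"`.
#' @return data.frame with columns `component`, `b_delta`, `f3`,
#'   `alpha_mean`, `alpha_sd`, `beta_mean`, `n_repeats`.
#' @export
sweep_fraction <- function(component = c("dot", "sphere"),
                           f3_grid = seq(0, 0.02, by = 0.01),
                           b_delta_list = c(-0.5, 1),
                           tissue_base = NULL,
                           protocol = NULL,
                           snr = 150, n_repeats = 20,
                           b_range = c(7, 10), seed = 42, R_s = 8) {
  component <- match.arg(component)
  if (any(f3_grid < 0 | f3_grid >= 1)) stop("f3_grid must lie in [0, 1)")
  if (is.null(tissue_base)) {
    tissue_base <- tissue_model(D_e_perp = 0.75,
                                radius_hist = default_radius_histogram(eta = 1.5))
  }
  rs <- if (component == "dot") 0 else R_s
  out <- NULL
  i <- 0
  for (bd in b_delta_list) {
    proto <- if (is.null(protocol)) {
      build_protocol("explicit", b_delta = bd,
                     shells = data.frame(b_smm2 = c(0, seq(7000, 10000, 500))),
                     n_dirs = 60, seed = seed)
    } else protocol
    pv <- protocol_volumes(proto)
    for (f3 in f3_grid) {
      i <- i + 1
      tis <- tissue_model(f1 = tissue_base$f1 / max(tissue_base$f1 + tissue_base$f2, 1e-12),
                          f3 = f3,
                          D_a_par = tissue_base$D_a_par,
                          D_e_par = tissue_base$D_e_par,
                          D_e_perp = tissue_base$D_e_perp,
                          kappa = tissue_base$kappa, mu = tissue_base$mu,
                          radius_hist = tissue_base$radius_hist, R_s = rs)
      clean <- simulate_volumes(tis, pv$b, pv$b_delta, pv$g, proto$timing)
      fits <- vapply(seq_len(n_repeats), function(r) {
        noisy <- add_rician_noise(clean, 1 / snr, seed = seed + 1000L * i + r)
        pa <- powder_average(noisy, proto)
        ft <- fit_powerlaw(pa$b, pa$curves, b_range = b_range)
        c(ft$alpha, ft$beta)
      }, numeric(2))
      out <- rbind(out, data.frame(component = component, b_delta = bd,
                                   f3 = f3,
                                   alpha_mean = mean(fits[1, ]),
                                   alpha_sd = stats::sd(fits[1, ]),
                                   beta_mean = mean(fits[2, ]),
                                   n_repeats = n_repeats))
    }
  }
  rownames(out) <- NULL
  out
}

#' Voxelwise power-law maps
#'
#' Applies [fit_powerlaw()] to every valid voxel of a dataset, returning
#' `alpha`, `beta` and `bic` volumes plus a histogram of `alpha` (per label
#' when the dataset carries a layout). Per-voxel failures are masked, not
#' fatal.
#'
#' @param dataset a `dwi_dataset`.
#' @param b_range fit window, ms/um^2.
#' @param breaks passed to [hist()] for the alpha histogram.
#' @return list with 3-D arrays `alpha`, `beta`, `bic`, logical `converged`,
#'   and `histogram` (overall) / `histograms` (per label, if available).
#' @export
alpha_map <- function(dataset, b_range = c(7, 10), breaks = 30) {
  pa <- powder_average(dataset)
  d <- dim(dataset$signals)[1:3]
  nv <- prod(d)
  curves <- matrix(pa$curves, nrow = nv)
  alpha <- beta <- bic <- rep(NA_real_, nv)
  conv <- rep(FALSE, nv)
  for (i in which(pa$valid)) {
    ft <- tryCatch(fit_powerlaw(pa$b, curves[i, ], b_range = b_range),
                   error = function(e) NULL)
    if (!is.null(ft)) {
      alpha[i] <- ft$alpha
      beta[i] <- ft$beta
      bic[i] <- ft$bic
      conv[i] <- ft$converged
    }
  }
  res <- list(alpha = array(alpha, d), beta = array(beta, d),
              bic = array(bic, d), converged = array(conv, d))
  ok <- is.finite(alpha)
  if (any(ok)) {
    res$histogram <- graphics::hist(alpha[ok], breaks = breaks, plot = FALSE)
  }
  if (!is.null(dataset$layout)) {
    labs <- sort(unique(dataset$layout[dataset$layout > 0]))
    res$histograms <- lapply(labs, function(l) {
      a <- alpha[as.vector(dataset$layout == l) & ok]
      if (length(a)) graphics::hist(a, breaks = breaks, plot = FALSE) else NULL
    })
    names(res$histograms) <- paste0("label", labs)
  }
  res
}
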