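#' Three-compartment Watson-dispersed tissue model
#'
#' Parameter container for the simulator:
#' \deqn{S/S_0 = f_1 \int W(n) S_{cyl}(n)\,dn
#'             + f_2 \int W(n) S_{ec}(n)\,dn + f_3 S_{sph},}
#' with an intra-axonal compartment of impermeable cylinders (radius
#' histogram with shrinkage, [radius_histogram()]), a Gaussian extra-axonal
#' compartment, and an isotropic restricted sphere or dot compartment, all
#' dispersed by a Watson orientation distribution of concentration `kappa`.
#'
#' Defaults are the simulation ground truth used throughout:
#' `f1 = 0.65`, `D_a_par = D_e_par = 2` um^2/ms, `D_e_perp = 0.5` um^2/ms,
#' `kappa = 11`, no sphere/dot fraction, and the packaged synthetic radius
#' histogram. When `f3 > 0` is requested the remaining fractions shrink
#' proportionally so the three always sum to one.
#'
#' @param f1,f3 intra-axonal and sphere/dot signal fractions (`f2` takes the
#'   remainder before `f3` rescaling).
#' @param D_a_par intra-axonal parallel diffusivity, um^2/ms.
#' @param D_e_par,D_e_perp extra-axonal diffusivities, um^2/ms.
#' @param kappa Watson concentration, `>= 0`.
#' @param mu mean orientation, unit 3-vector.
#' @param radius_hist a [radius_histogram()]; `eta` there sets shrinkage.
#' @param R_s sphere radius, um (`0` = dot).
#' @return object of class `tissue_model` with fields `f1, f2, f3` summing
#'   to 1.
#' @export
#' @examples
#' tissue_model()                      # white-matter-like defaults
#' tissue_model(f3 = 0.1, R_s = 8)     # add a restricted sphere compartment
tissue_model <- function(f1 = 0.65, f3 = 0, D_a_par = 2, D_e_par = 2,
                         D_e_perp = 0.5, kappa = 11, mu = c(0, 0, 1),
                         radius_hist = default_radius_histogram(eta = 0),
                         R_s = 0) {
  if (f1 < 0 || f3 < 0 || f1 > 1 || f3 > 1) stop("fractions must be in [0, 1]")
  f2 <- 1 - f1
  # requested f3 displaces f1 and f2 proportionally
  f1 <- f1 * (1 - f3)
  f2 <- f2 * (1 - f3)
  stopifnot(abs(f1 + f2 + f3 - 1) < 1e-9)
  if (kappa < 0) stop("kappa must be nonnegative")
  mu <- mu / sqrt(sum(mu^2))
  structure(list(f1 = f1, f2 = f2, f3 = f3, D_a_par = D_a_par,
                 D_e_par = D_e_par, D_e_perp = D_e_perp, kappa = kappa,
                 mu = mu, radius_hist = radius_hist, R_s = R_s),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("Three-compartment Watson tissue model\n")
  cat(sprintf("  fractions: intra %.3f / extra %.3f / sphere-dot %.3f\n",
              x$f1, x$f2, x$f3))
  cat(sprintf("  D_a_par %.2f, D_e_par %.2f, D_e_perp %.2f um^2/ms; kappa %.1f\n",
              x$D_a_par, x$D_e_par, x$D_e_perp, x$kappa))
  cat(sprintf("  radius histogram: %d bins, eta = %g; R_s = %g um\n",
              length(x$radius_hist$radii), x$radius_hist$eta, x$R_s))
  invisible(x)
}

#' Noise-free voxel signals
#'
#' Evaluates the three-compartment model for every volume of a protocol.
#' The orientation integrals over the Watson distribution use a spherical
#' product quadrature ([sphere_quadrature()]), with the polar rule switched
#' to a boundary-layer form automatically for large `kappa`. Signals are
#' normalized so `S(b = 0) = 1`.
#'
#' @param tissue a [tissue_model()].
#' @param protocol a [build_protocol()] object.
#' @param n_theta,n_phi quadrature orders (defaults are accurate to ~1e-6
#'   for `kappa <= 30`; see the methods vignette).
#' @return numeric vector, one noise-free signal fraction per volume (b0
#'   volumes first when the protocol stores them that way).
#' @export
#' @examples
#' p <- build_protocol("explicit", b_delta = -0.5,
#'                     shells = data.frame(b_smm2 = c(0, 10000)), n_dirs = 6)
#' simulate_voxel(tissue_model(), p)
simulate_voxel <- function(tissue, protocol, n_theta = 48, n_phi = 96) {
  v <- protocol_volumes(protocol)
  simulate_volumes(tissue, v$b, v$b_delta, v$g, protocol$timing,
                   n_theta, n_phi)
}

# core vectorized evaluation given per-volume (b, b_delta, g)
simulate_volumes <- function(tissue, b, b_delta, g, timing,
                             n_theta = 48, n_phi = 96) {
  kappa <- tissue$kappa
  if (kappa > 30) n_theta <- max(n_theta, 48)   # Laguerre rule takes over
  quad <- sphere_quadrature(n_theta, n_phi, kappa = kappa)
  ww <- watson_weights(quad, tissue$mu, kappa)
  C2 <- (g %*% t(ww$nodes))^2            # V x Q: cos^2 between g_v and n_q
  w <- ww$weights
  V <- length(b)

  # exp(A + B*C2) %*% w: A, B are length-V, C2 is V x Q; column-major
  # recycling applies A and B down each column
  orient_avg <- function(d_par, d_perp) {
    A <- -b / 3 * (1 - b_delta) * (d_par + 2 * d_perp) - b * b_delta * d_perp
    B <- -b * b_delta * (d_par - d_perp)
    as.vector(exp(A + C2 * B) %*% w)
  }

  s_intra <- radius_weighted_average(function(r) {
    dp <- cylinder_perp_diffusivity(r, timing$D0, timing$delta, timing$Delta)
    orient_avg(tissue$D_a_par, dp)
  }, tissue$radius_hist)
  s_extra <- orient_avg(tissue$D_e_par, tissue$D_e_perp)
  s_sph <- sphere_signal(b, tissue$R_s, timing)
  s <- tissue$f1 * s_intra + tissue$f2 * s_extra + tissue$f3 * s_sph
  s[b == 0] <- 1
  s
}

#' Rician noise
#'
#' Magnitude-MRI noise model: returns
#' \eqn{S_n = \sqrt{(S + N_r)^2 + N_i^2}} with independent
#' \eqn{N_r, N_i \sim N(0, \sigma)} per sample. Deterministic for a fixed
#' seed. In b0-normalized signal units `sigma = 1 / SNR_b0`.
#'
#' @param signals numeric vector/array of noise-free signals.
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return noisy signals, same shape.
#' @export
add_rician_noise <- function(signals, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(signals)
  if (!is.null(seed)) set.seed(seed)
  nr <- stats::rnorm(length(signals), 0, sigma)
  ni <- stats::rnorm(length(signals), 0, sigma)
  out <- sqrt((signals + nr)^2 + ni^2)
  dim(out) <- dim(signals)
  out
}

#' Synthetic phantom volume
#'
#' Builds a 4-D DWI dataset from a 3-D integer layout: label 0 voxels are
#' background (pure noise, `S = 0`, so Rayleigh-based noise estimation is
#' exercisable), labels `1..K` index `tissue_presets`. Identical presets are
#' simulated once and shared. Rician noise at `sigma = 1/snr_b0` in
#' b0-normalized units.
#'
#' @param layout 3-D integer array of preset labels (0 = background).
#' @param tissue_presets list of [tissue_model()] objects.
#' @param protocol a `dwi_protocol`.
#' @param snr_b0 signal-to-noise ratio of the b = 0 image, `> 0`.
#' @param seed integer seed for the noise.
#' @return object of class `dwi_dataset`: list with `signals` (4-D array,
#'   x,y,z,volume), `protocol`, `sigma`, `layout`, `seed`.
#' @export
make_phantom_volume <- function(layout, tissue_presets, protocol,
                                snr_b0 = 150, seed = 1) {
  if (length(layout) == 0 || all(layout == 0)) stop("layout has no tissue voxels")
  if (snr_b0 <= 0) stop("snr_b0 must be positive")
  labs <- sort(unique(layout[layout > 0]))
  if (max(labs) > length(tissue_presets)) stop("layout labels exceed presets")
  v <- protocol_volumes(protocol)
  nv <- length(v$b)
  sig <- array(0, c(dim(layout), nv))
  per_label <- lapply(labs, function(l) {
    simulate_volumes(tissue_presets[[l]], v$b, v$b_delta, v$g, protocol$timing)
  })
  for (i in seq_along(labs)) {
    idx <- which(layout == labs[i], arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      sig[idx[r, 1], idx[r, 2], idx[r, 3], ] <- per_label[[i]]
    }
  }
  sigma <- 1 / snr_b0
  noisy <- add_rician_noise(sig, sigma, seed = seed)
  structure(list(signals = noisy, protocol = protocol, sigma = sigma,
                 layout = layout, seed = seed),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("dwi_dataset: %d x %d x %d voxels, %d volumes; sigma = %g\n",
              d[1], d[2], d[3], d[4], x$sigma))
  invisible(x)
}

#' Write / read a DWI dataset
#'
#' 4-D NIfTI-1 volume plus FSL-style `.bval`/`.bvec` and the `.bdelta`
#' sidecar (see [write_bval_bvec()]); the layout and noise level go into a
#' small JSON manifest next to the image. `read_dwi_dataset(write_dwi_dataset(x))`
#' preserves signals to float32 and the gradient table exactly.
#'
#' @param dataset a `dwi_dataset`.
#' @param stem output path stem (directory must exist); writes
#'   `<stem>.nii.gz`, `.bval`, `.bvec`, `.bdelta`, `.json`.
#' @export
write_dwi_dataset <- function(dataset, stem) {
  RNifti::writeNifti(RNifti::asNifti(dataset$signals, datatype = "float"),
                     paste0(stem, ".nii.gz"))
  write_bval_bvec(dataset$protocol, stem)
  meta <- list(sigma = dataset$sigma, seed = dataset$seed,
               timing = dataset$protocol$timing,
               n_b0 = dataset$protocol$n_b0)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(dataset$layout)) {
    RNifti::writeNifti(RNifti::asNifti(dataset$layout + 0L),
                       paste0(stem, "_labels.nii.gz"))
  }
  invisible(stem)
}

#' @rdname write_dwi_dataset
#' @export
read_dwi_dataset <- function(stem) {
  img <- RNifti::readNifti(paste0(stem, ".nii.gz"))
  grad <- read_bval_bvec(stem)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  lab_file <- paste0(stem, "_labels.nii.gz")
  layout <- if (file.exists(lab_file)) {
    as.array(RNifti::readNifti(lab_file))
  } else NULL
  sig <- as.array(img)
  if (dim(sig)[4] != length(grad$b)) {
    stop("volume count (", dim(sig)[4], ") does not match sidecars (",
         length(grad$b), ")")
  }
  protocol <- protocol_from_volumes(grad$b, grad$b_delta, grad$g,
                                    timing = meta$timing,
                                    n_b0 = meta$n_b0)
  structure(list(signals = sig, protocol = protocol, sigma = meta$sigma,
                 layout = layout, seed = meta$seed),
            class = "dwi_dataset")
}

# reassemble a protocol object from per-volume vectors (shells grouped by
# (b, b_delta) in order of first appearance)
protocol_from_volumes <- function(b, b_delta, g, timing, n_b0 = NULL) {
  key <- paste(signif(b, 10), signif(b_delta, 10))
  first <- !duplicated(key)
  sh <- lapply(which(first), function(i) {
    sel <- key == key[i]
    list(b = b[i], b_delta = b_delta[i],
         directions = g[sel, , drop = FALSE])
  })
  structure(list(shells = sh,
                 n_b0 = if (is.null(n_b0)) sum(b == 0) else as.integer(n_b0),
                 timing = timing, preset = "explicit", seed = NA),
            class = "dwi_protocol")
}
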