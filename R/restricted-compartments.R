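# Gaussian-phase-approximation (GPA) machinery for restricted compartments.
#
# Both the cylinder and the sphere reduce, under the GPA with rectangular
# pulsed gradients (width delta, separation Delta), to a Bessel-root series
# for the log-attenuation per axis:
#
#   ln E = -(gamma g)^2 sum_k c_k / (D0 a_k^2)^2 * psi(D0 a_k^2; delta, Delta)
#   psi(u) = 2 [ u d - 1 + e^{-u d} + e^{-u D} - (e^{-u(D-d)} + e^{-u(D+d)})/2 ]
#
# with a_k = mu_k / r, where mu_k are the roots of J1'(x) (cylinder,
# van Gelderen) or of j1'(x) (sphere, Murday-Cotts), and
# c_k = 2 r^2 / (mu_k^2 (mu_k^2 - s)) with s = 1 (cylinder), 2 (sphere) --
# the coefficients of the restricted displacement autocorrelation.
# Dividing by b = (gamma g delta)^2 (Delta - delta/3) maps the attenuation
# to an effective diffusivity that composes with the b-tensor closed forms.

roots_cache <- new.env(parent = emptyenv())

# roots of J1'(x) = 0 (x > 0), i.e. of J0(x) - J1(x)/x
bessel_j1prime_roots <- function(n) {
  key <- paste0("cyl", n)
  if (!is.null(roots_cache[[key]])) return(roots_cache[[key]])
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  roots <- numeric(n)
  lo <- 0.5
  for (k in seq_len(n)) {
    hi <- lo + 0.1
    while (f(lo) * f(hi) > 0) {
      hi <- hi + 0.1
      if (hi - lo > 2 * pi) stop("failed to bracket J1' root ", k)
    }
    roots[k] <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
    lo <- roots[k] + 1.5
  }
  roots_cache[[key]] <- roots
  roots
}

# roots of d/dx j1(x) = 0 with j1 the spherical Bessel function:
# j1'(x) = 0  <=>  (x^2 - 2) sin x + 2 x cos x = 0
sphere_j1prime_roots <- function(n) {
  key <- paste0("sph", n)
  if (!is.null(roots_cache[[key]])) return(roots_cache[[key]])
  f <- function(x) (x^2 - 2) * sin(x) + 2 * x * cos(x)
  roots <- numeric(n)
  lo <- 1
  for (k in seq_len(n)) {
    hi <- lo + 0.1
    while (f(lo) * f(hi) > 0) {
      hi <- hi + 0.1
      if (hi - lo > 2 * pi) stop("failed to bracket j1' root ", k)
    }
    roots[k] <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
    lo <- roots[k] + 2
  }
  roots_cache[[key]] <- roots
  roots
}

# psi(u; delta, Delta) per axis, with a series branch for small u where the
# closed form cancels catastrophically (free-diffusion limit)
gpa_psi <- function(u, delta, Delta) {
  small <- u * (Delta + delta) < 1e-3
  out <- numeric(length(u))
  us <- u[small]
  out[small] <- us^3 * delta^2 * (Delta - delta / 3) - us^4 * Delta^2 * delta^2 / 2
  ul <- u[!small]
  out[!small] <- 2 * (ul * delta - 1 + exp(-ul * delta) + exp(-ul * Delta) -
                        0.5 * exp(-ul * (Delta - delta)) -
                        0.5 * exp(-ul * (Delta + delta)))
  out
}

gpa_effective_diffusivity <- function(r, D0, delta, Delta, geometry = c("cylinder", "sphere"),
                                      n_roots = 20) {
  geometry <- match.arg(geometry)
  if (r < 0) stop("radius must be nonnegative")
  if (D0 <= 0) stop("D0 must be positive")
  if (delta <= 0 || Delta < delta) stop("need 0 < delta <= Delta")
  if (r == 0) return(0)
  mu <- if (geometry == "cylinder") bessel_j1prime_roots(n_roots) else
    sphere_j1prime_roots(n_roots)
  s <- if (geometry == "cylinder") 1 else 2
  ck <- 2 * r^2 / (mu^2 * (mu^2 - s))
  u <- D0 * mu^2 / r^2
  terms <- ck / u^2 * gpa_psi(u, delta, Delta)   # (D0 a_k^2) = u
  lnE_per_g2 <- sum(terms)                       # times -(gamma g)^2
  if (n_roots >= 2) {
    tail_ratio <- abs(terms[n_roots]) / max(sum(abs(terms)), .Machine$double.xmin)
    if (tail_ratio > 1e-2) stop("GPA Bessel-root series not converged; increase n_roots")
  }
  Deff <- lnE_per_g2 / (delta^2 * (Delta - delta / 3))
  min(max(Deff, 0), D0)
}

#' Effective perpendicular diffusivity of a restricted cylinder
#'
#' Maps the Gaussian-phase-approximation (van Gelderen) attenuation of
#' diffusion restricted perpendicular to an impermeable cylinder of radius
#' `r` to an effective diffusivity \eqn{D_\perp^{eff} = -\ln E_\perp / b},
#' for rectangular pulsed gradients of width `delta` and separation `Delta`.
#' `D_perp_eff` is 0 at `r = 0` (stick) and tends to `D0` for radii much
#' larger than the diffusion length.
#'
#' @param r cylinder radius, um.
#' @param D0 intrinsic diffusivity, um^2/ms.
#' @param delta gradient pulse width, ms.
#' @param Delta pulse separation, ms (`delta <= Delta`).
#' @param n_roots number of Bessel-root terms (roots of J1').
#' @return effective perpendicular diffusivity in `[0, D0]`, um^2/ms.
#' @export
#' @examples
#' cylinder_perp_diffusivity(0, 2, 15, 30)    # 0: a stick
#' cylinder_perp_diffusivity(1, 2, 15, 30)    # small but nonzero
cylinder_perp_diffusivity <- function(r, D0, delta, Delta, n_roots = 20) {
  gpa_effective_diffusivity(r, D0, delta, Delta, "cylinder", n_roots)
}

#' Powder-averaged finite-radius cylinder signal
#'
#' Composes the cylinder's effective perpendicular diffusivity with the
#' closed-form powder average: equals
#' `powder_signal(b, b_delta, d_par, D_perp_eff(r))`. Reduces to the stick
#' results at `r = 0`.
#'
#' @inheritParams powder_signal
#' @param r cylinder radius, um.
#' @param timing list with `delta`, `Delta` (ms) and `D0` (um^2/ms).
#' @export
cylinder_powder_signal <- function(b, b_delta, d_par, r,
                                   timing = list(delta = 15, Delta = 30, D0 = 2)) {
  dp <- cylinder_perp_diffusivity(r, timing$D0, timing$delta, timing$Delta)
  powder_signal(b, b_delta, d_par, dp)
}

#' Restricted sphere (and dot) signal
#'
#' Isotropic attenuation \eqn{\exp(-b D_s^{eff})} of diffusion restricted in
#' an impermeable sphere of radius `R_s`, with the effective diffusivity from
#' the Gaussian-phase-approximation series at the protocol timing. By
#' isotropy the signal is independent of the b-tensor shape and direction.
#' `R_s = 0` is the "dot" (still water) compartment: signal 1 at every b.
#'
#' @param b b-value(s), ms/um^2.
#' @param R_s sphere radius, um (`0` = dot).
#' @param timing list with `delta`, `Delta` (ms), `D0` (um^2/ms).
#' @param n_roots Bessel-root terms (roots of j1').
#' @export
#' @examples
#' sphere_signal(5, 0)    # 1: dot compartment
#' sphere_signal(5, 8)    # restricted sphere, R_s = 8 um
sphere_signal <- function(b, R_s, timing = list(delta = 15, Delta = 30, D0 = 2),
                          n_roots = 20) {
  if (any(b < 0)) stop("b must be nonnegative")
  if (R_s == 0) return(rep(1, length(b)))
  ds <- gpa_effective_diffusivity(R_s, timing$D0, timing$delta, timing$Delta,
                                  "sphere", n_roots)
  exp(-b * ds)
}

#' Axon radius histogram
#'
#' Radius distribution used to average the cylinder signal over axon
#' calibers, with weights proportional to bin count times \eqn{r^2} (volume
#' weighting) and a shrinkage factor `eta` multiplying every radius
#' (`eta = 0` collapses every axon to a stick). The packaged default,
#' `default_radius_histogram()`, is a synthetic 10-bin discretized lognormal
#' stand-in (median 0.6 um, sigma_log 0.45) shipped as
#' `extdata/axon_radius_hist_synthetic.tsv`; real histology histograms can be
#' loaded with `read_radius_histogram()` from a two-column TSV
#' (radius_um, count).
#'
#' @param radii bin-centre radii, um.
#' @param counts nonnegative bin weights, summing to > 0.
#' @param eta shrinkage factor, dimensionless.
#' @return object of class `radius_histogram`.
#' @export
radius_histogram <- function(radii, counts, eta = 1) {
  stopifnot(length(radii) == length(counts))
  if (any(radii < 0) || any(counts < 0) || sum(counts) <= 0) {
    stop("radii must be >= 0, counts >= 0 with positive sum")
  }
  structure(list(radii = radii, counts = counts, eta = eta),
            class = "radius_histogram")
}

#' @rdname radius_histogram
#' @param eta shrinkage factor for the packaged default.
#' @export
default_radius_histogram <- function(eta = 1) {
  f <- system.file("extdata", "axon_radius_hist_synthetic.tsv",
                   package = "powderlaw", mustWork = TRUE)
  read_radius_histogram(f, eta = eta)
}

#' @rdname radius_histogram
#' @param path two-column TSV (radius_um, count) with header.
#' @export
read_radius_histogram <- function(path, eta = 1) {
  d <- utils::read.delim(path)
  radius_histogram(d$radius_um, d$count, eta = eta)
}

#' Radius-weighted signal average
#'
#' Averages a per-radius signal over a [radius_histogram()], weighting each
#' bin by `count * r^2` and evaluating the signal at the shrunk radius
#' `eta * r`. With `eta = 0` this returns `signal_fn(0)` (the stick signal)
#' for any histogram.
#'
#' @param signal_fn function of a single radius (um) returning a signal.
#' @param histogram a `radius_histogram`.
#' @return weighted average of `signal_fn(eta * r_i)`.
#' @export
radius_weighted_average <- function(signal_fn, histogram) {
  stopifnot(inherits(histogram, "radius_histogram"))
  w <- histogram$counts * histogram$radii^2
  if (sum(w) <= 0) stop("all radius weights are zero (counts * r^2)")
  w <- w / sum(w)
  vals <- lapply(histogram$radii * histogram$eta, signal_fn)
  Reduce(`+`, Map(`*`, vals, w))
}
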