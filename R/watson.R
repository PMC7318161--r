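#' Watson orientation density
#'
#' Antipodally symmetric axial distribution on the unit sphere,
#' \deqn{W(n) = \frac{\exp\left(\kappa (\mu\cdot n)^2\right)}
#'                   {4\pi\, M(1/2, 3/2, \kappa)},}
#' with concentration `kappa >= 0` around the mean axis `mu` and the Kummer
#' confluent hypergeometric normalizer ([kummer_m_half()]). Integrates to 1
#' over the sphere; `kappa = 0` is the uniform density \eqn{1/4\pi}.
#'
#' @param n unit vector(s): length-3 vector or m x 3 matrix.
#' @param mu mean orientation, unit length-3 vector.
#' @param kappa concentration, `>= 0`.
#' @return density value(s).
#' @export
#' @examples
#' watson_density(c(0,0,1), c(0,0,1), 0)    # 1/(4*pi)
watson_density <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be nonnegative")
  if (is.null(dim(n))) n <- matrix(n, ncol = 3)
  ct <- as.vector(n %*% mu)
  exp(kappa * ct^2) / (4 * pi * kummer_m_half(kappa))
}

#' Spherical quadrature grid
#'
#' Product quadrature on the unit sphere: Gauss-Legendre nodes in
#' \eqn{\cos\theta} times an equally spaced (trapezoidal, exact for
#' trigonometric polynomials) azimuthal grid. Weights sum to \eqn{4\pi}.
#' For integrands concentrated at the poles by a Watson factor with large
#' `kappa` (boundary-layer width \eqn{\sim 1/\sqrt\kappa}), pass `kappa` to
#' switch the polar rule to a Gauss-Laguerre rule in the stretched variable
#' \eqn{x = \kappa(1 - \cos^2\theta)}, which stays accurate for
#' arbitrarily large concentrations. In that case the returned weights
#' *include* the factor \eqn{e^{\kappa(\cos^2\theta - 1)}}, i.e. they are
#' weights for \eqn{\int f(n) e^{\kappa((\mu_z\cdot n)^2 - 1)} d\Omega} with
#' the concentration axis along +z; use `watson_weights()` below rather than
#' multiplying by the density again.
#'
#' @param n_theta polar nodes; @param n_phi azimuthal nodes.
#' @param kappa optional concentration for the boundary-layer rule
#'   (used when `kappa > 30`).
#' @return list with `nodes` (Q x 3) and `weights` (length Q).
#' @keywords internal
sphere_quadrature <- function(n_theta = 48, n_phi = 96, kappa = 0) {
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  wphi <- rep(2 * pi / n_phi, n_phi)
  if (kappa <= 30) {
    gl <- gauss_legendre(n_theta)
    t <- gl$nodes
    wt <- gl$weights
    damp <- rep(1, length(t))         # no Watson factor folded in
  } else {
    # boundary layer at t = +-1: x = kappa (1 - t^2), Gauss-Laguerre in x.
    # e^{kappa t^2} = e^{kappa} e^{-x}; fold e^{kappa(t^2 - 1)} = e^{-x}
    # into the weights (both hemispheres).
    gla <- gauss_laguerre(ceiling(n_theta / 2))
    keep <- gla$nodes < 0.999 * kappa
    x <- gla$nodes[keep]
    wx <- gla$weights[keep]
    tpos <- sqrt(1 - x / kappa)
    jac <- 1 / (2 * kappa * tpos)     # |dt/dx|
    t <- c(tpos, -tpos)
    wt <- rep(wx * jac, 2)            # weights already contain e^{-x}
    damp <- rep(1, length(t))
  }
  nodes <- matrix(0, length(t) * n_phi, 3)
  wts <- numeric(length(t) * n_phi)
  s <- sqrt(pmax(1 - t^2, 0))
  idx <- 1
  for (i in seq_along(t)) {
    rng <- idx:(idx + n_phi - 1)
    nodes[rng, 1] <- s[i] * cos(phi)
    nodes[rng, 2] <- s[i] * sin(phi)
    nodes[rng, 3] <- t[i]
    wts[rng] <- wt[i] * wphi * damp[i]
    idx <- idx + n_phi
  }
  list(nodes = nodes, weights = wts, boundary_layer = kappa > 30, kappa = kappa)
}

# Normalized Watson quadrature weights for orientation integrals
# int W(n) f(n) dOmega ~= sum w_q f(n_q). Rotates the grid so its pole is
# along mu; renormalizes to unit sum (removes residual quadrature error in
# the normalizer).
watson_weights <- function(quad, mu, kappa) {
  z <- mu / sqrt(sum(mu^2))
  ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  x <- ref - z * sum(ref * z)
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- cbind(x, y, z, deparse.level = 0)
  nodes <- quad$nodes %*% t(R)
  t2 <- pmin(as.vector(nodes %*% z)^2, 1)
  w <- if (quad$boundary_layer) {
    # weights already include e^{kappa (t^2 - 1)}
    quad$weights
  } else {
    quad$weights * exp(kappa * (t2 - 1))
  }
  list(nodes = nodes, weights = w / sum(w))
}
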