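# Independent numerical oracles used across the suite.

# Dawson function by direct quadrature of its definition.
dawson_oracle <- function(x) {
  vapply(x, function(xx) {
    stats::integrate(function(t) exp(t^2 - xx^2), 0, xx,
                     rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
}

# Uniform sphere average of the per-direction compartment signal, on a dense
# product grid; checks the closed-form powder average from direction space.
sphere_average_oracle <- function(b, b_delta, d_par, d_perp,
                                  n_theta = 64, n_phi = 128) {
  q <- powderlaw:::sphere_quadrature(n_theta, n_phi)
  s <- compartment_signal_direction(b, b_delta, q$nodes, d_par, d_perp,
                                    c(0, 0, 1))
  sum(s * q$weights) / (4 * pi)
}

# Gaussian-phase-approximation phase variance by numerical time integration
# of the displacement autocorrelation C(tau) = sum_k c_k exp(-u_k tau) over
# the two rectangular gradient pulses; independent of the closed-form time
# integrals used by the implementation. Returns the effective diffusivity.
gpa_oracle_deff <- function(r, D0, delta, Delta,
                            geometry = c("cylinder", "sphere"),
                            n_roots = 60, n_gauss = 60) {
  geometry <- match.arg(geometry)
  if (r == 0) return(0)
  mu <- if (geometry == "cylinder") powderlaw:::bessel_j1prime_roots(n_roots)
        else powderlaw:::sphere_j1prime_roots(n_roots)
  s <- if (geometry == "cylinder") 1 else 2
  ck <- 2 * r^2 / (mu^2 * (mu^2 - s))
  u <- D0 * mu^2 / r^2
  gl <- powderlaw:::gauss_legendre(n_gauss)
  # map [-1,1] -> [a,b]
  map <- function(a, b) list(x = (gl$nodes + 1) / 2 * (b - a) + a,
                             w = gl$weights / 2 * (b - a))
  # integral of (delta - |tau|) e^{-u(tau + off)} over tau in [lo, hi];
  # the domain is clipped where the exponential has fully decayed so the
  # fixed-order rule resolves fast decays (small radii)
  tri <- function(uk, off, lo, hi) {
    hi <- min(hi, lo + 80 / uk)
    m <- map(lo, hi)
    sum(m$w * (delta - abs(m$x)) * exp(-uk * (m$x + off)))
  }
  var_phi <- 0
  for (k in seq_along(mu)) {
    # diagonal square: int int over [0,delta]^2 of e^{-u|t-t'|}
    # = 2 * int_0^delta (delta - tau) e^{-u tau} dtau
    i_diag <- 2 * tri(u[k], 0, 0, delta)
    # cross square [0,delta] x [Delta, Delta+delta] (opposite pulse signs):
    # = int_{-delta}^{delta} (delta - |tau|) e^{-u (Delta + tau)} dtau
    i_cross <- tri(u[k], Delta, -delta, delta)
    var_phi <- var_phi + ck[k] * (2 * i_diag - 2 * i_cross)
  }
  # ln E = -var_phi/2 per (gamma g)^2; D_eff = -lnE / (delta^2 (Delta - delta/3))
  (var_phi / 2) / (delta^2 * (Delta - delta / 3))
}

# best-of-restarts oracle for the repulsion scheme quality
best_min_angle <- function(n, n_restarts, iters = 300) {
  max(vapply(seq_len(n_restarts), function(r) {
    X <- powderlaw:::repulsion_set(n, seed = 7000 + r, iters = iters,
                                   restarts = 1)
    powderlaw:::min_pairwise_angle(X)
  }, numeric(1)))
}

# log-log slope of a signal curve over a bD window
loglog_slope <- function(fn, lo = 100, hi = 1000, n = 25) {
  bD <- exp(seq(log(lo), log(hi), length.out = n))
  S <- fn(bD)
  stats::coef(stats::lm(log(S) ~ log(bD)))[[2]]
}
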