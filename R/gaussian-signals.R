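#' Per-direction Gaussian compartment signal
#'
#' Signal fraction \eqn{\exp(-\mathrm{tr}(B D))} of an axially symmetric
#' Gaussian compartment with diffusion tensor
#' \eqn{D = (D_\parallel - D_\perp)\, n n^T + D_\perp I} probed by the
#' axisymmetric b-tensor `(b, b_delta, g)`. With `c = g . n`,
#' \deqn{\mathrm{tr}(BD) = \tfrac{b}{3}(1-b_\Delta)(D_\parallel + 2D_\perp)
#'   + b\,b_\Delta\,(D_\perp + (D_\parallel - D_\perp)c^2).}
#' Vectorized over `b`, `b_delta` and rows of `g`.
#'
#' @param b b-value(s), ms/um^2.
#' @param b_delta shape parameter(s) in `[-0.5, 1]`.
#' @param g encoding symmetry axis: length-3 vector or n x 3 matrix.
#' @param d_par,d_perp parallel/perpendicular diffusivities, um^2/ms, `>= 0`.
#' @param axis compartment symmetry axis, unit length-3 vector.
#' @return signal fraction(s) in (0, 1]; 1 at `b = 0`.
#' @export
#' @examples
#' compartment_signal_direction(1, 1, c(0,0,1), 2, 0, c(0,0,1))  # exp(-2)
#' compartment_signal_direction(1, 1, c(1,0,0), 2, 0, c(0,0,1))  # 1 (stick _|_ g)
compartment_signal_direction <- function(b, b_delta, g, d_par, d_perp, axis) {
  if (d_par < 0 || d_perp < 0) stop("diffusivities must be nonnegative")
  check_b_delta(b_delta)
  if (is.null(dim(g))) g <- matrix(g, ncol = 3)
  c2 <- as.vector(g %*% axis)^2
  tr_bd <- b / 3 * (1 - b_delta) * (d_par + 2 * d_perp) +
    b * b_delta * (d_perp + (d_par - d_perp) * c2)
  exp(-tr_bd)
}

# kernel K(z) = sqrt(pi) * erf(sqrt(z)) / (2 sqrt(z)), analytically continued
# to z < 0 where it becomes e^{|z|} D(sqrt(|z|)) / sqrt(|z|); near z = 0 a
# Taylor series keeps the branches continuous (K(0) = 1).
powder_kernel <- function(z, eps = 1e-9) {
  out <- numeric(length(z))
  small <- abs(z) <= 1e-4
  pos <- z > 1e-4
  neg <- z < -1e-4
  zs <- z[small]
  out[small] <- 1 - zs / 3 + zs^2 / 10 - zs^3 / 42 + zs^4 / 216
  if (any(pos)) {
    sz <- sqrt(z[pos])
    out[pos] <- sqrt(pi) * erf_base(sz) / (2 * sz)
  }
  if (any(neg)) {
    y <- sqrt(-z[neg])
    out[neg] <- exp(y^2) * dawson(y) / y
  }
  out
}

erf_base <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Powder-averaged Gaussian compartment signal
#'
#' Closed-form orientation average of [compartment_signal_direction()] over a
#' uniform axis distribution:
#' \deqn{\bar S(b) = \sqrt{\pi}\,
#'   e^{-\frac{b}{3}\left(D_\parallel + 2D_\perp -
#'       b_\Delta (D_\parallel - D_\perp)\right)}
#'   \frac{\mathrm{erf}\!\left(\sqrt{b\,b_\Delta (D_\parallel - D_\perp)}\right)}
#'        {2\sqrt{b\,b_\Delta (D_\parallel - D_\perp)}}.}
#' For negative argument \eqn{z = b\,b_\Delta(D_\parallel - D_\perp)} the
#' error function becomes imaginary and the expression is evaluated
#' overflow-free through the Dawson function; for \eqn{|z|} below a branch
#' threshold a series limit gives the spherical-encoding exponential
#' \eqn{\exp(-b(D_\parallel + 2D_\perp)/3)}. The three branches are
#' continuous.
#'
#' @inheritParams compartment_signal_direction
#' @return powder-averaged signal fraction(s); 1 at `b = 0`.
#' @export
#' @examples
#' powder_signal(3, 0, 2, 0.5)     # exp(-3), isotropic encoding
#' powder_signal(7, -0.5, 2, 0)    # 0.0784..., planar stick, bD = 14
#' powder_signal(7, 1, 2, 0)       # 0.2369..., linear stick, bD = 14
powder_signal <- function(b, b_delta, d_par, d_perp) {
  if (any(d_par < 0) || any(d_perp < 0)) stop("diffusivities must be nonnegative")
  check_b_delta(b_delta)
  n <- max(length(b), length(b_delta), length(d_par), length(d_perp))
  b <- rep_len(b, n); b_delta <- rep_len(b_delta, n)
  d_par <- rep_len(d_par, n); d_perp <- rep_len(d_perp, n)
  z <- b * b_delta * (d_par - d_perp)
  expo <- -b / 3 * (d_par + 2 * d_perp - b_delta * (d_par - d_perp))
  # combine exponent with the e^{|z|} factor of the Dawson branch before
  # exponentiating, so large-b planar signals do not overflow
  out <- numeric(n)
  neg <- z < -1e-4
  if (any(neg)) {
    y <- sqrt(-z[neg])
    out[neg] <- exp(expo[neg] + y^2) * dawson(y) / y
  }
  if (any(!neg)) out[!neg] <- exp(expo[!neg]) * powder_kernel(z[!neg])
  out
}

#' Spherical tensor encoding signal
#'
#' Pure exponential \eqn{\exp(-b (D_\parallel + 2 D_\perp)/3)}; the
#' `b_delta = 0` limit of [powder_signal()] (for a stick,
#' \eqn{\exp(-b D_\parallel / 3)}).
#'
#' @inheritParams powder_signal
#' @export
ste_signal <- function(b, d_par, d_perp = 0) {
  exp(-b * (d_par + 2 * d_perp) / 3)
}

#' Planar-encoding stick signal
#'
#' The powder-averaged signal of a stick (\eqn{D_\perp = 0}) under pure
#' planar encoding, as a function of the dimensionless weighting
#' \eqn{bD = b D_{a\parallel}}:
#' \deqn{S(bD) = \sqrt{\pi}\, e^{-bD/2}\,
#'   \frac{\mathrm{erfi}(\sqrt{bD/2})}{2\sqrt{bD/2}}
#'   = \frac{D(\sqrt{bD/2})}{\sqrt{bD/2}},}
#' where \eqn{D(\cdot)} is the Dawson function ([dawson()]), which keeps the
#' evaluation overflow-free at arbitrarily large `bD`. Tends to 1 as
#' `bD -> 0` and to `1/bD` as `bD -> Inf` (the 1/b power law).
#'
#' @param bD dimensionless `b * D_par`, `>= 0`.
#' @export
#' @examples
#' pte_stick_signal(c(0, 3, 14))   # 1, 0.4097, 0.0784
pte_stick_signal <- function(bD) {
  if (any(bD < 0)) stop("bD must be nonnegative")
  x <- sqrt(bD / 2)
  ifelse(bD == 0, 1, dawson(x) / x)
}

#' Asymptotic expansion of the planar stick signal
#'
#' High-b approximation
#' \deqn{\hat S(bD) = \frac{1}{bD}\sum_{k=0}^{N} \frac{(2k-1)!!}{(bD)^k},}
#' with the convention \eqn{(-1)!! = 1} so the `k = 0` term is `1/bD`. The
#' series is asymptotic (divergent): for fixed `bD` the error is smallest
#' for a truncation order no larger than about `floor(bD)` and grows beyond
#' it.
#'
#' @param bD dimensionless `b * D_par`, `> 0`.
#' @param N truncation order (the sum runs k = 0..N), `N >= 0`.
#' @return list of class `pte_asymptotic` with `N`, `bD`, `value` and
#'   `normalized_error` relative to the exact [pte_stick_signal()].
#' @export
#' @examples
#' pte_asymptotic(10, 0)$value    # 0.1
#' pte_asymptotic(10, 2)$value    # 0.113
pte_asymptotic <- function(bD, N) {
  stopifnot(bD > 0, N >= 0)
  k <- 0:N
  value <- sum(double_factorial_odd(k) / bD^k) / bD
  exact <- pte_stick_signal(bD)
  structure(list(N = as.integer(N), bD = bD, value = value,
                 normalized_error = normalized_error(exact, value)),
            class = "pte_asymptotic")
}

#' @export
print.pte_asymptotic <- function(x, ...) {
  cat(sprintf("PTE stick asymptotic series: bD = %g, N = %d\n", x$bD, x$N))
  cat(sprintf("  value = %.6g, normalized error vs exact = %.3g\n",
              x$value, x$normalized_error))
  invisible(x)
}

#' Normalized approximation error
#'
#' \eqn{|S - \hat S| / S} between an exact signal `s_exact > 0` and an
#' approximation `s_approx`.
#'
#' @param s_exact exact signal, `> 0`; @param s_approx approximated signal.
#' @export
normalized_error <- function(s_exact, s_approx) {
  if (any(s_exact <= 0)) stop("s_exact must be positive")
  abs(s_exact - s_approx) / s_exact
}

#' Minimum truncation order table
#'
#' For each error threshold and each `bD`, the smallest truncation order `N`
#' (searched over `N = 0..floor(bD)`, past which the asymptotic series
#' diverges) whose normalized error does not exceed the threshold; `NA` when
#' no order qualifies.
#'
#' @param bD_grid positive dimensionless weightings.
#' @param thresholds error thresholds in (0, 1).
#' @return integer matrix, rows = thresholds, columns = `bD_grid`.
#' @export
#' @examples
#' min_terms_table(c(10, 20), c(0.01, 0.5))
min_terms_table <- function(bD_grid = 3:20,
                            thresholds = c(0.06, 0.05, 0.04, 0.03, 0.02, 0.01)) {
  stopifnot(all(bD_grid > 0), all(thresholds > 0 & thresholds < 1))
  out <- matrix(NA_integer_, length(thresholds), length(bD_grid),
                dimnames = list(format(thresholds), format(bD_grid)))
  for (j in seq_along(bD_grid)) {
    bD <- bD_grid[j]
    Ns <- 0:floor(bD)
    errs <- vapply(Ns, function(N) pte_asymptotic(bD, N)$normalized_error,
                   numeric(1))
    for (i in seq_along(thresholds)) {
      ok <- which(errs <= thresholds[i])
      if (length(ok)) out[i, j] <- Ns[ok[1]]
    }
  }
  out
}

#' Power-law existence classifier
#'
#' Decides whether the powder-averaged signal of an axially symmetric
#' Gaussian compartment under shape `b_delta` decays as a power law
#' \eqn{b^{-\alpha}} at high b, and with which exponent. Setting the
#' exponential prefactor of the closed form to one requires
#' \eqn{D_\perp / D_\parallel = (b_\Delta - 1)/(b_\Delta + 2)} (negative for
#' any admissible shape except the endpoints), so a power law exists only in
#' three cases:
#'
#' * `b_delta = 1`, stick (`d_perp = 0`, `d_par > 0`): `alpha = 1/2`;
#' * `b_delta = -1/2`, stick: `alpha = 1`;
#' * `b_delta = 1`, pancake (`d_par = 0`, `d_perp > 0`): `alpha = 1`.
#'
#' Everything else decays exponentially (super-polynomially). Equalities are
#' tested with tolerance 1e-9.
#'
#' @inheritParams powder_signal
#' @return list with `exists` (logical) and `alpha` (exponent or `NA`).
#' @export
#' @examples
#' powerlaw_condition(1, 2, 0)      # stick, LTE: alpha = 1/2
#' powerlaw_condition(-0.5, 2, 0)   # stick, PTE: alpha = 1
#' powerlaw_condition(0, 2, 0)      # STE: no power law
powerlaw_condition <- function(b_delta, d_par, d_perp, tol = 1e-9) {
  check_b_delta(b_delta)
  if (d_par < 0 || d_perp < 0) stop("diffusivities must be nonnegative")
  is1 <- abs(b_delta - 1) <= tol
  isP <- abs(b_delta + 0.5) <= tol
  stick <- d_perp <= tol && d_par > tol
  pancake <- d_par <= tol && d_perp > tol
  if (is1 && stick) return(list(exists = TRUE, alpha = 0.5))
  if (isP && stick) return(list(exists = TRUE, alpha = 1))
  if (is1 && pancake) return(list(exists = TRUE, alpha = 1))
  list(exists = FALSE, alpha = NA_real_)
}
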