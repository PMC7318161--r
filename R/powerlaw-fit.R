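#' Fit a power law to a direction-averaged decay curve
#'
#' Least-squares fit of \deqn{S(b) = \beta\, b^{-\alpha}} to a
#' powder-averaged, b0-normalized signal curve, in linear signal space, by
#' bounded trust-region Levenberg-Marquardt iteration from the fixed start
#' `(alpha, beta) = (1, 0.2)` with bounds `alpha` in `[0, 5]`, `beta` in
#' `[0, 10]`. `b` is in ms/um^2 so that `beta` is on the scale of
#' `fraction / diffusivity`. Goodness of fit is summarized by
#' \deqn{BIC = n \ln(RSS/n) + p \ln(n), \quad p = 2.}
#'
#' For stick-like tissue the theoretical exponents are `alpha = 1/2`
#' (linear encoding) and `alpha = 1` (planar encoding), with
#' `beta ~ f / D_par` for the planar case at large b.
#'
#' @param b shell b-values, ms/um^2 (use `b_smm2/1000` for s/mm^2 input).
#' @param S direction-averaged, b0-normalized signals, same length as `b`.
#' @param b_range fit window `c(lo, hi)` in ms/um^2, default `c(7, 10)`
#'   (7000-10000 s/mm^2); at least 2 shells must fall inside.
#' @param start,lower,upper optimizer initialization and bounds,
#'   `c(alpha, beta)`.
#' @return object of class `powerlaw_fit` with components `alpha`, `beta`,
#'   `rss`, `bic`, `n_points`, `converged`, `b`, `S`, `fitted`.
#' @seealso [powder_average()], [alpha_map()]
#' @export
#' @examples
#' b <- c(7, 8, 9, 10)
#' fit <- fit_powerlaw(b, 0.3 * b^-1)
#' coef(fit)                      # alpha = 1, beta = 0.3
#' predict(fit, newdata = data.frame(b = 12))
fit_powerlaw <- function(b, S, b_range = c(7, 10),
                         start = c(alpha = 1, beta = 0.2),
                         lower = c(0, 0), upper = c(5, 10)) {
  stopifnot(length(b) == length(S))
  sel <- b >= b_range[1] & b <= b_range[2]
  if (sum(sel) < 2) stop("need at least 2 shells inside b_range")
  b <- b[sel]
  S <- S[sel]
  if (any(!is.finite(S)) || any(S <= 0)) {
    stop("non-positive or non-finite signals in the fit window")
  }
  resid_fn <- function(p) S - p[2] * b^(-p[1])
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  opt <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn, control = ctl)
  alpha <- unname(opt$par[1])
  beta <- unname(opt$par[2])
  n <- length(b)
  rss <- sum(opt$fvec^2)
  at_bound <- any(abs(c(alpha, beta) - lower) < 1e-10) ||
    any(abs(c(alpha, beta) - upper) < 1e-10)
  converged <- opt$info %in% 1:3 && !at_bound
  structure(list(alpha = alpha, beta = beta, rss = rss,
                 bic = n * log(rss / n) + 2 * log(n),
                 n_points = n, converged = converged,
                 b = b, S = S, fitted = beta * b^(-alpha),
                 optim_info = opt$info, message = opt$message),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, digits = 4, ...) {
  cat("Power-law fit S(b) = beta * b^-alpha  (b in ms/um^2)\n")
  cat(sprintf("  alpha = %.*g, beta = %.*g\n", digits, x$alpha, digits, x$beta))
  cat(sprintf("  %d shells, RSS = %.3g, BIC = %.4g%s\n", x$n_points, x$rss,
              x$bic, if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  out <- data.frame(b = object$b, S = object$S, fitted = object$fitted,
                    residual = object$S - object$fitted)
  cat("Power-law fit S(b) = beta * b^-alpha\n\n")
  print(data.frame(alpha = object$alpha, beta = object$beta,
                   rss = object$rss, bic = object$bic,
                   n = object$n_points, converged = object$converged),
        row.names = FALSE)
  cat("\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
predict.powerlaw_fit <- function(object, newdata = NULL, ...) {
  b <- if (is.null(newdata)) object$b else newdata$b
  object$beta * b^(-object$alpha)
}

#' @export
residuals.powerlaw_fit <- function(object, ...) {
  object$S - object$fitted
}

#' @export
plot.powerlaw_fit <- function(x, ...) {
  inv_b <- 1 / x$b
  graphics::plot(inv_b, x$S, xlab = "1/b (um^2/ms)",
                 ylab = "direction-averaged S/S0",
                 main = sprintf("S = %.3g b^-%.3g", x$beta, x$alpha), ...)
  o <- order(inv_b)
  graphics::lines(inv_b[o], x$fitted[o], lty = 2, col = "red")
  invisible(x)
}

#' @export
simulate.powerlaw_fit <- function(object, nsim = 1, seed = NULL,
                                  sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- sqrt(object$rss / object$n_points)
  replicate(nsim, add_rician_noise(object$fitted, sigma), simplify = FALSE)
}
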