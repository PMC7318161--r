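#' Uniform gradient direction schemes
#'
#' Generates `n` unit vectors approximately uniformly distributed with
#' antipodal symmetry by minimizing the antipodal electrostatic (Coulomb)
#' energy
#' \deqn{E = \sum_{i<j} \left( \|x_i - x_j\|^{-1} + \|x_i + x_j\|^{-1} \right)}
#' with projected-gradient descent from several random starts, keeping the
#' lowest-energy configuration. This is the standard construction for
#' diffusion-encoding schemes, where `g` and `-g` are equivalent. A faster
#' deterministic Fibonacci-hemisphere lattice is available as a fallback; it
#' is noticeably less uniform and should not be used for the rotational
#' invariance analyses.
#'
#' @param n number of directions, `n >= 1`.
#' @param seed integer seed; the scheme is deterministic given `(n, seed)`.
#' @param method `"repulsion"` (default) or `"fibonacci"`.
#' @param iters gradient-descent iterations per restart.
#' @param restarts random restarts (best-of).
#' @return object of class `direction_set`: list with `vectors` (n x 3,
#'   unit rows), `n_dirs`, `seed`.
#' @export
#' @examples
#' d <- generate_directions(6, seed = 1)
#' range(rowSums(d$vectors^2))   # all 1
generate_directions <- function(n, seed = 42,
                                method = c("repulsion", "fibonacci"),
                                iters = 300, restarts = 10) {
  if (n < 1) stop("n must be >= 1")
  method <- match.arg(method)
  X <- if (n == 1) {
    matrix(c(0, 0, 1), 1, 3)
  } else if (method == "fibonacci") {
    fibonacci_hemisphere(n)
  } else {
    repulsion_set(n, seed, iters, restarts)
  }
  structure(list(vectors = X, n_dirs = as.integer(n), seed = seed,
                 method = method),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("direction_set: %d unit vectors (%s, seed %s)\n",
              x$n_dirs, x$method, format(x$seed)))
  if (x$n_dirs > 1) {
    cat(sprintf("  minimum antipodal pairwise angle: %.2f deg\n",
                min_pairwise_angle(x$vectors)))
  }
  invisible(x)
}

# smallest antipodal angle (degrees) between any two directions
min_pairwise_angle <- function(X) {
  G <- abs(X %*% t(X))
  diag(G) <- 0
  acos(min(1, max(G))) * 180 / pi
}

antipodal_energy <- function(X) {
  G <- X %*% t(X)
  G[G > 1] <- 1; G[G < -1] <- -1
  dm <- sqrt(pmax(2 - 2 * G, 0)); dp <- sqrt(2 + 2 * G)
  diag(dm) <- Inf; diag(dp) <- Inf
  sum(1 / dm + 1 / dp) / 2
}

repulsion_set <- function(n, seed, iters, restarts) {
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  best <- NULL
  best_e <- Inf
  for (r in seq_len(restarts)) {
    set.seed(seed + 1000L * (r - 1L))
    X <- matrix(stats::rnorm(n * 3), n, 3)
    X <- X / sqrt(rowSums(X^2))
    step <- 0.1
    e <- antipodal_energy(X)
    for (it in seq_len(iters)) {
      G <- X %*% t(X)
      G[G > 1] <- 1; G[G < -1] <- -1
      d2m <- 2 - 2 * G; d2p <- 2 + 2 * G
      diag(d2m) <- Inf; diag(d2p) <- Inf
      cm <- d2m^(-1.5); cp <- d2p^(-1.5)
      # Coulomb force on each point from charges and antipodes
      Fi <- rowSums(cm) * X - cm %*% X + rowSums(cp) * X + cp %*% X
      Fi <- Fi - X * rowSums(Fi * X)            # tangential component
      nrm <- max(sqrt(rowSums(Fi^2)))
      if (nrm == 0) break
      Xn <- X + step * Fi / nrm
      Xn <- Xn / sqrt(rowSums(Xn^2))
      en <- antipodal_energy(Xn)
      if (en < e) {
        X <- Xn; e <- en; step <- step * 1.05
      } else {
        step <- step * 0.5
      }
      if (step < 1e-9) break
    }
    if (e < best_e) {
      best_e <- e
      best <- X
    }
  }
  best
}

fibonacci_hemisphere <- function(n) {
  i <- seq(0, n - 1)
  phi <- (1 + sqrt(5)) / 2
  z <- (i + 0.5) / n
  th <- 2 * pi * i / phi
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(th), s * sin(th), z)
}

#' Uniformly distributed rotation set
#'
#' Builds `m` rotation matrices whose images of the z-axis form a
#' uniformly distributed orientation set (electrostatic repulsion), with a
#' deterministic golden-angle roll about each axis. Used to rotate a test
#' tensor when assessing rotational invariance of the powder average.
#'
#' @param m number of rotations.
#' @param seed integer seed.
#' @param iters,restarts passed to the repulsion construction of the axes.
#' @return list of `m` 3x3 rotation matrices (orthogonal, det +1).
#' @export
generate_rotations <- function(m, seed = 42, iters = 300, restarts = 2) {
  if (m < 1) stop("m must be >= 1")
  axes <- if (m == 1) matrix(c(0, 0, 1), 1, 3) else
    repulsion_set(m, seed, iters, restarts)
  golden <- pi * (3 - sqrt(5))
  lapply(seq_len(m), function(i) {
    z <- axes[i, ]
    ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    x <- ref - z * sum(ref * z)
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    a <- golden * (i - 1)
    xr <- cos(a) * x + sin(a) * y
    yr <- -sin(a) * x + cos(a) * y
    R <- cbind(xr, yr, z, deparse.level = 0)
    R
  })
}
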