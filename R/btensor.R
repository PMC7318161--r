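#' Construct an axisymmetric b-tensor
#'
#' Builds the 3x3 b-matrix
#' \deqn{B = \frac{b}{3}(1 - b_\Delta) I + b\, b_\Delta\, g g^T}
#' whose trace is the b-value and whose shape is set by the dimensionless
#' parameter \eqn{b_\Delta = (b_\parallel - b_\perp)/(b_\parallel + 2 b_\perp)}:
#' 1 for linear (LTE), 0 for spherical (STE), -1/2 for planar (PTE) encoding.
#'
#' Units: `b` is taken in ms/um^2 throughout the package so that `b * D` is
#' dimensionless with diffusivities in um^2/ms. File I/O (bval files) uses
#' s/mm^2 and converts explicitly; see [write_bval_bvec()].
#'
#' @param b diffusion weighting, ms/um^2, `b >= 0`.
#' @param b_delta shape parameter in `[-0.5, 1]` (eigenvalue nonnegativity).
#' @param g symmetry axis, length-3 vector. Normalized with a warning when
#'   within 1e-6 of unit length, otherwise an error.
#' @return 3x3 symmetric positive-semidefinite matrix with `sum(diag(B)) == b`.
#' @export
#' @examples
#' make_btensor(1, 0, c(0, 0, 1))        # (1/3) I, spherical
#' make_btensor(1, 1, c(0, 0, 1))        # diag(0, 0, 1), pure linear
#' make_btensor(2, -0.5, c(0, 0, 1))     # diag(1, 1, 0), pure planar
make_btensor <- function(b, b_delta, g) {
  stopifnot(length(b) == 1, length(b_delta) == 1, length(g) == 3)
  if (b < 0) stop("b must be nonnegative")
  check_b_delta(b_delta)
  ng <- sqrt(sum(g^2))
  if (abs(ng - 1) > 1e-6) {
    stop("g must be a unit vector (|g| = ", format(ng), ")")
  } else if (ng != 1) {
    if (abs(ng - 1) > 1e-12) warning("normalizing g (|g| - 1 = ", format(ng - 1), ")")
    g <- g / ng
  }
  b / 3 * (1 - b_delta) * diag(3) + b * b_delta * tcrossprod(g)
}

check_b_delta <- function(b_delta) {
  if (any(b_delta < -0.5 - 1e-12 | b_delta > 1 + 1e-12)) {
    stop("b_delta must lie in [-0.5, 1] (got ", paste(b_delta, collapse = ", "), ")")
  }
  invisible(b_delta)
}

#' Shape parameter from b-tensor eigenvalues
#'
#' `b_delta_from_eigenvalues()` recovers
#' \eqn{b_\Delta = (b_\parallel - b_\perp)/(b_\parallel + 2b_\perp)} and
#' `btensor_eigenvalues()` maps the other way,
#' \eqn{b_\parallel = b(1 + 2b_\Delta)/3}, \eqn{b_\perp = b(1 - b_\Delta)/3}.
#' The two functions round-trip to machine precision.
#'
#' @param b_par,b_perp axial and radial b-tensor eigenvalues.
#' @return dimensionless shape parameter.
#' @export
b_delta_from_eigenvalues <- function(b_par, b_perp) {
  (b_par - b_perp) / (b_par + 2 * b_perp)
}

#' @rdname b_delta_from_eigenvalues
#' @param b b-value (trace); @param b_delta shape parameter.
#' @export
btensor_eigenvalues <- function(b, b_delta) {
  check_b_delta(b_delta)
  list(b_par = b * (1 + 2 * b_delta) / 3, b_perp = b * (1 - b_delta) / 3)
}

#' Multi-shell acquisition protocols
#'
#' Builds a `dwi_protocol`: a list of shells, each a `(b, b_delta, directions)`
#' triple, plus b = 0 volumes and the gradient timing used by the restricted
#' compartments. Two presets mirror common simulated and in vivo designs:
#'
#' * `"sim21"`: 21 b-values from 0 to 10000 s/mm^2 in steps of 500, 60
#'   uniformly distributed directions per shell.
#' * `"invivo10"`: 10 shells from 1000 to 10000 s/mm^2 in steps of 1000, 60
#'   directions each, with one interleaved b = 0 volume per shell.
#'
#' @param preset `"sim21"`, `"invivo10"`, or `"explicit"` with `shells` given.
#' @param b_delta shape parameter applied to every shell (scalar or one per shell).
#' @param n_dirs directions per shell for the presets.
#' @param shells for `preset = "explicit"`: data.frame with columns `b_smm2`
#'   (s/mm^2) and optionally `b_delta` and `n_dirs`.
#' @param seed RNG seed for the direction scheme.
#' @param timing list with gradient pulse width `delta` (ms), separation
#'   `Delta` (ms) and intrinsic diffusivity `D0` (um^2/ms) for restricted
#'   compartments. Defaults 15/30 ms and 2 um^2/ms.
#' @param dir_method passed to [generate_directions()].
#' @return object of class `dwi_protocol`.
#' @export
#' @examples
#' p <- build_protocol("sim21", b_delta = -0.5)
#' length(p$shells)   # 21
build_protocol <- function(preset = c("sim21", "invivo10", "explicit"),
                           b_delta = 1, n_dirs = 60, shells = NULL, seed = 42,
                           timing = list(delta = 15, Delta = 30, D0 = 2),
                           dir_method = c("repulsion", "fibonacci")) {
  preset <- match.arg(preset)
  dir_method <- match.arg(dir_method)
  if (preset == "sim21") {
    b_smm2 <- seq(0, 10000, by = 500)
    n_b0 <- 1L
  } else if (preset == "invivo10") {
    b_smm2 <- seq(1000, 10000, by = 1000)
    n_b0 <- length(b_smm2)
  } else {
    if (is.null(shells)) stop("preset 'explicit' needs a 'shells' data.frame")
    b_smm2 <- shells$b_smm2
    if (!is.null(shells$b_delta)) b_delta <- shells$b_delta
    if (!is.null(shells$n_dirs)) n_dirs <- shells$n_dirs
    n_b0 <- sum(b_smm2 == 0)
    if (n_b0 == 0) n_b0 <- 1L
  }
  if (any(b_smm2 < 0)) stop("b-values must be nonnegative")
  b_delta <- rep_len(b_delta, length(b_smm2))
  n_dirs <- rep_len(n_dirs, length(b_smm2))
  check_b_delta(b_delta)
  dirs <- generate_directions(max(n_dirs), seed = seed, method = dir_method)
  sh <- lapply(seq_along(b_smm2), function(i) {
    list(b = b_smm2[i] / 1000,           # internal ms/um^2
         b_delta = b_delta[i],
         directions = dirs$vectors[seq_len(n_dirs[i]), , drop = FALSE])
  })
  structure(list(shells = sh, n_b0 = as.integer(n_b0), timing = timing,
                 preset = preset, seed = seed),
            class = "dwi_protocol")
}

#' @export
print.dwi_protocol <- function(x, ...) {
  b <- vapply(x$shells, `[[`, numeric(1), "b")
  bd <- vapply(x$shells, `[[`, numeric(1), "b_delta")
  nd <- vapply(x$shells, function(s) nrow(s$directions), integer(1))
  cat("Multi-shell DWI protocol (", x$preset, ")\n", sep = "")
  cat(sprintf("  %d shells, b = %s ms/um^2\n", length(b),
              paste(format(range(b)), collapse = " .. ")))
  cat(sprintf("  b_delta: %s; directions/shell: %s; %d b0 volume(s)\n",
              paste(unique(bd), collapse = ", "),
              paste(unique(nd), collapse = ", "), x$n_b0))
  cat(sprintf("  timing: delta = %g ms, Delta = %g ms, D0 = %g um^2/ms\n",
              x$timing$delta, x$timing$Delta, x$timing$D0))
  invisible(x)
}

# flatten a protocol into per-volume vectors (b0 volumes first)
protocol_volumes <- function(protocol) {
  b <- c()
  bd <- c()
  g <- NULL
  shell_id <- c()
  for (i in seq_along(protocol$shells)) {
    s <- protocol$shells[[i]]
    n <- if (s$b == 0) 1L else nrow(s$directions)
    dirs <- if (s$b == 0) matrix(c(0, 0, 1), 1, 3) else s$directions
    b <- c(b, rep(s$b, n))
    bd <- c(bd, rep(s$b_delta, n))
    g <- rbind(g, dirs)
    shell_id <- c(shell_id, rep(i, n))
  }
  has_b0 <- any(b == 0)
  if (!has_b0 && protocol$n_b0 > 0) {
    b <- c(rep(0, protocol$n_b0), b)
    bd <- c(rep(0, protocol$n_b0), bd)
    g <- rbind(matrix(c(0, 0, 1), protocol$n_b0, 3, byrow = TRUE), g)
    shell_id <- c(rep(0L, protocol$n_b0), shell_id)
  }
  list(b = b, b_delta = bd, g = g, shell = shell_id)
}

#' Read and write FSL-style gradient sidecars
#'
#' `write_bval_bvec()` writes the per-volume b-values (`.bval`, s/mm^2, one
#' row), gradient directions (`.bvec`, three rows) and b-tensor shapes
#' (`.bdelta`, one row) for a protocol; `read_bval_bvec()` reads them back.
#' Internal b units are ms/um^2; the files follow the FSL s/mm^2 convention
#' with an explicit factor of 1000.
#'
#' @param protocol a `dwi_protocol`.
#' @param stem path stem; `.bval`, `.bvec`, `.bdelta` are appended.
#' @return `read_bval_bvec()` returns a list with per-volume `b` (ms/um^2),
#'   `b_delta` and `g` (n x 3).
#' @export
write_bval_bvec <- function(protocol, stem) {
  v <- protocol_volumes(protocol)
  writeLines(paste(format(v$b * 1000, trim = TRUE, scientific = FALSE),
                   collapse = " "), paste0(stem, ".bval"))
  bv <- apply(t(v$g), 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(bv, paste0(stem, ".bvec"))
  writeLines(paste(format(v$b_delta, trim = TRUE), collapse = " "),
             paste0(stem, ".bdelta"))
  invisible(stem)
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(stem) {
  fb <- paste0(stem, ".bval")
  fv <- paste0(stem, ".bvec")
  fd <- paste0(stem, ".bdelta")
  for (f in c(fb, fv, fd)) {
    if (!file.exists(f)) stop("missing sidecar file: ", f)
  }
  b <- scan(fb, quiet = TRUE) / 1000
  g <- t(matrix(scan(fv, quiet = TRUE), nrow = 3, byrow = TRUE))
  bd <- scan(fd, quiet = TRUE)
  if (length(b) != nrow(g) || length(b) != length(bd)) {
    stop("sidecar lengths disagree: ", length(b), " bvals, ",
         nrow(g), " bvecs, ", length(bd), " bdeltas")
  }
  list(b = b, b_delta = bd, g = g)
}
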