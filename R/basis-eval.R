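# 1-D evaluation of the interpolating scaling functions and derivatives.

#' Shannon (sinc) scaling function
#'
#' Evaluates \eqn{\phi(x) = \sin(\pi x)/(\pi x)} or its first or second
#' analytic derivative, with the removable singularity at \eqn{x = 0} handled
#' by series expansion. A total function: defined for every real `x`.
#'
#' @param x numeric vector of evaluation points (grid units).
#' @param deriv derivative order, 0, 1 or 2.
#' @param truncation_radius optional; when supplied, values with
#'   `|x| > truncation_radius` are set to 0 (the compact-support
#'   approximation used in collocation matrices).
#' @return numeric vector of the same length as `x`.
#' @examples
#' eval_shannon(0)      # 1
#' eval_shannon(0.5)    # 2/pi
#' @export
eval_shannon <- function(x, deriv = 0L, truncation_radius = NULL) {
  stopifnot(deriv %in% 0:2)
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xb <- x[!small]
  p <- pi
  if (any(!small)) {
    s <- sin(p * xb); c0 <- cos(p * xb)
    out[!small] <- switch(deriv + 1L,
      s / (p * xb),
      (c0 * p * xb - s) / (p * xb^2),
      (-p^2 * s * xb^2 - 2 * c0 * p * xb + 2 * s) / (p * xb^3))
  }
  if (any(small)) {
    xs <- x[small]
    # Taylor of sinc about 0: 1 - (pi x)^2/6 + (pi x)^4/120
    out[small] <- switch(deriv + 1L,
      1 - (p * xs)^2 / 6 + (p * xs)^4 / 120,
      -p^2 * xs / 3 + p^4 * xs^3 / 30,
      -p^2 / 3 + p^4 * xs^2 / 10)
  }
  if (!is.null(truncation_radius)) out[abs(x) > truncation_radius] <- 0
  out
}

#' Shannon-Gabor scaling function
#'
#' The sinc function under a Gaussian window,
#' \eqn{w(x) = \mathrm{sinc}(x) \exp(-x^2 / (2\sigma^2))}, which localises the
#' slowly decaying Shannon basis so that derivatives at a point depend mostly
#' on nearby nodal values. The window sacrifices orthogonality but keeps the
#' interpolation property (the Gaussian is 1 at 0 and the sinc zeros stand).
#'
#' @inheritParams eval_shannon
#' @param sigma positive window width.
#' @return numeric vector of evaluations.
#' @examples
#' eval_shannon_gabor(0.5, sigma = 1)   # (2/pi) * exp(-1/8)
#' @export
eval_shannon_gabor <- function(x, sigma, deriv = 0L, truncation_radius = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive real")
  stopifnot(deriv %in% 0:2)
  g <- exp(-x^2 / (2 * sigma^2))
  out <- switch(deriv + 1L,
    eval_shannon(x) * g,
    {
      s0 <- eval_shannon(x); s1 <- eval_shannon(x, 1L)
      g1 <- -x / sigma^2 * g
      s1 * g + s0 * g1
    },
    {
      s0 <- eval_shannon(x); s1 <- eval_shannon(x, 1L); s2 <- eval_shannon(x, 2L)
      g1 <- -x / sigma^2 * g
      g2 <- (x^2 / sigma^4 - 1 / sigma^2) * g
      s2 * g + 2 * s1 * g1 + s0 * g2
    })
  if (!is.null(truncation_radius)) out[abs(x) > truncation_radius] <- 0
  out
}

#' Evaluate a scaling function or its derivatives
#'
#' Family dispatch over [scaling_spec()]: analytic formulas for
#' `shannon` and `shannon_gabor` (with the spec's truncation radius applied),
#' dyadic-table lookup with cubic interpolation for `daub_autocorr`
#' (exact at table abscissae; see [build_daub_autocorrelation()]).
#'
#' @param spec a [scaling_spec()].
#' @param x numeric vector of points, in grid units.
#' @param deriv derivative order 0, 1 or 2.
#' @return numeric vector of evaluations.
#' @export
phi_eval <- function(spec, x, deriv = 0L) {
  stopifnot(inherits(spec, "scaling_spec"), deriv %in% 0:2)
  dim_in <- dim(x)
  out <- switch(spec$family,
    shannon = eval_shannon(x, deriv, spec$truncation_radius),
    shannon_gabor = eval_shannon_gabor(x, spec$sigma, deriv, spec$truncation_radius),
    daub_autocorr = daub_eval(spec, x, deriv))
  dim(out) <- dim_in
  out
}

#' Tensor-product 2-D basis function
#'
#' Evaluates \eqn{\partial_x^m \partial_y^n [\phi(2^j x' - k_1)\,
#' \phi(2^j y' - k_2)]} where \eqn{x', y'} are the coordinates normalised to
#' the computational square, with the \eqn{(2^j / \mathrm{width})^{m}}
#' chain-rule factors applied. The 2-D basis is the tensor product of the 1-D
#' scaling functions, the construction consistent with the separable index
#' structure of the multilevel grid.
#'
#' @param spec a [scaling_spec()].
#' @param j resolution level.
#' @param k1,k2 integer translation indices (x and y).
#' @param x,y evaluation coordinates.
#' @param m,n derivative orders in x and y; `m + n <= 2`.
#' @param domain computational rectangle `c(xmin, xmax, ymin, ymax)`.
#' @return numeric vector of evaluations.
#' @export
eval_basis_2d <- function(spec, j, k1, k2, x, y, m = 0L, n = 0L,
                          domain = c(0, 1, 0, 1)) {
  if (m + n > 2L) stop("unsupported derivative: m + n must be <= 2")
  wx <- domain[2] - domain[1]; wy <- domain[4] - domain[3]
  tx <- 2^j * (x - domain[1]) / wx - k1
  ty <- 2^j * (y - domain[3]) / wy - k2
  phi_eval(spec, tx, m) * (2^j / wx)^m * phi_eval(spec, ty, n) * (2^j / wy)^n
}
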