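#' Interpolating scaling-function specification
#'
#' Describes which interpolating scaling function \eqn{\phi} is in play and
#' its numerical parameters. All families satisfy the interpolation property
#' \eqn{\phi(0) = 1}, \eqn{\phi(n) = 0} for nonzero integers \eqn{n}, so nodal
#' values serve directly as collocation expansion coefficients.
#'
#' @param family one of `"shannon"` (the sinc function
#'   \eqn{\sin(\pi x)/(\pi x)}), `"shannon_gabor"` (sinc windowed by a
#'   Gaussian of width `sigma`), or `"daub_autocorr"` (the autocorrelation of
#'   the orthonormal Daubechies scaling function with `M` vanishing moments;
#'   the Deslauriers-Dubuc fundamental function, compactly supported on
#'   \eqn{[-(2M-1), 2M-1]}).
#' @param M vanishing-moment order, integer >= 2; used by `daub_autocorr`
#'   only. `M = 3` (the default) is the smallest order whose autocorrelation
#'   has enough smoothness for second-derivative collocation.
#' @param sigma positive window width of the Gaussian, in grid units;
#'   `shannon_gabor` only.
#' @param truncation_radius positive integer half-width, in grid units, beyond
#'   which the (slowly decaying) `shannon` / `shannon_gabor` bases are treated
#'   as exactly zero. A documented approximation knob, not part of the math.
#' @param dyadic_resolution integer r >= 8; `daub_autocorr` values are
#'   precomputed on a \eqn{2^{-r}} dyadic grid of the support.
#'
#' @return An object of class `"scaling_spec"`.
#' @examples
#' phi_eval(scaling_spec("shannon"), 0.5)           # 2/pi
#' phi_eval(scaling_spec("daub_autocorr", M = 3), 0:5)
#' @export
scaling_spec <- function(family = c("shannon", "shannon_gabor", "daub_autocorr"),
                         M = 3L, sigma = 3, truncation_radius = 40L,
                         dyadic_resolution = 10L) {
  family <- match.arg(family)
  spec <- list(family = family)
  if (family == "daub_autocorr") {
    if (!is.numeric(M) || length(M) != 1L || M < 2 || M != round(M))
      stop("'M' must be an integer >= 2 for the daub_autocorr family")
    if (dyadic_resolution < 8 || dyadic_resolution != round(dyadic_resolution))
      stop("'dyadic_resolution' must be an integer >= 8")
    spec$M <- as.integer(M)
    spec$dyadic_resolution <- as.integer(dyadic_resolution)
    spec$support <- 2L * spec$M - 1L
  } else {
    if (!is.numeric(truncation_radius) || truncation_radius <= 0)
      stop("'truncation_radius' must be a positive number")
    spec$truncation_radius <- truncation_radius
    if (family == "shannon_gabor") {
      if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
        stop("'sigma' must be a positive real (window width)")
      spec$sigma <- sigma
    }
  }
  class(spec) <- "scaling_spec"
  spec
}

#' @export
print.scaling_spec <- function(x, ...) {
  cat("Interpolating scaling function:", x$family, "\n")
  if (x$family == "daub_autocorr")
    cat("  vanishing moments M =", x$M, " support [-", x$support, ",", x$support,
        "]  dyadic resolution 2^-", x$dyadic_resolution, "\n")
  if (x$family == "shannon_gabor")
    cat("  window sigma =", x$sigma, "\n")
  if (!is.null(x$truncation_radius))
    cat("  truncated to |x| <=", x$truncation_radius, "grid units\n")
  invisible(x)
}

# stable cache key for basis-matrix / table caches
spec_key <- function(spec) {
  switch(spec$family,
    shannon = paste0("sh:", spec$truncation_radius),
    shannon_gabor = paste0("sg:", spec$sigma, ":", spec$truncation_radius),
    daub_autocorr = paste0("da:", spec$M, ":", spec$dyadic_resolution))
}
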