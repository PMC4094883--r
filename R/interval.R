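# Interval interpolation basis: Lagrange extension to external collocation
# points (static L) and the Newton divided-difference variant whose
# incremental structure drives the dynamic choice of L.

#' Dyadic interval grid
#'
#' The \eqn{2^j + 1} equispaced nodes
#' \eqn{x_{j,k} = x_{min} + k (x_{max} - x_{min}) / 2^j}, k = 0..2^j.
#'
#' @param xmin,xmax domain endpoints, `xmax > xmin`.
#' @param j level, integer >= 0.
#' @return An object of class `"interval_grid"`: list with `xmin`, `xmax`,
#'   `j`, `h` (spacing) and `nodes`.
#' @examples
#' interval_grid(0, 1, 2)$nodes   # 0 0.25 0.5 0.75 1
#' @export
interval_grid <- function(xmin, xmax, j) {
  if (!(xmax > xmin)) stop("invalid domain: 'xmax' must exceed 'xmin'")
  if (j < 0 || j != round(j)) stop("'j' must be a nonnegative integer")
  j <- as.integer(j)
  n <- 2L^j
  h <- (xmax - xmin) / n
  structure(list(xmin = xmin, xmax = xmax, j = j, h = h,
                 nodes = xmin + (0:n) * h),
            class = "interval_grid")
}

# Lagrange basis weights for predicting value at xe from nodes xs.
lagrange_row <- function(xe, xs) {
  vapply(seq_along(xs), function(k) {
    prod((xe - xs[-k]) / (xs[k] - xs[-k]))
  }, numeric(1))
}

#' Lagrange extension weights for external collocation points
#'
#' Degree-(L-1) Lagrange weights that predict the L external nodes on each
#' side of an interval grid from the L internal nodes nearest that side:
#' left externals \eqn{x_{j,-1..-L}} from \eqn{x_{j,0..L-1}}, right externals
#' \eqn{x_{j,2^j+1..2^j+L}} from \eqn{x_{j,2^j-L+1..2^j}}. Each weight row
#' sums to 1 (constants are reproduced) and the extension is exact for
#' polynomials of degree <= L-1.
#'
#' @param grid an [interval_grid()].
#' @param L number of external points per side, `1 <= L <= 2^j`.
#' @return list with `L`, `left` (L x L matrix, row i = weights for external
#'   node `x_{j,-i}`) and `right` (row i = weights for `x_{j,2^j+i}`, columns
#'   over internal nodes `2^j-L+1..2^j`).
#' @export
lagrange_extension_coeffs <- function(grid, L) {
  stopifnot(inherits(grid, "interval_grid"))
  n <- 2L^grid$j
  if (L < 1 || L > n || L != round(L))
    stop("'L' must be an integer in 1..2^j")
  L <- as.integer(L)
  # unit-spaced abscissae are sufficient (weights are affine-invariant)
  left <- t(vapply(1:L, function(i) lagrange_row(-i, 0:(L - 1)),
                   numeric(L)))
  right <- t(vapply(1:L, function(i) lagrange_row(n + i, (n - L + 1):n),
                    numeric(L)))
  dim(left) <- c(L, L); dim(right) <- c(L, L)
  list(L = L, left = left, right = right)
}

#' Extrapolate values to the external collocation points (Lagrange form)
#'
#' Evaluates the degree-(L-1) Lagrange polynomial through the L internal
#' nodes nearest each boundary at the L external nodes beyond it — the
#' boundary-extension values of the interval wavelet construction.
#'
#' @param values numeric vector of length `2^j + 1`: nodal values.
#' @param grid an [interval_grid()].
#' @param L external points per side.
#' @return list with `left` (values at `x_{j,-1..-L}`) and `right`
#'   (values at `x_{j,2^j+1..2^j+L}`).
#' @export
extrapolate_external_lagrange <- function(values, grid, L) {
  stopifnot(inherits(grid, "interval_grid"))
  n <- 2L^grid$j
  if (length(values) != n + 1L)
    stop("shape error: 'values' must have 2^j + 1 entries")
  w <- lagrange_extension_coeffs(grid, L)
  list(left = as.numeric(w$left %*% values[1:L]),
       right = as.numeric(w$right %*% values[(n - L + 2):(n + 1)]))
}

#' Newton divided-difference table
#'
#' The triangular table of divided differences
#' \eqn{f[x_i..x_{i+m}]} built by the standard recurrence
#' \eqn{f[x_i..x_{i+m}] = (f[x_{i+1}..x_{i+m}] - f[x_i..x_{i+m-1}]) /
#' (x_{i+m} - x_i)}. The top row `f[x_0..x_m]` supplies both the Newton-form
#' extrapolation coefficients and the magnitude-decay criterion for the
#' dynamic choice of L.
#'
#' @param nodes distinct abscissae.
#' @param values function values at `nodes`.
#' @param depth highest difference order to compute
#'   (default `length(nodes) - 1`).
#' @return object of class `"divided_differences"`: list with `nodes`,
#'   `table` (list; element m+1 holds the order-m differences) and `top`
#'   (numeric vector, `top[m+1] = f[x_0..x_m]`).
#' @examples
#' divided_differences(c(0, 1, 2), c(0, 1, 4))$top   # 0 1 1
#' @export
divided_differences <- function(nodes, values, depth = length(nodes) - 1L) {
  stopifnot(length(nodes) == length(values), length(nodes) >= 1L)
  if (anyDuplicated(nodes)) stop("invalid nodes: abscissae must be distinct")
  if (depth >= length(nodes)) stop("'depth' must be < number of nodes")
  tab <- vector("list", depth + 1L)
  tab[[1]] <- values
  if (depth >= 1L) for (m in 1:depth) {
    prev <- tab[[m]]
    i <- seq_len(length(prev) - 1L)
    tab[[m + 1L]] <- (prev[i + 1L] - prev[i]) / (nodes[i + m] - nodes[i])
  }
  structure(list(nodes = nodes,
                 table = tab,
                 top = vapply(tab, `[`, numeric(1), 1L)),
            class = "divided_differences")
}

#' Newton-form extrapolation from a divided-difference table
#'
#' Evaluates the truncated Newton interpolant
#' \eqn{f(x_0) + (x-x_0) f[x_0,x_1] + \dots} through the first `L` nodes
#' (orders 0..L-1) at `x` — algebraically identical to the degree-(L-1)
#' Lagrange extrapolant, but incrementally extensible: raising `L` by one
#' adds a single product term and reuses everything already computed (the
#' inheritance property that makes the dynamic-L search cheap, O(L) new
#' multiplications per increment rather than a recomputed basis).
#'
#' @param dd a [divided_differences()] table.
#' @param x evaluation point (scalar).
#' @param L number of nodes used, `1 <= L <= depth + 1`.
#' @return the extrapolated value, with attributes `partials` (value after
#'   each order, length L) and `ops` (multiplication count).
#' @export
extrapolate_external_newton <- function(dd, x, L) {
  stopifnot(inherits(dd, "divided_differences"))
  if (L < 1 || L > length(dd$top))
    stop("insufficient table: 'L' exceeds divided-difference depth + 1")
  acc <- dd$top[1]
  partials <- numeric(L)
  partials[1] <- acc
  prod_term <- 1
  ops <- 0L
  if (L >= 2L) for (m in 1:(L - 1L)) {
    prod_term <- prod_term * (x - dd$nodes[m])   # one new factor per order
    acc <- acc + prod_term * dd$top[m + 1L]
    ops <- ops + 2L                              # product update + term
    partials[m + 1L] <- acc
  }
  structure(acc, partials = partials, ops = ops)
}

#' Configuration of the dynamic external-point rule
#'
#' @param T_a absolute tolerance on divided-difference magnitude (the
#'   termination criterion of the dynamic rule). Default 1e-3, scaled to
#'   intensities in \[0,1\].
#' @param eps threshold on the raw difference coefficient; defaults to `T_a`
#'   (the two thresholds are exposed separately but play the same role
#'   unless configured otherwise).
#' @param L_max hard cap on L (default 6; capped further at `2M-1` for the
#'   compactly supported autocorrelation family by the solver).
#' @param cond_ratio_max maximum allowed growth ratio
#'   `cond(A_{L+1}) / cond(A_L)` when raising L (default 10).
#' @return list of class `"dynamic_l_config"`.
#' @export
dynamic_l_config <- function(T_a = 1e-3, eps = T_a, L_max = 6L,
                             cond_ratio_max = 10) {
  stopifnot(T_a > 0, eps > 0, L_max >= 1, cond_ratio_max > 0)
  structure(list(T_a = T_a, eps = eps, L_max = as.integer(L_max),
                 cond_ratio_max = cond_ratio_max),
            class = "dynamic_l_config")
}

# Core rule on a vector of |f[x_0..x_m]| magnitudes (index m = order).
# Returns smallest L with |d_L| < T_a, or (L >= 2) |d_L| < |d_{L-1}|;
# falls back to L_max with a warning when the sequence never settles.
select_L_from_magnitudes <- function(dmag, cfg) {
  L_max <- min(cfg$L_max, length(dmag))
  for (m in seq_len(L_max)) {
    if (dmag[m] < cfg$T_a) return(m)
    if (m >= 2L && dmag[m] < dmag[m - 1L]) return(m)
  }
  warning("dynamic-L rule did not terminate below L_max; using L_max = ", L_max)
  L_max
}

apply_cond_cap <- function(L, cond_probe, cfg) {
  if (is.null(cond_probe) || L <= 1L) return(L)
  prev <- cond_probe(1L)
  for (l in 2:L) {
    cur <- cond_probe(l)
    if (!is.finite(cur) || cur / prev >= cfg$cond_ratio_max) return(l - 1L)
    prev <- cur
  }
  L
}

#' Dynamic choice of the number of external collocation points
#'
#' Implements the adaptive termination rule on the decay of divided
#' differences: starting from the boundary, L is the smallest order whose
#' (absolute) divided difference either falls below the tolerance `T_a` or
#' stops decreasing relative to the previous order; capped at `L_max`. When a
#' condition-number probe is supplied, a candidate increment to `L+1` is
#' rejected whenever `cond_probe(L+1)/cond_probe(L)` meets or exceeds
#' `cond_ratio_max`, so ill-conditioning of the discretised system always
#' takes precedence over the smoothness criterion. Divided differences are
#' taken on unit-spaced (index) abscissae so that `T_a` has a fixed meaning
#' on \[0,1\]-scaled intensities.
#'
#' @param boundary_values values at the `L_max + 1` nodes nearest the
#'   boundary, boundary-first.
#' @param cfg a [dynamic_l_config()].
#' @param cond_probe optional function(L) returning a positive condition
#'   estimate of the discretised system with L external points.
#' @return integer L, with attribute `capped_by_cond` (logical).
#' @export
select_L_dynamic <- function(boundary_values, cfg = dynamic_l_config(),
                             cond_probe = NULL) {
  if (length(boundary_values) < 2L)
    stop("insufficient data: need at least 2 boundary values")
  dd <- divided_differences(seq_along(boundary_values) - 1, boundary_values)
  dmag <- abs(dd$top[-1])                     # orders 1, 2, ...
  L <- select_L_from_magnitudes(dmag, cfg)
  Lc <- apply_cond_cap(L, cond_probe, cfg)
  structure(as.integer(Lc), capped_by_cond = Lc < L)
}

#' Interval interpolant with boundary extension
#'
#' Builds the evaluator of the interval wavelet approximation
#' \eqn{f_j(x) = \sum_n LS_L(x_n)\,\omega(2^j x - n) + \sum_k f_k\,
#' \omega(2^j x - k) + \sum_n LE_L(x_n)\,\omega(2^j x - n)}: interior nodal
#' terms plus extension terms whose external values come from Lagrange
#' extrapolation, so that boundary artifacts are confined to the
#' extension zone outside the domain.
#'
#' @param values nodal values, length `2^j + 1`.
#' @param grid an [interval_grid()].
#' @param L external points per side.
#' @param spec a [scaling_spec()].
#' @return function `f(x, deriv = 0)` evaluating the interpolant (or its
#'   first/second derivative) inside `[xmin, xmax]`.
#' @export
interval_interpolant <- function(values, grid, L, spec) {
  stopifnot(inherits(grid, "interval_grid"), inherits(spec, "scaling_spec"))
  n <- 2L^grid$j
  if (length(values) != n + 1L)
    stop("shape error: 'values' must have 2^j + 1 entries")
  force(L)
  function(x, deriv = 0L) {
    if (any(x < grid$xmin - 1e-12) || any(x > grid$xmax + 1e-12))
      stop("out of domain: evaluation outside [xmin, xmax]")
    B <- level_basis(x, grid$j, spec, c(grid$xmin, grid$xmax),
                     L_left = L, L_right = L, deriv = deriv)
    as.numeric(B %*% values)
  }
}
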