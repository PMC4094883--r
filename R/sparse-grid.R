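# Multilevel 2-D interpolation on dyadic grids: interpolatory wavelet
# coefficients (hierarchical surpluses) alpha1/alpha2/alpha3 for the three
# new-node families, thresholded active masks, and evaluation of the field
# and its derivatives by level-wise separable matrix products.

#' Multilevel dyadic grid on a rectangle
#'
#' Nested dyadic grids from coarsest level `j0` to finest level `J`;
#' level-j nodes are \eqn{x^j_{k} = xmin + k (xmax - xmin)/2^j} (and likewise
#' in y), so each level's nodes are a subset of the next ((2^j+1)^2 points at
#' level j).
#'
#' @param j0 coarsest level >= 0.
#' @param J finest level > j0.
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)`.
#' @return object of class `"multilevel_grid"`.
#' @export
multilevel_grid <- function(j0, J, domain = c(0, 1, 0, 1)) {
  stopifnot(j0 >= 0, J > j0, j0 == round(j0), J == round(J),
            domain[2] > domain[1], domain[4] > domain[3])
  structure(list(j0 = as.integer(j0), J = as.integer(J), domain = domain,
                 N = 2L^as.integer(J) + 1L),
            class = "multilevel_grid")
}

grid_xs <- function(grid, j = grid$J)
  grid$domain[1] + (0:(2^j)) * (grid$domain[2] - grid$domain[1]) / 2^j
grid_ys <- function(grid, j = grid$J)
  grid$domain[3] + (0:(2^j)) * (grid$domain[4] - grid$domain[3]) / 2^j

#' Restriction predicate on multilevel node indices
#'
#' Indicator that two (level, index, index) pairs name the same physical
#' grid point: 1 iff \eqn{x^l_{k_1} = x^j_{m_1}} and \eqn{y^l_{k_2} =
#' y^j_{m_2}} under dyadic nesting, else 0.
#'
#' @param l,k1,k2 level and x/y indices of the first point.
#' @param j,m1,m2 level and x/y indices of the second point.
#' @return 0 or 1.
#' @examples
#' restriction_indicator(1, 1, 1, 2, 2, 2)   # 1: both are (0.5, 0.5)
#' @export
restriction_indicator <- function(l, k1, k2, j, m1, m2) {
  as.integer(k1 * 2^j == m1 * 2^l && k2 * 2^j == m2 * 2^l)
}

# per-side L normalised to a named vector
ext_sides <- function(L) {
  if (length(L) == 1L) L <- c(left = L, right = L, top = L, bottom = L)
  stopifnot(all(c("left", "right", "top", "bottom") %in% names(L)))
  L
}

# family index matrices within a level-(j+1) coefficient layout:
# family 1: x odd, y even; family 2: x even, y odd; family 3: both odd.
fam_rows <- function(np1, fam) switch(fam, seq(1, np1, 2), seq(2, np1, 2),
                                      seq(2, np1, 2))  # y index (rows)
fam_cols <- function(np1, fam) switch(fam, seq(2, np1, 2), seq(1, np1, 2),
                                      seq(2, np1, 2))  # x index (cols)

#' Multilevel interpolatory wavelet decomposition
#'
#' Level-by-level computation of the hierarchical surpluses: for each level
#' j from `j0` to `J-1`, the partial interpolant through all coarser levels
#' (with the interval extension applied at the domain edges) is evaluated at
#' the three families of level-(j+1) new nodes, and the residuals are stored
#' as the wavelet coefficients \eqn{\alpha^1} (x odd, y even), \eqn{\alpha^2}
#' (x even, y odd), \eqn{\alpha^3} (both odd). With all coefficients active
#' the transform is lossless: reconstruction at every level-J node returns
#' the nodal value to machine precision.
#'
#' @param values `(2^J+1) x (2^J+1)` matrix of nodal values; rows index y
#'   (image rows), columns index x.
#' @param grid a [multilevel_grid()].
#' @param spec a [scaling_spec()].
#' @param L external points per side: scalar or named vector
#'   `c(left=, right=, top=, bottom=)`.
#' @return object of class `"sparse_coeffs"`: coarse nodal values, per-level
#'   coefficient matrices `a1/a2/a3`, all-active masks, `threshold = 0`, and
#'   the operation counter `counter` (number of coefficients computed, the
#'   quantity whose O(4^J) growth the recursive route achieves).
#' @export
sg_decompose <- function(values, grid, spec, L = 3L) {
  stopifnot(inherits(grid, "multilevel_grid"), inherits(spec, "scaling_spec"))
  N <- grid$N
  if (!is.matrix(values) || any(dim(values) != N))
    stop("shape error: 'values' must be a (2^J+1) x (2^J+1) matrix")
  L <- ext_sides(L)
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  domx <- grid$domain[1:2]; domy <- grid$domain[3:4]
  j0 <- grid$j0; J <- grid$J
  s0 <- 2L^(J - j0)
  coarse <- values[seq(1, N, s0), seq(1, N, s0), drop = FALSE]
  counter <- length(coarse)
  # running evaluation of the partial multilevel interpolant on the full grid
  Bx <- level_basis(xs, j0, spec, domx, L["left"], L["right"])
  By <- level_basis(ys, j0, spec, domy, L["top"], L["bottom"])
  G <- By %*% coarse %*% t(Bx)
  detail <- list(); masks <- list()
  for (j in j0:(J - 1L)) {
    s <- 2L^(J - j - 1L)                     # level-(j+1) stride on full grid
    np1 <- 2L^(j + 1L) + 1L
    Rres <- values - G
    lev <- list(); msk <- list()
    for (fam in 1:3) {
      r <- fam_rows(np1, fam); cc <- fam_cols(np1, fam)
      a <- Rres[(r - 1L) * s + 1L, (cc - 1L) * s + 1L, drop = FALSE]
      lev[[fam]] <- a
      msk[[fam]] <- matrix(TRUE, nrow(a), ncol(a))
      counter <- counter + length(a)
    }
    names(lev) <- names(msk) <- c("a1", "a2", "a3")
    detail[[as.character(j)]] <- lev
    masks[[as.character(j)]] <- msk
    C <- coeff_layout(lev, msk, np1)
    Bx1 <- level_basis(xs, j + 1L, spec, domx, L["left"], L["right"])
    By1 <- level_basis(ys, j + 1L, spec, domy, L["top"], L["bottom"])
    G <- G + By1 %*% C %*% t(Bx1)
  }
  structure(list(grid = grid, spec = spec, L = L, coarse = coarse,
                 detail = detail, mask = masks, threshold = 0,
                 counter = counter),
            class = "sparse_coeffs")
}

# embed the three families (masked) into a full level-(j+1) coefficient
# matrix with zeros at the nodes inherited from level j
coeff_layout <- function(lev, msk, np1) {
  C <- matrix(0, np1, np1)
  for (fam in 1:3) {
    a <- lev[[fam]] * msk[[fam]]
    C[fam_rows(np1, fam), fam_cols(np1, fam)] <- a
  }
  C
}

# evaluate the (masked) multilevel interpolant / derivatives at the tensor
# grid xs x ys; m = x-derivative order, n = y-derivative order.
sg_eval_grid <- function(coeffs, xs, ys, m = 0L, n = 0L) {
  grid <- coeffs$grid; spec <- coeffs$spec; L <- coeffs$L
  domx <- grid$domain[1:2]; domy <- grid$domain[3:4]
  Bx <- level_basis(xs, grid$j0, spec, domx, L["left"], L["right"], deriv = m)
  By <- level_basis(ys, grid$j0, spec, domy, L["top"], L["bottom"], deriv = n)
  G <- By %*% coeffs$coarse %*% t(Bx)
  for (j in names(coeffs$detail)) {
    jv <- as.integer(j)
    np1 <- 2L^(jv + 1L) + 1L
    C <- coeff_layout(coeffs$detail[[j]], coeffs$mask[[j]], np1)
    Bx1 <- level_basis(xs, jv + 1L, spec, domx, L["left"], L["right"], deriv = m)
    By1 <- level_basis(ys, jv + 1L, spec, domy, L["top"], L["bottom"], deriv = n)
    G <- G + By1 %*% C %*% t(Bx1)
  }
  G
}

#' Evaluate the multilevel interpolant or its derivatives
#'
#' Sums the coarse-level term and the active wavelet coefficients against the
#' tensor-product basis (or its x/y derivatives) at the requested point(s).
#' With `m = n = 0` at an active level-J node this returns the stored nodal
#' value (interpolation property).
#'
#' @param coeffs a [sg_decompose()] result (possibly [sg_compress()]ed).
#' @param x,y coordinates (scalars or equal-length vectors; evaluated
#'   pointwise).
#' @param m,n derivative orders in x and y (`m, n <= 2`).
#' @return numeric vector of evaluations.
#' @export
sg_reconstruct <- function(coeffs, x, y, m = 0L, n = 0L) {
  grid <- coeffs$grid
  if (any(x < grid$domain[1] - 1e-12) || any(x > grid$domain[2] + 1e-12) ||
      any(y < grid$domain[3] - 1e-12) || any(y > grid$domain[4] + 1e-12))
    stop("out of domain")
  stopifnot(length(x) == length(y))
  vapply(seq_along(x), function(i)
    sg_eval_grid(coeffs, x[i], y[i], m, n)[1, 1], numeric(1))
}

#' Threshold the wavelet coefficients
#'
#' Sets the active mask to `|alpha| >= threshold`; coarse-level values are
#' always active. Deactivated coefficients are omitted from reconstruction
#' and derivative sums, so the reconstruction error at a deactivated node is
#' bounded by a basis-dependent multiple of the threshold.
#'
#' @param coeffs a `"sparse_coeffs"` object.
#' @param threshold nonnegative magnitude cutoff (absolute, on the intensity
#'   scale of the field).
#' @return the object with updated masks and `threshold`.
#' @export
sg_compress <- function(coeffs, threshold) {
  if (!is.numeric(threshold) || threshold < 0)
    stop("invalid parameter: 'threshold' must be >= 0")
  for (j in names(coeffs$detail))
    for (fam in c("a1", "a2", "a3"))
      coeffs$mask[[j]][[fam]] <-
        abs(coeffs$detail[[j]][[fam]]) >= threshold
  coeffs$threshold <- threshold
  coeffs
}

#' Number of active collocation points
#'
#' Coarse nodes (always active) plus active wavelet coefficients — the size
#' of the sparse grid actually carried by the representation.
#'
#' @param coeffs a `"sparse_coeffs"` object.
#' @return integer count.
#' @export
active_point_count <- function(coeffs) {
  n <- length(coeffs$coarse)
  for (j in names(coeffs$mask))
    for (fam in c("a1", "a2", "a3"))
      n <- n + sum(coeffs$mask[[j]][[fam]])
  as.integer(n)
}

#' @export
print.sparse_coeffs <- function(x, ...) {
  g <- x$grid
  cat("Multilevel wavelet coefficients: levels", g$j0, "to", g$J,
      "(", g$N, "x", g$N, "grid )\n")
  cat("  basis:", x$spec$family, " threshold:", x$threshold, "\n")
  cat("  active points:", active_point_count(x), "of",
      g$N^2, "\n")
  invisible(x)
}

#' Explicit multilevel extension operators (small-grid oracle)
#'
#' Assembles, level by level, the dense tensors C1/C2/C3 that map the full
#' level-J nodal values directly to the wavelet coefficients of each family:
#' each row is the point-selection (restriction) row of the new node minus
#' the coarse interpolation row and the basis-weighted rows of all coarser
#' detail operators. This is the explicit-operator route whose assembly work
#' grows like the square of the grid size; the package's primary path is the
#' recursive residual computation in [sg_decompose()], and this assembly
#' exists as an independent verification oracle on small grids.
#'
#' @param grid a [multilevel_grid()] (intended for small `J`).
#' @param spec a [scaling_spec()].
#' @param L external points per side (scalar or named vector).
#' @return list over levels `j0..J-1`; each element holds matrices `C1`,
#'   `C2`, `C3` with one row per coefficient (row-major over the family's
#'   (k2, k1) layout) and one column per level-J node (column-major,
#'   y fastest — matching `as.vector` of the values matrix).
#' @export
extension_operators <- function(grid, spec, L = 3L) {
  stopifnot(inherits(grid, "multilevel_grid"))
  L <- ext_sides(L)
  N <- grid$N; j0 <- grid$j0; J <- grid$J
  xs <- grid_xs(grid); ys <- grid_ys(grid)
  domx <- grid$domain[1:2]; domy <- grid$domain[3:4]
  # selection row for full-grid node (xi_idx, yi_idx) at level J (1-based)
  sel_row <- function(ix, iy) {
    r <- numeric(N * N)
    r[(ix - 1L) * N + iy] <- 1           # column-major: y fastest
    r
  }
  # interpolation row of the coarse level at a point (x, y):
  # row vector over full-grid nodes via restriction of coarse nodes
  s0 <- 2L^(J - j0)
  ops <- list()
  for (j in j0:(J - 1L)) {
    np1 <- 2L^(j + 1L) + 1L
    sJ <- 2L^(J - j - 1L)
    lev <- list()
    for (fam in 1:3) {
      rws <- fam_rows(np1, fam); cls <- fam_cols(np1, fam)
      nr <- length(rws) * length(cls)
      Cf <- matrix(0, nr, N * N)
      row_i <- 0L
      for (cx in cls) for (cy in rws) {    # column-major over (k1, k2)
        row_i <- row_i + 1L
        px <- xs[(cx - 1L) * sJ + 1L]; py <- ys[(cy - 1L) * sJ + 1L]
        rowv <- sel_row((cx - 1L) * sJ + 1L, (cy - 1L) * sJ + 1L)
        # coarse interpolation at (px, py): weights over coarse nodes,
        # scattered onto the full grid through the restriction predicate
        bx0 <- level_basis(px, j0, spec, domx, L["left"], L["right"], cache = FALSE)
        by0 <- level_basis(py, j0, spec, domy, L["top"], L["bottom"], cache = FALSE)
        wts <- as.vector(outer(as.numeric(by0), as.numeric(bx0)))  # y fastest
        full_idx <- as.vector(outer(seq(1, N, s0),
                                    (seq(1, N, s0) - 1L) * N, `+`))
        rowv[full_idx] <- rowv[full_idx] - wts
        # coarser detail operators weighted by their basis at (px, py)
        if (j > j0) for (j1 in j0:(j - 1L)) {
          nlev <- 2L^(j1 + 1L) + 1L
          bx1 <- level_basis(px, j1 + 1L, spec, domx, L["left"], L["right"], cache = FALSE)
          by1 <- level_basis(py, j1 + 1L, spec, domy, L["top"], L["bottom"], cache = FALSE)
          prev <- ops[[as.character(j1)]]
          for (f2 in 1:3) {
            rw2 <- fam_rows(nlev, f2); cl2 <- fam_cols(nlev, f2)
            # rows of prev[[f2]] run k1 (x) slow, k2 (y) fast; match that order
            wrow <- as.vector(vapply(cl2, function(c2)
              as.numeric(bx1)[c2] * as.numeric(by1)[rw2], numeric(length(rw2))))
            rowv <- rowv - as.numeric(wrow %*% prev[[f2]])
          }
        }
        Cf[row_i, ] <- rowv
      }
      lev[[fam]] <- Cf
    }
    names(lev) <- c("C1", "C2", "C3")
    ops[[as.character(j)]] <- lev
  }
  ops
}

#' Apply explicit extension operators to nodal values
#'
#' Companion to [extension_operators()]: applies the assembled C1/C2/C3
#' tensors to a full-grid value matrix and returns coefficients shaped like
#' the `detail` component of [sg_decompose()].
#'
#' @param ops result of [extension_operators()].
#' @param values `(2^J+1)^2` value matrix (rows y, columns x).
#' @return list over levels of lists `a1`, `a2`, `a3`.
#' @export
apply_extension_operators <- function(ops, values) {
  v <- as.vector(values)                   # column-major: y fastest
  out <- list()
  for (j in names(ops)) {
    np1 <- 2L^(as.integer(j) + 1L) + 1L
    lev <- list()
    for (fam in 1:3) {
      nr <- length(fam_rows(np1, fam)); nc <- length(fam_cols(np1, fam))
      a <- matrix(as.numeric(ops[[j]][[paste0("C", fam)]] %*% v), nr, nc)
      lev[[fam]] <- a
    }
    names(lev) <- c("a1", "a2", "a3")
    out[[j]] <- lev
  }
  out
}
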