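# Interval-extended collocation basis matrix at one level.
#
# level_basis(x, j, spec, dom, L_left, L_right, deriv) returns the
# length(x) x (2^j + 1) matrix B with B[i, k+1] = w_{j,k}^{(deriv)}(x_i),
# where w_{j,k} is the interval basis: the translate phi(2^j x' - k) plus,
# for the L internal nodes nearest each boundary, the Lagrange-weighted
# external translates folded in. Chain-rule factor (2^j / width)^deriv
# applied. This matrix is the single building block behind the interval
# interpolant, the multilevel transform and the differentiation matrices.

level_basis <- function(x, j, spec, dom = c(0, 1), L_left = 3L, L_right = L_left,
                        deriv = 0L, cache = TRUE) {
  n <- 2L^j
  L_left <- min(as.integer(L_left), n)
  L_right <- min(as.integer(L_right), n)
  key <- NULL
  if (cache) {
    key <- paste0("B:", spec_key(spec), ":", j, ":", deriv, ":", L_left, ":",
                  L_right, ":", dom[1], ":", dom[2], ":", length(x), ":",
                  x[1], ":", x[length(x)], ":",
                  format(sum(x), digits = 17), ":",
                  x[(length(x) + 1L) %/% 2L])
    hit <- .pmwave_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  w <- dom[2] - dom[1]
  t <- n * (x - dom[1]) / w                 # node k sits at t = k
  ks <- (-L_left):(n + L_right)
  P <- phi_eval(spec, outer(t, ks, "-"), deriv) * (n / w)^deriv
  B <- P[, L_left + 1L + (0:n), drop = FALSE]
  if (L_left >= 1L) {
    # external columns n = -1..-L folded onto internal k = 0..L-1
    WL <- lagrange_ext_unit(L_left, side = "left")
    B[, 1:L_left] <- B[, 1:L_left] +
      P[, L_left:1, drop = FALSE] %*% WL      # cols for n = -1..-L
  }
  if (L_right >= 1L) {
    WR <- lagrange_ext_unit(L_right, side = "right", n = n)
    idx <- (n + 1L - L_right + 1L):(n + 1L)   # internal cols n-L+1..n
    B[, idx] <- B[, idx] +
      P[, (L_left + n + 2L):(L_left + n + 1L + L_right), drop = FALSE] %*% WR
  }
  if (cache) .pmwave_cache[[key]] <- B
  B
}

# Unit-spacing Lagrange extension weights. Rows: external nodes (-1..-L or
# n+1..n+L); columns: the L internal nodes they are predicted from.
lagrange_ext_unit <- function(L, side = c("left", "right"), n = NULL) {
  side <- match.arg(side)
  if (side == "left") {
    t(vapply(1:L, function(i) lagrange_row(-i, 0:(L - 1)), numeric(L)))
  } else {
    t(vapply(1:L, function(i) lagrange_row(n + i, (n - L + 1):n), numeric(L)))
  }
}
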