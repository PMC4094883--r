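# Independent oracles used across the suite.

# Cascade-evaluate the orthonormal Daubechies-M scaling function on a dyadic
# grid, then Riemann-sum the autocorrelation integral at lag x0. Independent
# of the package's interpolatory-subdivision route.
oracle_autocorr <- function(M, r, x0) {
  h <- pmwave:::daub_filter(M)
  s <- 2 * M - 1
  n <- s - 1
  T <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    k <- 2 * i - j + 1
    if (k >= 1 && k <= length(h)) T[i, j] <- h[k]
  }
  ev <- eigen(T)
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  v <- v / sum(v)
  val <- c(0, v, 0)
  for (l in 1:r) {
    nold <- length(val)
    newv <- numeric(2 * nold - 1)
    newv[seq(1, length(newv), 2)] <- val
    odd <- seq(2, length(newv) - 1, 2)
    kk <- odd - 1
    acc <- numeric(length(odd))
    for (q in seq_along(h)) {
      jj <- kk - (q - 1) * 2^(l - 1)
      ok <- jj >= 0 & jj <= (nold - 1)
      acc[ok] <- acc[ok] + h[q] * val[jj[ok] + 1]
    }
    newv[odd] <- acc
    val <- newv
  }
  step <- 2^-r
  m <- round(x0 / step)
  n2 <- length(val)
  sum(val[(m + 1):n2] * val[1:(n2 - m)]) * step
}

# dense evaluation of the interpolating polynomial through (xs, ys) at x
oracle_poly_interp <- function(xs, ys, x) {
  vapply(x, function(xx)
    sum(vapply(seq_along(xs), function(k)
      ys[k] * prod((xx - xs[-k]) / (xs[k] - xs[-k])), numeric(1))),
    numeric(1))
}

daub3 <- function() scaling_spec("daub_autocorr", M = 3)
shan <- function() scaling_spec("shannon")
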