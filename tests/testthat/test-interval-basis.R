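test_that("interval grids are the dyadic node formula", {
  expect_equal(interval_grid(0, 1, 2)$nodes, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(interval_grid(0, 1, 0)$nodes, c(0, 1))
  expect_equal(interval_grid(-1, 1, 1)$nodes, c(-1, 0, 1))
  expect_error(interval_grid(1, 0, 2), "domain")
})

test_that("Lagrange extension weights reproduce constants and known rows", {
  g <- interval_grid(0, 1, 2)
  w1 <- lagrange_extension_coeffs(g, 1)
  expect_equal(as.numeric(w1$left[1, 1]), 1)        # constant extrapolation
  w2 <- lagrange_extension_coeffs(g, 2)
  expect_equal(as.numeric(w2$left[1, ]), c(2, -1))  # brute-force Lagrange row
  for (L in 1:4) {
    w <- lagrange_extension_coeffs(g, L)
    expect_equal(rowSums(w$left), rep(1, L))
    expect_equal(rowSums(w$right), rep(1, L))
  }
  expect_error(lagrange_extension_coeffs(g, 5), "L")
})

test_that("external extrapolation reproduces polynomials of degree < L", {
  g <- interval_grid(0, 1, 2)
  # constants, any L
  for (L in 1:4)
    expect_equal(extrapolate_external_lagrange(rep(5, 5), g, L),
                 list(left = rep(5, L), right = rep(5, L)))
  # linear data, L = 2
  e <- extrapolate_external_lagrange(g$nodes, g, 2)
  expect_equal(e$left[1], -0.25)
  # quadratic data, L = 3: exact at external abscissae (oracle: dense
  # interpolating polynomial through the three boundary-nearest nodes)
  v <- g$nodes^2
  e3 <- extrapolate_external_lagrange(v, g, 3)
  expect_equal(e3$left, oracle_poly_interp(g$nodes[1:3], v[1:3],
                                           -(1:3) * 0.25), tolerance = 1e-12)
  expect_equal(e3$right, (1 + (1:3) * 0.25)^2, tolerance = 1e-12)
  expect_error(extrapolate_external_lagrange(rep(1, 4), g, 2), "shape")
})

test_that("divided differences satisfy the recurrence and classic examples", {
  dd <- divided_differences(c(0, 1, 2), c(0, 1, 4))
  expect_equal(dd$top, c(0, 1, 1))
  expect_equal(divided_differences(0:5, rep(3, 6))$top[-1], rep(0, 5))
  expect_error(divided_differences(c(0, 0, 1), 1:3), "distinct")
  # Newton evaluation from the table equals the Lagrange interpolant
  set.seed(11)
  xs <- sort(runif(6)); ys <- rnorm(6)
  dd2 <- divided_differences(xs, ys)
  xq <- runif(20)
  newt <- vapply(xq, function(x)
    as.numeric(extrapolate_external_newton(dd2, x, 6)), numeric(1))
  expect_equal(newt, oracle_poly_interp(xs, ys, xq), tolerance = 1e-12)
})

test_that("Newton and Lagrange extrapolation agree over random cases", {
  set.seed(42)
  g <- interval_grid(0, 1, 3)
  worst <- 0
  for (rep in 1:100) {
    v <- rnorm(9)
    L <- sample(1:6, 1)
    la <- extrapolate_external_lagrange(v, g, L)
    dd <- divided_differences(0:(L - 1), v[1:L])
    ne <- vapply(1:L, function(i)
      as.numeric(extrapolate_external_newton(dd, -i, L)), numeric(1))
    worst <- max(worst, max(abs(la$left - ne) / pmax(abs(la$left), 1)))
  }
  expect_lt(worst, 1e-10)
})

test_that("Newton form is incremental: one product term per added point, O(L) work", {
  dd <- divided_differences(0:6, c(0.2, 0.5, 0.1, 0.9, 0.4, 0.8, 0.3))
  x <- -1.5
  vals <- lapply(1:7, function(L) extrapolate_external_newton(dd, x, L))
  for (L in 2:7) {
    partials <- attr(vals[[L]], "partials")
    # value at truncation L-1 is embedded unchanged (inheritance)
    expect_equal(partials[L - 1], as.numeric(vals[[L - 1]]), tolerance = 1e-14)
    # adding exactly one product term reconstructs the increment
    prod_term <- prod(x - dd$nodes[1:(L - 1)]) * dd$top[L]
    expect_equal(partials[L] - partials[L - 1], prod_term, tolerance = 1e-12)
  }
  # operation counter grows linearly in L
  ops <- vapply(vals, function(v) attr(v, "ops"), integer(1))
  expect_equal(diff(ops), rep(2L, 6))
})

test_that("dynamic L follows the divided-difference termination rule", {
  cfg <- dynamic_l_config()
  expect_equal(as.integer(select_L_dynamic(rep(1, 7), cfg)), 1L)
  # exactly linear data with slope above tolerance: second difference is 0
  expect_equal(as.integer(select_L_dynamic(0.1 * (0:6), cfg)), 2L)
  # condition cap: ratio 200/10 = 20 >= 10 rejects the step to L = 3
  probe <- function(L) c(5, 10, 200, 400, 800, 1600)[L]
  got <- select_L_dynamic(c(0, 0.1, 0.5, 1.2, 2.5, 4.4, 7), cfg, probe)
  expect_equal(as.integer(got), 2L)
  expect_true(attr(got, "capped_by_cond"))
  expect_error(select_L_dynamic(1, cfg), "insufficient")
})

test_that("raising T_a never raises the selected L", {
  set.seed(7)
  for (case in 1:30) {
    v <- cumsum(rnorm(7, sd = runif(1, 0.001, 1)))
    Ls <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1, 1), function(ta)
      as.integer(suppressWarnings(
        select_L_dynamic(v, dynamic_l_config(T_a = ta)))), integer(1))
    expect_true(all(diff(Ls) <= 0))
  }
})

test_that("interval interpolant interpolates nodal values and reproduces constants", {
  sp <- daub3()
  g <- interval_grid(0, 1, 5)
  set.seed(3)
  v <- runif(33)
  f <- interval_interpolant(v, g, 4, sp)
  expect_lt(max(abs(f(g$nodes) - v)), 1e-10)
  fc <- interval_interpolant(rep(0.7, 33), g, 4, sp)
  xs <- seq(0, 1, by = 2^-9)               # dyadic probe grid
  expect_lt(max(abs(fc(xs) - 0.7)), 1e-8)
  expect_error(f(1.5), "domain")
})

test_that("more external points reduce the boundary error of a cubic", {
  sp <- daub3()
  g <- interval_grid(0, 1, 5)
  v <- g$nodes^3
  xs <- seq(0, 1, by = 2^-10)
  e4 <- max(abs(interval_interpolant(v, g, 4, sp)(xs) - xs^3))
  e1 <- max(abs(interval_interpolant(v, g, 1, sp)(xs) - xs^3))
  expect_lt(e4, e1)
  expect_lt(e4, 1e-10)                     # degree-3 exact with L = 4
})
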