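test_that("restriction predicate identifies shared dyadic nodes", {
  expect_equal(restriction_indicator(2, 1, 1, 2, 1, 1), 1L)
  expect_equal(restriction_indicator(2, 1, 1, 2, 1, 2), 0L)
  expect_equal(restriction_indicator(1, 1, 1, 2, 2, 2), 1L)   # (0.5, 0.5) twice
  expect_equal(restriction_indicator(1, 1, 0, 3, 4, 1), 0L)
})

test_that("decompose/reconstruct round-trips losslessly at threshold 0", {
  set.seed(21)
  for (spec in list(daub3(), shan())) {
    for (J in 3:5) {
      g <- multilevel_grid(2, J)
      U <- matrix(rnorm(g$N^2), g$N, g$N)
      co <- sg_decompose(U, g, spec, L = 2)
      R <- pmwave:::sg_eval_grid(co, pmwave:::grid_xs(g), pmwave:::grid_ys(g))
      expect_lt(max(abs(R - U)), 1e-10,
                label = paste(spec$family, "J =", J))
    }
  }
})

test_that("fields in the coarse space produce vanishing detail coefficients", {
  g <- multilevel_grid(2, 4)
  xs <- pmwave:::grid_xs(g); ys <- pmwave:::grid_ys(g)
  # bilinear field, linear-reproducing basis with support-covering extension
  B <- outer(ys, xs, function(y, x) 2 * x - 3 * y + 0.5)
  co <- sg_decompose(B, g, daub3(), L = 4)
  expect_lt(max(abs(unlist(co$detail))), 1e-9)
  # nesting: a field sampled from a coarser reconstruction decomposes to zero
  set.seed(5)
  U <- matrix(rnorm(g$N^2), g$N, g$N)
  c0 <- sg_decompose(U, g, daub3(), L = 2)
  c0$detail[["3"]]$a1[] <- 0; c0$detail[["3"]]$a2[] <- 0; c0$detail[["3"]]$a3[] <- 0
  V <- pmwave:::sg_eval_grid(c0, xs, ys)
  c1 <- sg_decompose(V, g, daub3(), L = 2)
  expect_lt(max(abs(unlist(c1$detail[["3"]]))), 1e-9)
})

test_that("a single fine-level surplus is recovered exactly", {
  g <- multilevel_grid(2, 3)
  U <- matrix(0, g$N, g$N)
  U[2, 3] <- 1                 # x index 2 (even), y index 1 (odd): family 2
  co <- sg_decompose(U, g, daub3(), L = 2)
  lev <- co$detail[["2"]]
  expect_equal(sum(lev$a2 == 1), 1L)
  expect_equal(sum(abs(lev$a2)), 1)
  expect_equal(max(abs(lev$a1)), 0)
  expect_equal(max(abs(lev$a3)), 0)
})

test_that("pointwise reconstruction interpolates and differentiates", {
  g <- multilevel_grid(2, 4)
  xs <- pmwave:::grid_xs(g); ys <- pmwave:::grid_ys(g)
  set.seed(8)
  U <- matrix(rnorm(g$N^2), g$N, g$N)
  co <- sg_decompose(U, g, daub3(), L = 2)
  expect_equal(sg_reconstruct(co, xs[5], ys[11]), U[11, 5], tolerance = 1e-12)
  # derivative of a reproduced linear field
  B <- outer(ys, xs, function(y, x) 0.4 * x + 0.2 * y + 0.1)
  cb <- sg_decompose(B, g, daub3(), L = 4)
  expect_equal(sg_reconstruct(cb, 0.43, 0.61, 1, 0), 0.4, tolerance = 1e-6)
  expect_equal(sg_reconstruct(cb, 0.43, 0.61, 0, 1), 0.2, tolerance = 1e-6)
  # second derivative vs dense central differences of the reconstruction
  S <- outer(ys, xs, function(y, x) sin(2 * pi * x) * cos(pi * y))
  cs <- sg_decompose(S, g, daub3(), L = 4)
  # dyadic FD step and node points: table lookups stay exact, so the second
  # difference is not polluted by off-dyadic interpolation noise
  h <- 2^-12
  for (pt in list(c(0.125, 0.25), c(0.3125, 0.6875))) {
    fd <- (sg_reconstruct(cs, pt[1] + h, pt[2]) -
             2 * sg_reconstruct(cs, pt[1], pt[2]) +
             sg_reconstruct(cs, pt[1] - h, pt[2])) / h^2
    an <- sg_reconstruct(cs, pt[1], pt[2], 2, 0)
    expect_lt(abs(fd - an) / abs(an), 1e-3)
  }
  expect_error(sg_reconstruct(co, 1.2, 0.5), "domain")
})

test_that("thresholding masks small surpluses and bounds the error", {
  g <- multilevel_grid(2, 5)
  xs <- pmwave:::grid_xs(g); ys <- pmwave:::grid_ys(g)
  S <- outer(ys, xs, function(y, x) 0.5 + 0.4 * sin(2 * pi * x) * sin(2 * pi * y))
  co <- sg_decompose(S, g, daub3(), L = 4)
  expect_equal(active_point_count(sg_compress(co, 0)), g$N^2)
  big <- sg_compress(co, 1e9)
  expect_equal(active_point_count(big), length(co$coarse))
  cc <- sg_compress(co, 1e-3)
  expect_lt(active_point_count(cc), g$N^2)
  R <- pmwave:::sg_eval_grid(cc, xs, ys)
  expect_lt(max(abs(R - S)), 1e-2)
  expect_error(sg_compress(co, -1), "threshold")
})

test_that("active point counts follow the dyadic grid arithmetic", {
  g <- multilevel_grid(0, 3)
  U <- matrix(stats::runif(81), 9, 9)
  co <- sg_decompose(U, g, daub3(), L = 1)
  expect_equal(active_point_count(co), 81L)           # (2^3+1)^2, threshold 0
  expect_equal(active_point_count(sg_compress(co, Inf)),
               (2^0 + 1)^2)
})

test_that("decompose cost counter scales like the fine-grid size", {
  set.seed(2)
  cnt <- vapply(5:7, function(J) {
    g <- multilevel_grid(2, J)
    U <- matrix(rnorm(g$N^2), g$N, g$N)
    sg_decompose(U, g, daub3(), L = 3)$counter
  }, numeric(1))
  ratios <- cnt[-1] / cnt[-3]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("explicitly assembled extension operators match the recursive path", {
  g <- multilevel_grid(1, 2)
  set.seed(14)
  U <- matrix(rnorm(g$N^2), g$N, g$N)
  for (spec in list(daub3(), shan())) {
    co <- sg_decompose(U, g, spec, L = 1)
    ops <- extension_operators(g, spec, L = 1)
    ap <- apply_extension_operators(ops, U)
    for (j in names(co$detail))
      for (fam in c("a1", "a2", "a3"))
        expect_lt(max(abs(ap[[j]][[fam]] - co$detail[[j]][[fam]])), 1e-10,
                  label = paste(spec$family, "level", j, fam))
  }
})
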